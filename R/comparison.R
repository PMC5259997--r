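# Statistical machinery of the buffer comparison: paired t tests and MSE on
# participant-matched BEM vectors, linear mixed association models of outcomes
# on standardized BEMs with a cluster random intercept, coefficient-difference
# z tests, and the significance-agreement tabulation.

#' Paired t test on participant-matched BEM vectors
#'
#' Standard paired t on the element-wise differences (df = n - 1, two-sided).
#' Degenerate inputs are flagged: identical vectors give t = 0, p = 1, status
#' `"identical"`; a constant non-zero difference gives p = 0, status
#' `"degenerate"`.
#'
#' @param x,y Equal-length numeric vectors paired by participant (n >= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`, `status`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = 0,
                status = "identical"))
  if (stats::sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                mean_diff = mean(d), status = "degenerate"))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), status = "ok")
}

#' Mean squared error between two BEM vectors
#' @param x,y Equal-length numeric vectors.
#' @return Mean of squared element-wise differences.
#' @export
mse <- function(x, y) {
  stopifnot(length(x) == length(y))
  mean((x - y)^2)
}

#' Simulate data with the association-model structure
#'
#' Outcome = `b * bem_z + covariate effect + cluster intercept + noise`, the
#' generating process the mixed model assumes; used for parameter-recovery
#' and calibration checks.
#'
#' @param n Participants.
#' @param n_clusters Clusters (random intercept sd `sd_cluster`).
#' @param b True coefficient per 1 sd of the BEM.
#' @param sd_cluster,sd_resid Random-intercept and residual sds.
#' @param seed Integer seed.
#' @return Data frame with `y`, `bem`, `age`, `cluster`.
#' @export
simulate_association_data <- function(n = 1000, n_clusters = 50, b = 0.3,
                                      sd_cluster = 0.5, sd_resid = 1,
                                      seed = 1) {
  set.seed(seed)
  cluster <- sample.int(n_clusters, n, replace = TRUE)
  bem <- stats::rnorm(n)
  age <- stats::rnorm(n, 42, 12)
  cl <- stats::rnorm(n_clusters, 0, sd_cluster)
  y <- b * bem + 0.02 * (age - 42) + cl[cluster] + stats::rnorm(n, 0, sd_resid)
  data.frame(y = y, bem = bem, age = age, cluster = factor(cluster))
}

#' Fit the association model of an outcome on a standardized BEM
#'
#' Additive mixed model `outcome ~ f(z(BEM)) + covariates + (1 | cluster)`,
#' fitted by maximum likelihood (lme4). With `term = "linear"` the reported
#' coefficient is the slope per 1 sd of the BEM with its standard error and a
#' Wald normal two-sided p value. With `term = "spline"` f is a fixed-df
#' natural-spline basis and the p value is an omnibus Wald chi-square on the
#' basis coefficients (coefficient/se report the leading basis column, for
#' shape diagnostics only).
#'
#' @param outcome Numeric outcome vector.
#' @param bem Numeric BEM vector (standardized internally to z-scores).
#' @param covariates Data frame of covariate columns (may be NULL).
#' @param cluster Cluster id vector (random intercept; >= 2 clusters).
#' @param term `"linear"` or `"spline"`.
#' @param spline_df Basis dimension when `term = "spline"`.
#' @param outcome_name,bem_name,method,trim,stratum Metadata carried into the
#'   result.
#' @return An `association_fit`: list with `b`, `se`, `p`, `n`, `term`,
#'   `converged`, and the metadata fields.
#' @export
fit_association <- function(outcome, bem, covariates = NULL, cluster,
                            term = c("linear", "spline"), spline_df = 4,
                            outcome_name = NA, bem_name = NA, method = NA,
                            trim = NA, stratum = "pooled") {
  term <- match.arg(term)
  stopifnot(length(outcome) == length(bem), length(outcome) == length(cluster))
  if (length(unique(cluster)) < 2) stop("need >= 2 clusters")
  s <- stats::sd(bem)
  bem_z <- if (is.finite(s) && s > 0) (bem - mean(bem)) / s else bem * 0
  dat <- data.frame(.y = outcome, .bem_z = bem_z, .cluster = factor(cluster))
  rhs <- if (term == "linear") ".bem_z" else
    sprintf("splines::ns(.bem_z, df = %d)", spline_df)
  if (!is.null(covariates) && ncol(covariates) > 0) {
    stopifnot(nrow(covariates) == length(outcome))
    dat <- cbind(dat, covariates)
    rhs <- paste(c(rhs, names(covariates)), collapse = " + ")
  }
  if (nrow(dat) <= ncol(dat) + 2) stop("too few observations for the model")
  fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .cluster)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = dat, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  converged <- length(fit@optinfo$conv$lme4) == 0 ||
    is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code >= 0
  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  idx <- grep("bem_z", names(fe))
  if (term == "linear") {
    b <- unname(fe[idx[1]])
    se <- sqrt(vc[idx[1], idx[1]])
    p <- 2 * stats::pnorm(-abs(b / se))
  } else {
    bvec <- fe[idx]
    W <- as.numeric(t(bvec) %*% solve(vc[idx, idx, drop = FALSE]) %*% bvec)
    p <- stats::pchisq(W, df = length(idx), lower.tail = FALSE)
    b <- unname(bvec[1])
    se <- sqrt(vc[idx[1], idx[1]])
  }
  structure(list(outcome_name = outcome_name, bem_name = bem_name,
                 method = method, trim = trim, stratum = stratum,
                 term = term, b = b, se = se, p = p, n = nrow(dat),
                 converged = converged),
            class = "association_fit")
}

#' @exportS3Method base::print
print.association_fit <- function(x, ...) {
  cat(sprintf("<association_fit> %s ~ %s [%s, trim %s, %s]: b=%.4f se=%.4f p=%.4g (n=%d%s)\n",
              x$outcome_name, x$bem_name, x$method, x$trim, x$stratum,
              x$b, x$se, x$p, x$n,
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' Compare two association coefficients by z test
#'
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided standard-normal p,
#' treating the two coefficients as independent (shared participants make the
#' test conservative; not corrected). The agreement status records which of
#' the two fits is individually significant at `alpha`.
#'
#' @param fit1,fit2 `association_fit` objects for the same outcome, BEM and
#'   stratum; both must have converged.
#' @param alpha Significance level (default 0.05).
#' @return A `coef_comparison`: list with `delta_b`, `z`, `p`, `status` in
#'   `both` / `neither` / `only_method_1` / `only_method_2`, and both fits.
#' @export
compare_coefficients <- function(fit1, fit2, alpha = 0.05) {
  if (!fit1$converged || !fit2$converged)
    stop("cannot compare non-converged fits")
  delta <- fit1$b - fit2$b
  z <- delta / sqrt(fit1$se^2 + fit2$se^2)
  s1 <- fit1$p < alpha
  s2 <- fit2$p < alpha
  status <- if (s1 && s2) "both" else if (!s1 && !s2) "neither" else
    if (s1) "only_method_1" else "only_method_2"
  structure(list(outcome_name = fit1$outcome_name, bem_name = fit1$bem_name,
                 stratum = fit1$stratum,
                 method_1 = fit1$method, method_2 = fit2$method,
                 b1 = fit1$b, b2 = fit2$b, p1 = fit1$p, p2 = fit2$p,
                 delta_b = delta, z = z, p = 2 * stats::pnorm(-abs(z)),
                 alpha = alpha, status = status),
            class = "coef_comparison")
}

#' Tabulate significance agreement across coefficient comparisons
#'
#' Per stratum and method pair: the number of model pairs where at least one
#' fit is significant, the number where exactly one is (the "differing"
#' count), split by which method, with percentages over all pairs.
#'
#' @param comparisons List of `coef_comparison` objects (or a data.frame from
#'   [comparisons_to_df()]).
#' @return Data frame with one row per (stratum, method pair).
#' @export
tabulate_agreement <- function(comparisons) {
  df <- if (is.data.frame(comparisons)) comparisons else
    comparisons_to_df(comparisons)
  key <- interaction(df$stratum, df$method_1, df$method_2, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    data.frame(stratum = g$stratum[1], method_1 = g$method_1[1],
               method_2 = g$method_2[1], n_pairs = nrow(g),
               n_any_significant = sum(g$status != "neither"),
               n_differing = sum(g$status %in% c("only_method_1",
                                                 "only_method_2")),
               n_only_method_1 = sum(g$status == "only_method_1"),
               n_only_method_2 = sum(g$status == "only_method_2"),
               pct_any_significant = 100 * mean(g$status != "neither"),
               pct_differing = 100 * mean(g$status %in% c("only_method_1",
                                                          "only_method_2")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flatten coefficient comparisons into a tidy data.frame
#' @param comparisons List of `coef_comparison` objects.
#' @return One row per comparison.
#' @export
comparisons_to_df <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(cc)
    data.frame(outcome_name = cc$outcome_name, bem_name = cc$bem_name,
               stratum = cc$stratum, method_1 = cc$method_1,
               method_2 = cc$method_2, b1 = cc$b1, b2 = cc$b2,
               p1 = cc$p1, p2 = cc$p2, delta_b = cc$delta_b, z = cc$z,
               p = cc$p, status = cc$status, stringsAsFactors = FALSE)))
}
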