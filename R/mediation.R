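#' Reciprocal of Trail Making Test A time
#'
#' 1/TMT-A aligns the score's direction with tests where higher is better.
#'
#' @param tmt_a completion time in seconds (> 0).
#' @return 1 / tmt_a.
#' @export
inverse_tmt <- function(tmt_a) {
  if (any(tmt_a <= 0)) stop("TMT-A times must be strictly positive")
  1 / tmt_a
}

std_design <- function(covariates, n) {
  X <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    if (nrow(X) != n) stop("covariate rows do not match data length")
  }
  X
}

## core two-regression estimator on standardized x, m, y
mediation_coefs <- function(x, m, y, C = NULL) {
  zx <- zscore_vec(x); zm <- zscore_vec(m); zy <- zscore_vec(y)
  X1 <- cbind(1, zx, C)
  X2 <- cbind(1, zx, zm, C)
  f1 <- stats::lm.fit(X1, zm)
  f2 <- stats::lm.fit(X2, zy)
  if (f1$rank < ncol(X1) || f2$rank < ncol(X2)) stop("rank-deficient mediation design")
  c(a = unname(f1$coefficients[2]),
    b = unname(f2$coefficients[3]),
    c_prime = unname(f2$coefficients[2]))
}

#' Fit the single-mediator path model
#'
#' Standardizes exposure, mediator and outcome, then fits the two
#' least-squares regressions `M ~ X + C` and `Y ~ X + M + C` (maximum
#' likelihood for this saturated recursive model). Covariates enter both
#' regressions. The indirect effect is `a * b`, the total effect
#' `c_prime + a * b`, which equals the X coefficient of `Y ~ X + C` exactly.
#'
#' @param x exposure (e.g. WMH volume).
#' @param m mediator (e.g. global GMV).
#' @param y outcome (e.g. DST or 1/TMT-A).
#' @param covariates optional data.frame of covariates.
#' @return a `cascn_mediation` list: a, b, c_prime, indirect, total,
#'   pct_direct, pct_indirect, n, covariates.
#' @export
fit_paths <- function(x, m, y, covariates = NULL) {
  keep <- stats::complete.cases(x, m, y,
                                if (is.null(covariates)) rep(TRUE, length(x)) else covariates)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  C <- std_design(if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE],
                  length(x))
  cf <- mediation_coefs(x, m, y, C)
  ind <- cf[["a"]] * cf[["b"]]
  tot <- cf[["c_prime"]] + ind
  pr <- effect_proportions(cf[["c_prime"]], ind)
  structure(list(a = cf[["a"]], b = cf[["b"]], c_prime = cf[["c_prime"]],
                 indirect = ind, total = tot,
                 pct_direct = pr[["pct_direct"]], pct_indirect = pr[["pct_indirect"]],
                 n = length(x),
                 covariates = if (is.null(covariates)) character(0) else names(covariates)),
            class = "cascn_mediation")
}

#' Bias-corrected bootstrap confidence intervals for mediation effects
#'
#' Case-resampling bootstrap of the indirect, direct and total effects with
#' bias-corrected percentile intervals. An effect is significant when its
#' interval excludes zero.
#'
#' @inheritParams fit_paths
#' @param n_boot number of resamples (>= 1000; the study used 5000).
#' @param seed RNG seed (fixed seed gives identical intervals).
#' @param conf confidence level.
#' @return the [fit_paths()] result augmented with `ci` (matrix with rows
#'   indirect/direct/total), `significant`, `n_boot`, `seed`.
#' @export
bootstrap_indirect <- function(x, m, y, covariates = NULL, n_boot = 5000,
                               seed = 1, conf = 0.95) {
  if (n_boot < 1000) stop("n_boot must be >= 1000")
  est <- fit_paths(x, m, y, covariates)
  keep <- stats::complete.cases(x, m, y,
                                if (is.null(covariates)) rep(TRUE, length(x)) else covariates)
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  C <- std_design(if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE],
                  length(x))
  n <- length(x)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("indirect", "direct", "total")))
  fail <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    cf <- tryCatch(mediation_coefs(x[idx], m[idx], y[idx],
                                   if (is.null(C)) NULL else C[idx, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(cf)) { fail <- fail + 1L; next }
    boot[b, ] <- c(cf[["a"]] * cf[["b"]], cf[["c_prime"]],
                   cf[["c_prime"]] + cf[["a"]] * cf[["b"]])
  }
  if (fail > 0.01 * n_boot) stop("bootstrap refit failure rate above 1%")
  point <- c(indirect = est$indirect, direct = est$c_prime, total = est$total)
  alpha <- 1 - conf
  ci <- t(vapply(colnames(boot), function(nm) {
    th <- boot[, nm]; th <- th[is.finite(th)]
    # bias-corrected percentile interval
    pr <- mean(th < point[[nm]])
    pr <- min(max(pr, 1 / (length(th) + 1)), length(th) / (length(th) + 1))
    z0 <- stats::qnorm(pr)
    lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha / 2))
    hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha / 2))
    stats::quantile(th, c(lo, hi), names = FALSE)
  }, numeric(2)))
  colnames(ci) <- c("lower", "upper")
  est$ci <- ci
  est$significant <- ci[, 1] > 0 | ci[, 2] < 0
  est$n_boot <- n_boot
  est$seed <- seed
  est
}

#' Direct and indirect effect proportions of the total effect
#'
#' @param c_prime direct effect.
#' @param indirect indirect (mediated) effect.
#' @return c(pct_direct, pct_indirect) in percent. When the effects have
#'   opposite signs the shares are not a meaningful decomposition; they are
#'   still returned relative to the total, with a warning.
#' @export
effect_proportions <- function(c_prime, indirect) {
  total <- c_prime + indirect
  if (total == 0) stop("total effect is zero; proportions undefined")
  if (sign(c_prime) * sign(indirect) < 0)
    warning("direct and indirect effects have opposite signs; proportions exceed [0, 100]")
  c(pct_direct = 100 * c_prime / total, pct_indirect = 100 * indirect / total)
}

#' Mediation of a cognitive outcome by global grey-matter volume
#'
#' Convenience wrapper: WMH volume as exposure, global GMV as mediator, DST
#' or 1/TMT-A as outcome, covariates age, sex, education and TIV, with
#' bias-corrected bootstrap inference.
#'
#' @param cohort phenotype table (patients are used).
#' @param outcome `"dst"` or `"inv_tmt"` (reciprocal TMT-A).
#' @param covariates cohort column names entering both regressions.
#' @param n_boot,seed,conf passed to [bootstrap_indirect()].
#' @return a `cascn_mediation` with bootstrap intervals.
#' @export
mediate_cognition <- function(cohort, outcome = c("dst", "inv_tmt"),
                              covariates = c("age", "sex", "education_years", "tiv"),
                              n_boot = 5000, seed = 1, conf = 0.95) {
  outcome <- match.arg(outcome)
  p <- cohort[cohort$group == "patient", , drop = FALSE]
  y <- if (outcome == "dst") p$dst else inverse_tmt(p$tmt_a)
  bootstrap_indirect(p$wmh_volume, p$global_gmv, y,
                     covariates = p[, covariates, drop = FALSE],
                     n_boot = n_boot, seed = seed, conf = conf)
}
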