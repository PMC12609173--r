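#' Fit WMH severity-stage thresholds
#'
#' Smooths global grey-matter volume against WMH volume with locally
#' weighted quadratic regression, then approximates the smoothed curve by a
#' continuous four-segment piecewise-linear function via exhaustive
#' breakpoint search on a candidate grid (least squares on a dense
#' evaluation grid). The three breakpoints are the stage thresholds.
#'
#' @param wmh patient WMH volumes (mL), length >= 20.
#' @param global_gmv per-patient global grey-matter volumes.
#' @param span loess smoothing fraction.
#' @param n_candidates size of the interior breakpoint candidate grid.
#' @param n_eval dense evaluation grid size.
#' @return increasing numeric vector of 3 thresholds (mL).
#' @export
fit_stage_thresholds <- function(wmh, global_gmv, span = 0.75,
                                 n_candidates = 28, n_eval = 200) {
  if (length(wmh) < 20) stop("need at least 20 patients")
  if (span <= 0) stop("span must be positive")
  if (stats::sd(global_gmv) == 0) stop("constant GMV: no stage structure to fit")
  o <- order(wmh)
  fit <- stats::loess(global_gmv[o] ~ wmh[o], span = span, degree = 2,
                      family = "gaussian")
  xg <- seq(min(wmh), max(wmh), length.out = n_eval)
  yg <- stats::predict(fit, newdata = xg)
  ok <- is.finite(yg); xg <- xg[ok]; yg <- yg[ok]

  cand <- seq(min(xg), max(xg), length.out = n_candidates + 2)[-c(1, n_candidates + 2)]
  best <- NULL; best_sse <- Inf
  combs <- utils::combn(cand, 3)
  for (c3 in seq_len(ncol(combs))) {
    t <- combs[, c3]
    X <- cbind(1, xg, pmax(xg - t[1], 0), pmax(xg - t[2], 0), pmax(xg - t[3], 0))
    cf <- qr.coef(qr(X), yg)
    cf[is.na(cf)] <- 0
    sse <- sum((yg - X %*% cf)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- t }
  }
  sort(best)
}

#' Assign severity stages from WMH thresholds
#'
#' Right-closed intervals: stage I = [0, t1], II = (t1, t2], III = (t2, t3],
#' IV = (t3, Inf).
#'
#' @param wmh WMH volumes (>= 0).
#' @param thresholds increasing vector of 3 thresholds.
#' @return factor with levels I-IV.
#' @export
assign_stages <- function(wmh, thresholds) {
  if (any(wmh < 0)) stop("negative WMH volume")
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("thresholds must be 3 strictly increasing values")
  lab <- c("I", "II", "III", "IV")
  idx <- 1L + (wmh > thresholds[1]) + (wmh > thresholds[2]) + (wmh > thresholds[3])
  factor(lab[idx], levels = lab)
}

#' Stage patients by Fazekas grade
#'
#' Identity mapping of grades 1-3 to stages I-III; grade 0 violates the
#' patient inclusion criterion and is an error.
#'
#' @param fazekas integer grades in 1-3.
#' @return factor with levels I-III.
#' @export
group_by_fazekas <- function(fazekas) {
  if (any(!fazekas %in% 1:3))
    stop("patient Fazekas grades must be in 1-3")
  factor(c("I", "II", "III")[fazekas], levels = c("I", "II", "III"))
}
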