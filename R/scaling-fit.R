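# Shared scaling-window selection: straight-line fits on log-log points,
# over every contiguous window spanning at least one order of magnitude in
# x; the window with maximal R^2 wins. Used by both the cumulative-mass
# (D_M) and box-counting (D_A) estimators.

#' Best power-law fit over decade-spanning windows
#'
#' Considers every contiguous window of the (x, y) points whose x-range
#' spans at least a factor `min_ratio` (default one order of magnitude),
#' fits `log10 y ~ log10 x` by ordinary least squares in each, and returns
#' the fit with the largest R^2.
#'
#' @param x,y Positive numeric vectors (same length, ordered in x).
#' @param min_ratio Minimum `max(x)/min(x)` of an admissible window.
#' @param min_points Minimum points per window.
#' @return A `scaling_fit`: list with `log_x`, `log_y`, `window` (index
#'   pair), `slope`, `slope_se`, `intercept`, `r_squared`, `n_points`.
#' @export
fit_scaling_window <- function(x, y, min_ratio = 10, min_points = 3) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  if (is.unsorted(x)) { o <- order(x); x <- x[o]; y <- y[o] }
  lx <- log10(x); ly <- log10(y)
  n <- length(lx)
  # slight tolerance so that an exactly-one-decade geometric series counts
  ratio_tol <- min_ratio * (1 - 1e-9)
  cx <- cumsum(c(0, lx)); cy <- cumsum(c(0, ly))
  cxx <- cumsum(c(0, lx^2)); cyy <- cumsum(c(0, ly^2))
  cxy <- cumsum(c(0, lx * ly))
  best <- NULL; best_r2 <- -Inf
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1 < min_points) next
      if (x[j] / x[i] < ratio_tol) next
      m <- j - i + 1
      Sx <- cx[j + 1] - cx[i]; Sy <- cy[j + 1] - cy[i]
      Sxx <- cxx[j + 1] - cxx[i]; Syy <- cyy[j + 1] - cyy[i]
      Sxy <- cxy[j + 1] - cxy[i]
      vx <- m * Sxx - Sx^2; vy <- m * Syy - Sy^2
      if (vx <= 0) next
      r2 <- if (vy <= 0) 1 else (m * Sxy - Sx * Sy)^2 / (vx * vy)
      if (r2 > best_r2) { best_r2 <- r2; best <- c(i, j) }
    }
  }
  if (is.null(best))
    stop(sprintf(paste0("no admissible scaling window: %d points over ",
                        "x in [%.3g, %.3g] cannot span a factor of %g"),
                 n, if (n) min(x) else NA, if (n) max(x) else NA, min_ratio))
  i <- best[1]; j <- best[2]
  fit <- stats::lm(ly[i:j] ~ lx[i:j])
  sm <- suppressWarnings(summary(fit))   # "essentially perfect fit" is fine
  structure(list(log_x = lx, log_y = ly, window = best,
                 slope = unname(stats::coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_points = j - i + 1),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  w <- x$window
  cat(sprintf(paste0("<scaling_fit> slope %.3f +/- %.3f (R^2 = %.4f), ",
                     "window x in [%.3g, %.3g] (%d points)\n"),
              x$slope, x$slope_se, x$r_squared,
              10^x$log_x[w[1]], 10^x$log_x[w[2]], x$n_points))
  invisible(x)
}
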