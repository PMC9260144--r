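# Connectivity-cost optimization: pools natural and distorted arbors,
# fits cubic polynomials C(D_A) and M(D_A) after max-normalization, forms
# the derivative ratio R_CM = C'(D_A) / M'(D_A) from the fitted
# polynomials (not from numerically differentiated data), and locates the
# interior peak D_O. Also the cross-arbor self-similarity exponent mu from
# the R_A ~ L_T^nu power law.

#' Fit normalized cubic C and M curves against D_A
#'
#' C and M are each normalized by their maximum within the observed (or
#' clipped) D_A range, then fitted with ordinary least-squares cubics.
#' Binned averages (default bin width 0.02 in D_A) are attached as a
#' diagnostic.
#'
#' @param points data.frame with columns `D_A`, `C`, `M` and optionally
#'   `category` (see [cm_point()]).
#' @param category Optional category filter (e.g. `"SH"`).
#' @param clip_range Optional length-2 D_A interval; points outside are
#'   dropped (outlier clipping).
#' @param bin_width Bin width for diagnostic binned averages.
#' @return An `rcm_curve`: list with `category`, `range` (D_A range used),
#'   `coef_C`, `coef_M` (cubic coefficients, ascending powers), `n`,
#'   `binned` (data.frame) and the normalization maxima `max_C`, `max_M`.
#' @export
fit_cm_curves <- function(points, category = NULL, clip_range = NULL,
                          bin_width = 0.02) {
  df <- as.data.frame(points)
  if (!is.null(category) && "category" %in% names(df))
    df <- df[df$category == category, , drop = FALSE]
  if (!is.null(clip_range))
    df <- df[df$D_A >= clip_range[1] & df$D_A <= clip_range[2], , drop = FALSE]
  if (nrow(df) < 20)
    stop("need at least 20 (D_A, C, M) points to fit cubic curves")
  rng <- range(df$D_A)
  if (diff(rng) < 0.1)
    stop(sprintf("D_A spread %.3f too narrow for a cubic fit", diff(rng)))
  max_C <- max(df$C); max_M <- max(df$M)
  Cn <- df$C / max_C; Mn <- df$M / max_M
  X <- stats::poly(df$D_A, 3, raw = TRUE)
  fc <- stats::lm(Cn ~ X)
  fm <- stats::lm(Mn ~ X)
  if (anyNA(stats::coef(fc)) || anyNA(stats::coef(fm)))
    stop("rank-deficient cubic fit: degenerate D_A spread")
  mids <- seq(floor(rng[1] / bin_width) * bin_width, rng[2] + bin_width,
              by = bin_width)
  bin <- findInterval(df$D_A, mids)
  binned <- data.frame(
    D_A = tapply(df$D_A, bin, mean),
    C = tapply(Cn, bin, mean),
    M = tapply(Mn, bin, mean),
    n = as.integer(table(bin)), row.names = NULL)
  structure(list(category = if (is.null(category)) NA_character_ else category,
                 range = rng,
                 coef_C = unname(stats::coef(fc)),
                 coef_M = unname(stats::coef(fm)),
                 n = nrow(df), binned = binned,
                 max_C = max_C, max_M = max_M),
            class = "rcm_curve")
}

# Evaluate a cubic (ascending coefficients) and its derivative.
poly3_eval <- function(coefs, x)
  coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
poly3_deriv <- function(coefs, x)
  coefs[2] + 2 * coefs[3] * x + 3 * coefs[4] * x^2

#' Locate the connectivity-cost optimization peak D_O
#'
#' Evaluates `R_CM(D_A) = C'(D_A) / M'(D_A)` from the fitted cubic
#' derivatives on a fine grid, masks grid points where `|M'|` vanishes,
#' and returns the argmax of the largest finite connected component that
#' contains an interior maximum. A monotone ratio (no interior maximum) is
#' flagged and the boundary argmax returned.
#'
#' @param curve An `rcm_curve` from [fit_cm_curves()].
#' @param step Grid step in D_A (default 0.001).
#' @return A list with `D_O`, `R_CM` (value at the peak), `grid`,
#'   `R_CM_grid`, and logical `interior` (FALSE when only a boundary
#'   maximum exists, with a warning).
#' @export
rcm_peak <- function(curve, step = 0.001) {
  g <- seq(curve$range[1], curve$range[2], by = step)
  dC <- poly3_deriv(curve$coef_C, g)
  dM <- poly3_deriv(curve$coef_M, g)
  eps <- 1e-6 * max(abs(dM))
  R <- ifelse(abs(dM) < eps, NA_real_, dC / dM)
  finite <- is.finite(R)
  if (!any(finite)) stop("R_CM undefined everywhere: M'(D_A) vanishes")
  comp <- cumsum(!finite)                  # component id for finite runs
  comp[!finite] <- NA
  best <- NULL
  for (id in unique(stats::na.omit(comp))) {
    idx <- which(!is.na(comp) & comp == id)
    if (length(idx) < 3) next
    r <- R[idx]
    m <- length(r)
    k <- 2:(m - 1)
    # local max: >= both neighbors and strictly above at least one
    locmax <- k[r[k] >= r[k - 1] & r[k] >= r[k + 1] &
                  (r[k] > r[k - 1] | r[k] > r[k + 1])]
    has_int <- length(locmax) > 0
    if (has_int && (is.null(best) || length(idx) > length(best$idx)))
      best <- list(idx = idx, interior = TRUE)
  }
  if (is.null(best)) {
    warning("no interior maximum in R_CM; reporting boundary argmax")
    idx <- which(finite)
    i <- idx[which.max(R[idx])]
    return(list(D_O = g[i], R_CM = R[i], grid = g, R_CM_grid = R,
                interior = FALSE))
  }
  i <- best$idx[which.max(R[best$idx])]
  list(D_O = g[i], R_CM = R[i], grid = g, R_CM_grid = R, interior = TRUE)
}

#' Cross-arbor self-similarity exponent mu
#'
#' Fits the power law `R_A ~ L_T^nu` across arbors by ordinary least
#' squares on the log10-log10 scale and reports `mu = 1/nu - 1` with a
#' first-order (delta-method) standard error.
#'
#' @param summaries data.frame with columns `L_T` and `R_A` (one row per
#'   arbor), e.g. rbind-ed [arbor_summary()] rows.
#' @return A list with `nu`, `nu_se`, `mu`, `mu_se`, `r_squared` and `n`.
#' @export
self_similarity <- function(summaries) {
  df <- as.data.frame(summaries)
  df <- df[is.finite(df$L_T) & is.finite(df$R_A) & df$L_T > 0 & df$R_A > 0, ]
  if (nrow(df) < 10) stop("need at least 10 arbors with positive L_T and R_A")
  fit <- stats::lm(log10(R_A) ~ log10(L_T), data = df)
  nu <- unname(stats::coef(fit)[2])
  if (nu <= 0) stop("non-positive scaling exponent nu: mu undefined")
  sm <- suppressWarnings(summary(fit))   # exact power laws fit perfectly
  nu_se <- sm$coefficients[2, 2]
  list(nu = nu, nu_se = nu_se,
       mu = 1 / nu - 1, mu_se = nu_se / nu^2,
       r_squared = sm$r.squared, n = nrow(df))
}
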