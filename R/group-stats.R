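# Group-level statistics: one-way ANOVA with Tukey-Kramer post-hoc
# contrasts (studentized range, honoring unequal group sizes) across the
# six lesion x housing x training groups, and per-radius Welch contrasts
# of Sholl curves between the SH and ATN categories.

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' Classic fixed-effects one-way ANOVA on an arbor-level metric followed
#' by Tukey-Kramer adjusted pairwise comparisons (via [stats::TukeyHSD()],
#' which implements the Kramer correction for unequal n).
#'
#' @param table data.frame with one row per arbor.
#' @param metric Column name of the metric to test.
#' @param group Column name of the grouping factor (default `"group"`).
#' @return A list with `F`, `df`, `p` (omnibus), and `pairwise`
#'   (data.frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`, `stars`).
#' @export
anova_tukey <- function(table, metric, group = "group") {
  df <- data.frame(y = table[[metric]], g = factor(table[[group]]))
  df <- df[is.finite(df$y), ]
  sizes <- table(df$g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         stars = p_stars(tk[, "p adj"]), row.names = NULL)
  list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
       p = an[1, "Pr(>F)"], pairwise = pairwise)
}

#' Per-radius contrast of Sholl curves between two categories
#'
#' Welch two-sample t-tests of per-arbor mean intersection counts at each
#' radius, plus the maximal contiguous radius range significant at the
#' threshold with a consistent sign. No multiplicity correction is applied
#' across radii (exploratory, per-radius threshold).
#'
#' @param ni_by_category Named list of two matrices (arbors x radii) of
#'   per-arbor mean N_I curves on a common radius grid.
#' @param radii The common radius grid (um).
#' @param threshold Per-radius significance threshold (default 0.01).
#' @return A list with `per_radius` (data.frame: `r`, `mean_1`, `mean_2`,
#'   `p`, `higher`), `significant_range` (range of the longest significant
#'   run, or NULL), and `direction` (which category is higher there).
#' @export
sholl_category_contrast <- function(ni_by_category, radii, threshold = 0.01) {
  if (length(ni_by_category) != 2) stop("exactly two categories required")
  A <- as.matrix(ni_by_category[[1]]); B <- as.matrix(ni_by_category[[2]])
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("each category needs at least 2 arbors")
  if (ncol(A) != length(radii) || ncol(B) != length(radii))
    stop("curve matrices do not match the radius grid")
  nm <- names(ni_by_category)
  if (is.null(nm)) nm <- c("cat1", "cat2")
  res <- lapply(seq_along(radii), function(j) {
    a <- A[, j]; b <- B[, j]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else stats::t.test(a, b)$p.value
    data.frame(r = radii[j], mean_1 = mean(a), mean_2 = mean(b), p = p,
               higher = nm[if (mean(a) >= mean(b)) 1 else 2])
  })
  per_radius <- do.call(rbind, res)
  sig <- per_radius$p <= threshold
  # longest run of significant radii with a consistent direction
  runs <- rle(ifelse(sig, per_radius$higher, NA_character_))
  if (all(is.na(runs$values))) {
    return(list(per_radius = per_radius, significant_range = NULL,
                direction = NULL))
  }
  lens <- ifelse(is.na(runs$values), 0L, runs$lengths)
  k <- which.max(lens)
  last <- cumsum(runs$lengths)[k]
  first <- last - runs$lengths[k] + 1
  list(per_radius = per_radius,
       significant_range = range(per_radius$r[first:last]),
       direction = runs$values[k])
}
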