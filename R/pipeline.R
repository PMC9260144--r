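# End-to-end orchestration: cohort (or supplied arbors) -> morphometry ->
# Sholl/mass profiles -> D_M/D_A -> distortion sweep -> C/M points ->
# R_CM peaks per category -> self-similarity -> group ANOVA. Stage
# outputs are plain data.frames/lists so each stage is independently
# testable; optional CSV/JSON export.

#' Run the full connectivity-cost optimization pipeline
#'
#' Orchestrates every analysis stage on a synthetic cohort (or a supplied
#' list of arbors with a matching group table). Problem sizes for the
#' expensive stages (Sholl profiling, connectivity raster) are
#' configurable; defaults are sized for cohort-scale runs on one CPU.
#'
#' @param cohort A list with `arbors` and `table` as returned by
#'   [make_cohort()]; by default a cohort is generated from `config`.
#' @param config A [cohort_config()] used when `cohort` is `NULL`.
#' @param alpha_grid Angle-scaling sweep grid (identity excluded).
#' @param n_origins Sholl origins per arbor.
#' @param sholl_arbors Number of arbors (per category) profiled for the
#'   Sholl stage; `Inf` profiles all.
#' @param sholl_r_max Largest profile radius (um); default twice the
#'   largest arbor radius. Capping it trades the far tail of the curves
#'   (where N_I has already fallen) for runtime.
#' @param cm_per_category Natural arbors per category entering the
#'   connectivity-cost stage (each contributes its full distortion
#'   sweep).
#' @param n_views,pixel,dilation Connectivity raster settings (see
#'   [connectivity()]); cohort-scale defaults trade ~0.5% accuracy in C
#'   for an order of magnitude in runtime.
#' @param clip_range Optional D_A clipping interval for the cubic fits.
#' @param seed Seed for stage-level sampling (origin draws, subsets).
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as CSV/JSON.
#' @return A list with `summaries`, `sholl` (per-radius category means,
#'   contrast), `dimensions` (per-arbor D_A/D_M table), `sweep_manifest`,
#'   `cm_points`, `rcm` (per-category curves/peaks), `self_similarity`,
#'   `anova`, and `settings`.
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         alpha_grid = default_alpha_grid(),
                         n_origins = 25, sholl_arbors = Inf,
                         sholl_r_max = NULL,
                         cm_per_category = 20,
                         n_views = 16, pixel = 1, dilation = 2,
                         clip_range = NULL, seed = 1, out_dir = NULL) {
  if (is.null(cohort)) cohort <- make_cohort(config)
  arbors <- cohort$arbors
  tab <- cohort$table
  n <- length(arbors)

  # --- morphometry ------------------------------------------------------
  summaries <- do.call(rbind, lapply(arbors, arbor_summary))
  summaries <- cbind(summaries, tab[, c("group", "category")])

  # --- per-arbor dimensions (D_A from the cohort table when present) ----
  D_A <- if ("D_A" %in% names(tab) && all(is.finite(tab$D_A))) tab$D_A
         else vapply(arbors, function(a)
           tryCatch(fit_box_dimension(a)$D_A, error = function(e) NA_real_),
           numeric(1))

  # --- Sholl / cumulative mass ------------------------------------------
  prof_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), tab$category), function(ix)
      if (length(ix) > sholl_arbors) sort(sample(ix, sholl_arbors)) else ix))
  })
  if (is.null(sholl_r_max)) sholl_r_max <- 2 * max(summaries$R_A)
  radii <- seq(2, sholl_r_max, by = 2)
  ni_curves <- matrix(NA_real_, length(prof_idx), length(radii))
  D_M <- rep(NA_real_, n)
  for (k in seq_along(prof_idx)) {
    i <- prof_idx[k]
    pr <- sholl_profile(arbors[[i]], n_origins = n_origins,
                        seed = seed + i, radii = radii)
    ni_curves[k, ] <- pr$mean_NI
    D_M[i] <- tryCatch(fit_mass_dimension(pr, extent = summaries$extent[i]),
                       error = function(e) NULL)$slope %||% NA_real_
  }
  cat_of <- tab$category[prof_idx]
  ni_by_cat <- lapply(split(seq_along(prof_idx), cat_of),
                      function(ix) ni_curves[ix, , drop = FALSE])
  contrast <- if (length(ni_by_cat) == 2 && all(vapply(ni_by_cat, nrow,
                                                       integer(1)) >= 2))
    sholl_category_contrast(ni_by_cat, radii) else NULL

  dimensions <- data.frame(label = tab$label, group = tab$group,
                           category = tab$category, D_A = D_A, D_M = D_M)

  # --- distortion sweep bookkeeping -------------------------------------
  sweep <- distortion_sweep(arbors, alpha_grid)

  # --- connectivity-cost points -----------------------------------------
  cm_idx <- with_seed(seed + 1, {
    unlist(lapply(split(seq_len(n), tab$category), function(ix)
      if (length(ix) > cm_per_category) sort(sample(ix, cm_per_category))
      else ix))
  })
  cm_rows <- list()
  for (i in cm_idx) {
    for (al in c(1, alpha_grid)) {
      a <- if (al == 1) arbors[[i]] else distort_arbor(arbors[[i]], al)
      row <- tryCatch(
        cm_point(a, alpha = al, group = tab$group[i],
                 category = tab$category[i], n_views = n_views,
                 pixel = pixel, dilation = dilation),
        error = function(e) NULL)
      if (!is.null(row)) cm_rows[[length(cm_rows) + 1]] <- row
    }
  }
  cm_points <- do.call(rbind, cm_rows)

  # --- R_CM per category -------------------------------------------------
  rcm <- lapply(split(cm_points, cm_points$category), function(df) {
    curve <- tryCatch(fit_cm_curves(df, clip_range = clip_range),
                      error = function(e) NULL)
    if (is.null(curve)) return(NULL)
    peak <- withCallingHandlers(rcm_peak(curve),
                                warning = function(w) invokeRestart("muffleWarning"))
    list(curve = curve, peak = peak)
  })

  # --- cohort-level statistics ------------------------------------------
  ss <- tryCatch(self_similarity(summaries), error = function(e)
    list(nu = NA_real_, mu = NA_real_, mu_se = NA_real_))
  stats_tab <- cbind(dimensions, R_A = summaries$R_A)
  anova_DA <- anova_tukey(stats_tab, "D_A")

  out <- list(summaries = summaries,
              sholl = list(radii = radii, by_category = ni_by_cat,
                           contrast = contrast, profiled = tab$label[prof_idx],
                           curves = ni_curves,
                           groups = tab$group[prof_idx]),
              dimensions = dimensions,
              sweep_manifest = sweep$manifest,
              cm_points = cm_points,
              rcm = rcm,
              self_similarity = ss,
              anova = anova_DA,
              settings = list(alpha_grid = alpha_grid, n_origins = n_origins,
                              n_views = n_views, pixel = pixel,
                              dilation = dilation, clip_range = clip_range,
                              seed = seed))
  if (!is.null(out_dir)) export_pipeline(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write the main stage outputs as CSV (plus a JSON summary if jsonlite is
# available).
export_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(res$dimensions, file.path(out_dir, "dimensions.csv"),
                   row.names = FALSE)
  utils::write.csv(res$sweep_manifest, file.path(out_dir, "sweep_manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cm_points, file.path(out_dir, "cm_points.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    top <- list(
      n_arbors = nrow(res$summaries),
      n_distorted = nrow(res$sweep_manifest),
      mean_R_A = mean(res$summaries$R_A),
      mean_D_A = mean(res$dimensions$D_A, na.rm = TRUE),
      mu = res$self_similarity$mu,
      D_O = lapply(res$rcm, function(x) if (is.null(x)) NULL else x$peak$D_O),
      anova_p_D_A = res$anova$p)
    jsonlite::write_json(top, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
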