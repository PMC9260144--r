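# One-way ANOVA with Tukey-Kramer post-hoc contrasts and the per-radius
# category contrast of Sholl curves.

fake_table <- function(means, n = 10, sd = 1, seed = 1) {
  withr_seed(seed)
  data.frame(group = rep(names(means), each = n),
             y = rnorm(n * length(means), rep(unlist(means), each = n), sd))
}

test_that("ANOVA F matches a brute-force sums-of-squares computation", {
  for (seed in 1:5) {
    tab <- fake_table(list(a = 0, b = 0.5, c = -0.3), n = 8, seed = seed)
    res <- anova_tukey(tab, "y")
    # brute force
    g <- split(tab$y, tab$group)
    grand <- mean(tab$y)
    ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                      numeric(1)))
    ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
    Fb <- (ssb / (length(g) - 1)) / (ssw / (nrow(tab) - length(g)))
    expect_rel_equal(res$F, Fb, 1e-9)
  }
})

test_that("duplicated groups give a null result", {
  withr_seed(3)
  v <- rnorm(20)
  tab <- data.frame(group = rep(c("g1", "g2"), each = 20), y = c(v, v))
  res <- anova_tukey(tab, "y")
  expect_lt(res$F, 1e-20)
  expect_gt(res$p, 0.999)
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise p-values", {
  for (seed in 1:4) {
    tab <- fake_table(list(a = 0, b = 0.4, c = 0.8, d = -0.2), n = 7,
                      seed = seed)
    res <- anova_tukey(tab, "y")
    # unadjusted pairwise p from the pooled-MSE t statistic
    fit <- aov(y ~ factor(group), tab)
    mse <- summary(fit)[[1]][2, "Mean Sq"]
    dfw <- summary(fit)[[1]][2, "Df"]
    g <- split(tab$y, tab$group)
    combs <- combn(names(g), 2)
    for (k in seq_len(ncol(combs))) {
      v1 <- g[[combs[1, k]]]; v2 <- g[[combs[2, k]]]
      se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
      p_un <- 2 * pt(-abs(mean(v1) - mean(v2)) / se, dfw)
      contrast <- paste(combs[2, k], combs[1, k], sep = "-")
      p_tk <- res$pairwise$p_adj[res$pairwise$contrast %in%
        c(contrast, paste(combs[1, k], combs[2, k], sep = "-"))]
      expect_gte(p_tk + 1e-12, p_un)
    }
  }
})

test_that("a strong two-group shift is detected at the 0.1% level", {
  withr_seed(99)
  hits <- 0
  for (i in 1:50) {
    tab <- data.frame(group = rep(c("g1", "g2"), each = 40),
                      y = c(rnorm(40), rnorm(40, 1.5)))
    res <- anova_tukey(tab, "y")
    hits <- hits + (res$pairwise$p_adj[1] <= 0.001)
  }
  expect_gte(hits / 50, 0.95)
})

test_that("undersized groups are named in errors", {
  tab <- data.frame(group = c("a", "a", "b"), y = c(1, 2, 3))
  expect_error(anova_tukey(tab, "y"), "b")
})

test_that("category contrast finds a planted peripheral effect", {
  withr_seed(21)
  radii <- seq(10, 100, by = 10)
  base <- matrix(rnorm(30 * 10, 10, 1), 30, 10)
  shifted <- matrix(rnorm(30 * 10, 10, 1), 30, 10)
  shifted[, radii >= 70] <- shifted[, radii >= 70] + 3   # peripheral only
  res <- sholl_category_contrast(list(SH = shifted, ATN = base), radii,
                                 threshold = 0.01)
  expect_equal(res$direction, "SH")
  # the significant run must sit in the periphery, not at small radii
  expect_gte(res$significant_range[1], 50)
  expect_equal(res$significant_range[2], 100)
})

test_that("identical cohorts rarely show significant radii", {
  withr_seed(5)
  n_sig <- vapply(1:20, function(i) {
    a <- matrix(rnorm(20 * 8, 5, 1), 20, 8)
    b <- matrix(rnorm(20 * 8, 5, 1), 20, 8)
    res <- sholl_category_contrast(list(x = a, y = b), 1:8, threshold = 0.01)
    sum(res$per_radius$p <= 0.01)
  }, numeric(1))
  # 160 null tests at the 1% level: expect only a small handful of hits
  expect_lte(sum(n_sig), 8)
  one <- matrix(rnorm(8), 1, 8)
  expect_error(sholl_category_contrast(list(x = one, y = one), 1:8),
               "at least 2")
})
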