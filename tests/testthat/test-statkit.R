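# statkit: ANOVA + Tukey, Spearman categories, t-tests, pipeline runner.

test_that("anova_tukey matches brute-force sums of squares and base R on textbook data", {
  g <- list(a = c(6.9, 5.4, 5.8, 4.6, 4.0),
            b = c(8.3, 6.8, 7.8, 9.2, 6.5),
            c = c(8.0, 10.5, 8.1, 6.9, 9.3))
  res <- anova_tukey(g)
  # brute-force oracle
  all_v <- unlist(g)
  grand <- mean(all_v)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)
  # base-R aov/TukeyHSD as an independent oracle
  df <- data.frame(v = all_v, grp = factor(rep(names(g), each = 5)))
  tk <- TukeyHSD(aov(v ~ grp, data = df))$grp
  expect_equal(sort(res$tukey$p_adj), sort(unname(tk[, "p adj"])),
               tolerance = 1e-8)
  # identical groups: F ~ 0, Tukey p ~ 1
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1))
  r0 <- anova_tukey(same)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  expect_true(all(r0$tukey$p_adj == 1))
  # two groups: F equals t^2 (equal-variance)
  set.seed(8)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  r2 <- anova_tukey(list(x = x, y = y))
  tt <- two_sample_t(x, y)
  expect_equal(r2$F, tt$t^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p, tolerance = 1e-10)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "single-observation")
  expect_error(anova_tukey(list(a = c(1, 2))), ">= 2 groups")
})

test_that("spearman_with_category: rho values, band mapping, errors", {
  mono <- spearman_with_category(1:10, (1:10)^3)
  expect_equal(mono$rho, 1)
  expect_identical(mono$category, "very strong")
  expect_match(mono$category_note, "extends")
  # constructed permutations with exact rho 0.5 and 0.4 (no ties)
  r05 <- spearman_with_category(1:5, c(1, 3, 5, 2, 4))
  expect_equal(r05$rho, 0.5, tolerance = 1e-12)
  expect_identical(r05$category, "moderate")
  r04 <- spearman_with_category(1:4, c(1, 3, 4, 2))
  expect_equal(r04$rho, 0.4, tolerance = 1e-12)
  expect_identical(r04$category, "moderate")    # inclusive lower bound
  # remaining bands
  set.seed(3)
  x <- rnorm(50)
  expect_identical(spearman_with_category(x, rnorm(50))$category
                   %in% c("little", "weak"), TRUE)
  expect_error(spearman_with_category(rep(1, 6), 1:6), "constant")
  expect_error(spearman_with_category(1:3, 3:1), "n >= 4")
  # KS normality pre-check reported with the estimated-parameter caveat
  expect_match(mono$ks$caveat, "Lilliefors")
  expect_true(is.finite(mono$ks$p_x))
})

test_that("paired and two-sample t-tests: trivial cases, closed-form oracle, power", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0)
  expect_equal(paired_t(x, x)$t, 0)
  expect_equal(paired_t(x, x)$p, 1)
  y <- c(1.0, 2.9, 2.8, 5.1, 4.3)
  got <- paired_t(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)
  expect_error(paired_t(1:3, 1:4), "equal-length")
  # power: delta = 1 SD at n = 50 rejects in >= 80% of 200 simulations
  set.seed(12)
  rej <- mean(replicate(200, two_sample_t(rnorm(50), rnorm(50, 1))$p < 0.05))
  expect_gte(rej, 0.8)
})

test_that("two-sample type-I error stays near nominal over 1000 null simulations", {
  set.seed(99)
  p <- replicate(1000, two_sample_t(rnorm(20), rnorm(20))$p)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("run_pipeline produces the full report schema and is deterministic", {
  cfg <- list(scene = tiny_nodule_config(seed = 21))
  out_dir <- file.path(tempdir(), "n4d_report")
  rep1 <- suppressWarnings(run_pipeline(cfg, out_dir = out_dir))
  expect_true(all(c("volume_um3", "area_um2", "delta_volume_um3",
                    "mip_ratio", "mean_delaunay_area_um2")
                  %in% names(rep1$timepoints)))
  expect_s3_class(rep1$cells, "data.frame")
  expect_equal(nrow(rep1$subroi[[1]]$table), 16L)
  expect_true(file.exists(file.path(out_dir, "timepoints.csv")))
  expect_true(file.exists(file.path(out_dir, "cells.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.txt")))
  rep2 <- suppressWarnings(run_pipeline(cfg))
  expect_equal(rep1$timepoints, rep2$timepoints)
  expect_equal(rep1$cells, rep2$cells)
  # bleb scenario report
  repb <- run_pipeline(list(scene = small_bleb_config(seed = 6, rate = 0.2,
                                                      T = 16L)))
  expect_true(all(c("mean_duration_s", "mean_max_area_um2")
                  %in% names(repb$bleb_summary)))
  # supplied stack without the SHG channel aborts at the segment stage
  arr <- array(runif(16 * 16 * 4 * 1 * 2), dim = c(16, 16, 4, 1, 2))
  st <- image_stack(arr, channels = "EGFP")
  expect_error(run_pipeline(list(scenario = "nodule", stack = st)),
               "segment.*SHG|SHG.*segment")
})
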