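# Statistical toolbox used by the readouts (one-way ANOVA + Tukey HSD,
# Spearman with strength categories, paired / two-sample t-tests) and the
# end-to-end pipeline runner.

#' One-way ANOVA with Tukey HSD post hoc
#'
#' F and p from the standard between/within sums of squares; all pairwise
#' comparisons via the studentized range distribution (Tukey-Kramer for
#' unbalanced groups). Groups of identical constants are handled (F = 0,
#' p = 1 when there is no between-group signal).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df`, and `tukey` (data.frame of pairwise
#'   mean differences and adjusted p-values).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("anova_tukey requires >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L))
    stop("every group needs n >= 2 (single-observation group supplied)")
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  msw <- ssw / df2
  if (ssb <= .Machine$double.eps * max(1, abs(grand))^2 * N) {
    f_stat <- 0; p <- 1
  } else if (msw == 0) {
    f_stat <- Inf; p <- 0
  } else {
    f_stat <- (ssb / df1) / msw
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(k, 2L)
  tukey <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    diff <- means[i2] - means[i1]
    se <- sqrt(msw / 2 * (1 / n[i1] + 1 / n[i2]))
    if (se == 0) {
      p_adj <- if (abs(diff) < 1e-300) 1 else 0
    } else {
      q <- abs(diff) / se
      p_adj <- stats::ptukey(q, k, df2, lower.tail = FALSE)
    }
    data.frame(comparison = paste(names(groups)[i2], "-", names(groups)[i1]),
               diff = unname(diff), p_adj = p_adj)
  }))
  rownames(tukey) <- NULL
  list(F = f_stat, p = p, df = c(df1, df2), tukey = tukey)
}

#' Spearman rank correlation with a strength category
#'
#' Average-rank Spearman rho and its p-value, labeled with the standard
#' strength bands on |rho| (inclusive lower bounds): \[0, 0.2) little,
#' \[0.2, 0.4) weak, \[0.4, 0.6) moderate, \[0.6, 0.8) strong; |rho| >= 0.8
#' is labeled "very strong" as an explicit extension of the published
#' band table and flagged as such. A Kolmogorov-Smirnov normality
#' pre-check on each input (with estimated parameters, hence a
#' Lilliefors-type bias, flagged in the output) is reported alongside.
#'
#' @param x,y numeric vectors, n >= 4; ties allowed.
#' @return list with `rho`, `p`, `category`, `category_note`, `ks`
#'   (per-input KS p-values plus bias caveat).
#' @export
spearman_with_category <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("Spearman correlation requires n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman rho is undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  band <- function(r) {
    a <- abs(r)
    if (a < 0.2) "little" else if (a < 0.4) "weak"
    else if (a < 0.6) "moderate" else if (a < 0.8) "strong" else "very strong"
  }
  ks_p <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    suppressWarnings(stats::ks.test((v - mean(v)) / stats::sd(v), "pnorm")$p.value)
  }
  cat_lab <- band(rho)
  list(rho = rho, p = ct$p.value, category = cat_lab,
       category_note = if (abs(rho) >= 0.8)
         "'very strong' extends the published band table (which stops at 0.8)"
       else NA_character_,
       ks = list(p_x = ks_p(x), p_y = ks_p(y),
                 caveat = "KS with estimated parameters (Lilliefors-type bias)"))
}

t_result <- function(t, df, p) list(t = t, df = df, p = p,
                                    significant = is.finite(p) && p < 0.05)

#' Paired t-test
#'
#' @param x,y paired numeric vectors of equal length n >= 2. Identical
#'   pairs give t = 0, p = 1.
#' @return list with `t`, `df`, `p`, `significant` (alpha = 0.05).
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired t-test requires equal-length vectors")
  n <- length(x)
  if (n < 2L) stop("paired t-test requires n >= 2")
  d <- x - y
  if (stats::sd(d) == 0)
    return(t_result(0, n - 1L, if (mean(d) == 0) 1 else 0))
  tt <- stats::t.test(x, y, paired = TRUE)
  t_result(unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' Two-sample t-test (equal variance)
#'
#' Classic pooled-variance two-sample test for comparisons without
#' correspondence (so that with two groups, F = t^2 matches the one-way
#' ANOVA).
#'
#' @param x,y numeric vectors, each n >= 2.
#' @param var_equal pool variances (default TRUE).
#' @return list with `t`, `df`, `p`, `significant` (alpha = 0.05).
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("two-sample t-test requires n >= 2 per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(t_result(0, length(x) + length(y) - 2L,
                    if (mean(x) == mean(y)) 1 else 0))
  tt <- stats::t.test(x, y, var.equal = var_equal)
  t_result(unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

# ---- pipeline orchestration ------------------------------------------------

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic-scenario pipeline
#'
#' Generates the configured scenario, then executes preprocess, segment,
#' morpho, spatial and (for bleb scenarios) bleb detection in order,
#' returning every result table plus a plain-text summary. With `out_dir`
#' set, all tables are written as CSV and the summary as text. Treatment
#' plots follow the mean +/- SE convention; everything else is
#' mean +/- SD.
#'
#' @param config list with `scene` (a [scene_config()]), optional
#'   `sphericity_threshold` (default 0.7), `shrink` (default 0.5), `grid`
#'   (default `c(4, 4)`).
#' @param out_dir optional output directory for CSV reports.
#' @return a report list; see details in the package vignette.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  scene <- config$scene %||% scene_config("nodule")
  thr_psi <- config$sphericity_threshold %||% 0.7
  shrink <- config$shrink %||% 0.5
  grid <- config$grid %||% c(4L, 4L)
  scenario <- config$scenario %||% scene$scenario
  if (!is.null(config$stack)) {
    # real-stack path: analyze a supplied ImageStack instead of generating
    stack <- config$stack
    truth <- NULL
  } else {
    gen <- pipeline_stage("synthgen", switch(scenario,
      nodule = generate_nodule_timecourse(scene),
      bio = generate_bio_experiment(scene),
      bleb = ,
      bleb4d = generate_bleb_movie(scene)))
    stack <- gen$stack
    truth <- gen$truth
  }
  report <- list(config = config, scenario = scenario, truth = truth)
  if (scenario %in% c("nodule", "bio")) {
    nT <- stack_dim(stack)[["T"]]
    surfaces <- pipeline_stage("segment",
      lapply(seq_len(nT), function(t) segment_shg(stack, "SHG", t)))
    records <- pipeline_stage("morpho", {
      recs <- lapply(seq_len(nT), function(t) {
        cells <- segment_cells(stack, "EGFP", t)
        r <- measure_cells(cells, t = t)
        r <- classify_compartment(r, surfaces[[t]], shrink = shrink)
        classify_high_sphericity(r, thr_psi)
      })
      do.call(rbind, recs)
    })
    spatial <- pipeline_stage("spatial", {
      crowd <- vapply(seq_len(nT), function(t) {
        inon <- records[records$t == t & records$compartment == "IN/ON" &
                          !records$clipped, , drop = FALSE]
        if (nrow(inon) >= 3L) delaunay_mean_area(inon)$mean_area else NA_real_
      }, numeric(1))
      subroi <- lapply(seq_len(nT - 1L), function(t)
        subroi_correlation(records[records$t == t, , drop = FALSE],
                           surfaces[[t]], surfaces[[t + 1L]], grid = grid))
      mip <- mip_ratio_series(stack)
      list(crowding = crowd, subroi = subroi, mip = mip)
    })
    tp <- surface_series_summary(surfaces)
    tp$mip_ratio <- spatial$mip$ratio
    tp$mip_change <- spatial$mip$change
    tp$mean_delaunay_area_um2 <- spatial$crowding
    report$timepoints <- tp
    report$cells <- records
    report$population <- population_summary(records)
    report$subroi <- spatial$subroi
    report$surfaces <- surfaces
  } else {
    blebs <- pipeline_stage("blebmot", detect_blebs_2d(stack))
    report$blebs <- blebs$tracks
    report$bleb_summary <- data.frame(
      n_tracks = nrow(blebs$tracks),
      mean_duration_s = mean(blebs$tracks$duration_s),
      sd_duration_s = stats::sd(blebs$tracks$duration_s),
      mean_max_area_um2 = mean(blebs$tracks$max_area_um2),
      sd_max_area_um2 = stats::sd(blebs$tracks$max_area_um2))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report$timepoints))
      write_table(report$timepoints, file.path(out_dir, "timepoints.csv"),
                  units = c(volume_um3 = "um^3", area_um2 = "um^2",
                            mean_delaunay_area_um2 = "um^2"))
    if (!is.null(report$cells))
      write_table(report$cells, file.path(out_dir, "cells.csv"),
                  units = c(volume_um3 = "um^3", area_um2 = "um^2",
                            x = "um", y = "um", z = "um"))
    if (!is.null(report$blebs))
      write_table(report$blebs, file.path(out_dir, "blebs.csv"),
                  units = c(duration_s = "s", max_area_um2 = "um^2"))
    writeLines(pipeline_summary_text(report),
               file.path(out_dir, "summary.txt"))
  }
  report
}

pipeline_summary_text <- function(report) {
  out <- c(sprintf("nodule4d pipeline report - scenario: %s", report$scenario))
  if (!is.null(report$timepoints)) {
    tp <- report$timepoints
    out <- c(out, "timepoint V_SHG(um3) A_SHG(um2) mip_ratio mean_tri(um2)",
             sprintf("%9d %10.0f %10.0f %9.3f %12.1f", tp$t, tp$volume_um3,
                     tp$area_um2, tp$mip_ratio, tp$mean_delaunay_area_um2))
  }
  if (!is.null(report$bleb_summary)) {
    bs <- report$bleb_summary
    out <- c(out, sprintf(
      "blebs: n=%d duration %.1f +/- %.1f s, max area %.2f +/- %.2f um2 (mean +/- SD)",
      bs$n_tracks, bs$mean_duration_s, bs$sd_duration_s,
      bs$mean_max_area_um2, bs$sd_max_area_um2))
  }
  out
}
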