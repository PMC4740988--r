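#' Default differentiation-course effects for the demo pipeline
#'
#' A small set of trends of the kind seen in differentiating ESCs: multiply
#' acetylated H4 aa 4-17 declines monotonically (strongest for the
#' tetra-acetylated form), singly acetylated H4 rises, H3K4me1 declines and
#' H3K9me2 rises.
#'
#' @param n_time Number of time points (trajectories are interpolated
#'   geometrically).
#' @return List of [effect_spec()] objects.
#' @export
demo_effects <- function(n_time = 5) {
  geom <- function(total_fold) total_fold^(seq(0, 1, length.out = n_time))
  list(
    effect_spec(trajectory = geom(1 / 5), histone = "H4", acetyl_count = 4),
    effect_spec(trajectory = geom(1 / 3), histone = "H4", acetyl_count = 2:3),
    effect_spec(trajectory = geom(1.8),  histone = "H4", acetyl_count = 1),
    effect_spec(trajectory = geom(1 / 1.4), mark = "H3K4me1"),
    effect_spec(trajectory = geom(2.5),  mark = "H3K9me2")
  )
}

#' Run the end-to-end demo pipeline on synthetic data
#'
#' Composes every stage on one synthetic study: peptidoform library ->
#' noisy peak areas over the 5 x 2 x 3 time-course design -> relative ratios
#' -> single-mark and acetyl-state profiles (technical averaging, row
#' z-scores) -> time-course ANOVA and PCA -> a two-dose inhibitor contrast
#' with t-tests, fold changes and dose concordance -> simulated ChIP coverage
#' with RPM normalization, specific/constitutive peak classification,
#' replicate merging and TF-site overlap. Deterministic under a fixed seed.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param design The MS [sample_design()].
#' @param tech_cv,bio_cv Noise CVs for the area simulation.
#' @param effects Time-course effects (default [demo_effects()]).
#' @param ppm_tol,window,fold,max_dist,alpha The pipeline constants: EIC
#'   tolerance (ppm), classification window (bp) and fold threshold, TF-site
#'   distance cutoff (bp), significance level.
#' @param out_dir Optional directory: interchange TSV/BED tables are written
#'   there.
#' @return A `ptm_report` list with the per-stage results and the parameters.
#' @export
run_demo_pipeline <- function(seed = 1L, design = sample_design(),
                              tech_cv = 0.05, bio_cv = 0.15,
                              effects = NULL,
                              ppm_tol = 10, window = 200L, fold = 4,
                              max_dist = 1000, alpha = 0.05,
                              out_dir = NULL) {
  seed <- as.integer(seed)
  lib <- default_histone_library()
  if (is.null(effects)) effects <- demo_effects(length(design$time_points))

  # --- quantification stage -------------------------------------------------
  sim <- simulate_area_table(lib, design, effects,
                             tech_cv = tech_cv, bio_cv = bio_cv, seed = seed)
  ratios <- relative_ratios(sim$areas)
  marks <- single_mark_abundance(ratios, lib)
  marks_bio <- average_technical_replicates(marks)
  mark_z <- zscore_rows(marks_bio)
  acetyl <- acetyl_state_profile(ratios, lib)
  acetyl_bio <- average_technical_replicates(acetyl)

  # --- time-course statistics ----------------------------------------------
  anova_res <- anova_timecourse(marks_bio)
  acetyl_anova <- anova_timecourse(acetyl_bio)
  pca <- pca_profiles(t(marks_bio))

  # --- inhibitor contrast (two doses, triplicate arms) ----------------------
  jq1_design <- sample_design(time_points = c("ctrl", "jq1"),
                              n_bio = 3, n_tech = 1)
  # BET inhibition regulates most marks: tetra-acetyl H4 up, di/tri-acetyl
  # down, H3K4me1 down, K9 acetyl/methyl up, K14ac down, mono-acetyl H4 down
  jq1_traj <- function(strength) list(
    effect_spec(trajectory = c(1, 2.0^strength), histone = "H4", acetyl_count = 4),
    effect_spec(trajectory = c(1, 0.5^strength), histone = "H4", acetyl_count = 2:3),
    effect_spec(trajectory = c(1, 0.7^strength), histone = "H4", acetyl_count = 1),
    effect_spec(trajectory = c(1, 0.6^strength), mark = "H3K4me1"),
    effect_spec(trajectory = c(1, 1.5^strength), mark = "H3K4me2"),
    effect_spec(trajectory = c(1, 1.8^strength), mark = "H3K9ac"),
    effect_spec(trajectory = c(1, 1.6^strength), mark = "H3K9me2"),
    effect_spec(trajectory = c(1, 1.4^strength), mark = "H3K9me3"),
    effect_spec(trajectory = c(1, 0.6^strength), mark = "H3K14ac"))
  jq1_marks <- function(s, strength) {
    simj <- simulate_area_table(lib, jq1_design, jq1_traj(strength),
                                tech_cv = tech_cv, bio_cv = bio_cv, seed = s)
    single_mark_abundance(relative_ratios(simj$areas), lib)
  }
  m100 <- jq1_marks(seed + 101L, 0.8)
  m200 <- jq1_marks(seed + 202L, 1.0)
  grp <- function(m, g) m[, parse_sample_ids(colnames(m))$time == g, drop = FALSE]
  diff_100 <- ttest_fold_change(grp(m100, "ctrl"), grp(m100, "jq1"), alpha)
  diff_200 <- ttest_fold_change(grp(m200, "ctrl"), grp(m200, "jq1"), alpha)
  concordance <- dose_concordance(diff_100, diff_200)

  # --- ChIP stage -----------------------------------------------------------
  chrom_sizes <- c(chrT = 200000L)
  n_pk <- 30L
  starts <- seq(2000L, by = 6000L, length.out = n_pk)
  fct <- rep(list(c(8, 1), c(1, 8), c(3, 3)), each = n_pk / 3)
  true_peaks <- data.frame(chrom = "chrT", start = starts, end = starts + 600L,
                           factor_a = vapply(fct, `[`, 0, 1L),
                           factor_b = vapply(fct, `[`, 0, 2L))
  chip <- simulate_chip_data(chrom_sizes, true_peaks, background_rate = 50,
                             bin_size = 50L, fold = fold, seed = seed + 303L)
  na <- rpm_normalize(chip$track_a); nb <- rpm_normalize(chip$track_b)
  classified <- classify_peaks(chip$peaks, na, nb, window = window, fold = fold)
  chip_accuracy <- mean(classified$label == chip$peaks$truth)

  set.seed(seed + 404L)
  jitter1 <- pmax(0L, true_peaks$start - sample(0:100, n_pk, TRUE))
  rep2 <- data.frame(chrom = "chrT", start = jitter1,
                     end = true_peaks$end + sample(0:100, n_pk, TRUE))
  merged <- merge_replicate_peaks(true_peaks[, c("chrom", "start", "end")], rep2)
  tf_near <- data.frame(chrom = "chrT",
                        start = true_peaks$start[1:10] + 700L,
                        end = true_peaks$start[1:10] + 720L)
  tf_far <- data.frame(chrom = "chrT",
                       start = true_peaks$start[11:20] + 4000L,
                       end = true_peaks$start[11:20] + 4020L)
  tf_sites <- rbind(tf_near, tf_far)
  tf_overlap <- overlap_fraction(tf_sites, merged, max_dist = max_dist)

  report <- structure(list(
    lib = lib, design = design,
    ratios = ratios, mark_profile = marks_bio, mark_zscores = mark_z,
    acetyl_states = acetyl_bio,
    anova = anova_res, acetyl_anova = acetyl_anova, pca = pca,
    jq1 = list(diff_100 = diff_100, diff_200 = diff_200,
               concordance = concordance),
    chip = list(classified = classified, accuracy = chip_accuracy,
                merged = merged, tf_overlap = tf_overlap),
    params = list(seed = seed, ppm_tol = ppm_tol, window = window,
                  fold = fold, max_dist = max_dist, alpha = alpha,
                  tech_cv = tech_cv, bio_cv = bio_cv)
  ), class = "ptm_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_area_table(sim$areas, file.path(out_dir, "areas.tsv"))
    write_area_table(ratios, file.path(out_dir, "ratios.tsv"))
    write_area_table(marks_bio, file.path(out_dir, "mark_profile.tsv"))
    write_area_table(acetyl_bio, file.path(out_dir, "acetyl_states.tsv"))
    utils::write.table(anova_res, file.path(out_dir, "anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff_100, file.path(out_dir, "jq1_100.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff_200, file.path(out_dir, "jq1_200.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cl <- classified
    cl$name <- cl$label
    cl$score <- round(cl$max_window_fold, 3)
    write_bed(cl, file.path(out_dir, "peaks_classified.bed"))
  }
  report
}

#' @export
print.ptm_report <- function(x, ...) {
  cat("Histone PTM pipeline report (seed ", x$params$seed, ")\n", sep = "")
  cat("  peptidoforms: ", nrow(x$lib), " in ",
      length(unique(family_of(x$lib$key))), " families\n", sep = "")
  cat("  samples: ", length(x$design$sample_ids), " (",
      length(x$design$time_points), " time points x ", x$design$n_bio,
      " bio x ", x$design$n_tech, " tech)\n", sep = "")
  sig <- x$anova$p_value < x$params$alpha
  cat("  ANOVA: ", sum(sig), "/", length(sig),
      " marks change across the time course (p < ", x$params$alpha, ")\n",
      sep = "")
  tp <- vapply(strsplit(colnames(x$acetyl_states), ".", fixed = TRUE),
               `[`, "", 1L)
  traj <- tapply(x$acetyl_states["4ac", ], factor(tp, unique(tp)), mean)
  cat("  tetra-ac H4 trajectory: ",
      paste(sprintf("%.3f", traj), collapse = " -> "), "\n", sep = "")
  cat("  JQ1 dose concordance r = ",
      sprintf("%.3f", x$jq1$concordance$correlation), "\n", sep = "")
  cat("  ChIP labels: ",
      paste(names(table(x$chip$classified$label)),
            table(x$chip$classified$label), sep = "=", collapse = ", "),
      " (accuracy ", sprintf("%.2f", x$chip$accuracy), ")\n", sep = "")
  cat("  TF sites within ", x$params$max_dist, " bp of a peak: ",
      sprintf("%.2f", x$chip$tf_overlap), "\n", sep = "")
  invisible(x)
}
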