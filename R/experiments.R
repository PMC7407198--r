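#' Homogeneous (null) cohort configuration
#'
#' Every analyte x group x depth shares one log-normal law: no group
#' effects, no depth effects. Used for calibration experiments (type-I
#' error of the ANOVA stage, behaviour of the radiality classifier on
#' exchangeable nodes) and as the base for planted-node recovery. Bounds
#' are wide open and outlier injection is off so the design stays complete
#' and the planted geometry reaches the distance stage intact.
#'
#' @param n_per_group Patients per group (scalar or named vector).
#' @param meanlog,sdlog Shared log-normal parameters.
#' @param seed Seed.
#' @return A [cohort_config()].
#' @export
homogeneous_config <- function(n_per_group = c(primary = 6, aseptic = 5, septic = 6),
                               meanlog = log(20), sdlog = 0.6, seed = 1L) {
  if (length(n_per_group) == 1) {
    n_per_group <- stats::setNames(rep(n_per_group, 3), GROUPS)
  }
  cat30 <- panel_catalog()
  eff <- tidyr::expand_grid(analyte = cat30$analyte, group = GROUPS,
                            depth = DEPTHS)
  eff$meanlog <- meanlog
  eff$sdlog <- sdlog
  bounds <- tibble::tibble(analyte = cat30$analyte, lloq = 1e-12, uloq = 1e12)
  cohort_config(
    n_patients_per_group = n_per_group,
    analyte_effects = eff,
    censor_bounds = bounds,
    outlier_rate = 0,
    outlier_multiplier = 10,
    seed = seed
  )
}

#' Planted-node recovery experiment
#'
#' For each replicate, generates a homogeneous cohort, displaces one node
#' toward the periphery of one network with [plant_peripheral_node()], runs
#' the full pipeline, and records whether the planted node attained the
#' minimum normalized radiality and a low significance call in its network.
#'
#' @param n_reps Number of seeded replicates.
#' @param shift Log-scale displacement (see [plant_peripheral_node()]).
#' @param analyte,group,depth The node and network to plant.
#' @param n_per_group,sdlog Cohort shape for [homogeneous_config()].
#' @param sd_convention Passed to [radiality_table()].
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Tibble with one row per replicate: `rep`, `min_is_planted`,
#'   `planted_low`, `n_low`, `n_high`.
#' @export
planted_recovery_experiment <- function(n_reps = 100, shift = 8,
                                        analyte = "p-AKT",
                                        group = "septic", depth = "ATL",
                                        n_per_group = 6, sdlog = 0.6,
                                        sd_convention = "sample",
                                        seed = 1L) {
  key <- paste(group, depth, sep = ".")
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- homogeneous_config(n_per_group = n_per_group, sdlog = sdlog,
                              seed = as.integer(seed) + r)
    rec <- generate_cohort(cfg)
    if (shift > 0) {
      rec <- plant_peripheral_node(rec, analyte, group, depth, shift)
    }
    pre <- preprocess_cohort(rec)
    tab <- radiality_table(pre$matrices[[key]], sd_convention = sd_convention)
    i <- match(analyte, tab$rows$analyte)
    tibble::tibble(
      rep = r,
      min_is_planted = which.min(tab$rows$normalized_radiality) == i,
      planted_low = tab$rows$call[i] == "low",
      n_low = sum(tab$rows$call == "low"),
      n_high = sum(tab$rows$call == "high")
    )
  })
  dplyr::bind_rows(rows)
}

#' Null low-call experiment
#'
#' Runs the pipeline on unplanted homogeneous cohorts and counts
#' significance calls in one network per replicate. Documents the
#' behaviour of the adaptive mean - SD threshold on exchangeable nodes:
#' because the rule is scale-free, a noise cohort flags the right tail of
#' its own average-distance distribution, so some low calls are expected
#' in every replicate (see the methods vignette).
#'
#' @inheritParams planted_recovery_experiment
#' @return Tibble with one row per replicate: `rep`, `n_low`, `n_high`.
#' @export
null_low_call_experiment <- function(n_reps = 100, group = "septic",
                                     depth = "ATL", n_per_group = 6,
                                     sdlog = 0.6, sd_convention = "sample",
                                     seed = 1L) {
  res <- planted_recovery_experiment(
    n_reps = n_reps, shift = 0, group = group, depth = depth,
    n_per_group = n_per_group, sdlog = sdlog,
    sd_convention = sd_convention, seed = seed
  )
  res[, c("rep", "n_low", "n_high")]
}

#' Type-I calibration of the ANOVA stage
#'
#' Generates null cohorts (no group or depth effects), runs the two-way
#' ANOVA with Bonferroni post-tests on every analyte, and reports the
#' fraction of analytes with at least one flagged contrast — the
#' family-wise type-I rate, which Bonferroni keeps at or just under alpha.
#'
#' By default the null values go straight from depth averaging into the
#' ANOVA, matching the stage's contract (groups drawn from one
#' distribution). Setting `iqr_filter = TRUE` interposes the pipeline's
#' per-cell 1.5xIQR outlier filter; on skewed data with small per-cell
#' samples that filter distorts the retained values' dependence structure
#' and inflates the family-wise error well above alpha — a pipeline
#' property documented in the methods vignette, measurable here.
#'
#' @param n_cohorts Number of null cohorts.
#' @param n_per_group Patients per group (reduced sizes keep the experiment
#'   fast; see the methods vignette for the sizes used).
#' @param sdlog Shared dispersion.
#' @param alpha Significance level.
#' @param iqr_filter Apply [filter_outliers()] before averaging.
#' @param seed Base seed; cohort c uses `seed + c`.
#' @return List with `flag_rate`, `n_analyte_tests`, and `per_cohort`
#'   (tibble of flagged-analyte counts).
#' @export
anova_null_calibration <- function(n_cohorts = 1000, n_per_group = 4,
                                   sdlog = 0.6, alpha = 0.05,
                                   iqr_filter = FALSE, seed = 1L) {
  per <- vapply(seq_len(n_cohorts), function(cix) {
    cfg <- homogeneous_config(n_per_group = n_per_group, sdlog = sdlog,
                              seed = as.integer(seed) + cix)
    rec <- drop_censored(generate_cohort(cfg))
    if (iqr_filter) rec <- filter_outliers(rec)
    avg <- depth_average(rec)
    res <- anova_all_analytes(avg, alpha = alpha)
    sum(vapply(res, function(s) any(s$posthoc$flagged), logical(1)))
  }, integer(1))
  n_analytes <- nrow(panel_catalog())
  list(
    flag_rate = sum(per) / (n_cohorts * n_analytes),
    n_analyte_tests = n_cohorts * n_analytes,
    per_cohort = tibble::tibble(cohort = seq_len(n_cohorts), n_flagged = per)
  )
}

#' Null calibration of the Pearson confounder screen
#'
#' Generates null cohorts with covariates drawn independently of every
#' analyte and counts, per cohort, the covariate x analyte pairs that
#' remain significant after Bonferroni correction. Under the null the
#' screen should report none in all but ~alpha of cohorts.
#'
#' @param n_cohorts Number of null cohorts.
#' @param n_per_group,sdlog Cohort shape.
#' @param alpha Significance level after correction.
#' @param seed Base seed.
#' @return Tibble with `cohort` and `n_significant`.
#' @export
pearson_null_calibration <- function(n_cohorts = 100, n_per_group = 6,
                                     sdlog = 0.6, alpha = 0.05, seed = 1L) {
  rows <- vapply(seq_len(n_cohorts), function(cix) {
    cfg <- homogeneous_config(n_per_group = n_per_group, sdlog = sdlog,
                              seed = as.integer(seed) + cix)
    rec <- generate_cohort(cfg)
    covs <- generate_covariates(rec, seed = as.integer(seed) + n_cohorts + cix)
    avg <- depth_average(filter_outliers(drop_censored(rec)))
    scr <- pearson_confounder_screen(covs, avg, alpha = alpha)
    sum(scr$significant, na.rm = TRUE)
  }, integer(1))
  tibble::tibble(cohort = seq_len(n_cohorts), n_significant = rows)
}
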