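#' Default generative effects for the synthetic cohort
#'
#' One (meanlog, sdlog) pair per analyte x group x depth, on the log scale of
#' a log-normal generative law. The defaults are illustrative: the underlying
#' study deposits no raw concentrations, so absolute scales are free
#' parameters chosen to look like multiplex immunoassay data (cytokines in
#' tens-to-hundreds of pg/mL with ~100% CV; phosphoproteins as relative
#' signals near unity with tighter spread). The qualitative group and depth
#' structure follows the reported trends: all cytokines higher in revision
#' than primary tissue and highest in septic revision, except IL-10 and
#' IL-12p70 which peak in aseptic revision; most phosphoproteins highest in
#' primary tissue, except p-c-Jun and p-BAD (aseptic) and p-PTEN (septic);
#' adjacent-layer responses generally exceed radial-layer responses.
#'
#' @return A tibble with columns `analyte`, `group`, `depth`, `meanlog`,
#'   `sdlog` (180 rows).
#' @export
default_analyte_effects <- function() {
  cat30 <- panel_catalog()
  grid <- tidyr::expand_grid(
    analyte = cat30$analyte, group = GROUPS, depth = DEPTHS
  )
  grid <- dplyr::left_join(grid, cat30[, c("analyte", "class")], by = "analyte")

  base <- ifelse(grid$class == "cytokine", 20, 2)

  # group multipliers relative to primary
  gm <- rep(1, nrow(grid))
  cy <- grid$class == "cytokine"
  gm[cy & grid$group == "aseptic"] <- 3
  gm[cy & grid$group == "septic"]  <- 8
  special_cy <- grid$analyte %in% c("IL-10", "IL-12p70")
  gm[special_cy & grid$group == "aseptic"] <- 5
  gm[special_cy & grid$group == "septic"]  <- 2
  ph <- !cy
  gm[ph & grid$group == "aseptic"] <- 0.5
  gm[ph & grid$group == "septic"]  <- 0.35
  apopt <- grid$analyte %in% c("p-c-Jun", "p-BAD")
  gm[apopt & grid$group == "aseptic"] <- 2.5
  gm[apopt & grid$group == "septic"]  <- 1.5
  pten <- grid$analyte == "p-PTEN"
  gm[pten & grid$group == "aseptic"] <- 0.8
  gm[pten & grid$group == "septic"]  <- 2.5

  # depth multipliers relative to ATL
  dm <- rep(1, nrow(grid))
  dm[grid$depth == "RTL"] <- 0.7
  rtl_up <- grid$analyte %in%
    c("p-BAD", "p-Src", "p-IkBa", "p-HSP27", "p-ERK1/2", "p-VEGFR2")
  dm[rtl_up & grid$depth == "RTL"] <- 1.3

  tibble::tibble(
    analyte = grid$analyte,
    group   = grid$group,
    depth   = grid$depth,
    meanlog = log(base * gm * dm),
    sdlog   = ifelse(cy, 1.0, 0.6)
  )
}

#' Default quantitation limits per analyte
#'
#' Wide limits typical of multiplex assays, so that censoring under the
#' default effects is sporadic rather than structural.
#'
#' @return A tibble with columns `analyte`, `lloq`, `uloq`.
#' @export
default_censor_bounds <- function() {
  cat30 <- panel_catalog()
  tibble::tibble(
    analyte = cat30$analyte,
    lloq = ifelse(cat30$class == "cytokine", 0.5, 0.05),
    uloq = ifelse(cat30$class == "cytokine", 25000, 100)
  )
}

#' Configuration of a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: per-group patient counts
#' (defaults match the study: 6 primary TKA, 5 aseptic TKR, 6 septic TKR),
#' the depth-to-location design (four ATL locations, three RTL locations),
#' per analyte x group x depth log-normal effects, quantitation limits,
#' an outlier-injection rate and multiplier, and a seed.
#'
#' @param n_patients_per_group Named positive integers for `primary`,
#'   `aseptic`, `septic`.
#' @param analyte_effects Tibble as from [default_analyte_effects()].
#' @param censor_bounds Tibble as from [default_censor_bounds()].
#' @param outlier_rate Probability in \[0,1\] that a single reading is
#'   multiplied by `outlier_multiplier`.
#' @param outlier_multiplier Factor (> 1) applied to injected outliers; the
#'   default 10 places them beyond the 1.5xIQR Tukey fence of their peer
#'   readings so the preprocessing filter can provably catch them.
#' @param seed Integer seed; generation is fully reproducible given the
#'   config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_per_group = c(primary = 6, aseptic = 5, septic = 6),
                          analyte_effects = default_analyte_effects(),
                          censor_bounds = default_censor_bounds(),
                          outlier_rate = 0.01,
                          outlier_multiplier = 10,
                          seed = 1L) {
  cfg <- structure(
    list(
      n_patients_per_group = n_patients_per_group,
      group_labels = GROUPS,
      depth_locations = DEPTH_LOCATIONS,
      analyte_effects = analyte_effects,
      censor_bounds = censor_bounds,
      outlier_rate = outlier_rate,
      outlier_multiplier = outlier_multiplier,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the design invariants and raises a configuration error naming the
#' offending field.
#'
#' @param config A `cohort_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  n <- config$n_patients_per_group
  if (!all(GROUPS %in% names(n)) || any(n[GROUPS] < 1) ||
      any(n[GROUPS] != round(n[GROUPS]))) {
    fail("n_patients_per_group",
         "must give a positive integer for each of primary, aseptic, septic")
  }
  if (!identical(sort(names(config$depth_locations)), sort(DEPTHS)) ||
      !setequal(config$depth_locations$ATL, c("F", "T", "LG", "PC")) ||
      !setequal(config$depth_locations$RTL, c("F", "T", "LG"))) {
    fail("depth_locations",
         "must map ATL to {F,T,LG,PC} and RTL to {F,T,LG} (PC is not collected at RTL)")
  }
  cat30 <- panel_catalog()
  eff <- config$analyte_effects
  need <- c("analyte", "group", "depth", "meanlog", "sdlog")
  if (!is.data.frame(eff) || !all(need %in% names(eff))) {
    fail("analyte_effects", "must be a data frame with columns analyte, group, depth, meanlog, sdlog")
  }
  full <- tidyr::expand_grid(analyte = cat30$analyte, group = GROUPS, depth = DEPTHS)
  have <- paste(eff$analyte, eff$group, eff$depth)
  miss <- setdiff(paste(full$analyte, full$group, full$depth), have)
  if (length(miss) > 0) {
    fail("analyte_effects",
         sprintf("is missing %d analyte x group x depth combinations (first: %s)",
                 length(miss), miss[1]))
  }
  if (any(!is.finite(eff$meanlog)) || any(eff$sdlog < 0)) {
    fail("analyte_effects", "must have finite meanlog and nonnegative sdlog")
  }
  cb <- config$censor_bounds
  if (!is.data.frame(cb) || !all(c("analyte", "lloq", "uloq") %in% names(cb)) ||
      !all(cat30$analyte %in% cb$analyte)) {
    fail("censor_bounds", "must give lloq and uloq for every catalog analyte")
  }
  if (any(!(cb$uloq > cb$lloq & cb$lloq > 0))) {
    fail("censor_bounds", "must satisfy ULOQ > LLOQ > 0 for every analyte")
  }
  if (config$outlier_rate < 0 || config$outlier_rate > 1) {
    fail("outlier_rate", "must lie in [0, 1]")
  }
  if (config$outlier_multiplier <= 0) {
    fail("outlier_multiplier", "must be positive")
  }
  if (length(config$seed) != 1 || is.na(config$seed)) {
    fail("seed", "must be a single integer")
  }
  invisible(config)
}

#' Generate a synthetic cohort of measurement records
#'
#' Draws one reading per patient x location x depth x analyte from the
#' config's log-normal effects, injects sporadic multiplicative outliers,
#' and flags readings outside the quantitation limits. Censored readings are
#' emitted with their raw value and a QC flag — omission is the
#' preprocessing stage's job, mirroring the analysis pipeline's order.
#'
#' @param config A [cohort_config()].
#' @return A tibble of measurement records with columns `patient_id`,
#'   `group`, `location`, `depth`, `analyte`, `value`, `qc`
#'   (`ok` / `below_lloq` / `above_uloq`) and `outlier` (provenance of
#'   injected outliers; carried for diagnostics, never consumed downstream).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients_per_group = c(primary = 2, aseptic = 2, septic = 2))
#' rec <- generate_cohort(cfg)
#' nrow(rec)  # 6 patients x 7 samples x 30 analytes = 1260
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cat30 <- panel_catalog()

  patients <- dplyr::bind_rows(lapply(GROUPS, function(g) {
    tibble::tibble(
      group = g,
      patient_id = sprintf("%s_%02d", g, seq_len(config$n_patients_per_group[[g]]))
    )
  }))
  samples <- dplyr::bind_rows(lapply(DEPTHS, function(d) {
    tibble::tibble(depth = d, location = config$depth_locations[[d]])
  }))

  grid <- tidyr::expand_grid(
    patients, samples, analyte = cat30$analyte
  )
  grid <- dplyr::left_join(grid, config$analyte_effects,
                           by = c("analyte", "group", "depth"))
  grid <- dplyr::left_join(grid, config$censor_bounds, by = "analyte")

  set.seed(config$seed)
  n <- nrow(grid)
  value <- stats::rlnorm(n, meanlog = grid$meanlog, sdlog = grid$sdlog)
  outlier <- stats::runif(n) < config$outlier_rate
  value[outlier] <- value[outlier] * config$outlier_multiplier

  qc <- rep("ok", n)
  qc[value < grid$lloq] <- "below_lloq"
  qc[value > grid$uloq] <- "above_uloq"

  tibble::tibble(
    patient_id = grid$patient_id,
    group = grid$group,
    location = grid$location,
    depth = grid$depth,
    analyte = grid$analyte,
    value = value,
    qc = qc,
    outlier = outlier
  )
}

#' Displace one node toward the periphery of one network
#'
#' Multiplies every reading of `analyte` in the given group x depth network
#' by `exp(-shift)`, pulling that node's replicate profile toward zero
#' relative to its across-network maximum. After per-analyte maximum
#' normalization the planted node's profile sits near the origin, far from
#' the remaining nodes, so at sufficient `shift` it maximizes summed
#' distance and attains the minimum radiality in its network. Used for
#' parameter-recovery experiments on the centrality pipeline.
#'
#' @param records Measurement records as from [generate_cohort()].
#' @param analyte,group,depth The node and network to displace.
#' @param shift Nonnegative displacement on the log scale; `shift = 0` is
#'   the identity.
#' @param censor_bounds Optional tibble (`analyte`, `lloq`, `uloq`); when
#'   supplied, QC flags of the displaced rows are recomputed against it.
#'   Recovery experiments typically run uncensored so the planted geometry
#'   reaches the distance stage intact.
#' @return The records with displaced values; the planted provenance
#'   (analyte, group, depth, shift, multiplier) is attached as attribute
#'   `"planted"`, accumulating across calls.
#' @export
plant_peripheral_node <- function(records, analyte, group, depth, shift,
                                  censor_bounds = NULL) {
  cat30 <- panel_catalog()
  if (!analyte %in% cat30$analyte) {
    stop(sprintf("unknown analyte '%s'", analyte), call. = FALSE)
  }
  if (!group %in% GROUPS) {
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  }
  if (!depth %in% DEPTHS) {
    stop(sprintf("unknown depth '%s'", depth), call. = FALSE)
  }
  if (!is.numeric(shift) || length(shift) != 1 || shift < 0) {
    stop("shift must be a single nonnegative number", call. = FALSE)
  }
  sel <- records$analyte == analyte & records$group == group &
    records$depth == depth
  records$value[sel] <- records$value[sel] * exp(-shift)
  if (!is.null(censor_bounds)) {
    b <- censor_bounds[censor_bounds$analyte == analyte, ]
    qc <- rep("ok", sum(sel))
    qc[records$value[sel] < b$lloq] <- "below_lloq"
    qc[records$value[sel] > b$uloq] <- "above_uloq"
    records$qc[sel] <- qc
  }
  prov <- tibble::tibble(
    analyte = analyte, group = group, depth = depth,
    shift = shift, multiplier = exp(-shift)
  )
  attr(records, "planted") <- dplyr::bind_rows(attr(records, "planted"), prov)
  records
}

#' Synthetic patient covariates
#'
#' Age, sex, and BMI per patient, drawn independently of every analyte
#' (the confounder screen's null). Ranges follow the study cohort
#' (ages 45-82, BMI 24.6-43.7, mixed sex).
#'
#' @param records Measurement records (patients are taken from them).
#' @param seed Integer seed.
#' @return Tibble with columns `patient_id`, `group`, `age`, `sex`
#'   (`"M"`/`"F"`), `bmi`.
#' @export
generate_covariates <- function(records, seed = 1L) {
  pats <- dplyr::distinct(records[, c("patient_id", "group")])
  set.seed(as.integer(seed))
  n <- nrow(pats)
  tibble::tibble(
    patient_id = pats$patient_id,
    group = pats$group,
    age = round(stats::runif(n, 45, 82)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    bmi = round(stats::runif(n, 24.6, 43.7), 1)
  )
}
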