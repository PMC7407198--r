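test_that("the 1.5 IQR rule removes values beyond interpolated-quartile fences", {
  r <- iqr_outlier_filter(c(1, 2, 3, 4, 100))
  expect_equal(r$kept, c(1, 2, 3, 4))   # Q1 = 2, Q3 = 4, fences [-1, 7]
  expect_equal(r$removed, 100)
  r <- iqr_outlier_filter(c(5, 5, 5, 5))
  expect_equal(r$kept, c(5, 5, 5, 5))
  expect_length(r$removed, 0)
  expect_warning(r <- iqr_outlier_filter(c(1, 1000)), "fewer than 4")
  expect_equal(r$kept, c(1, 1000))
  expect_error(iqr_outlier_filter(numeric(0)), "empty")
})

test_that("an injected outlier beyond the fence is exactly what the filter removes", {
  # one isolated cell: 11 well-behaved readings plus one planted far beyond
  # the Tukey fence
  set.seed(17)
  peers <- rlnorm(11, log(20), 0.2)
  q <- quantile(peers, c(0.25, 0.75), type = 7, names = FALSE)
  planted <- q[2] + 10 * (q[2] - q[1]) + 10
  rec <- tibble::tibble(
    patient_id = paste0("p", 1:12), group = "primary", depth = "ATL",
    location = "F", analyte = "IL-6", value = c(peers, planted), qc = "ok"
  )
  filtered <- filter_outliers(rec)
  log <- attr(filtered, "outlier_log")
  expect_equal(log$analyte, "IL-6")
  expect_equal(log$n_removed, 1L)
  expect_false(planted %in% filtered$value)
  expect_equal(sort(filtered$value), sort(peers))

  # within a full cohort, the planted cell loses exactly the planted value
  cfg <- homogeneous_config(n_per_group = 4, sdlog = 0.3, seed = 17)
  rec2 <- generate_cohort(cfg)
  sel <- which(rec2$analyte == "IL-6" & rec2$group == "primary" &
                 rec2$depth == "ATL" & rec2$location == "F")
  q2 <- quantile(rec2$value[sel[-1]], c(0.25, 0.75), type = 7, names = FALSE)
  rec2$value[sel[1]] <- q2[2] + 10 * (q2[2] - q2[1]) + 10
  filtered2 <- filter_outliers(rec2)
  log2 <- attr(filtered2, "outlier_log")
  cell <- log2[log2$analyte == "IL-6" & log2$group == "primary" &
                 log2$depth == "ATL" & log2$location == "F", ]
  expect_equal(cell$n_removed, 1L)
  expect_false(rec2$value[sel[1]] %in% filtered2$value)
})

test_that("depth averaging is the arithmetic mean over surviving locations", {
  rec <- tibble::tibble(
    patient_id = "p1", group = "primary",
    depth = c("ATL", "ATL", "ATL", "ATL", "RTL", "RTL"),
    location = c("F", "T", "LG", "PC", "F", "T"),
    analyte = "IL-6",
    value = c(1, 2, 3, 6, 2, 4),
    qc = "ok"
  )
  avg <- depth_average(rec)
  expect_equal(avg$value[avg$depth == "ATL"], 3)
  expect_equal(avg$value[avg$depth == "RTL"], 3)   # LG removed upstream
  expect_equal(avg$n_locations[avg$depth == "RTL"], 2L)
  # a fully censored patient x depth x analyte is absent, not NA
  expect_equal(nrow(avg), 2)
})

test_that("max normalization scales each analyte to its global maximum", {
  avg <- tibble::tibble(
    patient_id = rep(c("a", "b", "c"), 2),
    group = rep(c("primary", "aseptic"), each = 3),
    depth = "ATL",
    analyte = rep(panel_catalog()$analyte[1:2], each = 3),
    value = c(2, 4, 8, 6, 1, 3),
    n_locations = 4L
  )
  # against the full catalog, an absent analyte is an error naming it
  expect_error(max_normalize(avg), "no data to normalize.*p-IkBa")

  one <- avg[avg$analyte == avg$analyte[1], ]
  got <- max_normalize(one, catalog = NULL)
  expect_equal(sort(got$value), c(0.25, 0.5, 1.0))
  # maximum maps to exactly 1; both analytes hit it despite different scales
  both <- max_normalize(avg, catalog = NULL)
  expect_equal(unname(vapply(split(both$value, both$analyte), max, numeric(1))),
               c(1, 1))
  # idempotence: a second pass divides by 1
  expect_equal(max_normalize(got, catalog = NULL), got)
  # degenerate single value maps to 1
  expect_equal(max_normalize(one[1, ], catalog = NULL)$value, 1)
})

test_that("the preprocessing pipeline matches an independent base-R re-derivation", {
  cfg <- tiny_config(n = 3, seed = 19)
  rec <- generate_cohort(cfg)
  pre <- preprocess_cohort(rec)

  # oracle: censor -> IQR filter -> location mean -> global-max scale,
  # written with split/vapply instead of the package's dplyr path
  ok <- rec[rec$qc == "ok", ]
  key <- paste(ok$analyte, ok$group, ok$depth, ok$location)
  keep <- unlist(lapply(split(seq_len(nrow(ok)), key), function(idx) {
    v <- ok$value[idx]
    if (length(v) < 4) return(idx)
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    idx[v >= q[1] - 1.5 * (q[2] - q[1]) & v <= q[2] + 1.5 * (q[2] - q[1])]
  }))
  ok <- ok[sort(keep), ]
  akey <- paste(ok$patient_id, ok$group, ok$depth, ok$analyte, sep = "|")
  means <- vapply(split(ok$value, akey), mean, numeric(1))
  parts <- do.call(rbind, strsplit(names(means), "|", fixed = TRUE))
  oracle <- data.frame(patient_id = parts[, 1], group = parts[, 2],
                       depth = parts[, 3], analyte = parts[, 4],
                       value = unname(means))
  amax <- vapply(split(oracle$value, oracle$analyte), max, numeric(1))
  oracle$value <- oracle$value / amax[oracle$analyte]

  got <- pre$normalized
  merged <- merge(as.data.frame(got[, c("patient_id", "group", "depth", "analyte", "value")]),
                  oracle, by = c("patient_id", "group", "depth", "analyte"))
  expect_equal(nrow(merged), nrow(got))
  expect_equal(merged$value.x, merged$value.y, tolerance = 1e-12)
})

test_that("averaging before normalizing is not interchangeable with the reverse", {
  cfg <- tiny_config(n = 3, seed = 23)
  rec <- generate_cohort(cfg)
  ok <- filter_outliers(drop_censored(rec))
  # pipeline order: average locations, then scale by the analyte max
  a_then_n <- max_normalize(depth_average(ok))
  # permuted order: scale raw readings by the analyte max, then average
  permuted <- ok
  amax <- vapply(split(permuted$value, permuted$analyte), max, numeric(1))
  permuted$value <- permuted$value / amax[permuted$analyte]
  n_then_a <- depth_average(permuted)
  merged <- merge(as.data.frame(a_then_n), as.data.frame(n_then_a),
                  by = c("patient_id", "group", "depth", "analyte"))
  expect_gt(max(abs(merged$value.x - merged$value.y)), 1e-3)
})

test_that("response matrices resolve gaps per the missing policy", {
  cfg <- tiny_config(n = 3, seed = 29)
  rec <- generate_cohort(cfg)
  norm <- max_normalize(depth_average(filter_outliers(drop_censored(rec))))
  # punch one gap: drop one patient's IL-13 entry in septic ATL
  victim <- norm$patient_id[norm$group == "septic" & norm$depth == "ATL"][1]
  gap <- !(norm$analyte == "IL-13" & norm$group == "septic" &
             norm$depth == "ATL" & norm$patient_id == victim)
  m_imp <- assemble_response_matrix(norm[gap, ], "septic", "ATL", "impute_mean")
  others <- m_imp$values["IL-13", setdiff(colnames(m_imp$values), victim)]
  expect_equal(unname(m_imp$values["IL-13", victim]), mean(others))
  expect_equal(m_imp$n_imputed, 1L)
  m_pair <- assemble_response_matrix(norm[gap, ], "septic", "ATL", "pairwise_complete")
  expect_true(is.na(m_pair$values["IL-13", victim]))
  # pairwise distances then use only the shared replicates
  net <- build_distance_network(m_pair)
  u <- m_pair$values["IL-13", ]; w <- m_pair$values["IL-6", ]
  shared <- !is.na(u)
  expect_equal(net$distances["IL-13", "IL-6"],
               sqrt(sum((u[shared] - w[shared])^2)))
})

test_that("a node with no data in a network is reported by name", {
  cfg <- tiny_config(n = 2, seed = 31)
  rec <- generate_cohort(cfg)
  norm <- max_normalize(depth_average(filter_outliers(drop_censored(rec))))
  gone <- !(norm$analyte == "TNF-a" & norm$group == "primary" & norm$depth == "RTL")
  expect_error(assemble_response_matrix(norm[gone, ], "primary", "RTL"),
               "TNF-a")
})

test_that("a complete cohort yields complete matrices and a clean QC report", {
  cfg <- homogeneous_config(n_per_group = 3, seed = 37)
  rec <- generate_cohort(cfg)
  pre <- preprocess_cohort(rec)
  expect_named(pre$matrices, c("primary.ATL", "primary.RTL", "aseptic.ATL",
                               "aseptic.RTL", "septic.ATL", "septic.RTL"),
               ignore.order = TRUE)
  m <- pre$matrices[["septic.ATL"]]
  expect_equal(dim(m$values), c(30, 3))
  expect_false(anyNA(m$values))
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_equal(pre$qc$n_censored, 0)
  txt <- withr::local_tempfile(fileext = ".txt")
  js <- withr::local_tempfile(fileext = ".json")
  write_qc_report(pre$qc, txt, js)
  expect_true(any(grepl("censored", readLines(txt))))
  expect_equal(jsonlite::fromJSON(js)$n_censored, 0)
})
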