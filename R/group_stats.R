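#' Two-way ANOVA with Bonferroni post-tests for one analyte
#'
#' Fixed-effects two-factor ANOVA (group x depth) on depth-averaged
#' patient-level values, with Type II sums of squares (the design is
#' unbalanced: the study groups have 6/5/6 patients). Post-tests are the
#' classical Bonferroni multiple-comparison procedure on cell means with
#' the pooled error from the full model: the three pairwise group contrasts
#' within each depth plus the ATL-vs-RTL contrast within each group
#' (9 comparisons; the family size is explicit in the result).
#'
#' @param data Tibble with columns `patient_id`, `group`, `depth`, `value`
#'   for a single analyte (e.g. one analyte's slice of [depth_average()]).
#' @param analyte Label carried into the result.
#' @param alpha Significance level for flagging (default 0.05).
#' @return Object of class `anova_result`: list with `analyte`, `terms`
#'   (tibble: term, df, sum_sq, F, p), `posthoc` (tibble: comparison, diff,
#'   se, t, p, p_adj, flagged), `alpha`, `m` (Bonferroni family size),
#'   `residual_df`, `sigma2`.
#' @export
two_way_anova_bonferroni <- function(data, analyte = NA_character_,
                                     alpha = 0.05) {
  data <- data[!is.na(data$value), , drop = FALSE]
  data$group <- factor(data$group, levels = intersect(GROUPS, unique(data$group)))
  data$depth <- factor(data$depth, levels = intersect(DEPTHS, unique(data$depth)))
  cell_n <- table(data$group, data$depth)
  if (nlevels(data$group) < 2 || any(cell_n < 2)) {
    stop(sprintf("analyte %s: insufficient replication (need >= 2 groups with >= 2 values per cell)",
                 analyte), call. = FALSE)
  }

  rss <- function(formula) {
    mm <- stats::model.matrix(formula, data = data)
    fit <- stats::lm.fit(mm, data$value)
    c(sum(fit$residuals^2), nrow(mm) - fit$rank)
  }
  r_full <- rss(~ group * depth)
  rss_full <- r_full[1]
  df_res <- r_full[2]
  sigma2 <- rss_full / df_res

  r_add <- rss(~ group + depth)
  r_g <- rss(~ depth)     # drop group from additive
  r_d <- rss(~ group)     # drop depth from additive

  ss <- c(group = r_g[1] - r_add[1],
          depth = r_d[1] - r_add[1],
          `group:depth` = r_add[1] - rss_full)
  df <- c(group = r_g[2] - r_add[2],
          depth = r_d[2] - r_add[2],
          `group:depth` = r_add[2] - df_res)
  ss <- pmax(ss, 0)  # guard floating cancellation
  # scale-aware zero: a saturated (constant-cell) response leaves only
  # floating-point dust in every sum of squares
  tol <- 1e-12 * (mean(data$value^2) + 1)
  if (sigma2 <= tol) {
    ss[ss <= tol] <- 0
    sigma2 <- 0
  }
  if (sigma2 > 0) {
    fstat <- (ss / df) / sigma2
    pval <- stats::pf(fstat, df, df_res, lower.tail = FALSE)
  } else {
    # saturated response: any nonzero term SS is infinitely significant
    fstat <- ifelse(ss > 0, Inf, 0)
    pval <- ifelse(ss > 0, 0, 1)
  }
  terms <- tibble::tibble(term = names(ss), df = unname(df),
                          sum_sq = unname(ss), F = unname(fstat),
                          p = unname(pval))

  cell_key <- interaction(data$group, data$depth, drop = FALSE, sep = "\r")
  cell_mean <- tapply(data$value, cell_key, mean)
  cell_size <- tapply(data$value, cell_key, length)
  ckey <- function(g, d) paste(g, d, sep = "\r")

  gl <- levels(data$group); dl <- levels(data$depth)
  pairs <- utils::combn(gl, 2)
  labels <- character(0); a_key <- character(0); b_key <- character(0)
  for (d in dl) {
    labels <- c(labels, sprintf("%s vs %s @ %s", pairs[1, ], pairs[2, ], d))
    a_key <- c(a_key, ckey(pairs[1, ], d))
    b_key <- c(b_key, ckey(pairs[2, ], d))
  }
  if (length(dl) == 2) {
    labels <- c(labels, sprintf("%s vs %s @ %s", dl[1], dl[2], gl))
    a_key <- c(a_key, ckey(gl, dl[1]))
    b_key <- c(b_key, ckey(gl, dl[2]))
  }
  m <- length(labels)
  diff <- as.vector(cell_mean[a_key] - cell_mean[b_key])
  se <- sqrt(sigma2 * as.vector(1 / cell_size[a_key] + 1 / cell_size[b_key]))
  if (sigma2 > 0) {
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df_res)
  } else {
    t <- rep(0, m)
    p <- ifelse(abs(diff) > sqrt(tol), 0, 1)
  }
  posthoc <- tibble::tibble(
    comparison = labels, diff = diff, se = se, t = t, p = p,
    p_adj = pmin(1, m * p)
  )
  posthoc$flagged <- posthoc$p_adj < alpha

  structure(
    list(analyte = analyte, terms = terms, posthoc = posthoc,
         alpha = alpha, m = m, residual_df = df_res, sigma2 = sigma2),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s (alpha = %g, Bonferroni family m = %d)\n",
              x$analyte, x$alpha, x$m))
  print(as.data.frame(x$terms), row.names = FALSE)
  flg <- x$posthoc[x$posthoc$flagged, ]
  cat(sprintf("  flagged contrasts: %s\n",
              if (nrow(flg) > 0) paste(flg$comparison, collapse = "; ") else "none"))
  invisible(x)
}

#' Run the ANOVA stage over every analyte
#'
#' @param depth_averaged Output of [depth_average()] (all analytes).
#' @param alpha Significance level.
#' @return Named list of `anova_result`, one per analyte present.
#' @export
anova_all_analytes <- function(depth_averaged, alpha = 0.05) {
  split_list <- split(depth_averaged, depth_averaged$analyte)
  lapply(split_list, function(d) {
    two_way_anova_bonferroni(d, analyte = d$analyte[1], alpha = alpha)
  })
}

#' Pearson confounder screen of patient covariates
#'
#' Correlates age, sex, and BMI with each analyte's per-patient response
#' (depth-averaged values, averaged over the two depths so each patient
#' contributes one value per analyte). Sex enters as a 0/1 indicator
#' (point-biserial correlation). A Bonferroni correction over the full
#' covariate x analyte family is applied; a constant covariate is reported
#' as not evaluable.
#'
#' @param covariates Tibble with `patient_id`, `age`, `sex`, `bmi`.
#' @param depth_averaged Output of [depth_average()].
#' @param alpha Significance level after correction (default 0.05).
#' @return Tibble with one row per covariate x analyte: `covariate`,
#'   `analyte`, `r`, `n`, `p`, `p_adj`, `significant`, `evaluable`. The
#'   Bonferroni family size is attached as attribute `"m"`.
#' @export
pearson_confounder_screen <- function(covariates, depth_averaged,
                                      alpha = 0.05) {
  per_patient <- dplyr::summarise(
    dplyr::group_by(depth_averaged, patient_id, analyte),
    value = mean(value), .groups = "drop"
  )
  miss <- setdiff(unique(per_patient$patient_id), covariates$patient_id)
  if (length(miss) > 0) {
    stop(sprintf("covariates missing for patient(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cov_num <- tibble::tibble(
    patient_id = covariates$patient_id,
    age = as.numeric(covariates$age),
    sex = as.numeric(factor(covariates$sex, levels = sort(unique(covariates$sex)))) - 1,
    bmi = as.numeric(covariates$bmi)
  )
  analytes <- unique(per_patient$analyte)
  cov_names <- c("age", "sex", "bmi")
  rows <- list()
  for (cv in cov_names) {
    for (an in analytes) {
      sub <- per_patient[per_patient$analyte == an, ]
      x <- cov_num[[cv]][match(sub$patient_id, cov_num$patient_id)]
      y <- sub$value
      keep <- !is.na(x) & !is.na(y)
      x <- x[keep]; y <- y[keep]
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          covariate = cv, analyte = an, r = NA_real_, n = length(x),
          p = NA_real_, evaluable = FALSE)
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        rows[[length(rows) + 1]] <- tibble::tibble(
          covariate = cv, analyte = an, r = unname(ct$estimate),
          n = length(x), p = ct$p.value, evaluable = TRUE)
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  m <- sum(res$evaluable)
  res$p_adj <- pmin(1, m * res$p)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "m") <- m
  res
}
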