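#' Split subjects by chronic-hyperglycemia status
#'
#' Divides a subject table at the guideline HbA1c cutoff: high group iff
#' `hba1c > threshold` (default 7%), otherwise low. A value exactly at
#' the threshold goes to the low group. Subjects with missing HbA1c are
#' excluded with a warning.
#'
#' @param profiles Data frame with at least `subject_id` and `hba1c`.
#' @param threshold HbA1c cutoff (percent). Default 7.
#' @return A list with data frames `low` and `high`.
#' @export
split_by_hba1c <- function(profiles, threshold = 7.0) {
  if (nrow(profiles) == 0) {
    return(list(low = profiles, high = profiles))
  }
  missing <- is.na(profiles$hba1c)
  if (any(missing)) {
    warning(sum(missing), " subject(s) excluded: missing HbA1c")
    profiles <- profiles[!missing, , drop = FALSE]
  }
  high <- profiles$hba1c > threshold
  list(low = profiles[!high, , drop = FALSE],
       high = profiles[high, , drop = FALSE])
}

#' Group summary table of demographics and outcomes
#'
#' Builds a two-group summary in the style of a clinical Table 1:
#' continuous rows as mean +/- SD per group with a Mann-Whitney U
#' p-value, categorical rows as count (percent) per group with a
#' two-sided Fisher exact p-value. The comparison is low-HbA1c vs
#' high-HbA1c; U and mean ranks are reported for the high group.
#'
#' @param profiles Subject table (must contain `hba1c`; demographics
#'   `age`, `sex`, `bmi`, `smoker`, `hypertension` are summarised when
#'   present).
#' @param cvr_results Data frame of per-subject outcomes as returned by
#'   [cvr_metrics()] (rows for both hemispheres).
#' @param covariates Optional data frame of additional per-subject
#'   continuous covariates (e.g. resting MAP, end-tidal CO2); must carry
#'   `subject_id`.
#' @param threshold HbA1c split (percent).
#' @param alpha Significance level used for flagging.
#' @return An object of class `group_summary`: a data frame with one row
#'   per variable and columns `variable`, `type`, `n_low`, `n_high`,
#'   `mean_low`, `sd_low`, `mean_high`, `sd_high`, `count_low`,
#'   `count_high`, `test`, `u`, `z`, `p`, `significant`.
#' @export
summarize_table1 <- function(profiles, cvr_results, covariates = NULL,
                             threshold = 7.0, alpha = 0.05) {
  groups <- split_by_hba1c(profiles, threshold)
  low_ids <- groups$low$subject_id
  high_ids <- groups$high$subject_id

  rows <- list()
  add_continuous <- function(name, low_vals, high_vals) {
    low_vals <- low_vals[!is.na(low_vals)]
    high_vals <- high_vals[!is.na(high_vals)]
    p <- u <- z <- NA_real_
    if (length(low_vals) >= 1 && length(high_vals) >= 1) {
      mw <- mann_whitney(high_vals, low_vals)
      u <- mw$u; z <- mw$z
      p <- if (!is.na(mw$p_exact)) mw$p_exact else mw$p_asymptotic
    }
    rows[[length(rows) + 1]] <<- data.frame(
      variable = name, type = "continuous",
      n_low = length(low_vals), n_high = length(high_vals),
      mean_low = mean(low_vals),
      sd_low = if (length(low_vals) > 1) stats::sd(low_vals) else NA_real_,
      mean_high = mean(high_vals),
      sd_high = if (length(high_vals) > 1) stats::sd(high_vals) else NA_real_,
      count_low = NA_integer_, count_high = NA_integer_,
      test = "mann_whitney", u = u, z = z, p = p,
      significant = !is.na(p) && p < alpha,
      stringsAsFactors = FALSE)
  }
  add_categorical <- function(name, low_flags, high_flags) {
    a <- sum(low_flags, na.rm = TRUE); b <- sum(!low_flags, na.rm = TRUE)
    cc <- sum(high_flags, na.rm = TRUE); d <- sum(!high_flags, na.rm = TRUE)
    p <- fisher_exact_2x2(a, b, cc, d)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = name, type = "categorical",
      n_low = a + b, n_high = cc + d,
      mean_low = NA_real_, sd_low = NA_real_,
      mean_high = NA_real_, sd_high = NA_real_,
      count_low = a, count_high = cc,
      test = "fisher_exact", u = NA_real_, z = NA_real_, p = p,
      significant = p < alpha,
      stringsAsFactors = FALSE)
  }

  for (dem in c("age", "bmi")) {
    if (dem %in% names(profiles)) {
      add_continuous(dem, groups$low[[dem]], groups$high[[dem]])
    }
  }
  if ("sex" %in% names(profiles)) {
    add_categorical("sex_male", groups$low$sex == "male",
                    groups$high$sex == "male")
  }
  for (dem in c("smoker", "hypertension")) {
    if (dem %in% names(profiles)) {
      add_categorical(dem, groups$low[[dem]], groups$high[[dem]])
    }
  }

  if (!is.null(cvr_results) && nrow(cvr_results)) {
    for (hemi in unique(cvr_results$hemisphere)) {
      sub <- cvr_results[cvr_results$hemisphere == hemi, ]
      for (out in c("mcav_rest", "cvr", "pct_change")) {
        lab <- sprintf("%s_%s", out, hemi)
        add_continuous(lab,
                       sub[[out]][sub$subject_id %in% low_ids],
                       sub[[out]][sub$subject_id %in% high_ids])
      }
    }
  }
  if (!is.null(covariates) && nrow(covariates)) {
    for (cv in setdiff(names(covariates), "subject_id")) {
      add_continuous(cv,
                     covariates[[cv]][covariates$subject_id %in% low_ids],
                     covariates[[cv]][covariates$subject_id %in% high_ids])
    }
  }

  out <- do.call(rbind, rows)
  structure(out, class = c("group_summary", "data.frame"),
            alpha = alpha, threshold = threshold)
}
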