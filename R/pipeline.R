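#' Pipeline configuration
#'
#' Collects every analysis constant in one place so sensitivity analyses
#' over the under-specified choices (window anchoring, the RR rule) are
#' single-field edits: censoring thresholds (`rate_max_hz` 5 Hz,
#' `jump_max` 10 cm/s, `discard_threshold` 0.15), the HbA1c split (7%),
#' alpha (0.05), analysis windows (rest `[0, 90)` s, steady state
#' `[180, 270)` s), and the synthetic-cohort parameters.
#'
#' @param synth A [synth_params()] object.
#' @param rate_max_hz,jump_max,discard_threshold Censoring thresholds.
#' @param hba1c_split HbA1c group cutoff (percent).
#' @param alpha Significance level.
#' @param rest_window,ss_window Analysis windows (s), half-open.
#' @param out_dir Optional output directory; when non-`NULL` all
#'   intermediate artifacts (recordings, cleaned series, results, report)
#'   are written there.
#' @param seed Root seed (overrides `synth$seed` when given).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_params(),
                            rate_max_hz = 5.0, jump_max = 10.0,
                            discard_threshold = 0.15,
                            hba1c_split = 7.0, alpha = 0.05,
                            rest_window = c(0, 90),
                            ss_window = c(180, 270),
                            out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) synth$seed <- as.integer(seed)
  cfg <- structure(list(synth = synth, rate_max_hz = rate_max_hz,
                        jump_max = jump_max,
                        discard_threshold = discard_threshold,
                        hba1c_split = hba1c_split, alpha = alpha,
                        rest_window = rest_window, ss_window = ss_window,
                        out_dir = out_dir, seed = synth$seed),
                   class = "pipeline_config")
  v <- validate_config(cfg)
  if (length(v)) stop("invalid configuration:\n  ",
                      paste(v, collapse = "\n  "))
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every configuration invariant and returns the violations (an
#' empty character vector means the configuration is valid).
#'
#' @param config A `pipeline_config` (or a plain list with the same
#'   fields).
#' @return Character vector of violations, each naming the field and the
#'   rule it breaks.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$rate_max_hz > 0, "rate_max_hz: must be positive")
  chk(config$jump_max > 0, "jump_max: must be positive")
  chk(config$discard_threshold > 0 && config$discard_threshold <= 1,
      "discard_threshold: must be in (0, 1]")
  chk(config$hba1c_split > 0, "hba1c_split: must be positive")
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must be in (0, 1)")
  chk(length(config$rest_window) == 2 &&
        config$rest_window[1] < config$rest_window[2],
      "rest_window: must be an increasing pair")
  chk(length(config$ss_window) == 2 &&
        config$ss_window[1] < config$ss_window[2],
      "ss_window: must be an increasing pair")
  if (length(config$rest_window) == 2 && length(config$ss_window) == 2) {
    chk(config$rest_window[2] <= config$ss_window[1] ||
          config$ss_window[2] <= config$rest_window[1],
        "rest_window/ss_window: windows must not overlap")
    if (!is.null(config$synth)) {
      chk(config$ss_window[2] <= config$synth$duration,
          "ss_window: must lie within the recording duration")
    }
  }
  if (!is.null(config$synth)) {
    ok <- tryCatch({validate_synth_params(config$synth); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) v <- c(v, paste0("synth: ", ok))
  }
  v
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synth <- do.call(synth_params, raw$synth %||% list())
  args <- raw[setdiff(names(raw), "synth")]
  do.call(pipeline_config, c(list(synth = synth), args))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$synth <- unclass(out$synth)
  out$out_dir <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates all stages: cohort simulation, per-bout waveform
#' simulation with optional artifact injection, preprocessing (cycle
#' extraction, censoring, discard rule, 2 Hz resampling, 3-s/9-s
#' smoothing), bout averaging, outcome metrics per hemisphere, and the
#' two-group statistical comparison. Deterministic given the
#' configuration seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: a list with `results` (the
#'   per-subject `cvr_result` table), `summary` (a `group_summary`),
#'   `tests` (the hemisphere-wise Mann-Whitney results on CVR), `truth`,
#'   `counts` (subjects in/out, bouts simulated/discarded), `config`, and
#'   `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid configuration: ", paste(viol, collapse = "; "))
  p <- config$synth
  cohort <- simulate_cohort(p)

  results <- list()
  excluded <- character(0)
  bouts_total <- 0L
  bouts_discarded <- 0L
  recordings <- if (!is.null(config$out_dir)) list() else NULL

  for (i in seq_len(nrow(cohort$profiles))) {
    prof <- cohort$profiles[i, ]
    truth <- cohort$truth[cohort$truth$subject_id == prof$subject_id, ]
    per_hemi <- list(stroke_affected = list(), non_affected = list())
    for (b in seq_len(p$n_bouts)) {
      rec <- simulate_recording(prof, truth, p, bout = b)
      if (p$artifact_spike_rate > 0 || p$short_rr_rate > 0) {
        rec <- inject_artifacts(rec, p)
      }
      if (!is.null(recordings)) recordings[[length(recordings) + 1]] <- rec
      bouts_total <- bouts_total + 1L
      for (hemi in names(per_hemi)) {
        pre <- preprocess_recording(rec, hemi, config$rate_max_hz,
                                    config$jump_max,
                                    config$discard_threshold)
        if (pre$discarded) {
          if (hemi == "stroke_affected") bouts_discarded <- bouts_discarded + 1L
        } else {
          per_hemi[[hemi]][[length(per_hemi[[hemi]]) + 1]] <- pre$series
        }
      }
    }
    subject_ok <- TRUE
    for (hemi in names(per_hemi)) {
      if (length(per_hemi[[hemi]]) == 0) {
        subject_ok <- FALSE
        next
      }
      avg <- average_bouts(per_hemi[[hemi]])
      results[[length(results) + 1]] <-
        cvr_metrics(avg, prof$subject_id, "3mo", hemi,
                    config$rest_window, config$ss_window)
    }
    if (!subject_ok) excluded <- c(excluded, prof$subject_id)
  }

  results <- do.call(rbind, results)
  if (is.null(results)) {
    results <- data.frame(subject_id = character(0), visit = character(0),
                          hemisphere = character(0), mcav_rest = numeric(0),
                          mcav_ss = numeric(0), cvr = numeric(0),
                          pct_change = numeric(0))
  }
  ok_ids <- setdiff(cohort$profiles$subject_id, excluded)
  results <- results[results$subject_id %in% ok_ids, , drop = FALSE]
  profiles_ok <- cohort$profiles[cohort$profiles$subject_id %in% ok_ids, ]

  summary <- summarize_table1(profiles_ok, results,
                              threshold = config$hba1c_split,
                              alpha = config$alpha)
  groups <- split_by_hba1c(profiles_ok, config$hba1c_split)
  tests <- lapply(c("stroke_affected", "non_affected"), function(hemi) {
    sub <- results[results$hemisphere == hemi, ]
    high <- sub$cvr[sub$subject_id %in% groups$high$subject_id]
    low <- sub$cvr[sub$subject_id %in% groups$low$subject_id]
    if (length(high) == 0 || length(low) == 0) return(NULL)
    mann_whitney(high, low)
  })
  names(tests) <- c("stroke_affected", "non_affected")

  report <- structure(
    list(results = results, summary = summary, tests = tests,
         truth = cohort$truth, profiles = cohort$profiles,
         counts = list(subjects_in = nrow(cohort$profiles),
                       subjects_out = length(ok_ids),
                       excluded = length(excluded),
                       n_low = nrow(groups$low), n_high = nrow(groups$high),
                       bouts_total = bouts_total,
                       bouts_discarded = bouts_discarded),
         config = config, seed = p$seed),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, recordings, config$out_dir)
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' Write a run report as JSON
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  tests <- lapply(report$tests, function(x) unclass(x))
  jsonlite::write_json(
    list(counts = report$counts,
         seed = report$seed,
         group_sizes = list(low = report$counts$n_low,
                            high = report$counts$n_high),
         cvr_tests = tests,
         summary = as.data.frame(report$summary)),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("CVR pipeline run report\n")
  cat(sprintf("  subjects: %d in, %d analysed (%d excluded); groups %d low / %d high\n",
              x$counts$subjects_in, x$counts$subjects_out,
              x$counts$excluded, x$counts$n_low, x$counts$n_high))
  cat(sprintf("  bouts: %d simulated, %d discarded\n",
              x$counts$bouts_total, x$counts$bouts_discarded))
  for (hemi in names(x$tests)) {
    t <- x$tests[[hemi]]
    if (is.null(t)) next
    cat(sprintf("  CVR %s: U = %g, z = %.3f, p_exact = %.4g\n",
                hemi, t$u, t$z, t$p_exact))
  }
  invisible(x)
}
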