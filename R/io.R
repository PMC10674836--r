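# File I/O: RR / ECG / label CSVs, YAML threshold configuration, JSON
# reports. Conventions enforced everywhere: times in seconds, voltages in
# millivolts, 0-based sample times starting at t = 0.

#' Read / write RR-interval CSV
#'
#' The interchange format is a long CSV with header
#' `record_id, idx, rr_seconds`, one row per interval.
#'
#' @param path File path.
#' @return A tibble with those three columns (`read_rr_csv`), or `path`
#'   invisibly (`write_rr_csv`).
#' @export
read_rr_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) stop("no records in ", path)
  need <- c("record_id", "idx", "rr_seconds")
  if (!all(need %in% names(df))) {
    stop("RR CSV must have header: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$rr_seconds) | df$rr_seconds <= 0)
  if (length(bad)) {
    stop("non-positive rr_seconds at row ", bad[1] + 1L, " of ", path)
  }
  tibble::as_tibble(df[need])
}

#' @param rr Long RR tibble (`record_id`, `idx`, `rr_seconds`) or a cohort
#'   tibble with an `rr` list-column.
#' @rdname read_rr_csv
#' @export
write_rr_csv <- function(rr, path) {
  if ("rr" %in% names(rr) && is.list(rr$rr)) {
    rr <- rr_long(rr)
  }
  readr::write_csv(rr[c("record_id", "idx", "rr_seconds")], path)
  invisible(path)
}

#' Flatten a cohort's RR list-column into a long table
#'
#' @param cohort Tibble with `record_id` and `rr` list-column.
#' @return Long tibble `record_id, idx, rr_seconds`.
#' @export
rr_long <- function(cohort) {
  dplyr::bind_rows(purrr::map2(
    cohort$record_id, cohort$rr,
    function(id, rr) tibble::tibble(record_id = id, idx = rr$idx,
                                    rr_seconds = rr$rr_seconds)
  ))
}

#' Read / write ECG CSV
#'
#' A sampled strip as `t_seconds, mv` with a uniform time grid starting at 0.
#'
#' @param path File path.
#' @param sampling_rate Hz; inferred from the time column when omitted.
#' @return An `ecg_record` (`read_ecg_csv`), or `path` invisibly.
#' @export
read_ecg_csv <- function(path, sampling_rate = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t_seconds", "mv") %in% names(df))) {
    stop("ECG CSV must have header: t_seconds, mv")
  }
  if (nrow(df) < 2) stop("no samples in ", path)
  dt <- diff(df$t_seconds)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  fs <- sampling_rate %||% (1 / stats::median(dt))
  if (any(abs(dt - 1 / fs) > 0.25 / fs)) {
    stop("time gaps: the time grid is not uniform at ", round(fs), " Hz")
  }
  out <- tibble::as_tibble(df[c("t_seconds", "mv")])
  class(out) <- c("ecg_record", class(out))
  attr(out, "sampling_rate") <- fs
  attr(out, "duration") <- nrow(out) / fs
  out
}

#' @param record An `ecg_record` or a `t_seconds, mv` data frame.
#' @rdname read_ecg_csv
#' @export
write_ecg_csv <- function(record, path) {
  readr::write_csv(tibble::as_tibble(record)[c("t_seconds", "mv")], path)
  invisible(path)
}

#' Read a labels CSV
#'
#' Header `record_id, label` with an optional `aw_verdict` column holding an
#' external classifier's verdicts (`AF` / `NOT_AF` / `INCONCLUSIVE`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_labels_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("record_id", "label") %in% names(df))) {
    stop("labels CSV must have header: record_id, label")
  }
  if (anyDuplicated(df$record_id)) stop("record_id values must be unique")
  tibble::as_tibble(df)
}

config_keys <- function() {
  c("count_rr_max", "svd_ratio_max", "required_cluster_count",
    "min_centroid_distance", "max_cluster_width", "k_max",
    "min_cluster_size", "n_restarts", "seed", "distance_method")
}

#' Read / write the thresholds YAML configuration
#'
#' Any key may be omitted (its default applies); unknown keys are rejected
#' with a spelling suggestion, guarding against silently ignored typos.
#'
#' @param path YAML file path.
#' @return A [decision_thresholds()] object (`read_config`), or `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- config_keys()
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    d <- drop(utils::adist(unknown[1], known, partial = TRUE)) / nchar(known)
    stop("unknown config key '", unknown[1], "'; did you mean '",
         known[which.min(d)], "'?")
  }
  cl_keys <- intersect(names(cfg), setdiff(known, c(
    "count_rr_max", "svd_ratio_max", "required_cluster_count")))
  cp <- do.call(cluster_params, cfg[cl_keys])
  th_keys <- intersect(names(cfg),
                       c("count_rr_max", "svd_ratio_max",
                         "required_cluster_count"))
  do.call(decision_thresholds, c(cfg[th_keys], list(cluster_params = cp)))
}

#' @param thresholds A [decision_thresholds()] object.
#' @rdname read_config
#' @export
write_config <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  cp <- thresholds$cluster_params
  yaml::write_yaml(list(
    count_rr_max = thresholds$count_rr_max,
    svd_ratio_max = thresholds$svd_ratio_max,
    required_cluster_count = thresholds$required_cluster_count,
    min_centroid_distance = cp$min_centroid_distance,
    max_cluster_width = cp$max_cluster_width,
    k_max = cp$k_max,
    min_cluster_size = cp$min_cluster_size,
    n_restarts = cp$n_restarts,
    seed = cp$seed,
    distance_method = cp$distance_method
  ), path)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Writes `rr.csv` (long RR table), one `ecg_<record_id>.csv` per record when
#' sampled ECGs are present, and `manifest.json` with the label, seed and
#' ground-truth R times of every record.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rr_csv(cohort, file.path(dir, "rr.csv"))
  manifest <- purrr::pmap(
    list(cohort$record_id, cohort$label, cohort$seed,
         if ("ecg" %in% names(cohort)) cohort$ecg else
           vector("list", nrow(cohort))),
    function(id, label, seed, ecg) {
      entry <- list(record_id = id, label = label, seed = seed)
      if (!is.null(ecg)) {
        f <- paste0("ecg_", id, ".csv")
        write_ecg_csv(ecg, file.path(dir, f))
        entry$ecg_file <- f
        entry$sampling_rate <- attr(ecg, "sampling_rate")
        entry$true_r_times <- attr(ecg, "true_r_times")
      }
      entry
    }
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
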