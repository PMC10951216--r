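#' Write a PPG record to CSV plus a JSON sidecar
#'
#' The samples go to `<prefix>.csv` with columns `time_s, value`; sampling
#' rate, polarity, seed and the ground-truth beat annotations (when present)
#' go to `<prefix>.json`.
#'
#' @param record a `ppg_record`.
#' @param prefix file path prefix (without extension).
#' @return invisibly, the two file paths written.
#' @export
write_ppg_record <- function(record, prefix) {
  stopifnot(inherits(record, "ppg_record"))
  csv_path <- paste0(prefix, ".csv")
  json_path <- paste0(prefix, ".json")
  n <- length(record$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / record$fs, value = record$samples),
    csv_path, row.names = FALSE)
  meta <- list(fs = record$fs, polarity = record$polarity,
               seed = record$seed, duration = record$duration,
               id = record$id %||% NA_character_,
               morphology_class = record$morphology_class %||% NA_integer_,
               truth = record$truth)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a PPG record written by [write_ppg_record]
#'
#' @param prefix file path prefix (without extension).
#' @return a `ppg_record`.
#' @export
read_ppg_record <- function(prefix) {
  dat <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  truth <- meta$truth
  if (!is.null(truth)) truth <- as.data.frame(truth)
  structure(
    list(samples = dat$value, fs = as.numeric(meta$fs),
         duration = as.numeric(meta$duration %||% (nrow(dat) / meta$fs)),
         polarity = meta$polarity, truth = truth, seed = meta$seed,
         id = if (is.null(meta$id) || is.na(meta$id)) NULL else meta$id,
         morphology_class = meta$morphology_class),
    class = "ppg_record"
  )
}
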