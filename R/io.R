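# Plain-text IO: tidy trace CSVs with JSON ground-truth sidecars, titration
# CSVs, and JSON reports.

#' Write a simulated ensemble to CSV (+ JSON ground-truth sidecar)
#' @param ensemble output of [simulate_ensemble()].
#' @param path CSV path for the tidy trace table; the ground truth is
#'   written next to it as `<path>.truth.json`.
#' @export
write_traces <- function(ensemble, path) {
  write.csv(ensemble$traces, path, row.names = FALSE)
  jsonlite::write_json(ensemble$ground_truth, paste0(path, ".truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(path)
}

#' Read a tidy trace CSV (columns molecule_id, frame, time_s, I_D, I_A)
#' @param path CSV path.
#' @export
read_traces <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "time_s", "I_D", "I_A")
  if (!all(need %in% names(tr)))
    stop(sprintf("trace CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  tr
}

#' Write / read titration tables (replicate_id, concentration_M, fraction_bound)
#' @param titration data.frame as produced by [simulate_titration()].
#' @param path CSV path.
#' @export
write_titration <- function(titration, path) {
  write.csv(titration, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  tt <- read.csv(path, stringsAsFactors = FALSE)
  if ("bound_signal" %in% names(tt) && !"fraction_bound" %in% names(tt)) {
    tt$fraction_bound <- compute_fraction_bound(tt$bound_signal, tt$unbound_signal)
    if (!"replicate_id" %in% names(tt)) tt$replicate_id <- "rep_1"
  }
  need <- c("concentration_M", "fraction_bound")
  if (!all(need %in% names(tt)))
    stop("titration CSV must carry concentration_M and fraction_bound ",
         "(or bound_signal/unbound_signal)", call. = FALSE)
  tt
}
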