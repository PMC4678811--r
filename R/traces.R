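# Trace-level analysis: apparent FRET, photobleach step detection,
# single-molecule QC and static/dynamic classification.

#' Apparent FRET efficiency of a two-channel trace
#'
#' Computes the proximity ratio `I_A / (I_A + I_D)` per frame. No gamma,
#' crosstalk or background-trend correction is applied: the quantity is the
#' *apparent* FRET efficiency. Frames whose total intensity falls below the
#' validity threshold (background, post-bleach) are flagged undefined, not
#' dropped, so frame indexing is preserved.
#'
#' @param trace data.frame with columns `molecule_id`, `frame`, `time_s`,
#'   `I_D`, `I_A` for a single molecule.
#' @param threshold total-intensity validity threshold; by default
#'   `3 * sigma_bg` where `sigma_bg` is a robust noise estimate from first
#'   differences of the total intensity (`mad(diff(total)) / sqrt(2)`).
#' @return object of class `fret_trace`: list with per-frame `fret`,
#'   `total`, `valid`, and QC fields (`bleach_frame`, `n_total_steps`,
#'   `qc_pass`, `qc_reason`, `is_static`, `mean_fret`) filled by
#'   [qc_select()] / [classify_static()].
#' @export
compute_fret <- function(trace, threshold = NULL) {
  stopifnot(all(c("I_D", "I_A") %in% names(trace)), nrow(trace) >= 1L)
  total <- trace$I_D + trace$I_A
  if (is.null(threshold)) {
    sigma_bg <- mad(diff(total)) / sqrt(2)
    threshold <- 3 * sigma_bg
  }
  valid <- total > threshold
  fret <- ifelse(valid, trace$I_A / total, NA_real_)
  structure(list(molecule_id = trace$molecule_id[1],
                 frame = trace$frame,
                 time_s = trace$time_s,
                 I_A = trace$I_A,
                 fret = fret,
                 total = total,
                 valid = valid,
                 threshold = threshold,
                 bleach_frame = NA_integer_,
                 n_total_steps = NA_integer_,
                 qc_pass = NA,
                 qc_reason = NA_character_,
                 is_static = NA,
                 mean_fret = NA_real_),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace %s: %d frames, qc_pass=%s, static=%s, mean FRET=%s>\n",
              x$molecule_id, length(x$fret), x$qc_pass, x$is_static,
              ifelse(is.na(x$mean_fret), "NA", sprintf("%.3f", x$mean_fret))))
  invisible(x)
}

#' Penalized least-squares step detection
#'
#' Segments a signal into piecewise-constant pieces by minimizing the
#' residual sum of squares plus `penalty` per change point (exact global
#' optimum via optimal partitioning with PELT pruning). The default penalty
#' is `5 * sigma^2 * log(n)` with `sigma` estimated robustly from first
#' differences; for a noiseless signal a vanishing positive penalty is
#' substituted so that exact steps are found and a constant signal yields
#' none.
#'
#' @param signal numeric vector, length >= 10.
#' @param penalty per-change-point penalty; `NULL` for the default.
#' @param min_size minimum segment length in frames.
#' @return object of class `step_fit`: `change_points` (first frame of each
#'   new segment, 1-based), `segment_means`, `penalty`, `objective`.
#' @export
detect_steps <- function(signal, penalty = NULL, min_size = 2L) {
  n <- length(signal)
  stopifnot(n >= 10L)
  if (is.null(penalty)) {
    sigma <- mad(diff(signal)) / sqrt(2)
    penalty <- 5 * sigma^2 * log(n)
    if (penalty <= 0)
      penalty <- 1e-8 * max(1, diff(range(signal))^2)
  }
  last_idx <- pelt_mean_cpp(as.numeric(signal), penalty, as.integer(min_size))
  bounds <- c(0L, last_idx, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(signal[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  rss <- sum(vapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- signal[(bounds[i] + 1L):bounds[i + 1L]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  structure(list(change_points = as.integer(last_idx + 1L),
                 segment_means = means,
                 penalty = penalty,
                 objective = rss + penalty * length(last_idx)),
            class = "step_fit")
}

#' Default QC policy for single-molecule selection
#'
#' @param min_prebleach_frames minimum frames before the first bleach event
#'   required to estimate a molecule's FRET.
#' @param background_frac a segment counts as background when its mean is
#'   below this fraction of the initial (first-segment) level of the
#'   channel being tested.
#' @export
qc_policy <- function(min_prebleach_frames = 10L,
                      background_frac = 0.35) {
  structure(list(min_prebleach_frames = as.integer(min_prebleach_frames),
                 background_frac = background_frac),
            class = "qc_policy")
}

.qc_one <- function(ft, policy) {
  n <- length(ft$total)
  steps_total <- detect_steps(ft$total)
  ft$n_total_steps <- length(steps_total$change_points)
  bg_level <- policy$background_frac * steps_total$segment_means[1]

  fail <- function(reason) {
    ft$qc_pass <- FALSE
    ft$qc_reason <- reason
    ft
  }
  if (ft$n_total_steps == 0L) return(fail("no_bleach_in_window"))
  if (ft$n_total_steps > 1L) return(fail("multiple_total_steps"))
  final_mean <- steps_total$segment_means[2]
  if (final_mean >= steps_total$segment_means[1]) return(fail("step_not_downward"))
  if (final_mean > bg_level) return(fail("final_segment_not_background"))

  donor_bleach <- steps_total$change_points[1]

  # acceptor-first bleaching: an earlier down-step of I_A to background
  # while total stays up; only the pre-donor-bleach stretch can carry it.
  # FRET transitions of a dynamic molecule also step I_A, so only a step
  # that lands at acceptor background counts as a bleach.
  acceptor_bleach <- NA_integer_
  if (donor_bleach > 11L) {
    steps_A <- detect_steps(ft$I_A[seq_len(donor_bleach - 1L)])
    bg_A <- policy$background_frac * steps_A$segment_means[1]
    for (i in seq_along(steps_A$change_points)) {
      if (steps_A$segment_means[i + 1] < min(bg_A, steps_A$segment_means[i])) {
        acceptor_bleach <- steps_A$change_points[i]
        break
      }
    }
  }
  bleach <- if (is.na(acceptor_bleach)) donor_bleach else min(donor_bleach, acceptor_bleach)
  pre <- seq_len(bleach - 1L)
  ok <- pre[ft$valid[pre]]
  if (length(ok) < policy$min_prebleach_frames) return(fail("short_prebleach"))

  ft$bleach_frame <- as.integer(bleach)
  ft$mean_fret <- mean(ft$fret[ok])
  ft$qc_pass <- TRUE
  ft$qc_reason <- "pass"
  ft
}

#' Select single-step-photobleaching molecules
#'
#' A molecule passes QC when its total-intensity trajectory shows exactly
#' one dominant downward step to background within the recording (the donor
#' bleach); an earlier acceptor bleach step in the acceptor channel is
#' permitted and moves the truncation point forward. The mean FRET is
#' computed strictly over valid frames before the first bleach event.
#' Aggregates (multiple total-intensity steps) and molecules that never
#' bleach (single-molecule status unverifiable) are rejected.
#'
#' @param traces tidy data.frame of one or more molecules (columns
#'   `molecule_id`, `frame`, `time_s`, `I_D`, `I_A`), or a list of
#'   single-molecule data.frames.
#' @param policy a [qc_policy()].
#' @return list of `fret_trace` objects with QC fields filled; attribute
#'   `"reason_tally"` counts outcomes. An ensemble with no survivors is
#'   returned as an (annotated) empty-pass result, not an error.
#' @export
qc_select <- function(traces, policy = qc_policy()) {
  if (is.data.frame(traces))
    traces <- split(traces, traces$molecule_id)
  stopifnot(length(traces) >= 1L)
  out <- lapply(traces, function(tr) .qc_one(compute_fret(tr), policy))
  names(out) <- vapply(out, `[[`, character(1), "molecule_id")
  tally <- table(vapply(out, `[[`, character(1), "qc_reason"))
  attr(out, "reason_tally") <- tally
  out
}

#' Classify a QC-passed trace as static or dynamic
#'
#' A trace is dynamic when the pre-bleach FRET series contains a change
#' point separating segments whose means differ by at least `delta`, with
#' both segments at least `min_dwell` frames long. The defaults (`delta`
#' 0.1 FRET, `min_dwell` 10 frames) correspond to the smallest distinction
#' the ensemble histograms resolve.
#'
#' @param ft a QC-passed `fret_trace`.
#' @param min_dwell minimum dwell, frames.
#' @param delta minimum FRET jump, dimensionless.
#' @return the `fret_trace` with `is_static` set (`NA`, flagged, when the
#'   pre-bleach region is shorter than `2 * min_dwell`).
#' @export
classify_static <- function(ft, min_dwell = 10L, delta = 0.1) {
  stopifnot(inherits(ft, "fret_trace"), isTRUE(ft$qc_pass))
  pre <- seq_len(ft$bleach_frame - 1L)
  x <- ft$fret[pre][ft$valid[pre]]
  if (length(x) < 2L * min_dwell) {
    ft$is_static <- NA
    ft$qc_reason <- "prebleach_too_short_for_dynamics"
    return(ft)
  }
  sf <- detect_steps(x, min_size = 2L)
  bounds <- c(0L, sf$change_points - 1L, length(x))
  lens <- diff(bounds)
  dynamic <- FALSE
  for (i in seq_along(sf$change_points)) {
    if (abs(sf$segment_means[i + 1] - sf$segment_means[i]) >= delta &&
        lens[i] >= min_dwell && lens[i + 1] >= min_dwell) {
      dynamic <- TRUE
      break
    }
  }
  ft$is_static <- !dynamic
  ft
}

#' Apply static/dynamic classification across an ensemble
#' @param fts list of `fret_trace` objects from [qc_select()].
#' @inheritParams classify_static
#' @export
classify_static_ensemble <- function(fts, min_dwell = 10L, delta = 0.1) {
  out <- lapply(fts, function(ft) {
    if (isTRUE(ft$qc_pass)) classify_static(ft, min_dwell, delta) else ft
  })
  attr(out, "reason_tally") <- attr(fts, "reason_tally")
  out
}

#' Summarize an ensemble of fret_traces as a per-molecule QC table
#' @param fts list of `fret_trace` objects.
#' @export
qc_table <- function(fts) {
  do.call(rbind, lapply(fts, function(ft) {
    data.frame(molecule_id = ft$molecule_id,
               qc_pass = isTRUE(ft$qc_pass),
               qc_reason = ft$qc_reason,
               bleach_frame = ft$bleach_frame,
               n_total_steps = ft$n_total_steps,
               is_static = ft$is_static,
               mean_fret = ft$mean_fret,
               stringsAsFactors = FALSE)
  }))
}
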