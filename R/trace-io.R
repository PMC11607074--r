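#' Write intensity traces to a delimited table
#'
#' Long-format CSV with the column schema (trace_id, frame, time_s, donor,
#' acceptor); one row per frame.  The round trip through
#' \code{\link{read_traces}} is lossless for these fields.
#'
#' @param traces list of \code{intensity_trace} objects
#' @param path output file
#' @export
write_traces <- function(traces, path) {
  tabs <- lapply(traces, function(tr) {
    data.frame(trace_id = attr(tr, "trace_id"), tr[, c("frame", "time_s",
               "donor", "acceptor")], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read intensity traces from a delimited table
#'
#' Expects the schema written by \code{\link{write_traces}}.  A missing
#' required column raises a schema error naming it; a trace whose frame
#' times are not a uniform grid is kept but flagged (attribute
#' \code{rejected}) with a warning.
#'
#' @param path input CSV file
#' @return named list of \code{intensity_trace} objects
#' @export
read_traces <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trace_id", "frame", "time_s", "donor", "acceptor")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(d, d$trace_id), function(g) {
    g <- g[order(g$frame), ]
    dt <- diff(g$time_s)
    exposure <- stats::median(dt)
    bad <- length(dt) > 0 && any(abs(dt - exposure) > 1e-6 * max(exposure, 1))
    if (bad) warning("non-uniform frame spacing in trace ", g$trace_id[1])
    structure(data.frame(frame = g$frame, time_s = g$time_s,
                         donor = g$donor, acceptor = g$acceptor),
              exposure = exposure, trace_id = g$trace_id[1],
              rejected = bad, class = c("intensity_trace", "data.frame"))
  })
  out[unique(d$trace_id)]
}

#' FRET efficiency from a two-channel intensity trace
#'
#' E = (IA - beta ID - bgA) / ((IA - beta ID - bgA) + gamma (ID - bgD)).
#' The defaults (gamma = 1, beta = 0, zero backgrounds) give the
#' uncorrected proximity ratio, which is what the TIRF state levels are
#' reported in.  Frames whose corrected denominator is <= 0 are flagged
#' invalid rather than clipped.
#'
#' @param trace an \code{intensity_trace}
#' @param gamma detection-correction factor (> 0)
#' @param beta donor-to-acceptor crosstalk factor
#' @param bg_donor,bg_acceptor per-frame background counts
#' @return a \code{fret_trace}: data frame (frame, time_s, E, valid) with
#'   trace_id, exposure and valid_range attributes
#' @export
compute_fret <- function(trace, gamma = 1, beta = 0, bg_donor = 0,
                         bg_acceptor = 0) {
  if (gamma <= 0) stop("gamma must be > 0")
  a <- trace$acceptor - beta * trace$donor - bg_acceptor
  d <- trace$donor - bg_donor
  den <- a + gamma * d
  valid <- is.finite(den) & den > 0
  E <- rep(NA_real_, length(den))
  E[valid] <- a[valid] / den[valid]
  vr <- attr(trace, "valid_range")
  if (is.null(vr)) vr <- c(1L, nrow(trace))
  structure(data.frame(frame = trace$frame, time_s = trace$time_s,
                       E = E, valid = valid),
            trace_id = attr(trace, "trace_id"),
            exposure = attr(trace, "exposure"),
            valid_range = vr,
            class = c("fret_trace", "data.frame"))
}

# Single-step bleach detection on one channel: the first windowed median
# jump (median of the following `window` frames minus median of the
# preceding `window` frames) that exceeds `threshold` times the
# frame-to-frame noise SD, takes the channel from clear signal to
# background, and leaves it there.  State-to-state FRET changes also
# produce large drops but fail the stays-at-background condition.
# Returns the last good frame, or NA.
detect_bleach_step <- function(x, threshold = 3, window = 5) {
  n <- length(x)
  if (n < 4 * window) return(NA_integer_)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) return(NA_integer_)
  idx <- window:(n - window)
  pre <- vapply(idx, function(j) stats::median(x[(j - window + 1):j]), 0)
  post <- vapply(idx, function(j) stats::median(x[(j + 1):(j + window)]), 0)
  jump <- post - pre
  cand <- idx[jump < -threshold * sigma]
  for (j in cand) {
    tail_med <- stats::median(x[min(n, j + window):min(n, j + window + 20)])
    pre_med <- stats::median(x[max(1, j - window - 20):j])
    if (tail_med < 2 * sigma && pre_med > 3 * sigma) {
      # refine to the sharpest drop near the window hit that actually
      # lands at background (state-to-state drops do not)
      w <- max(2, j - window):min(n - 1, j + window + 20)
      lands <- w[x[w + 1] < 3 * sigma]
      if (!length(lands)) lands <- w
      return(as.integer(lands[which.min(x[lands + 1] - x[lands])]))
    }
  }
  NA_integer_
}

#' Filter criteria for trace-level quality control
#'
#' The defaults are declared, overridable choices: at least 100 frames,
#' mean total intensity above half the dataset median, no single-bleach
#' requirement, and truncation at the first detected single-step donor or
#' acceptor bleach.
#'
#' @param min_length minimum number of frames in the valid range
#' @param min_total_intensity absolute threshold on mean total counts, or
#'   \code{NULL} for half the dataset median (resolved per call)
#' @param max_E_excursion optional cap on |E| computed as proximity ratio;
#'   traces exceeding it are rejected as outliers
#' @param min_mean_E reject traces whose mean proximity ratio over the
#'   valid range is below this: donor-only (zero-FRET) molecules carry no
#'   acceptor information and are excluded from FRET analysis
#' @param require_single_bleach if TRUE, keep only traces where a bleach
#'   step was found
#' @param truncate_bleach truncate the valid range at a detected bleach
#' @param bleach_threshold step-detection threshold in noise-SD units
#' @export
filter_criteria <- function(min_length = 100, min_total_intensity = NULL,
                            max_E_excursion = 1.5, min_mean_E = 0.05,
                            require_single_bleach = FALSE,
                            truncate_bleach = TRUE, bleach_threshold = 3) {
  list(min_length = min_length, min_total_intensity = min_total_intensity,
       max_E_excursion = max_E_excursion, min_mean_E = min_mean_E,
       require_single_bleach = require_single_bleach,
       truncate_bleach = truncate_bleach,
       bleach_threshold = bleach_threshold)
}

#' Apply trace-level quality filters
#'
#' Deterministic: every rejection carries a machine-readable reason.
#' Bleach truncation sets the valid range of a kept trace to the frames
#' before the first detected single-step acceptor or donor bleach; the
#' detector only examines the current valid range, so filtering the kept
#' set again changes nothing.
#'
#' @param traces list of \code{intensity_trace} objects
#' @param criteria a \code{\link{filter_criteria}} list
#' @return list with \code{kept} (traces carrying a valid_range attribute)
#'   and \code{rejected} (data frame of trace_id, reason)
#' @export
filter_traces <- function(traces, criteria = filter_criteria()) {
  if (length(traces) == 0)
    return(list(kept = list(),
                rejected = data.frame(trace_id = character(0),
                                      reason = character(0))))
  mean_tot <- vapply(traces, function(tr) {
    vr <- attr(tr, "valid_range"); if (is.null(vr)) vr <- c(1L, nrow(tr))
    idx <- vr[1]:vr[2]
    mean(tr$donor[idx] + tr$acceptor[idx])
  }, 0)
  thr <- criteria$min_total_intensity
  if (is.null(thr)) thr <- stats::median(mean_tot) / 2
  kept <- list(); rid <- character(0); rwhy <- character(0)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    id <- attr(tr, "trace_id")
    vr <- attr(tr, "valid_range"); if (is.null(vr)) vr <- c(1L, nrow(tr))
    bleach_seen <- isTRUE(attr(tr, "bleach_detected"))
    if (criteria$truncate_bleach) {
      idx <- vr[1]:vr[2]
      j_a <- detect_bleach_step(tr$acceptor[idx], criteria$bleach_threshold)
      tot <- tr$donor[idx] + tr$acceptor[idx]
      j_t <- detect_bleach_step(tot, criteria$bleach_threshold)
      j <- suppressWarnings(min(c(j_a, j_t), na.rm = TRUE))
      if (is.finite(j)) {
        vr[2] <- vr[1] + as.integer(j) - 1L
        bleach_seen <- TRUE
      }
    }
    n_valid <- vr[2] - vr[1] + 1
    reason <- NULL
    if (n_valid < criteria$min_length) reason <- "short"
    else if (mean_tot[i] < thr) reason <- "dim"
    else {
      idx <- vr[1]:vr[2]
      tot <- tr$donor[idx] + tr$acceptor[idx]
      E <- ifelse(tot > 0, tr$acceptor[idx] / tot, 0)
      if (!is.null(criteria$max_E_excursion) &&
          any(abs(E) > criteria$max_E_excursion, na.rm = TRUE))
        reason <- "E_excursion"
      else if (!is.null(criteria$min_mean_E) &&
               mean(E, na.rm = TRUE) < criteria$min_mean_E)
        reason <- "donor_only"
    }
    if (is.null(reason) && criteria$require_single_bleach && !bleach_seen)
      reason <- "no_bleach_step"
    if (is.null(reason)) {
      attr(tr, "valid_range") <- vr
      attr(tr, "bleach_detected") <- bleach_seen
      kept[[id]] <- tr
    } else {
      rid <- c(rid, id); rwhy <- c(rwhy, reason)
    }
  }
  list(kept = kept,
       rejected = data.frame(trace_id = rid, reason = rwhy,
                             stringsAsFactors = FALSE))
}
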