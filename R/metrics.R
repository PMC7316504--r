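# Detection/termination metrics computed from a saved record: channel
# activation time, tissue synchronization and reset durations, rhythm
# classification and per-node cycle length. All metrics work from the
# record alone (per-frame summaries, activation log, probe traces).

#' Channel activation time
#'
#' First time at which the spatial maximum of the absolute channel current
#' exceeds `current_threshold`, relative to the arrhythmia onset stored in
#' the record (by convention the S2 time).
#'
#' @param record a `bioicd_record`.
#' @param current_threshold pA/pF, default 1.
#' @param absolute return the absolute time instead of onset-relative.
#' @return Time in ms, or `NA` if the channel never activates (or is off).
#' @export
activation_time <- function(record, current_threshold = 1, absolute = FALSE) {
  if (!record$bioicd) return(NA_real_)
  fr <- record$frames
  if (is.null(fr) || !nrow(fr)) stop("record carries no frame summaries")
  hit <- which(fr$max_ibio > current_threshold)
  if (!length(hit)) return(NA_real_)
  t_abs <- fr$time[hit[1]]
  if (absolute) t_abs else t_abs - record$onset
}

#' Synchronization and reset durations
#'
#' Synchronization: time from channel activation until at least
#' `sync_level` of myocyte nodes are simultaneously depolarized beyond the
#' record's `sync_v` threshold. Reset: time from activation until at least
#' `reset_level` of nodes are repolarized below `reset_v`. Thresholds used
#' for the stored fractions are fixed at run time (config-exposed); pass
#' different voltage thresholds only when snapshots are present.
#'
#' @param record a `bioicd_record`.
#' @param sync_level,reset_level node fractions (defaults 0.95, 0.99).
#' @param current_threshold activation threshold (pA/pF).
#' @return List with `activation` (absolute ms), `sync_duration`,
#'   `reset_duration` (ms, `NA` when never reached).
#' @export
synchronization_and_reset <- function(record, sync_level = 0.95,
                                      reset_level = 0.99,
                                      current_threshold = 1) {
  t_act <- activation_time(record, current_threshold, absolute = TRUE)
  fr <- record$frames
  if (is.na(t_act))
    return(list(activation = NA_real_, sync_duration = NA_real_,
                reset_duration = NA_real_))
  after <- fr$time >= t_act
  s <- which(after & fr$frac_sync >= sync_level)
  sync_dur <- if (length(s)) fr$time[s[1]] - t_act else NA_real_
  r <- which(after & fr$frac_reset >= reset_level)
  reset_dur <- if (length(r)) fr$time[r[1]] - t_act else NA_real_
  list(activation = t_act, sync_duration = sync_dur,
       reset_duration = reset_dur)
}

#' Classify the rhythm in a time window
#'
#' Reads the probe traces and the activation log over the final `window` ms
#' (or an explicit interval): `sinus_1to1` if every pacing stimulus elicits
#' exactly one activation at each probe and no unstimulated activations
#' occur; `reentry` if activations occur without stimuli (or at a shorter
#' cycle length than pacing); `quiescent` if there are no upstrokes;
#' `depolarized_block` if the voltage stays above -20 mV throughout.
#'
#' @param record a `bioicd_record`.
#' @param window window length (ms) ending at the record end.
#' @param interval optional explicit `c(t_from, t_to)` (overrides `window`).
#' @param capture_delay_ms max stimulus-to-upstroke delay counted as capture.
#' @return One of `"sinus_1to1"`, `"reentry"`, `"quiescent"`,
#'   `"depolarized_block"`.
#' @export
rhythm_classifier <- function(record, window = 2000, interval = NULL,
                              capture_delay_ms = 150) {
  tend <- max(record$probes$time)
  if (is.null(interval)) interval <- c(tend - window, tend)
  if (interval[1] < min(record$probes$time) - 1e-6)
    stop("window exceeds the record")
  sel <- record$probes$time >= interval[1] & record$probes$time <= interval[2]
  vwin <- record$probes$v[sel, , drop = FALSE]
  if (all(vwin > -20)) return("depolarized_block")
  stims <- stim_times(record, label = "pacing")
  stims <- stims[stims >= interval[1] & stims <= interval[2] - capture_delay_ms]
  probe_nodes <- record$probes$index
  acts <- record$activations
  ok_1to1 <- length(stims) > 0
  any_act <- FALSE
  for (pn in probe_nodes) {
    at <- acts$time[acts$node == pn & acts$time >= interval[1] &
                      acts$time <= interval[2]]
    any_act <- any_act || length(at) > 0
    if (!ok_1to1) next
    captured <- vapply(stims, function(s)
      sum(at >= s & at <= s + capture_delay_ms) == 1, logical(1))
    extra <- vapply(at, function(a)
      !any(a >= stims & a <= stims + capture_delay_ms), logical(1))
    ok_1to1 <- all(captured) && !any(extra)
  }
  if (ok_1to1) return("sinus_1to1")
  if (!any_act) return("quiescent")
  "reentry"
}

#' Per-node cycle-length map
#'
#' Median inter-activation interval per node from the record's activation
#' log (upstrokes: -20 mV upward crossings with a 50 ms lockout). Nodes
#' with fewer than `min_activations` activations are `NA`.
#'
#' @param record a `bioicd_record`.
#' @param interval optional `c(t_from, t_to)` restriction.
#' @param min_activations minimum activations per node (default 3).
#' @return An `nx` by `ny` matrix of cycle lengths (ms).
#' @export
cycle_length_map <- function(record, interval = NULL, min_activations = 3) {
  acts <- record$activations
  if (!is.null(interval))
    acts <- acts[acts$time >= interval[1] & acts$time <= interval[2], ]
  n <- record$substrate$nx * record$substrate$ny
  out <- rep(NA_real_, n)
  if (nrow(acts)) {
    sp <- split(acts$time, acts$node)
    keep <- vapply(sp, length, integer(1)) >= min_activations
    cl <- vapply(sp[keep], function(tt) stats::median(diff(sort(tt))),
                 numeric(1))
    out[as.integer(names(cl))] <- cl
  }
  matrix(out, record$substrate$nx, record$substrate$ny)
}

#' Restoration time of 1:1 paced rhythm
#'
#' The first pacing stimulus from which every subsequent pacing stimulus in
#' the record elicits exactly one activation at each probe with no
#' unstimulated activations in between, requiring at least `min_beats`
#' such beats. Returns the time of that stimulus.
#'
#' @param record a `bioicd_record`.
#' @param min_beats minimum consecutive 1:1 beats (default 2).
#' @param capture_delay_ms as in [rhythm_classifier()].
#' @return Absolute time (ms) or `NA`.
#' @export
restoration_time <- function(record, min_beats = 2, capture_delay_ms = 150) {
  stims <- stim_times(record, label = "pacing")
  tend <- max(record$probes$time)
  stims <- stims[stims <= tend - capture_delay_ms]
  if (length(stims) < min_beats) return(NA_real_)
  acts <- record$activations
  probe_nodes <- record$probes$index
  for (k in seq_along(stims)) {
    if (length(stims) - k + 1 < min_beats) break
    t_from <- stims[k]
    ok <- TRUE
    for (pn in probe_nodes) {
      at <- acts$time[acts$node == pn & acts$time >= t_from &
                        acts$time <= tend]
      later <- stims[k:length(stims)]
      captured <- vapply(later, function(s)
        sum(at >= s & at <= s + capture_delay_ms) == 1, logical(1))
      extra <- vapply(at, function(a)
        !any(a >= later & a <= later + capture_delay_ms), logical(1))
      if (!(all(captured) && !any(extra))) { ok <- FALSE; break }
    }
    if (ok) return(t_from)
  }
  NA_real_
}

#' Full termination report
#'
#' Combines the timing metrics into one report: onset (S2), channel
#' activation delay, synchronization and reset durations, whether 1:1 paced
#' rhythm was restored, and the total onset-to-restoration time.
#'
#' @param record a `bioicd_record`.
#' @param sync_level,reset_level,current_threshold metric conventions.
#' @return An object of class `termination_report` (named list).
#' @export
termination_report <- function(record, sync_level = 0.95, reset_level = 0.99,
                               current_threshold = 1) {
  sr <- synchronization_and_reset(record, sync_level, reset_level,
                                  current_threshold)
  t_rest <- restoration_time(record)
  restored <- !is.na(t_rest) && !is.na(sr$reset_duration) &&
    t_rest > sr$activation
  structure(list(
    arrhythmia_onset = record$onset,
    bioicd_activation_time = if (is.na(sr$activation)) NA_real_
                             else sr$activation - record$onset,
    synchronization_duration = sr$sync_duration,
    reset_duration = sr$reset_duration,
    restored = restored,
    total_time_onset_to_restoration =
      if (restored) t_rest - record$onset else NA_real_),
    class = "termination_report")
}

#' @export
print.termination_report <- function(x, ...) {
  cat("Arrhythmia termination report\n")
  cat(sprintf("  onset (S2):              %8.1f ms\n", x$arrhythmia_onset))
  cat(sprintf("  channel activation:      %8.1f ms after onset\n",
              x$bioicd_activation_time))
  cat(sprintf("  synchronization:         %8.1f ms after activation\n",
              x$synchronization_duration))
  cat(sprintf("  reset:                   %8.1f ms after activation\n",
              x$reset_duration))
  cat(sprintf("  restored 1:1 rhythm:     %s\n", x$restored))
  if (x$restored)
    cat(sprintf("  onset to restoration:    %8.1f ms\n",
                x$total_time_onset_to_restoration))
  invisible(x)
}
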