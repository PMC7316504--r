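# In-silico dynamic-clamp emulation: the six-phase stimulus train used to
# validate the frequency-sensing channel in patched myocytes, with light
# pulses emulated as rectangular depolarizing current injections and the
# feedback rule that detects pacing block (a fully refractory beat) and
# drops the pacing rate back to baseline.

#' Dynamic-clamp protocol definition
#'
#' Phase order is fixed: (i) 7 pre-pacing pulses at the baseline rate with
#' the channel enabled, (ii) 8 more baseline pulses with the channel
#' enabled, (iii) fast pacing with the channel enabled until the feedback
#' detects a refractory beat (termination) or a stable state is reached,
#' (iv) 7 baseline pulses with the channel enabled, (v) 8 baseline pulses
#' with the channel disabled, (vi) fast pacing with the channel disabled
#' (no feedback) for contrast.
#'
#' @param fast_freq fast pacing rate (Hz), must exceed `baseline_freq`.
#' @param pre_pace_pulses,baseline_pulses pulse counts of phases i/iv and
#'   ii/v.
#' @param baseline_freq baseline rate (Hz).
#' @param pulse_duration injected-pulse duration (ms); 10 ms emulates the
#'   optical stimulus.
#' @param pulse_amp injected-pulse amplitude (pA/pF); the default -6 is 1.5x
#'   the model's diastolic threshold for a 10 ms pulse.
#' @param refractory_threshold mV; a beat is refractory when the membrane
#'   stays above this for the entire pulse.
#' @param refractory_consecutive consecutive refractory beats required for
#'   block detection. The default 2 distinguishes sustained channel-driven
#'   depolarization from the ordinary 2:1 response of a long-AP ventricular
#'   cell paced below its APD, where refractory and captured beats
#'   alternate. Set to 1 for the raw single-beat rule.
#' @param max_fast_pulses safety cap on phases iii and vi.
#' @param stable_beats,stable_tol phase-iii exit: this many consecutive fast
#'   beats whose APD90 varies by less than `stable_tol` (relative).
#' @return An object of class `dynamic_clamp_protocol`.
#' @export
dynamic_clamp_protocol <- function(fast_freq, pre_pace_pulses = 7L,
                                   baseline_pulses = 8L, baseline_freq = 1,
                                   pulse_duration = 10, pulse_amp = -6,
                                   refractory_threshold = -20,
                                   refractory_consecutive = 2L,
                                   max_fast_pulses = 120L,
                                   stable_beats = 10L,
                                   stable_tol = 0.01) {
  stopifnot(pulse_duration > 0, fast_freq > baseline_freq, baseline_freq > 0)
  structure(list(fast_freq = fast_freq,
                 pre_pace_pulses = as.integer(pre_pace_pulses),
                 baseline_pulses = as.integer(baseline_pulses),
                 baseline_freq = baseline_freq,
                 pulse_duration = pulse_duration, pulse_amp = pulse_amp,
                 refractory_threshold = refractory_threshold,
                 refractory_consecutive = as.integer(refractory_consecutive),
                 max_fast_pulses = as.integer(max_fast_pulses),
                 stable_beats = as.integer(stable_beats),
                 stable_tol = stable_tol),
            class = "dynamic_clamp_protocol")
}

#' Refractory-beat detection
#'
#' A pulse is scored refractory when the membrane potential is more
#' positive than the threshold during the entire pulse.
#'
#' @param v voltage samples spanning exactly the pulse window (mV).
#' @param threshold mV (default -20).
#' @return Logical.
#' @export
detect_refractory_beat <- function(v, threshold = -20) {
  if (!length(v)) stop("empty trace")
  all(v > threshold)
}

# run one inter-pulse cycle: pulse at the start, length = cycle length
run_pulse_cycle <- function(state, cl, proto, params, bioicd, bioicd_pars,
                            dt, t0) {
  tr <- run_cell(state = state, params = params, duration = cl, dt = dt,
                 pulse_times = t0, pulse_dur = proto$pulse_duration,
                 pulse_amp = proto$pulse_amp, bioicd = bioicd,
                 bioicd_pars = bioicd_pars, record_every = 0.5, t0 = t0)
  pulse_sel <- tr$time - t0 <= proto$pulse_duration + 1e-9
  tr$refractory <- detect_refractory_beat(tr$v[pulse_sel],
                                          proto$refractory_threshold)
  tr
}

#' Run the dynamic-clamp protocol
#'
#' Executes phases i-vi on the single-cell model. In phase iii a detected
#' refractory beat triggers the feedback: no further fast pulse is emitted
#' and pacing returns to baseline; `time_to_termination` is the time from
#' the first fast pulse to the detection. If the cell fails 1:1 capture
#' during baseline pacing the protocol is invalid.
#'
#' @param protocol a [dynamic_clamp_protocol()].
#' @param params a [cell_params()] object.
#' @param bioicd_pars a [bioicd_params()] object.
#' @param dt integration step (ms).
#' @param phases subset of phases to run (default all six); phase iii keeps
#'   its exit rules regardless.
#' @return A list of class `dynamic_clamp_record`: concatenated trace
#'   (`time`, `v`, `i_bioicd`, `phase`), per-pulse table (`pulses`),
#'   `terminated`, `time_to_termination` (ms), `stable` flag.
#' @export
run_dynamic_clamp <- function(protocol, params = cell_params(),
                              bioicd_pars = bioicd_params(), dt = 0.02,
                              phases = 1:6) {
  proto <- protocol
  bcl_base <- 1000 / proto$baseline_freq
  bcl_fast <- 1000 / proto$fast_freq
  state <- cell_init()
  t <- 0
  trace <- list(time = numeric(0), v = numeric(0), i_bioicd = numeric(0),
                phase = integer(0))
  pulses <- data.frame(time = numeric(0), phase = integer(0),
                       refractory = logical(0))
  terminated <- FALSE
  stable <- FALSE
  time_to_termination <- NA_real_
  apds <- numeric(0)
  phase_plan <- list(
    list(ph = 1L, n = proto$pre_pace_pulses, cl = bcl_base, bio = TRUE),
    list(ph = 2L, n = proto$baseline_pulses, cl = bcl_base, bio = TRUE),
    list(ph = 3L, n = proto$max_fast_pulses, cl = bcl_fast, bio = TRUE),
    list(ph = 4L, n = proto$pre_pace_pulses, cl = bcl_base, bio = TRUE),
    list(ph = 5L, n = proto$baseline_pulses, cl = bcl_base, bio = FALSE),
    list(ph = 6L, n = proto$max_fast_pulses, cl = bcl_fast, bio = FALSE))
  t_first_fast <- NA_real_
  n_refr <- 0L
  for (pl in phase_plan) {
    if (!(pl$ph %in% phases)) next
    if (pl$ph == 3L) apds <- numeric(0)
    k <- 0L
    while (k < pl$n) {
      k <- k + 1L
      tr <- run_pulse_cycle(state, pl$cl, proto, params, pl$bio,
                            bioicd_pars, dt, t)
      state <- tr$state
      keep <- seq_len(length(tr$time) - 1L) # drop duplicated endpoint
      trace$time <- c(trace$time, tr$time[keep])
      trace$v <- c(trace$v, tr$v[keep])
      trace$i_bioicd <- c(trace$i_bioicd, tr$i_bioicd[keep])
      trace$phase <- c(trace$phase, rep(pl$ph, length(keep)))
      pulses <- rbind(pulses, data.frame(time = t, phase = pl$ph,
                                         refractory = tr$refractory))
      if (pl$ph %in% c(1L, 2L) && !any(tr$v > 0))
        stop("protocol invalid: no 1:1 capture at baseline pacing")
      if (pl$ph == 3L) {
        if (is.na(t_first_fast)) t_first_fast <- t
        n_refr <- if (tr$refractory) n_refr + 1L else 0L
        if (n_refr >= proto$refractory_consecutive) {
          terminated <- TRUE
          time_to_termination <- t + proto$pulse_duration - t_first_fast
          t <- t + pl$cl
          break
        }
        a <- tryCatch(apd90(tr$time, tr$v), error = function(e) NA_real_)
        apds <- c(apds, a)
        nb <- proto$stable_beats
        if (length(apds) >= nb) {
          lastn <- utils::tail(apds, nb)
          if (all(is.finite(lastn)) &&
              diff(range(lastn)) / mean(lastn) < proto$stable_tol) {
            stable <- TRUE
            t <- t + pl$cl
            break
          }
        }
      }
      t <- t + pl$cl
    }
    if (pl$ph == 3L && stable) break # stable fast state: protocol terminates
  }
  structure(list(trace = trace, pulses = pulses, terminated = terminated,
                 time_to_termination = time_to_termination, stable = stable,
                 protocol = proto),
            class = "dynamic_clamp_record")
}

#' @export
print.dynamic_clamp_record <- function(x, ...) {
  cat(sprintf("Dynamic-clamp run: fast rate %.2f Hz, %d pulses\n",
              x$protocol$fast_freq, nrow(x$pulses)))
  if (x$terminated)
    cat(sprintf("  terminated %.0f ms after the first fast pulse\n",
                x$time_to_termination))
  else if (x$stable) cat("  stable fast 1:1 state reached (no termination)\n")
  else cat("  no termination\n")
  invisible(x)
}

#' Maximal terminating cycle length vs baseline APD
#'
#' For each cell variant (produced by scaling the repolarizing currents,
#' which shifts the baseline APD90), the basic cycle length is decreased
#' over `bcl_grid` until the protocol terminates; the maximal terminating
#' BCL is reported together with the variant's baseline APD90 at 1 Hz. The
#' expectation is a non-decreasing maximal BCL with baseline APD: longer
#' APs activate the channel at longer cycle lengths.
#'
#' @param variants list of [cell_params()] objects, or a numeric vector of
#'   IKr/IKs scale factors (each builds a variant).
#' @param bcl_grid decreasing cycle lengths to scan (ms).
#' @param bioicd_pars a [bioicd_params()] object.
#' @param dt integration step (ms).
#' @param protocol_args extra arguments for [dynamic_clamp_protocol()].
#' @return data.frame with `variant`, `baseline_apd90`, `max_terminating_bcl`
#'   (`NA` = censored: none in the scanned range terminated).
#' @export
termination_threshold_scan <- function(variants = c(0.5, 0.75, 1.0, 1.5, 2.0),
                                       bcl_grid = seq(400, 200, by = -25),
                                       bioicd_pars = bioicd_params(),
                                       dt = 0.02, protocol_args = list()) {
  if (is.numeric(variants))
    variants <- lapply(variants, function(s)
      cell_params(scales = c(i_kr = s, i_ks = s)))
  if (length(variants) < 2) stop("at least 2 cell variants required")
  stopifnot(all(diff(bcl_grid) < 0))
  out <- data.frame(variant = seq_along(variants),
                    baseline_apd90 = NA_real_,
                    max_terminating_bcl = NA_real_)
  for (i in seq_along(variants)) {
    p <- variants[[i]]
    base <- pace_cell(frequency = 1, n_beats = 6, params = p, dt = dt,
                      tail_ms = 500)
    out$baseline_apd90[i] <- apd90(base)
    for (bcl in bcl_grid) {
      proto <- do.call(dynamic_clamp_protocol,
                       c(list(fast_freq = 1000 / bcl), protocol_args))
      run <- run_dynamic_clamp(proto, params = p, bioicd_pars = bioicd_pars,
                               dt = dt, phases = 1:3)
      if (run$terminated) {
        out$max_terminating_bcl[i] <- bcl
        break
      }
    }
  }
  out
}
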