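# Human ventricular myocyte: epicardial ten Tusscher-Panfilov 2006
# formulation (12 sarcolemmal currents, SR calcium cycling, dynamic
# intracellular Na+/K+), with the frequency-sensing channel added to the
# total ionic current. All currents in pA/pF, voltages in mV, time in ms,
# concentrations in mM.

CELL_STATE_NAMES <- c("v", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d",
                      "f", "f2", "fcass", "rr", "cai", "casr", "cass", "nai",
                      "ki", "o", "a1")

CURRENT_NAMES <- c("i_na", "i_cal", "i_k1", "i_to", "i_naca", "i_nak",
                   "i_kr", "i_ks", "i_bna", "i_bca", "i_pca", "i_pk")

#' Grey-zone current scale factors
#'
#' The partially remodelled border tissue around a scar carries reduced
#' repolarizing and depolarizing currents: IKs scaled to 0.20 (an 80%
#' reduction), IKr to 0.30, ICaL to 0.31 and INa to 0.38.
#'
#' @return Named numeric vector of the four scale factors.
#' @export
grey_zone_scales <- function() {
  c(i_ks = 0.20, i_kr = 0.30, i_cal = 0.31, i_na = 0.38)
}

#' Ventricular cell parameters
#'
#' @param subtype transmural cell subtype; the epicardial variant is the
#'   default, mid-myocardial and endocardial variants differ in the
#'   transient-outward and slow-delayed-rectifier conductances and the
#'   s-gate kinetics.
#' @param variant `"default"` for the standard (moderate restitution slope)
#'   parameter set; `"steep"` for the published steep-restitution variant
#'   (plateau current maxima 0.8666 / 0.00219, f-gate twice as fast) that
#'   produces spiral-wave breakup and serves as the fibrillation substrate.
#' @param scales named per-current multiplicative scale factors (names among
#'   `r paste(CURRENT_NAMES, collapse = ", ")`), default all 1.
#' @param grey_zone logical; apply [grey_zone_scales()] on top of `scales`.
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(subtype = c("epi", "endo", "mid"),
                        variant = c("default", "steep"),
                        scales = NULL, grey_zone = FALSE) {
  subtype <- match.arg(subtype)
  variant <- match.arg(variant)
  sc <- stats::setNames(rep(1, 12), CURRENT_NAMES)
  if (!is.null(scales)) {
    bad <- setdiff(names(scales), CURRENT_NAMES)
    if (length(bad)) stop("unknown current scale(s): ", paste(bad, collapse = ", "))
    if (any(scales < 0)) stop("current scale factors must be >= 0")
    sc[names(scales)] <- scales
  }
  if (grey_zone) {
    gz <- grey_zone_scales()
    sc[names(gz)] <- sc[names(gz)] * gz
  }
  p <- list(
    Ko = 5.4, Cao = 2.0, Nao = 140.0,
    Gna = 14.838, Gcal = 3.98e-5, Gk1 = 5.405,
    Gto = switch(subtype, epi = 0.294, mid = 0.294, endo = 0.073),
    Gkr = 0.153,
    Gks = switch(subtype, epi = 0.392, endo = 0.392, mid = 0.098),
    Gbna = 0.00029, Gbca = 0.000592,
    Gpca = if (variant == "steep") 0.8666 else 0.1238,
    Gpk = if (variant == "steep") 0.00219 else 0.0146,
    subtype = switch(subtype, epi = 0L, endo = 1L, mid = 2L),
    tauf_scale = if (variant == "steep") 0.5 else 1.0,
    scales = unname(sc))
  structure(c(p, list(subtype_name = subtype, variant = variant,
                      scale_names = CURRENT_NAMES)),
            class = "cell_params")
}

#' Initial (resting) cell state
#'
#' The published resting initial conditions of the ventricular model with
#' the frequency-sensing channel fully closed (`o = 0`, `a1 = 0`).
#'
#' @return Named numeric vector of length 21 (`v` plus 18 ionic-model state
#'   variables plus `o`, `a1`).
#' @export
cell_init <- function() {
  stats::setNames(
    c(-86.2, 0, 0.75, 0.75, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1,
      7e-5, 1.3, 7e-5, 7.67, 138.3, 0, 0),
    CELL_STATE_NAMES)
}

validate_cell_state <- function(state) {
  if (length(state) != 21L) stop("invalid state: expected 21 state variables")
  if (any(!is.finite(state))) {
    bad <- CELL_STATE_NAMES[which(!is.finite(state))[1]]
    stop("invalid state: non-finite variable ", bad)
  }
  gates <- state[c(2:14, 20, 21)]
  if (any(gates < -1e-9) || any(gates > 1 + 1e-9))
    stop("invalid state: gating variable outside [0, 1]")
  conc <- state[15:19]
  if (any(conc <= 0)) stop("invalid state: non-positive concentration")
  invisible(state)
}

#' Total ionic current with per-current breakdown
#'
#' Sums the twelve ventricular currents plus the frequency-sensing channel
#' current (zero when `bioicd = FALSE` or the channel is closed). Reversal
#' potentials are computed from the state's intracellular concentrations.
#'
#' @param state named state vector as from [cell_init()].
#' @param params a [cell_params()] object.
#' @param bioicd logical, include the channel current.
#' @param bioicd_pars a [bioicd_params()] object.
#' @return Named numeric vector: the 12 ionic currents, `i_bioicd`, and
#'   `total` (pA/pF).
#' @export
ionic_currents <- function(state, params = cell_params(), bioicd = FALSE,
                           bioicd_pars = bioicd_params()) {
  validate_cell_state(state)
  .ionic_currents_cpp(unname(state), unclass(params), unclass(bioicd_pars),
                      bioicd)
}

#' Run the single-cell model
#'
#' Advances the cell for `duration` ms with rectangular stimulus pulses at
#' the given start times. Gates use the Rush-Larsen exponential scheme,
#' concentrations forward Euler, the channel states their exact per-step
#' exponential update, and the membrane potential forward Euler with the
#' channel conductance treated semi-implicitly.
#'
#' @param state initial state vector (default [cell_init()]).
#' @param params a [cell_params()] object.
#' @param duration run length (ms).
#' @param dt time step (ms), default 0.02.
#' @param pulse_times stimulus onset times (ms); may be empty.
#' @param pulse_dur,pulse_amp stimulus duration (ms) and amplitude (pA/pF);
#'   the default -52 pA/pF for 2 ms is a twice-diastolic-threshold
#'   rectangular pulse (negative = depolarizing under the monodomain sign
#'   convention).
#' @param bioicd logical, enable the frequency-sensing channel.
#' @param bioicd_pars a [bioicd_params()] object.
#' @param record_every sampling interval of the returned trace (ms).
#' @param use_tables use voltage lookup tables (default) or direct
#'   evaluation of all rate functions.
#' @param erev_every recompute reversal potentials every this many steps
#'   (concentrations drift slowly; default every 25 steps = 0.5 ms at the
#'   default dt).
#' @param t0 time origin (ms) of the returned trace.
#' @return A list of class `cell_trace`: `time`, `v`, `i_bioicd`, `o`, `a1`,
#'   `stim` vectors plus the final `state`.
#' @export
run_cell <- function(state = cell_init(), params = cell_params(),
                     duration = 1000, dt = 0.02, pulse_times = numeric(),
                     pulse_dur = 2, pulse_amp = -52, bioicd = FALSE,
                     bioicd_pars = bioicd_params(), record_every = 0.5,
                     use_tables = TRUE, erev_every = 25L, t0 = 0) {
  validate_cell_state(state)
  stopifnot(dt > 0, duration > 0)
  out <- .run_cell_cpp(unname(state), unclass(params), unclass(bioicd_pars),
                       bioicd, dt, duration, as.numeric(sort(pulse_times)),
                       pulse_dur, pulse_amp, record_every, use_tables,
                       as.integer(erev_every), t0)
  out$state <- stats::setNames(out$state, CELL_STATE_NAMES)
  class(out) <- "cell_trace"
  out
}

#' Pace the cell periodically
#'
#' Applies `n_beats` stimulus pulses at the given frequency and returns the
#' voltage/current trace. If a stimulus fails to elicit an action potential
#' (no upstroke above 0 mV within its cycle) the beat is flagged in
#' `capture`, not raised as an error.
#'
#' @param frequency pacing rate (Hz), > 0.
#' @param n_beats number of stimuli, >= 1.
#' @param tail_ms extra quiescent time after the last cycle (ms).
#' @inheritParams run_cell
#' @return A `cell_trace` with additional elements `stim_times`, `capture`
#'   (logical per beat) and `frequency`.
#' @export
pace_cell <- function(frequency, n_beats, state = cell_init(),
                      params = cell_params(), dt = 0.02, pulse_dur = 2,
                      pulse_amp = -52, bioicd = FALSE,
                      bioicd_pars = bioicd_params(), record_every = 0.5,
                      tail_ms = 0, ...) {
  stopifnot(frequency > 0)
  n_beats <- as.integer(n_beats)
  if (n_beats < 1L) stop("invalid input: n_beats must be >= 1")
  cl <- 1000 / frequency
  starts <- (seq_len(n_beats) - 1) * cl + 5
  duration <- n_beats * cl + tail_ms
  out <- run_cell(state = state, params = params, duration = duration,
                  dt = dt, pulse_times = starts, pulse_dur = pulse_dur,
                  pulse_amp = pulse_amp, bioicd = bioicd,
                  bioicd_pars = bioicd_pars, record_every = record_every, ...)
  capture <- vapply(seq_len(n_beats), function(b) {
    sel <- out$time >= starts[b] & out$time < starts[b] + cl
    any(out$v[sel] > 0)
  }, logical(1))
  out$stim_times <- starts
  out$capture <- capture
  out$frequency <- frequency
  out
}

#' Action potential duration at 90% repolarization
#'
#' Detects the AP upstroke as the maximum-dV/dt sample, measures the AP
#' amplitude relative to the pre-upstroke diastolic level, and returns the
#' time from the upstroke until the voltage has recovered 90% of that
#' amplitude. With `all = TRUE`, returns one value per detected AP.
#'
#' @param time,v trace vectors (ms, mV); alternatively pass a `cell_trace`
#'   as `time`.
#' @param all return APD90 of every complete AP instead of the last.
#' @param upstroke_v threshold used to segment APs (mV).
#' @return APD90 in ms (or vector). Errors with "not measurable" when the
#'   trace contains no complete AP.
#' @export
apd90 <- function(time, v = NULL, all = FALSE, upstroke_v = -20) {
  if (is.list(time) && is.null(v)) { v <- time$v; time <- time$time }
  stopifnot(length(time) == length(v), length(v) > 2)
  above <- v > upstroke_v
  d <- diff(as.integer(above))
  ups <- which(d == 1)
  downs <- which(d == -1)
  if (!length(ups)) stop("not measurable: no complete action potential")
  vals <- numeric(0)
  for (u in ups) {
    dn <- downs[downs > u]
    if (!length(dn)) next
    dn <- dn[1]
    # refine upstroke: max dV/dt in a window around the threshold crossing
    w0 <- max(1, u - 20)
    dv <- diff(v[w0:min(u + 20, length(v))])
    t_up <- time[w0 + which.max(dv)]
    base_sel <- time < t_up & time >= t_up - 50
    v_base <- if (any(base_sel)) min(v[base_sel]) else v[w0]
    v_peak <- max(v[u:dn])
    v90 <- v_peak - 0.9 * (v_peak - v_base)
    # first downward crossing of v90 after the peak
    pk <- u - 1 + which.max(v[u:dn])
    rest <- pk:length(v)
    cross <- which(v[rest] <= v90)
    if (!length(cross)) next
    i2 <- rest[cross[1]]
    if (i2 == 1) next
    # linear interpolation between samples
    t90 <- time[i2 - 1] + (time[i2] - time[i2 - 1]) *
      (v[i2 - 1] - v90) / (v[i2 - 1] - v[i2])
    vals <- c(vals, t90 - t_up)
  }
  if (!length(vals)) stop("not measurable: no complete action potential")
  if (all) vals else vals[length(vals)]
}

#' APD restitution curve
#'
#' Dynamic (steady-state pacing) protocol: for each cycle length in
#' `cycle_lengths` the cell is paced for `pre_beats` conditioning beats, the
#' final APD90 is recorded, and the diastolic interval is the cycle length
#' minus the preceding APD90. Cycle lengths with 2:1 block (a stimulus that
#' fails to elicit an AP) are flagged and excluded. The cell state carries
#' over between cycle lengths, emulating a pacing-down ramp.
#'
#' @param cycle_lengths monotone sequence of cycle lengths (ms).
#' @param pre_beats conditioning beats per cycle length (default 20).
#' @param params,bioicd,bioicd_pars,dt passed to the cell model.
#' @return A data.frame with columns `cl`, `di`, `apd90`, `blocked`, plus
#'   attributes `max_slope` and `slope_gt1_di` (range of DI where the local
#'   slope exceeds 1).
#' @export
restitution_curve <- function(cycle_lengths = seq(1000, 300, by = -50),
                              pre_beats = 20, params = cell_params(),
                              bioicd = FALSE, bioicd_pars = bioicd_params(),
                              dt = 0.02) {
  if (any(diff(cycle_lengths) > 0) && any(diff(cycle_lengths) < 0))
    stop("cycle_lengths must be monotone")
  state <- cell_init()
  res <- data.frame(cl = cycle_lengths, di = NA_real_, apd90 = NA_real_,
                    blocked = FALSE)
  for (i in seq_along(cycle_lengths)) {
    cl <- cycle_lengths[i]
    tr <- pace_cell(frequency = 1000 / cl, n_beats = pre_beats, state = state,
                    params = params, dt = dt, bioicd = bioicd,
                    bioicd_pars = bioicd_pars, record_every = 0.5,
                    tail_ms = 0)
    state <- tr$state
    if (!all(tr$capture)) { res$blocked[i] <- TRUE; next }
    # APD of the last two beats: DI = CL - APD of the beat before last.
    # A point only counts as clean 1:1 capture: alternans (last two APDs
    # differing > 20%) and implausible diastolic intervals are flagged and
    # excluded like 2:1 block.
    sel <- tr$time >= (pre_beats - 2) * cl
    a <- tryCatch(apd90(tr$time[sel], tr$v[sel], all = TRUE),
                  error = function(e) numeric(0))
    if (length(a) < 2) { res$blocked[i] <- TRUE; next }
    a2 <- a[length(a) - 1]
    a1 <- a[length(a)]
    di <- cl - a2
    if (di <= 0 || di >= cl || abs(a1 - a2) / mean(c(a1, a2)) > 0.2) {
      res$blocked[i] <- TRUE
      next
    }
    res$apd90[i] <- a1
    res$di[i] <- di
  }
  ok <- !res$blocked & is.finite(res$apd90)
  out <- res
  sl <- rep(NA_real_, nrow(res))
  okn <- which(ok)
  if (length(okn) >= 2) {
    o <- okn[order(res$di[okn])]
    s <- diff(res$apd90[o]) / diff(res$di[o])
    sl[o[-1]] <- s
    attr(out, "max_slope") <- max(s, na.rm = TRUE)
    gt1 <- which(s > 1)
    attr(out, "slope_gt1_di") <-
      if (length(gt1)) range(res$di[o][c(gt1, gt1 + 1)]) else NULL
  } else {
    attr(out, "max_slope") <- NA_real_
    attr(out, "slope_gt1_di") <- NULL
  }
  out
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("Single-cell trace: %.0f ms, %d samples, V in [%.1f, %.1f] mV\n",
              max(x$time) - min(x$time), length(x$time), min(x$v), max(x$v)))
  invisible(x)
}
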