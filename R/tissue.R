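# 2D monodomain solver front end: explicit finite-difference
# reaction-diffusion stepping on a substrate grid, stimulus scheduling,
# S1-S2 cross-field induction and the pathological-substrate scenarios.

#' Anisotropic diffusion tensor from a fiber direction
#'
#' `D_ij = (D_l - D_t) * alpha_i * alpha_j + D_t * delta_ij`, with `alpha`
#' the unit vector along the fiber. In 2D monolayers isotropy is assumed
#' (scalar D); the tensor is provided for anisotropic configurations and
#' future 3D use, with the ventricular transverse coefficient one quarter
#' of the longitudinal one by default.
#'
#' @param fiber unit vector (length 2 or 3) along the fiber direction.
#' @param d_long longitudinal diffusion coefficient (cm^2/s).
#' @param d_trans transverse diffusion coefficient (cm^2/s); default
#'   `d_long / 4`.
#' @return A symmetric positive-definite matrix.
#' @export
diffusion_tensor <- function(fiber, d_long = 1.54, d_trans = d_long / 4) {
  nrm <- sqrt(sum(fiber^2))
  if (abs(nrm - 1) > 1e-6)
    stop("normalization error: fiber vector must have unit norm")
  k <- length(fiber)
  (d_long - d_trans) * outer(fiber, fiber) + d_trans * diag(k)
}

#' No-flux diffusion operator
#'
#' Five-point centred discretization of `div(D grad V)` with mirrored ghost
#' values at the domain edges and internal no-flux faces at fibroblast-void
#' and scar-core nodes.
#'
#' @param v voltage field: vector of length `nx * ny` or an `nx` by `ny`
#'   matrix (x is the contiguous dimension).
#' @param substrate a `bioicd_substrate`.
#' @return Field of the same shape as `v`, in mV/ms (diffusion coefficient
#'   converted from cm^2/s).
#' @export
laplacian_no_flux <- function(v, substrate) {
  was_mat <- is.matrix(v)
  if (was_mat) {
    stopifnot(nrow(v) == substrate$nx, ncol(v) == substrate$ny)
    v <- as.numeric(v)
  }
  if (length(v) != substrate$nx * substrate$ny)
    stop("shape mismatch between field and substrate")
  out <- .laplacian_cpp(v, substrate$node_class, substrate$nx, substrate$ny,
                        substrate$dx, substrate$diffusion / 1000)
  if (was_mat) matrix(out, substrate$nx, substrate$ny) else out
}

# ------------------------------------------------------------------ stimuli

#' Stimulus events and electrode regions
#'
#' An event is a rectangular current pulse applied over a node region,
#' one-shot or periodic. Regions are integer node indices (1-based); the
#' helpers build common electrode geometries.
#'
#' @param t_start onset time (ms).
#' @param duration pulse duration (ms), > 0.
#' @param amplitude current density (pA/pF); negative depolarizes.
#' @param region integer node indices (1-based).
#' @param period repeat period (ms); `NA` for one-shot.
#' @param label optional label used in the event log.
#' @return `stim_event`: a list describing the event.
#' @export
stim_event <- function(t_start, duration, amplitude, region, period = NA,
                       label = "stim") {
  stopifnot(duration > 0, t_start >= 0, length(region) >= 1)
  structure(list(t_start = t_start, duration = duration,
                 amplitude = amplitude, region = as.integer(region),
                 period = if (is.na(period)) -1 else period, label = label),
            class = "stim_event")
}

#' @rdname stim_event
#' @param substrate a `bioicd_substrate`.
#' @param side edge for the strip electrode.
#' @param width strip width in nodes.
#' @export
region_edge_strip <- function(substrate, side = c("left", "right", "bottom",
                                                  "top"), width = 2L) {
  side <- match.arg(side)
  nx <- substrate$nx; ny <- substrate$ny
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  sel <- switch(side,
                left = xs <= width, right = xs > nx - width,
                bottom = ys <= width, top = ys > ny - width)
  which(sel)
}

#' @rdname stim_event
#' @param quadrant which quadrant of the domain.
#' @export
region_quadrant <- function(substrate, quadrant = c("lower_left",
                                                    "lower_right",
                                                    "upper_left",
                                                    "upper_right")) {
  quadrant <- match.arg(quadrant)
  nx <- substrate$nx; ny <- substrate$ny
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  sel <- switch(quadrant,
                lower_left = xs <= nx / 2 & ys <= ny / 2,
                lower_right = xs > nx / 2 & ys <= ny / 2,
                upper_left = xs <= nx / 2 & ys > ny / 2,
                upper_right = xs > nx / 2 & ys > ny / 2)
  which(sel)
}

#' @rdname stim_event
#' @param x0,x1,y0,y1 rectangle bounds in cm.
#' @export
region_rect <- function(substrate, x0, x1, y0, y1) {
  nx <- substrate$nx; ny <- substrate$ny; dx <- substrate$dx
  xs <- (rep(seq_len(nx), times = ny) - 0.5) * dx
  ys <- (rep(seq_len(ny), each = nx) - 0.5) * dx
  which(xs >= x0 & xs <= x1 & ys >= y0 & ys <= y1)
}

# ------------------------------------------------------------------- config

#' Tissue simulation configuration
#'
#' @param dt time step (ms); default 0.02 for the ventricular model. Must
#'   satisfy the explicit-diffusion stability bound `dt < dx^2 / (4 D)`.
#' @param duration run length (ms).
#' @param probe_every probe sampling interval (ms).
#' @param frame_every interval (ms) of the per-frame field summaries
#'   (spatial max channel current, depolarized and repolarized node
#'   fractions) from which the timing metrics are computed.
#' @param snapshot_every full-field snapshot interval (ms); 0 disables
#'   snapshots.
#' @param probes list of (x, y) grid coordinates (nodes); default the
#'   domain centre and an off-centre point.
#' @param bioicd logical: channel present in every myocyte.
#' @param bioicd_pars a [bioicd_params()] object.
#' @param cell_pars a [cell_params()] object for ordinary myocytes (the
#'   grey-zone variant is derived from it).
#' @param sync_v,reset_v voltage thresholds (mV) used for the depolarized
#'   and repolarized fractions.
#' @param act_v,act_lockout upstroke-detection threshold (mV) and refractory
#'   lockout (ms) for the per-node activation log.
#' @param use_tables,erev_every numerical switches, see [run_cell()].
#' @param stop_if_quiescent stop early once the tissue is fully repolarized
#'   and no stimulus is pending.
#' @param stop_after_reset_from if finite, stop at the first frame at or
#'   after this time (ms) where at least 99% of myocyte nodes are below
#'   `reset_v` -- i.e. once the tissue-wide reset has been recorded.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.02, duration = 1000, probe_every = 1,
                       frame_every = 5, snapshot_every = 100, probes = NULL,
                       bioicd = TRUE, bioicd_pars = bioicd_params(),
                       cell_pars = cell_params(), sync_v = -20, reset_v = -75,
                       act_v = -20, act_lockout = 50, use_tables = TRUE,
                       erev_every = 25L, stop_if_quiescent = FALSE,
                       stop_after_reset_from = Inf) {
  stopifnot(dt > 0, duration > 0, frame_every > 0, probe_every > 0)
  structure(list(dt = dt, duration = duration, probe_every = probe_every,
                 frame_every = frame_every, snapshot_every = snapshot_every,
                 probes = probes, bioicd = bioicd, bioicd_pars = bioicd_pars,
                 cell_pars = cell_pars, sync_v = sync_v, reset_v = reset_v,
                 act_v = act_v, act_lockout = act_lockout,
                 use_tables = use_tables, erev_every = as.integer(erev_every),
                 stop_if_quiescent = stop_if_quiescent,
                 stop_after_reset_from = stop_after_reset_from),
            class = "sim_config")
}

node_index <- function(substrate, x, y) (y - 1L) * substrate$nx + x

# probes must sit on state-carrying nodes; snap to the nearest myocyte
nearest_myocyte <- function(substrate, idx) {
  cls <- substrate$node_class
  if (cls[idx] < 2L) return(idx)
  nx <- substrate$nx; ny <- substrate$ny
  x0 <- (idx - 1L) %% nx + 1L
  y0 <- (idx - 1L) %/% nx + 1L
  for (r in seq_len(max(nx, ny))) {
    xs <- max(1L, x0 - r):min(nx, x0 + r)
    ys <- max(1L, y0 - r):min(ny, y0 + r)
    ring <- expand.grid(x = xs, y = ys)
    ring <- ring[pmax(abs(ring$x - x0), abs(ring$y - y0)) == r, ]
    ring$idx <- (ring$y - 1L) * nx + ring$x
    ring <- ring[cls[ring$idx] < 2L, ]
    if (nrow(ring)) {
      d2 <- (ring$x - x0)^2 + (ring$y - y0)^2
      return(ring$idx[which.min(d2)])
    }
  }
  stop("substrate contains no myocyte nodes")
}

default_probes <- function(substrate) {
  nx <- substrate$nx; ny <- substrate$ny
  list(centre = c(round(nx / 2), round(ny / 2)),
       off_centre = c(round(nx / 4), round(3 * ny / 4)))
}

check_stability <- function(substrate, dt) {
  dmax <- substrate$diffusion / 1000 # cm^2/ms
  bound <- substrate$dx^2 / (4 * dmax)
  if (dt >= bound)
    stop(sprintf("dt = %g ms violates the diffusion stability bound %g ms",
                 dt, bound))
  invisible(bound)
}

# ------------------------------------------------------------------- runner

#' Run the 2D monodomain model
#'
#' Advances the reaction-diffusion system on the substrate with the given
#' stimulus schedule and returns a `bioicd_record` containing probe traces,
#' per-frame field summaries, optional full-field snapshots, the per-node
#' activation log and the final state.
#'
#' @param substrate a `bioicd_substrate`.
#' @param config a [sim_config()].
#' @param events list of [stim_event()] objects.
#' @param state0 optional initial state matrix (`n` x 21); default resting.
#' @param t0 time origin (ms).
#' @param onset arrhythmia-onset time (ms) stored in the record (by
#'   convention the S2 time); `NA` if not applicable.
#' @return A `bioicd_record`.
#' @export
run_tissue <- function(substrate, config = sim_config(), events = list(),
                       state0 = NULL, t0 = 0, onset = NA_real_) {
  check_stability(substrate, config$dt)
  n <- substrate$nx * substrate$ny
  if (is.null(state0)) {
    state0 <- matrix(rep(cell_init(), each = n), nrow = n)
  }
  stopifnot(nrow(state0) == n, ncol(state0) == 21L)
  probes <- config$probes
  if (is.null(probes)) probes <- default_probes(substrate)
  pidx <- vapply(probes, function(p) node_index(substrate, p[1], p[2]),
                 numeric(1))
  pidx <- vapply(pidx, function(i) nearest_myocyte(substrate, i), numeric(1))
  ev_cpp <- lapply(events, function(e)
    list(t_start = e$t_start, duration = e$duration, amplitude = e$amplitude,
         period = e$period, mask = e$region - 1L))
  gz_pars <- grey_zone_params(config$cell_pars)
  out <- .run_tissue_cpp(substrate$node_class, substrate$nx, substrate$ny,
                         substrate$dx, substrate$diffusion / 1000, state0,
                         unclass(config$cell_pars), unclass(gz_pars),
                         unclass(config$bioicd_pars), config$bioicd,
                         config$dt, config$duration, t0, ev_cpp,
                         as.integer(pidx - 1L), config$probe_every,
                         config$frame_every, config$snapshot_every,
                         config$sync_v, config$reset_v, config$act_v,
                         config$act_lockout, config$use_tables,
                         config$erev_every, config$stop_if_quiescent,
                         config$stop_after_reset_from %||% Inf)
  np <- out$n_probe_rec
  keep <- seq_len(np)
  nsnap <- out$n_snap
  rec <- structure(list(
    substrate = substrate, config = config, events = events,
    probes = list(time = out$probe_time[keep],
                  names = names(probes), index = pidx,
                  v = out$probe_v[keep, , drop = FALSE],
                  i_bioicd = out$probe_ibio[keep, , drop = FALSE],
                  o = out$probe_o[keep, , drop = FALSE],
                  a1 = out$probe_a1[keep, , drop = FALSE]),
    frames = data.frame(time = out$frame_time,
                        max_ibio = out$frame_max_ibio,
                        frac_sync = out$frame_frac_sync,
                        frac_reset = out$frame_frac_reset),
    snapshots = if (nsnap > 0)
      list(time = out$snap_time[seq_len(nsnap)],
           v = out$snap_v[, seq_len(nsnap), drop = FALSE],
           i_bioicd = out$snap_ibio[, seq_len(nsnap), drop = FALSE])
    else NULL,
    activations = data.frame(node = out$act_node + 1L, time = out$act_time),
    state = out$state, t0 = t0, onset = onset, bioicd = config$bioicd,
    stopped_at = out$stopped_at), class = "bioicd_record")
  rec
}

grey_zone_params <- function(cell_pars) {
  sc <- stats::setNames(cell_pars$scales, cell_pars$scale_names)
  gz <- grey_zone_scales()
  sc[names(gz)] <- sc[names(gz)] * gz
  p <- unclass(cell_pars)
  p$scales <- unname(sc)
  structure(p, class = "cell_params")
}

#' Expanded pacing stimulus times of a record
#'
#' One-shot events contribute their start; periodic events are expanded over
#' the record's time span.
#'
#' @param record a `bioicd_record`.
#' @param label restrict to events with this label (default all).
#' @return Sorted numeric vector of stimulus onset times (ms).
#' @export
stim_times <- function(record, label = NULL) {
  tend <- max(record$frames$time)
  out <- numeric(0)
  for (e in record$events) {
    if (!is.null(label) && !identical(e$label, label)) next
    if (e$period > 0) {
      out <- c(out, seq(e$t_start, tend, by = e$period))
    } else out <- c(out, e$t_start)
  }
  sort(out[out <= tend])
}

#' @export
print.bioicd_record <- function(x, ...) {
  cat(sprintf("Monodomain record: %d x %d nodes, t = [%g, %g] ms, channel %s\n",
              x$substrate$nx, x$substrate$ny, x$t0, max(x$frames$time),
              if (x$bioicd) "on" else "off"))
  cat(sprintf("  %d stimulus events, %d activations logged\n",
              length(x$events), nrow(x$activations)))
  invisible(x)
}

# --------------------------------------------------------------- protocols

#' S1-S2 cross-field induction
#'
#' A planar S1 wave is launched from the left edge; after the coupling
#' interval an S2 stimulus covers the lower-left quadrant. Reentry is scored
#' as established when activations persist for at least one second beyond
#' the end of the S2 stimulus.
#'
#' @param substrate a `bioicd_substrate`.
#' @param config a [sim_config()]; its duration should cover S2 + 1 s.
#' @param s2_coupling_interval ms between S1 and S2 onsets.
#' @param s1_time S1 onset (ms).
#' @param pulse_amp,pulse_dur stimulus amplitude (pA/pF) and duration (ms).
#' @return The record, with elements `reentry` (logical) and `onset` set to
#'   the S2 time.
#' @export
s1s2_crossfield <- function(substrate, config = sim_config(),
                            s2_coupling_interval, s1_time = 20,
                            pulse_amp = -52, pulse_dur = 2) {
  if (min(substrate$nx, substrate$ny) * substrate$dx < 4)
    warning("domain smaller than ~4 x 4 cm; reentry may not be sustained")
  s2_time <- s1_time + s2_coupling_interval
  events <- list(
    stim_event(s1_time, pulse_dur, pulse_amp,
               region_edge_strip(substrate, "left"), label = "s1"),
    stim_event(s2_time, pulse_dur, pulse_amp,
               region_quadrant(substrate, "lower_left"), label = "s2"))
  rec <- run_tissue(substrate, config, events, onset = s2_time)
  horizon <- s2_time + pulse_dur + 1000
  rec$reentry <- any(rec$activations$time >= horizon) &&
    max(rec$frames$time) >= horizon
  rec
}

#' Vulnerable-window scan
#'
#' Brute-force scan of S1-S2 coupling intervals; each candidate run is
#' stopped early once the tissue is quiescent. Returns the scan table and
#' the window of intervals that produced sustained reentry.
#'
#' @param substrate a `bioicd_substrate`.
#' @param couplings candidate coupling intervals (ms).
#' @param config base [sim_config()]; duration is set per run to cover the
#'   persistence horizon.
#' @param ... passed to [s1s2_crossfield()].
#' @return data.frame with columns `coupling` and `reentry`, with attribute
#'   `window` (range of reentrant couplings, or NULL).
#' @export
scan_vulnerable_window <- function(substrate, couplings = seq(250, 400, 10),
                                   config = sim_config(bioicd = FALSE), ...) {
  res <- data.frame(coupling = couplings, reentry = FALSE)
  for (i in seq_along(couplings)) {
    cfg <- config
    cfg$duration <- 20 + couplings[i] + 1400
    cfg$stop_if_quiescent <- TRUE
    cfg$snapshot_every <- 0
    rec <- s1s2_crossfield(substrate, cfg, couplings[i], ...)
    res$reentry[i] <- rec$reentry
  }
  w <- which(res$reentry)
  attr(res, "window") <- if (length(w)) range(couplings[w]) else NULL
  res
}

# ------------------------------------------------------------- scenarios

SCENARIOS <- c("vt", "vf", "fibrosis", "scar", "scar_large")

#' Pathological-substrate scenarios
#'
#' Builds one of the study's monolayer scenarios, induces the arrhythmia by
#' S1-S2 cross-field and keeps a 1.2 Hz sinus-surrogate pacing train running
#' from the left edge strip throughout:
#' \describe{
#'   \item{vt}{homogeneous sheet, functional (figure-of-eight) reentry.}
#'   \item{vf}{homogeneous sheet with the steep-restitution cell variant, so
#'     the induced reentry breaks up into fibrillatory activity.}
#'   \item{fibrosis}{20% uncoupled fibroblast voids.}
#'   \item{scar}{inexcitable scar (3.4 cm) with a 0.5 cm grey zone;
#'     anatomical reentry.}
#'   \item{scar_large}{as `scar` with a 5.8 cm scar, whose longer rotation
#'     period stays below the channel's detection threshold.}
#' }
#'
#' @param name scenario name.
#' @param bioicd logical: channel expressed.
#' @param nx,ny grid size; the default 256 x 256 at dx = 0.025 cm is the
#'   scaled-down standard domain (6.4 x 6.4 cm).
#' @param duration run length (ms).
#' @param seed seed for substrate generation.
#' @param s2_coupling S1-S2 coupling interval (ms); the defaults were
#'   located with [scan_vulnerable_window()] for each substrate.
#' @param pacing_freq sinus-surrogate pacing rate (Hz).
#' @param config optional [sim_config()] overriding the defaults (its
#'   duration and bioicd flag are taken from the arguments).
#' @param scar_length_cm scar length override for the scar scenarios.
#' @return A `bioicd_record` with `onset` at the S2 time.
#' @export
run_scenario <- function(name = SCENARIOS, bioicd = TRUE, nx = 256, ny = 256,
                         duration = 4200, seed = 1L, s2_coupling = NULL,
                         pacing_freq = 1.2, config = NULL,
                         scar_length_cm = NULL) {
  name <- match.arg(name)
  dx <- 0.025
  substrate <- switch(name,
    vt = build_homogeneous(nx, ny, dx),
    vf = build_homogeneous(nx, ny, dx),
    fibrosis = build_fibrosis(nx, ny, dx, fraction = 0.20, seed = seed),
    scar = build_scar(nx, ny, dx,
                      scar_length_cm = scar_length_cm %||% 3.4,
                      gz_width_cm = 0.5, seed = seed),
    scar_large = build_scar(nx, ny, dx,
                            scar_length_cm = scar_length_cm %||% 5.8,
                            gz_width_cm = 0.5, seed = seed))
  cellp <- if (name == "vf") cell_params(variant = "steep") else cell_params()
  if (is.null(config)) config <- sim_config()
  config$cell_pars <- cellp
  config$bioicd <- bioicd
  config$duration <- duration
  if (is.null(s2_coupling))
    s2_coupling <- switch(name, vt = 340, vf = 320, fibrosis = 340,
                          scar = 340, scar_large = 340)
  period <- 1000 / pacing_freq
  s1_time <- 20
  s2_time <- s1_time + s2_coupling
  # cross-field S2: lower-left quadrant for the functional-reentry
  # substrates; for scar substrates, the half-plane below the scar core so
  # the broken wave anchors to the scar + grey zone
  s2_region <- if (name %in% c("scar", "scar_large")) {
    b_core <- substrate$params$scar_length_cm / 2 * substrate$params$aspect
    region_rect(substrate, 0, substrate$nx * substrate$dx,
                0, substrate$ny * substrate$dx / 2 - b_core)
  } else {
    region_quadrant(substrate, "lower_left")
  }
  events <- list(
    stim_event(s1_time, 2, -52, region_edge_strip(substrate, "left"),
               period = period, label = "pacing"),
    stim_event(s2_time, 2, -52, s2_region, label = "s2"))
  rec <- run_tissue(substrate, config, events, onset = s2_time)
  rec$scenario <- name
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
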