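# Shared test utilities: independent brute-force oracles and synthetic
# record fixtures.

# Forward-Euler integration of the channel ODEs at fixed voltage, vectorized
# over steps (linear time-varying recurrences solved with cumulative
# products). Independent of the package's exponential update path.
euler_channel_fixed_v <- function(v, t_end, dt, o0 = 0, a10 = 0,
                                  pars = bioicd_params()) {
  n <- ceiling(t_end / dt)
  below <- v < pars$v_gate
  win <- v > pars$v_cat_low & v < pars$v_cat_high
  k_co <- if (below) 0 else pars$k_co_on
  k_oc <- if (below) pars$k_oc_base else 0
  k01 <- if (win) pars$k01_on else 0
  k10 <- if (win) 0 else pars$k10_off
  # a1 recurrence has constant coefficients
  qa <- 1 - dt * (k01 + k10) / pars$tau_a
  ba <- dt * k01 / pars$tau_a
  steps <- seq_len(n)
  a1 <- if (k01 + k10 > 0) {
    a_inf <- k01 / (k01 + k10)
    a_inf + (a10 - a_inf) * qa^steps
  } else rep(a10, n)
  a1_prev <- c(a10, a1[-n])
  # O recurrence is linear with time-varying coefficient via koc'(a1);
  # solved blockwise with renormalized cumulative products so the running
  # product cannot underflow on long traces
  koce <- k_oc + pars$k_oc_catalysis_scale * a1_prev^pars$catalyst_power
  qo <- 1 - dt * (k_co + koce) / pars$tau_o
  bo <- dt * k_co / pars$tau_o
  o <- numeric(n)
  o_run <- o0
  blk <- 1000L
  for (start in seq(1L, n, by = blk)) {
    idx <- start:min(n, start + blk - 1L)
    P <- cumprod(qo[idx])
    o[idx] <- P * (o_run + cumsum(bo / P))
    o_run <- o[idx[length(idx)]]
  }
  list(time = steps * dt, o = o, a1 = a1)
}

# Minimal synthetic bioicd_record for metrics tests.
synthetic_record <- function(frame_time, max_ibio, frac_sync, frac_reset,
                             onset = 0, bioicd = TRUE, nx = 4, ny = 4,
                             activations = data.frame(node = integer(),
                                                      time = numeric()),
                             probe_time = frame_time,
                             probe_v = matrix(-85, length(frame_time), 1),
                             probe_index = 1L, events = list()) {
  structure(list(
    substrate = build_homogeneous(max(nx, 16), max(ny, 16)),
    config = sim_config(duration = max(frame_time) + 1),
    events = events,
    probes = list(time = probe_time, names = "p1", index = probe_index,
                  v = probe_v,
                  i_bioicd = matrix(0, length(probe_time), 1),
                  o = matrix(0, length(probe_time), 1),
                  a1 = matrix(0, length(probe_time), 1)),
    frames = data.frame(time = frame_time, max_ibio = max_ibio,
                        frac_sync = frac_sync, frac_reset = frac_reset),
    snapshots = NULL,
    activations = activations,
    state = NULL, t0 = 0, onset = onset, bioicd = bioicd,
    stopped_at = NA_real_), class = "bioicd_record")
}

# Dense-matrix no-flux diffusion operator, assembled explicitly from the
# stencil definition (independent of the solver's fused loop).
dense_laplacian_oracle <- function(substrate) {
  nx <- substrate$nx; ny <- substrate$ny; n <- nx * ny
  w <- substrate$diffusion / 1000 / substrate$dx^2
  cls <- substrate$node_class
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (cls[i] >= 2L) next
    x <- (i - 1L) %% nx; y <- (i - 1L) %/% nx
    for (j in c(if (x > 0) i - 1L, if (x < nx - 1) i + 1L,
                if (y > 0) i - nx, if (y < ny - 1) i + nx)) {
      if (cls[j] >= 2L) next
      L[i, j] <- L[i, j] + w
      L[i, i] <- L[i, i] - w
    }
  }
  L
}

# planar-wave conduction velocity on a thin strip (cm/s), measured between
# the actual probe-node positions
measure_cv <- function(dx_cm, dt = 0.02, length_cm = 6.4) {
  nx <- as.integer(round(length_cm / dx_cm))
  ny <- as.integer(round(0.4 / dx_cm))
  sub <- build_homogeneous(nx, ny, dx_cm)
  xa <- as.integer(nx * 0.4); xb <- as.integer(nx * 0.8)
  cfg <- sim_config(dt = dt, duration = 120, snapshot_every = 0,
                    frame_every = 20, bioicd = FALSE,
                    probes = list(a = c(xa, ny %/% 2), b = c(xb, ny %/% 2)))
  ev <- list(stim_event(5, 2, -52, region_edge_strip(sub, "left")))
  rec <- run_tissue(sub, cfg, ev)
  acts <- rec$activations
  idx <- rec$probes$index
  t1 <- min(acts$time[acts$node == idx[1]])
  t2 <- min(acts$time[acts$node == idx[2]])
  ((xb - xa) * dx_cm) / (t2 - t1) * 1000
}

# square-wave action-potential surrogate voltage at time t (ms)
square_wave_v <- function(t, freq_hz, apd = 300, v_plateau = 0,
                          v_rest = -85) {
  period <- 1000 / freq_hz
  phase <- t %% period
  ifelse(phase < min(apd, period), v_plateau, v_rest)
}
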