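# Monodomain solver: diffusion tensor, no-flux operator vs a dense-matrix
# oracle, conservation, quiescence, single-cell equivalence and conduction.

test_that("diffusion tensor follows the fiber-projection formula", {
  D <- diffusion_tensor(c(1, 0), d_long = 1.54, d_trans = 0.385)
  expect_equal(D, matrix(c(1.54, 0, 0, 0.385), 2, 2))
  # isotropic limit: D * identity for any unit fiber
  a <- c(1, 2) / sqrt(5)
  Di <- diffusion_tensor(a, d_long = 1.2, d_trans = 1.2)
  expect_equal(Di, 1.2 * diag(2))
  # trace identity and symmetry for random unit vectors
  set.seed(1)
  for (k in 1:5) {
    v <- stats::rnorm(2); v <- v / sqrt(sum(v^2))
    Dk <- diffusion_tensor(v, 1.54)
    expect_equal(sum(diag(Dk)), 1.54 + 1.54 / 4)
    expect_equal(Dk, t(Dk))
    expect_true(all(eigen(Dk)$values > 0))
  }
  expect_error(diffusion_tensor(c(1, 1)), "unit norm")
})

test_that("no-flux operator equals the dense-matrix oracle on small grids", {
  set.seed(42)
  sub <- build_fibrosis(16, 16, fraction = 0.15, seed = 8)
  L <- dense_laplacian_oracle(sub)
  myo <- sub$node_class < 2L
  # operator symmetry of the assembled stencil
  expect_equal(L, t(L))
  # a single-node bump and a random field, compared exactly
  for (field in list({v <- rep(0, 256); v[137] <- 1; v},
                     stats::rnorm(256))) {
    got <- laplacian_no_flux(field, sub)
    want <- as.numeric(L %*% field)
    expect_equal(got, want, tolerance = 1e-12)
    # zero-flux conservation: diffusion conserves total voltage
    expect_lt(abs(sum(got[myo])), 1e-10 * max(1, sum(abs(field))))
  }
  # constant field annihilated; linear ramp annihilated in the interior
  hom <- build_homogeneous(16, 16)
  expect_equal(laplacian_no_flux(rep(3.3, 256), hom), rep(0, 256))
  ramp <- matrix(rep(seq_len(16), times = 16), 16, 16) # linear in x
  lr <- laplacian_no_flux(ramp, hom)
  expect_equal(lr[2:15, 2:15], matrix(0, 14, 14))
  expect_error(laplacian_no_flux(rep(0, 100), hom), "shape mismatch")
})

test_that("quiescent tissue stays quiescent", {
  sub <- build_homogeneous(24, 24)
  cfg <- sim_config(duration = 1000, snapshot_every = 0)
  rec <- run_tissue(sub, cfg, events = list())
  v <- rec$probes$v[, 1]
  # no upstrokes anywhere, and the residual relaxation of the published
  # initial state decays (per-ms drift well below a mV and shrinking)
  expect_equal(nrow(rec$activations), 0L)
  late <- abs(diff(tail(v, 200)))
  expect_lt(max(late), 2e-3)
  expect_lt(max(late), max(abs(diff(head(v, 200)))))
  expect_lt(max(abs(v - v[1])), 0.5)
})

test_that("an isolated tissue node reproduces the single-cell module", {
  # 5x5 grid, all voids except the centre node
  cls <- rep(2L, 25); cls[13] <- 0L
  sub <- bioicd:::new_substrate(cls, 5, 5, 0.025, 1.54)
  cfg <- sim_config(duration = 400, probe_every = 0.5, frame_every = 50,
                    snapshot_every = 0, probes = list(c = c(3, 3)),
                    bioicd = TRUE)
  ev <- list(stim_event(10, 2, -52, region = 13L))
  rec <- run_tissue(sub, cfg, ev)
  cell <- run_cell(duration = 400, pulse_times = 10, record_every = 0.5,
                   bioicd = TRUE)
  expect_lt(max(abs(rec$probes$v[, 1] - cell$v)), 1e-9)
  expect_lt(max(abs(rec$probes$o[, 1] - cell$o)), 1e-12)
})

test_that("planar-wave conduction velocity is physiological", {
  cv1 <- measure_cv(0.025)
  expect_gt(cv1, 55); expect_lt(cv1, 85)
})

test_that("stimulus scheduling and stability guard work", {
  sub <- build_homogeneous(16, 16)
  expect_error(run_tissue(sub, sim_config(dt = 0.2, duration = 1)),
               "stability")
  # periodic stimulus fires the expected number of times
  cfg <- sim_config(duration = 950, snapshot_every = 0, bioicd = FALSE)
  ev <- list(stim_event(5, 2, -52, region_edge_strip(sub, "left"),
                        period = 400, label = "pacing"))
  rec <- run_tissue(sub, cfg, ev)
  expect_equal(length(stim_times(rec, "pacing")), 3L) # t = 5, 405, 805
  # all nodes activate after each stimulus on this small sheet
  expect_equal(nrow(rec$activations), 3L * 256L)
})
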