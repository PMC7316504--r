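# Dynamic-clamp emulation: refractory-beat rule, phase bookkeeping,
# feedback, and the frequency dependence of termination.

test_that("refractory-beat rule reads the whole pulse window", {
  expect_true(detect_refractory_beat(rep(-10, 20)))
  expect_false(detect_refractory_beat(c(rep(-10, 10), -30, rep(-10, 9))))
  expect_error(detect_refractory_beat(numeric(0)), "empty")
})

test_that("sub-threshold fast rate reaches a stable 1:1 state with full
           phase bookkeeping", {
  r <- run_dynamic_clamp(dynamic_clamp_protocol(fast_freq = 1.2))
  expect_false(r$terminated)
  expect_true(r$stable)
  counts <- table(r$pulses$phase)
  expect_equal(as.integer(counts[c("1", "2")]), c(7L, 8L))
  # stable-state exit terminates the protocol during phase iii
  expect_gte(as.integer(counts["3"]), 10L)
  expect_false(any(r$pulses$phase > 3))
  # phase annotations partition the trace time axis monotonically
  expect_true(all(diff(r$trace$phase) >= 0))
  expect_true(all(diff(r$trace$time) > 0))
  # no refractory beats anywhere at this gentle rate
  expect_false(any(r$pulses$refractory))
})

test_that("fast pacing with the channel terminates; detection matches a
           brute-force per-pulse scan and feedback stops fast pacing", {
  r <- run_dynamic_clamp(dynamic_clamp_protocol(fast_freq = 5.0))
  expect_true(r$terminated)
  # oracle: recompute every fast pulse's refractory flag from the raw
  # trace and locate the first run of two consecutive refractory pulses
  p3 <- r$pulses[r$pulses$phase == 3, ]
  flags <- vapply(p3$time, function(t0) {
    sel <- r$trace$time >= t0 & r$trace$time <= t0 + 10 + 1e-9
    all(r$trace$v[sel] > -20)
  }, logical(1))
  runs <- rle(flags)
  stopifnot(any(runs$values & runs$lengths >= 2))
  first_block <- cumsum(runs$lengths)[which(runs$values &
                                              runs$lengths >= 2)[1] - 1] + 2
  t_detect <- p3$time[first_block] + 10
  expect_equal(r$time_to_termination, t_detect - p3$time[1])
  expect_identical(p3$refractory, flags)
  # feedback: no fast-rate pulse after the detected block
  expect_equal(nrow(p3), first_block)
  after <- r$pulses[r$pulses$time > p3$time[first_block], ]
  expect_true(all(after$phase >= 4))
  if (nrow(after) > 1)
    expect_true(all(diff(after$time[after$phase %in% 4:5]) > 900))
})

test_that("time to termination decreases with pacing frequency and the
           channel-off control never terminates", {
  r1 <- run_dynamic_clamp(dynamic_clamp_protocol(fast_freq = 4.6),
                          phases = 1:3)
  r2 <- run_dynamic_clamp(dynamic_clamp_protocol(fast_freq = 5.0),
                          phases = 1:3)
  expect_true(r1$terminated && r2$terminated)
  expect_lt(r2$time_to_termination, r1$time_to_termination)
  # phases v-vi: same fast rate, channel disabled -> ordinary 2:1 response,
  # never two consecutive refractory beats, no termination
  off <- run_dynamic_clamp(dynamic_clamp_protocol(fast_freq = 5.0),
                           phases = 5:6)
  expect_false(off$terminated)
  refr <- off$pulses$refractory[off$pulses$phase == 6]
  cons <- rle(refr)
  expect_lte(max(c(0, cons$lengths[cons$values])), 1L)
})

test_that("threshold scan is deterministic and brackets under grid
           refinement", {
  dup <- termination_threshold_scan(variants = c(1, 1), bcl_grid = c(280),
                                    protocol_args = list(max_fast_pulses = 60L))
  expect_equal(dup$baseline_apd90[1], dup$baseline_apd90[2])
  expect_equal(dup$max_terminating_bcl[1], dup$max_terminating_bcl[2])
  coarse <- termination_threshold_scan(variants = c(1, 1),
                                       bcl_grid = seq(300, 260, -20))
  fine <- termination_threshold_scan(variants = c(1, 1),
                                     bcl_grid = seq(300, 260, -10))
  expect_lte(abs(coarse$max_terminating_bcl[1] - fine$max_terminating_bcl[1]),
             20)
  expect_error(termination_threshold_scan(variants = c(1)), "2 cell variants")
})
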