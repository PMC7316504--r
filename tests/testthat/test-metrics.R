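# Metrics on synthetic records with known answers, plus oracle agreement.

test_that("activation time reads the first supra-threshold frame", {
  fr_t <- seq(1000, 2000, by = 2)
  ibio <- ifelse(fr_t >= 1234, 5, 0)
  rec <- synthetic_record(fr_t, ibio, frac_sync = 0, frac_reset = 1,
                          onset = 1000)
  expect_equal(activation_time(rec), 234)
  expect_equal(activation_time(rec, absolute = TRUE), 1234)
  # brute-force frame scan oracle
  expect_equal(activation_time(rec, absolute = TRUE),
               min(fr_t[abs(ibio) > 1]))
  # channel-off records have no activation
  rec_off <- synthetic_record(fr_t, ibio * 0, 0, 1, onset = 1000,
                              bioicd = FALSE)
  expect_true(is.na(activation_time(rec_off)))
  # threshold is configurable
  expect_equal(activation_time(rec, current_threshold = 10), NA_real_)
})

test_that("synchronization and reset durations from constructed fractions", {
  fr_t <- seq(0, 3000, by = 10)
  ibio <- ifelse(fr_t >= 700, 5, 0)
  sync <- ifelse(fr_t >= 900, 0.97, 0.4)
  reset <- ifelse(fr_t >= 1500, 0.995, 0)
  rec <- synthetic_record(fr_t, ibio, sync, reset, onset = 300)
  sr <- synchronization_and_reset(rec)
  expect_equal(sr$activation, 700)
  expect_equal(sr$sync_duration, 200)
  expect_equal(sr$reset_duration, 800)
  # all-quiescent record: sync never reached, reset immediately
  rec2 <- synthetic_record(fr_t, ibio, frac_sync = rep(0, length(fr_t)),
                           frac_reset = rep(1, length(fr_t)), onset = 300)
  sr2 <- synchronization_and_reset(rec2)
  expect_true(is.na(sr2$sync_duration))
  expect_equal(sr2$reset_duration, 0)
  # invariance to frame-cadence refinement within one cadence interval
  fr_f <- seq(0, 3000, by = 2)
  rec3 <- synthetic_record(fr_f, ifelse(fr_f >= 700, 5, 0),
                           ifelse(fr_f >= 900, 0.97, 0.4),
                           ifelse(fr_f >= 1500, 0.995, 0), onset = 300)
  sr3 <- synchronization_and_reset(rec3)
  expect_lt(abs(sr3$sync_duration - sr$sync_duration), 10)
  expect_lt(abs(sr3$reset_duration - sr$reset_duration), 10)
})

test_that("rhythm classifier distinguishes the four regimes", {
  fr_t <- seq(0, 4000, by = 5)
  pace <- stim_event(100, 2, -52, region = 1L, period = 833, label = "pacing")
  # paced 1:1: one activation shortly after each stimulus
  st <- seq(100, 4000, by = 833)
  acts <- data.frame(node = 1L, time = st + 20)
  v <- rep(-80, length(fr_t)); v[(fr_t %% 833) < 300] <- 0
  rec <- synthetic_record(fr_t, 0, 0, 1, activations = acts,
                          probe_v = matrix(v, ncol = 1),
                          events = list(pace))
  expect_equal(rhythm_classifier(rec, window = 2500), "sinus_1to1")
  # reentry: activations at CL 250 without stimuli
  acts2 <- data.frame(node = 1L, time = seq(100, 4000, by = 250))
  rec2 <- synthetic_record(fr_t, 0, 0, 0, activations = acts2,
                           probe_v = matrix(v, ncol = 1),
                           events = list(pace))
  expect_equal(rhythm_classifier(rec2, window = 2500), "reentry")
  # quiescent: no upstrokes anywhere
  rec3 <- synthetic_record(fr_t, 0, 0, 1,
                           probe_v = matrix(-85, length(fr_t), 1),
                           events = list())
  expect_equal(rhythm_classifier(rec3, window = 2500), "quiescent")
  # depolarized block: v above -20 mV throughout
  rec4 <- synthetic_record(fr_t, 0, 1, 0,
                           probe_v = matrix(-5, length(fr_t), 1),
                           events = list())
  expect_equal(rhythm_classifier(rec4, window = 2500), "depolarized_block")
  expect_error(rhythm_classifier(rec3, window = 99999), "window exceeds")
})

test_that("cycle-length map recovers the pacing interval", {
  # uniform 1.2 Hz activations on every node of a 16x16 sheet
  period <- 1000 / 1.2
  nodes <- seq_len(256)
  acts <- data.frame(node = rep(nodes, each = 5),
                     time = rep(seq(0, by = period, length.out = 5),
                                times = 256))
  rec <- synthetic_record(seq(0, 4000, 10), 0, 0, 1, activations = acts)
  clm <- cycle_length_map(rec)
  expect_equal(dim(clm), c(16, 16))
  expect_true(all(abs(clm - period) < 1e-9))
  # quiescent record: all missing
  rec2 <- synthetic_record(seq(0, 4000, 10), 0, 0, 1)
  expect_true(all(is.na(cycle_length_map(rec2))))
  # below the minimum activation count: missing
  acts3 <- data.frame(node = 1L, time = c(0, period))
  rec3 <- synthetic_record(seq(0, 4000, 10), 0, 0, 1, activations = acts3)
  expect_true(all(is.na(cycle_length_map(rec3))))
})

test_that("termination report composes the metrics consistently", {
  fr_t <- seq(0, 4000, by = 5)
  ibio <- ifelse(fr_t >= 800, 5, 0)
  sync <- ifelse(fr_t >= 1000 & fr_t < 1500, 0.99, 0.1)
  reset <- ifelse(fr_t >= 1600, 1, 0) # stays reset (no later beats in fracs)
  pace <- stim_event(100, 2, -52, region = 1L, period = 833, label = "pacing")
  st <- seq(100, 4000, by = 833)
  # probe captures only the stimuli after the reset
  post <- st[st > 1700]
  acts <- data.frame(node = 1L, time = post + 15)
  rec <- synthetic_record(fr_t, ibio, sync, reset, onset = 400,
                          activations = acts, events = list(pace))
  rep <- termination_report(rec)
  expect_equal(rep$arrhythmia_onset, 400)
  expect_equal(rep$bioicd_activation_time, 400)
  expect_equal(rep$synchronization_duration, 200)
  expect_equal(rep$reset_duration, 800)
  expect_true(rep$restored)
  expect_equal(rep$total_time_onset_to_restoration, post[1] - 400)
  # ordering invariant when restored
  expect_true(rep$bioicd_activation_time > 0 &&
              rep$synchronization_duration < rep$reset_duration)
})
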