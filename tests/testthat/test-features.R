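test_that("spike detection counts and measures constructed spikes", {
  p50 <- default_cip(50)
  flat <- make_spike_trace(numeric(0), protocol = p50)
  expect_equal(nrow(detect_spikes(flat)), 0)

  # train of 28 identical waveforms inside the pulse
  times <- seq(150, 1060, length.out = 28)
  tr <- make_spike_trace(times, protocol = p50)
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 28)

  # hand-constructed triangular spike: threshold -44, peak +18
  tr1 <- make_spike_trace(500, thr = -44, peak = 18, rise = 0.5, fall = 0.8,
                          dt = 0.01, protocol = p50)
  sp1 <- detect_spikes(tr1)
  expect_equal(nrow(sp1), 1)
  expect_equal(sp1$threshold, -44, tolerance = 0.5)
  expect_equal(sp1$amplitude, 62, tolerance = 1)
  # half-amplitude level is -13 mV; width from the constructed ramps:
  # rise crosses at 31/62 * 0.5 ms before peak, fall at 31/88 * 0.8 ms after
  hw_expected <- 0.5 * 31 / 62 + 0.8 * 31 / 88
  expect_equal(sp1$half_width, hw_expected, tolerance = 0.05)

  # sub-threshold noise below 1 mV does not change the count
  noisy <- tr
  noisy$V <- noisy$V +
    withr::with_seed(11, runif(length(noisy$V), -0.4, 0.4))
  expect_equal(nrow(detect_spikes(noisy)), 28)
})

test_that("measurement sets have the contracted sizes 5/1/10/2 per CIP class", {
  expect_length(measurement_names("hyperpolarizing"), 5)
  expect_length(measurement_names("passive_depol"), 1)
  expect_length(measurement_names("active_depol"), 10)
  expect_length(measurement_names("depol_block"), 2)
  expect_error(measurement_names("weird"), "unknown")
})

test_that("hyperpolarizing measurements on a clean step have no sag", {
  p <- default_cip(-100)
  t <- seq(0, 1300, by = 0.05)
  V <- ifelse(t >= 100 & t < 1100, -105, -70)
  tr <- structure(list(t = t, V = V, protocol = p), class = "ns_trace")
  fv <- measure_cip(tr)
  expect_equal(unname(fv["hyperpol_vm_diff"]), -35)
  expect_equal(unname(fv["potential_sag"]), 0)
  expect_equal(unname(fv["sag_time_constant"]), 0)
  expect_equal(unname(fv["min_potential"]), -105)
})

test_that("sag and its time constant are recovered from an exponential rebound", {
  p <- default_cip(-100)
  t <- seq(0, 1300, by = 0.05)
  V <- rep(-70, length(t))
  pulse <- t >= 100 & t < 1100
  # drop to -112, rebound to steady -105 with tau = 15 ms
  tp <- t[pulse] - 100
  V[pulse] <- -105 - 7 * exp(-pmax(tp - 40, 0) / 15)
  V[pulse][tp < 40] <- -70 + (-112 + 70) * tp[tp < 40] / 40
  tr <- structure(list(t = t, V = V, protocol = p), class = "ns_trace")
  fv <- measure_cip(tr)
  expect_equal(unname(fv["min_potential"]), -112, tolerance = 0.01)
  expect_equal(unname(fv["min_potential_time"]), 40, tolerance = 0.5)
  expect_equal(unname(fv["potential_sag"]), 7, tolerance = 0.05)
  expect_equal(unname(fv["sag_time_constant"]), 15, tolerance = 1)
})

test_that("depolarization-block measurements use the final 700 ms and first 100 ms", {
  p <- default_cip(500)
  # 6 evenly spaced spikes within the first 100 ms, then silence
  tr <- make_spike_trace(seq(105, 195, length.out = 6), protocol = p)
  fv <- measure_cip(tr)
  expect_equal(unname(fv["initial_rate_100ms"]), 60)
  # Vm difference over the final 700 ms only
  t <- tr$t
  late <- t >= 400 & t < 1100
  base <- t < 100
  expect_equal(unname(fv["depol_block_vm_diff"]),
               mean(tr$V[late]) - mean(tr$V[base]), tolerance = 1e-9)
})

test_that("active-depolarization measurements match their construction", {
  p <- default_cip(50)
  times <- seq(133.1, by = 36.69, length.out = 12)
  tr <- make_spike_trace(times, protocol = p)
  fv <- measure_cip(tr)
  expect_equal(unname(fv["n_spikes"]), 12)
  expect_equal(unname(fv["first_spike_time"]), 33.1, tolerance = 0.2)
  expect_equal(unname(fv["interspike_interval"]), 36.69, tolerance = 0.05)
  expect_equal(unname(fv["spike_rate"]), 12 / 1.0)
  expect_equal(unname(fv["spike_freq_adaptation"]), 1, tolerance = 0.01)
})

test_that("measurements are invariant to shifting the time axis", {
  p <- default_cip(50)
  times <- seq(140, 1000, length.out = 9)
  tr <- make_spike_trace(times, protocol = p)
  fv0 <- measure_cip(tr)
  shift <- 500
  p2 <- cip_protocol(50, baseline = 100 + shift, pulse = 1000,
                     recovery = 200, cip_class = "active_depol")
  # same waveform, clock offset by +500 ms
  tr2 <- make_spike_trace(times + shift, total = 1300 + shift, protocol = p2)
  fv2 <- measure_cip(tr2)
  expect_equal(fv2, fv0, tolerance = 1e-6)
})

test_that("elimination implements the five failure criteria and the accepting case", {
  mk <- function(amp, times, tail_V = NULL) {
    p <- default_cip(amp)
    tr <- make_spike_trace(times, protocol = p)
    if (!is.null(tail_V)) tr$V[tr$t >= 1100] <- tail_V
    tr
  }
  ok <- list(hyperpolarizing = mk(-100, numeric(0)),
             passive_depol = mk(20, numeric(0)),
             active_depol = mk(50, seq(150, 1050, length.out = 10)),
             depol_block = mk(500, seq(105, 350, length.out = 15)))
  res <- eliminate_model(ok)
  expect_true(res$passed)
  expect_length(res$reasons, 0)

  cases <- list(
    list(sub = list(passive_depol = mk(20, 300)), reason = "spikes_20pA"),
    list(sub = list(active_depol = mk(50, c(200, 400))),
         reason = "few_spikes_50pA"),
    list(sub = list(active_depol = {
      tr <- mk(50, seq(150, 1050, length.out = 10), tail_V = -40); tr
    }), reason = "no_repolarization_50pA"),
    list(sub = list(depol_block = mk(500, c(150, 950))),
         reason = "late_spikes_500pA"),
    list(sub = list(depol_block = mk(500, c(150, 1150))),
         reason = "recovery_spikes_500pA"),
    list(sub = list(depol_block = {
      tr <- mk(500, 150, tail_V = -30); tr
    }), reason = "no_repolarization_500pA"))
  for (cs in cases) {
    sims <- ok
    sims[names(cs$sub)] <- cs$sub
    res <- eliminate_model(sims)
    expect_false(res$passed)
    expect_true(cs$reason %in% res$reasons)
  }
  expect_error(eliminate_model(ok[-4]), "missing CIP")
})

test_that("removing late spikes can only flip the late-spike criterion fail to pass", {
  p <- default_cip(500)
  failing <- list(
    hyperpolarizing = make_spike_trace(numeric(0), protocol = default_cip(-100)),
    passive_depol = make_spike_trace(numeric(0), protocol = default_cip(20)),
    active_depol = make_spike_trace(seq(150, 1050, length.out = 8),
                                    protocol = default_cip(50)),
    depol_block = make_spike_trace(c(150, 250, 700, 950), protocol = p))
  r1 <- eliminate_model(failing)
  expect_true("late_spikes_500pA" %in% r1$reasons)
  fixed <- failing
  fixed$depol_block <- make_spike_trace(c(150, 250), protocol = p)
  r2 <- eliminate_model(fixed)
  expect_false("late_spikes_500pA" %in% r2$reasons)
  # monotone: no new reasons appear
  expect_true(all(r2$reasons %in% r1$reasons))
})

test_that("the packaged IS3 reference constants are complete and consistent", {
  ref <- is3_reference()
  for (cl in names(ref))
    expect_identical(names(ref[[cl]]), measurement_names(cl))
  expect_equal(unname(ref$active_depol["n_spikes"]), 28)
  expect_equal(unname(ref$depol_block["initial_rate_100ms"]), 60)
})
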