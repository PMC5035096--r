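# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; no binary data.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_morph <- function() fx("morph", function() make_fixture_morphology())

fx_cmodel <- function() fx("cmodel", function() fixture_cmodel())

fx_truth <- function() fx("truth", function() ground_truth("SDprox.2"))

fx_truth_model <- function() fx("truth_model", function()
  build_model(fx_cmodel(), fx_truth()$scenario, fx_truth()$densities,
              d = fx_truth()$d))

fx_reference <- function() fx("reference", function()
  make_reference(fx_truth(), fx_cmodel()))

fx_truth_sims <- function() fx("truth_sims", function()
  run_cips(fx_truth_model()))

# the shared 27-model screening database (the expensive fixture)
fx_db <- function() fx("db", function()
  generate_database(fx_cmodel(), fx_truth()$scenario,
                    fixture_grid("SDprox.2"), fx_reference(),
                    store_traces = TRUE))

# simple geometric morphologies built from package internals
ns_internal <- function(name) get(name, envir = asNamespace("neuroscreen"))

make_cylinder_morph <- function(soma_len = 10, soma_diam = 10,
                                dend_len = 500, dend_diam = 2,
                                name = "cyl") {
  new_section <- ns_internal("new_section")
  new_morphology <- ns_internal("new_morphology")
  soma <- cbind(x = c(-soma_len / 2, 0, soma_len / 2), y = 0, z = 0,
                diam = soma_diam)
  dend <- cbind(x = c(soma_len / 2, soma_len / 2 + dend_len), y = 0, z = 0,
                diam = dend_diam)
  new_morphology(list(
    new_section(1L, "soma", "soma", soma, NULL),
    new_section(2L, "dendrite", "1", dend, list(id = 1L, frac = 1))), name)
}

make_big_iso_soma <- function(len = 50, diam = 50) {
  new_section <- ns_internal("new_section")
  new_morphology <- ns_internal("new_morphology")
  soma <- cbind(x = c(0, len), y = 0, z = 0, diam = diam)
  new_morphology(list(new_section(1L, "soma", "soma", soma, NULL)), "iso")
}

# synthetic voltage trace with triangular spikes at given times
make_spike_trace <- function(spike_times, baseline = -70, thr = -44,
                             peak = 18, dt = 0.05, total = 1300,
                             rise = 0.5, fall = 0.8, protocol = NULL) {
  t <- seq(0, total, by = dt)
  V <- rep(baseline, length(t))
  for (ts in spike_times) {
    # ramp baseline->peak over (rise + pre) and back down
    pre <- 2   # slow approach from baseline to threshold
    idx <- which(t >= ts - pre & t <= ts + fall)
    for (i in idx) {
      ti <- t[i]
      V[i] <- max(V[i],
        if (ti <= ts - rise) baseline + (thr - baseline) * (ti - (ts - pre)) / (pre - rise)
        else if (ti <= ts) thr + (peak - thr) * (ti - (ts - rise)) / rise
        else peak + (baseline - peak) * (ti - ts) / fall)
    }
  }
  structure(list(t = t, V = V, dt = dt, protocol = protocol),
            class = "ns_trace")
}

default_cip <- function(amp, cip_class = NULL)
  cip_protocol(amp, baseline = 100, pulse = 1000, recovery = 200,
               cip_class = cip_class)
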