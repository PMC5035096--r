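# ---------------------------------------------------------------------------
# Current-clamp protocols, synapses, noise, and the simulation front end.
#
# Internal units contract: mV, ms, um, S/cm^2, uF/cm^2, Ohm cm; point
# currents nA; synaptic weight uS.  Protocol amplitudes are taken in pA at
# the user surface and converted once, here.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' @param dt time step, ms.
#' @param method \code{"backward_euler"} (robust default for screening
#'   sweeps) or \code{"crank_nicolson"}.
#' @param record list of record locations \code{c(section_id, fraction)};
#'   \code{NULL} records the soma center.
#' @param settle_ms settle-to-steady-state pre-run before each protocol,
#'   ms (discarded from analysis).
#' @param record_stride record every this-many steps (1 = every step).
#' @return list of class \code{ns_simconfig}.
#' @export
sim_config <- function(dt = 0.025, method = c("backward_euler", "crank_nicolson"),
                       record = NULL, settle_ms = 500, record_stride = 1) {
  stopifnot(dt > 0)
  method <- match.arg(method)
  structure(list(dt = dt, method = method, record = record,
                 settle_ms = settle_ms, record_stride = record_stride),
            class = "ns_simconfig")
}

#' Current-injection protocol (CIP)
#'
#' A somatic current step of fixed amplitude with a silent baseline before
#' and a recovery period after.  The CIP class used by feature extraction is
#' inferred from the amplitude unless given: negative amplitudes are
#' hyperpolarizing, small positive ones passive depolarization, moderate
#' ones active depolarization, and large ones depolarization block.
#'
#' @param amp_pA step amplitude, pA.
#' @param baseline,pulse,recovery durations, ms.
#' @param cip_class optional explicit class.
#' @param site injection location \code{c(section_id, fraction)};
#'   \code{NULL} = soma center.
#' @return object of class \code{ns_protocol}.
#' @export
cip_protocol <- function(amp_pA, baseline = 100, pulse = 1000, recovery = 200,
                         cip_class = NULL, site = NULL) {
  if (is.null(cip_class)) {
    cip_class <- if (amp_pA < 0) "hyperpolarizing"
      else if (amp_pA <= 30) "passive_depol"
      else if (amp_pA <= 200) "active_depol"
      else "depol_block"
  }
  structure(list(
    pulses = data.frame(onset = baseline, dur = pulse, amp_pA = amp_pA),
    baseline = baseline, pulse = pulse, recovery = recovery,
    total_ms = baseline + pulse + recovery,
    amp_pA = amp_pA, cip_class = cip_class, site = site),
    class = "ns_protocol")
}

#' Backpropagating action potential protocol
#'
#' Train of brief strong somatic pulses (default three 2 ms, 800 pA steps at
#' 10 ms onset spacing) used to evoke backpropagating spikes.
#'
#' @param n_pulses number of pulses.
#' @param amp_pA pulse amplitude, pA.
#' @param dur pulse duration, ms.
#' @param interval onset-to-onset spacing, ms.
#' @param baseline,recovery quiet periods, ms.
#' @param site injection location; \code{NULL} = soma center.
#' @return object of class \code{ns_protocol}.
#' @export
bap_protocol <- function(n_pulses = 3, amp_pA = 800, dur = 2, interval = 10,
                         baseline = 50, recovery = 80, site = NULL) {
  onsets <- baseline + (seq_len(n_pulses) - 1) * interval
  structure(list(
    pulses = data.frame(onset = onsets, dur = dur, amp_pA = amp_pA),
    baseline = baseline, pulse = max(onsets) + dur - baseline,
    recovery = recovery,
    total_ms = max(onsets) + dur + recovery,
    amp_pA = amp_pA, cip_class = "bap", site = site),
    class = "ns_protocol")
}

#' Double-exponential synapse specification
#'
#' Two-state kinetic synapse G(t) = weight * factor *
#' (exp(-t/tau2) - exp(-t/tau1)) for each presynaptic spike, with the factor
#' normalizing the peak conductance of a single event to the weight.
#'
#' @param location \code{c(section_id, fraction)}.
#' @param weight peak synaptic conductance, uS (>= 0).
#' @param onsets presynaptic spike times, ms.
#' @param tau1 rise time constant, ms.
#' @param tau2 decay time constant, ms.
#' @param e reversal potential, mV.
#' @return object of class \code{ns_synapse}.
#' @export
synapse_spec <- function(location, weight, onsets, tau1 = 0.2, tau2 = 2,
                         e = 0) {
  if (tau1 <= 0 || tau1 >= tau2) stop("require 0 < tau1 < tau2")
  if (weight < 0) stop("weight must be >= 0")
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  factor <- 1 / (exp(-tp / tau2) - exp(-tp / tau1))
  structure(list(location = location, weight = weight, onsets = onsets,
                 tau1 = tau1, tau2 = tau2, e = e, factor = factor,
                 t_peak = tp),
            class = "ns_synapse")
}

#' Synaptic conductance time course
#'
#' @param spec an \code{ns_synapse}.
#' @param t time(s), ms (same clock as the onsets).
#' @return conductance, uS.
#' @export
synaptic_conductance <- function(spec, t) {
  G <- numeric(length(t))
  for (on in spec$onsets) {
    td <- t - on
    act <- td > 0
    G[act] <- G[act] + spec$weight * spec$factor *
      (exp(-td[act] / spec$tau2) - exp(-td[act] / spec$tau1))
  }
  G
}

#' Gaussian white-noise injected current
#'
#' Zero-mean Gaussian samples, one per time step, reproducible for a given
#' seed (the global RNG state is restored afterwards).
#'
#' @param noise list with \code{sd_pA} and \code{seed} (see
#'   \code{\link{noise_spec}}).
#' @param dt time step, ms (one sample per step).
#' @param n_steps number of samples.
#' @return numeric vector of currents, pA.
#' @export
inject_noise <- function(noise, dt, n_steps) {
  if (is.null(noise) || !isTRUE(noise$enabled) || noise$sd_pA == 0)
    return(numeric(n_steps))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  rnorm(n_steps, mean = 0, sd = noise$sd_pA)
}

#' Noise specification
#' @param sd_pA standard deviation of the white-noise current, pA.
#' @param seed RNG seed (required for reproducibility).
#' @param site injection location; \code{NULL} = soma center.
#' @param enabled logical.
#' @export
noise_spec <- function(sd_pA, seed, site = NULL, enabled = TRUE) {
  list(sd_pA = sd_pA, seed = as.integer(seed), site = site, enabled = enabled)
}

# ---------------------------------------------------------------------------
# Assembly: biophysical model -> integrator arguments
# ---------------------------------------------------------------------------

VGRID_MIN <- -150
VGRID_MAX <- 100
VGRID_STEP <- 0.05

assemble_system <- function(model, dt) {
  cc <- model$cmodel$comps
  vgrid <- seq(VGRID_MIN, VGRID_MAX, by = VGRID_STEP)
  chans <- lapply(names(model$channels), function(nm) {
    ch <- model$channels[[nm]]
    gates <- lapply(ch$gates, function(g) {
      tau <- gate_tau(g, vgrid)
      list(exponent = as.integer(g$exponent),
           inf = gate_inf(g, vgrid),
           efac = exp(-dt / tau))
    })
    list(name = nm, erev = ch$erev, gbar = model$gbar_uS[, nm], gates = gates)
  })
  list(parent = as.integer(cc$parent) - 1L,   # 0-based; root -1
       g_ax = cc$g_ax,
       cap = model$cap_nF,
       g_pas = model$g_pas_uS,
       e_pas = model$e_pas_mV,
       vmin = VGRID_MIN, vstep = VGRID_STEP, ntab = length(vgrid),
       channels = chans)
}

initial_state <- function(model, V = NULL) {
  n <- nrow(model$cmodel$comps)
  if (is.null(V)) V <- model$e_pas_mV
  if (length(V) == 1) V <- rep(V, n)
  gates <- lapply(model$channels, function(ch) {
    gm <- vapply(ch$gates, function(g) gate_inf(g, V), numeric(n))
    matrix(gm, nrow = n)
  })
  list(V = V, gates = unname(gates))
}

resolve_site <- function(model, site) {
  if (is.null(site)) soma_comp(model$cmodel)
  else comp_at(model$cmodel, site[1], site[2])
}

#' Resting state of a model
#'
#' Settles the model to steady state with zero stimulus and returns the
#' final state, reusable as \code{init_state} in \code{\link{simulate_model}}
#' to avoid repeating the settle run (e.g. across a threshold-weight scan).
#'
#' @param model an \code{ns_biomodel}.
#' @param config an \code{ns_simconfig}.
#' @param settle_ms settle duration, ms.
#' @return an opaque state list.
#' @export
resting_state <- function(model, config = sim_config(),
                          settle_ms = config$settle_ms) {
  sys <- assemble_system(model, config$dt)
  theta <- if (config$method == "crank_nicolson") 0.5 else 1
  n_steps <- max(1L, as.integer(round(settle_ms / config$dt)))
  res <- .cable_sim(sys,
                    list(pulses = matrix(0, 0, 4), synapses = list(),
                         noise = numeric(0), noise_comp = -1L),
                    initial_state(model), config$dt, n_steps,
                    record = as.integer(soma_comp(model$cmodel)) - 1L,
                    theta = theta, t0 = 0, record_stride = n_steps)
  res$state
}

#' Simulate a model under a current-clamp protocol
#'
#' Integrates the branched-cable equations with an implicit tree solver.
#' Unless an initial state is supplied the model is first settled to steady
#' state for \code{config$settle_ms} (discarded).  Deterministic given the
#' noise seed.
#'
#' @param model an \code{ns_biomodel}.
#' @param protocol an \code{ns_protocol}.
#' @param synapses list of \code{ns_synapse} (onset times on the protocol
#'   clock, where 0 is the start of the baseline).
#' @param noise optional \code{\link{noise_spec}}.
#' @param config an \code{ns_simconfig}.
#' @param init_state optional state from \code{\link{resting_state}} or a
#'   previous run.
#' @return list of traces (class \code{ns_trace}: \code{t} ms, \code{V} mV,
#'   site, dt), one per record location, with the final state in attribute
#'   \code{"state"} and the protocol in attribute \code{"protocol"}.
#' @export
simulate_model <- function(model, protocol, synapses = list(), noise = NULL,
                           config = sim_config(), init_state = NULL) {
  stopifnot(inherits(model, "ns_biomodel"), inherits(protocol, "ns_protocol"))
  sys <- assemble_system(model, config$dt)
  theta <- if (config$method == "crank_nicolson") 0.5 else 1
  if (is.null(init_state)) {
    init_state <- if (config$settle_ms > 0)
      resting_state(model, config) else initial_state(model)
  }
  n_steps <- as.integer(round(protocol$total_ms / config$dt))
  inj_comp <- resolve_site(model, protocol$site)
  pulses <- if (nrow(protocol$pulses)) {
    cbind(inj_comp - 1L, protocol$pulses$onset, protocol$pulses$dur,
          protocol$pulses$amp_pA / 1000)  # pA -> nA
  } else matrix(0, 0, 4)
  syns <- lapply(synapses, function(sy) {
    list(comp = resolve_site(model, sy$location) - 1L, e = sy$e,
         tau1 = sy$tau1, tau2 = sy$tau2, weight = sy$weight,
         factor = sy$factor, onsets = as.numeric(sy$onsets))
  })
  noise_comp <- -1L
  noise_series <- numeric(0)
  if (!is.null(noise) && isTRUE(noise$enabled)) {
    noise_comp <- resolve_site(model, noise$site) - 1L
    noise_series <- inject_noise(noise, config$dt, n_steps) / 1000  # pA -> nA
  }
  rec_sites <- config$record
  if (is.null(rec_sites)) rec_sites <- list(NULL)
  rec_comps <- vapply(rec_sites, function(s) resolve_site(model, s), integer(1))
  res <- .cable_sim(sys,
                    list(pulses = pulses, synapses = syns,
                         noise = noise_series, noise_comp = noise_comp),
                    init_state, config$dt, n_steps,
                    record = as.integer(rec_comps) - 1L, theta = theta,
                    t0 = 0, record_stride = config$record_stride)
  traces <- lapply(seq_along(rec_comps), function(r) {
    structure(list(t = res$t, V = res$V[, r],
                   site = rec_sites[[r]], comp = rec_comps[r],
                   dt = config$dt * config$record_stride),
              class = "ns_trace")
  })
  attr(traces, "state") <- res$state
  attr(traces, "protocol") <- protocol
  traces
}

#' @export
print.ns_trace <- function(x, ...) {
  cat("Voltage trace: ", length(x$t), " samples, dt = ", x$dt, " ms, V in [",
      round(min(x$V), 2), ", ", round(max(x$V), 2), "] mV\n", sep = "")
  invisible(x)
}

#' Write a trace as two-column delimited text (time_ms, voltage_mV)
#' @param trace an \code{ns_trace}.
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  write.table(data.frame(time_ms = trace$t, voltage_mV = trace$V),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the leak reversal so the model rests at a target potential
#'
#' For a passive model the resting potential equals a uniform leak reversal
#' by construction; with active channels open at rest the two differ.  This
#' adjusts a uniform e_leak by root finding on the settled somatic potential.
#'
#' @param model an \code{ns_biomodel}.
#' @param target target somatic resting potential, mV.
#' @param config an \code{ns_simconfig}.
#' @param tol tolerance on the resting potential, mV.
#' @return the model with adjusted \code{e_pas_mV}.
#' @export
fit_eleak <- function(model, target = -69.7, config = sim_config(),
                      tol = 0.05) {
  soma <- soma_comp(model$cmodel)
  rest_at <- function(el) {
    m <- model
    m$e_pas_mV <- rep(el, length(m$e_pas_mV))
    st <- resting_state(m, config)
    st$V[soma] - target
  }
  if (is_passive_model(model)) {
    model$e_pas_mV <- rep(target, length(model$e_pas_mV))
    return(model)
  }
  lo <- target - 15; hi <- target + 5
  r <- uniroot(rest_at, c(lo, hi), tol = tol, extendInt = "upX")
  model$e_pas_mV <- rep(r$root, length(model$e_pas_mV))
  model
}
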