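# ---------------------------------------------------------------------------
# Signature-feature extraction and criterion-based model elimination.
#
# Each CIP class carries a fixed measurement set: 5 at the hyperpolarizing
# step, 1 at the passive depolarization, 10 at the active depolarization,
# 2 at the depolarization-block step.  Vm differences are mean-during-pulse
# minus mean-during-baseline; the depolarization-block Vm difference uses
# only the final 700 ms of the pulse.
# ---------------------------------------------------------------------------

#' Feature-extraction configuration
#'
#' @param detect_level voltage a spike peak must exceed, mV.
#' @param slope_crit dV/dt criterion locating the spike threshold, mV/ms.
#' @param repol_tol repolarization tolerance: the mean potential over the
#'   last \code{repol_window} ms of the recovery period must return to
#'   within this many mV of baseline, mV.
#' @param repol_window window for the repolarization check, ms.
#' @param sag_min minimum rebound treated as a sag, mV (smaller sags get a
#'   0 time constant).
#' @param adaptation \code{"last2_over_first2"} (ratio of the mean of the
#'   last two ISIs to the mean of the first two) — configurable because
#'   toolbox definitions differ.
#' @export
feature_config <- function(detect_level = 0, slope_crit = 20,
                           repol_tol = 10, repol_window = 50,
                           sag_min = 0.1,
                           adaptation = "last2_over_first2") {
  list(detect_level = detect_level, slope_crit = slope_crit,
       repol_tol = repol_tol, repol_window = repol_window,
       sag_min = sag_min, adaptation = adaptation)
}

#' Detect spikes and per-spike shape measures in a voltage trace
#'
#' Spikes are local maxima above \code{detect_level} following an upward
#' crossing.  The per-spike threshold is the voltage where dV/dt first
#' exceeds \code{slope_crit} during the upstroke; amplitude is peak minus
#' threshold; half-width is measured at threshold + amplitude/2; the
#' afterhyperpolarization depth is threshold minus the post-spike minimum
#' before the next spike.
#'
#' @param trace an \code{ns_trace} (or list with \code{t}, \code{V}).
#' @param config a \code{\link{feature_config}}.
#' @return data.frame of class \code{ns_spiketrain} with columns
#'   \code{time, peak, threshold, amplitude, half_width, ahp} (possibly
#'   zero rows).
#' @export
detect_spikes <- function(trace, config = feature_config()) {
  t <- trace$t; V <- trace$V
  n <- length(V)
  empty <- data.frame(time = numeric(0), peak = numeric(0),
                      threshold = numeric(0), amplitude = numeric(0),
                      half_width = numeric(0), ahp = numeric(0))
  class(empty) <- c("ns_spiketrain", "data.frame")
  if (n < 3) return(empty)
  lev <- config$detect_level
  above <- V >= lev
  up <- which(!above[-n] & above[-1]) + 1L     # first sample at/above level
  if (!length(up)) return(empty)
  dt <- diff(t)
  dVdt <- c(diff(V) / dt, 0)
  rows <- list()
  for (k in seq_along(up)) {
    i0 <- up[k]
    i1 <- if (k < length(up)) up[k + 1] - 1L else n
    # end of the supra-level excursion
    below <- which(!above[i0:i1])
    iend <- if (length(below)) i0 + below[1] - 2L else i1
    pk <- i0 - 1L + which.max(V[i0:iend])
    # threshold: first supra-criterion dV/dt during this upstroke
    wstart <- if (k > 1) up[k - 1L] else 1L
    trough <- wstart - 1L + which.min(V[wstart:pk])
    cand <- which(dVdt[trough:(pk - 1L)] >= config$slope_crit)
    j <- if (length(cand)) trough + cand[1] - 1L else i0
    thr <- V[j]
    amp <- V[pk] - thr
    if (amp <= 0) next
    half_lev <- thr + amp / 2
    # half-width: interpolated crossings of half_lev around the peak
    iu <- pk
    while (iu > 1L && V[iu - 1L] >= half_lev) iu <- iu - 1L
    t_up <- if (iu > 1L && V[iu] != V[iu - 1L])
      t[iu - 1L] + (half_lev - V[iu - 1L]) / (V[iu] - V[iu - 1L]) *
        (t[iu] - t[iu - 1L]) else t[iu]
    id <- pk
    while (id < n && V[id + 1L] >= half_lev) id <- id + 1L
    t_dn <- if (id < n && V[id] != V[id + 1L])
      t[id] + (half_lev - V[id]) / (V[id + 1L] - V[id]) *
        (t[id + 1L] - t[id]) else t[id]
    # AHP: minimum before the next spike's upstroke (or end of trace)
    inext <- if (k < length(up)) up[k + 1] else n
    ahp <- if (inext > pk) thr - min(V[pk:inext]) else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(time = t[pk], peak = V[pk], threshold = thr,
                 amplitude = amp, half_width = t_dn - t_up, ahp = ahp)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("ns_spiketrain", "data.frame")
  out
}

#' Measurement names per CIP class
#' @param cip_class one of "hyperpolarizing", "passive_depol",
#'   "active_depol", "depol_block".
#' @return character vector of measurement names (lengths 5, 1, 10, 2).
#' @export
measurement_names <- function(cip_class) {
  switch(cip_class,
    hyperpolarizing = c("hyperpol_vm_diff", "min_potential_time",
                        "min_potential", "potential_sag",
                        "sag_time_constant"),
    passive_depol = "passive_vm_diff",
    active_depol = c("active_vm_diff", "interspike_interval",
                     "first_spike_time", "spike_threshold_mean",
                     "spike_halfwidth_mean", "spike_amplitude_mean",
                     "spike_rate", "spike_ahp_mean", "n_spikes",
                     "spike_freq_adaptation"),
    depol_block = c("depol_block_vm_diff", "initial_rate_100ms"),
    stop("unknown CIP class: ", cip_class))
}

# single-exponential fit of the sag rebound; returns tau in ms
fit_sag_tau <- function(t, V, v_ss) {
  # V(t) = v_ss - A exp(-t/tau); log-linear fit on v_ss - V where positive
  y <- v_ss - V
  keep <- y > 1e-6
  if (sum(keep) < 3) return(0)
  fit <- try(lm(log(y[keep]) ~ t[keep]), silent = TRUE)
  if (inherits(fit, "try-error")) return(0)
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(0)
  as.numeric(-1 / slope)
}

#' Extract the CIP measurement set from a voltage trace
#'
#' @param trace an \code{ns_trace} carrying its protocol (from
#'   \code{\link{simulate_model}}), or any list with \code{t}, \code{V} if
#'   \code{protocol} is supplied.
#' @param cip_class CIP class; defaults to the protocol's.
#' @param protocol the \code{ns_protocol} defining baseline/pulse/recovery
#'   windows.
#' @param config a \code{\link{feature_config}}.
#' @return named numeric feature vector (see
#'   \code{\link{measurement_names}}).
#' @export
measure_cip <- function(trace, cip_class = NULL, protocol = trace$protocol,
                        config = feature_config()) {
  if (is.null(protocol)) stop("trace carries no protocol")
  if (is.null(cip_class)) cip_class <- protocol$cip_class
  t <- trace$t; V <- trace$V
  t_on <- protocol$pulses$onset[1]
  t_off <- t_on + protocol$pulses$dur[1]
  in_base <- t < t_on
  in_pulse <- t >= t_on & t < t_off
  if (!any(in_base) || !any(in_pulse))
    stop("trace does not cover the protocol window")
  v_base <- mean(V[in_base])
  out <- switch(cip_class,
    hyperpolarizing = {
      vmin_i <- which(in_pulse)[which.min(V[in_pulse])]
      v_ss <- mean(V[t >= t_off - 0.1 * protocol$pulses$dur[1] & t < t_off])
      sag <- v_ss - V[vmin_i]
      tau <- if (sag >= config$sag_min) {
        seg <- t >= t[vmin_i] & t < t_off
        fit_sag_tau(t[seg] - t[vmin_i], V[seg], v_ss)
      } else 0
      c(hyperpol_vm_diff = mean(V[in_pulse]) - v_base,
        min_potential_time = t[vmin_i] - t_on,
        min_potential = V[vmin_i],
        potential_sag = max(sag, 0),
        sag_time_constant = tau)
    },
    passive_depol = c(passive_vm_diff = mean(V[in_pulse]) - v_base),
    active_depol = {
      sp <- detect_spikes(trace, config)
      sp <- sp[sp$time >= t_on & sp$time < t_off, , drop = FALSE]
      nsp <- nrow(sp)
      isi <- if (nsp >= 2) diff(sp$time) else numeric(0)
      adap <- if (length(isi) >= 2) {
        k <- min(2, length(isi))
        mean(tail(isi, k)) / mean(head(isi, k))
      } else NA_real_
      c(active_vm_diff = mean(V[in_pulse]) - v_base,
        interspike_interval = if (length(isi)) mean(isi) else NA_real_,
        first_spike_time = if (nsp) sp$time[1] - t_on else NA_real_,
        spike_threshold_mean = if (nsp) mean(sp$threshold) else NA_real_,
        spike_halfwidth_mean = if (nsp) mean(sp$half_width) else NA_real_,
        spike_amplitude_mean = if (nsp) mean(sp$amplitude) else NA_real_,
        spike_rate = nsp / (protocol$pulses$dur[1] / 1000),
        spike_ahp_mean = if (nsp) mean(sp$ahp, na.rm = TRUE) else NA_real_,
        n_spikes = nsp,
        spike_freq_adaptation = adap)
    },
    depol_block = {
      sp <- detect_spikes(trace, config)
      late <- t >= t_off - 700 & t < t_off
      n100 <- sum(sp$time >= t_on & sp$time < t_on + 100)
      c(depol_block_vm_diff = mean(V[late]) - v_base,
        initial_rate_100ms = n100 / 0.1)
    },
    stop("unknown CIP class: ", cip_class))
  stopifnot(identical(names(out), measurement_names(cip_class)))
  out
}

# does the trace repolarize to near baseline by the end of the recovery?
repolarizes <- function(trace, protocol, config = feature_config()) {
  t <- trace$t; V <- trace$V
  t_end <- protocol$total_ms
  w <- t >= t_end - config$repol_window
  v_base <- mean(V[t < protocol$pulses$onset[1]])
  abs(mean(V[w]) - v_base) <= config$repol_tol
}

#' Run the four screening CIPs on a model
#'
#' @param model an \code{ns_biomodel}.
#' @param amps_pA the four CIP amplitudes, pA.
#' @param config an \code{ns_simconfig}.
#' @param init_state optional precomputed resting state (computed once and
#'   shared across the CIPs otherwise).
#' @param ... passed to \code{\link{cip_protocol}}.
#' @return named list of somatic traces, one per CIP class.
#' @export
run_cips <- function(model, amps_pA = c(-100, 20, 50, 500),
                     config = sim_config(), init_state = NULL, ...) {
  if (is.null(init_state)) init_state <- resting_state(model, config)
  out <- list()
  for (amp in amps_pA) {
    p <- cip_protocol(amp, ...)
    tr <- simulate_model(model, p, config = config, init_state = init_state)[[1]]
    tr$protocol <- p
    out[[p$cip_class]] <- tr
  }
  out
}

#' Apply the elimination criteria to the four CIP responses
#'
#' A model is eliminated if it spikes during the passive (+20 pA) step, fires
#' fewer than three spikes or fails to repolarize at the +50 pA step, or —
#' at the +500 pA step — spikes during the last 700 ms of the pulse, spikes
#' during the recovery period, or fails to repolarize.  The hyperpolarizing
#' step never eliminates.
#'
#' @param sims named list of traces from \code{\link{run_cips}} (classes
#'   hyperpolarizing, passive_depol, active_depol, depol_block).
#' @param config a \code{\link{feature_config}}.
#' @return list of class \code{ns_elimination}: \code{passed} flag and
#'   \code{reasons} (character vector of criterion identifiers, empty iff
#'   passed).
#' @export
eliminate_model <- function(sims, config = feature_config()) {
  need <- c("hyperpolarizing", "passive_depol", "active_depol", "depol_block")
  missing <- setdiff(need, names(sims))
  if (length(missing))
    stop("missing CIP simulations: ", paste(missing, collapse = ", "))
  reasons <- character(0)
  pulse_spikes <- function(tr) {
    p <- tr$protocol
    sp <- detect_spikes(tr, config)
    sp[sp$time >= p$pulses$onset[1] &
         sp$time < p$pulses$onset[1] + p$pulses$dur[1], , drop = FALSE]
  }
  tr20 <- sims$passive_depol
  if (nrow(pulse_spikes(tr20)) > 0) reasons <- c(reasons, "spikes_20pA")
  tr50 <- sims$active_depol
  if (nrow(pulse_spikes(tr50)) < 3) reasons <- c(reasons, "few_spikes_50pA")
  if (!repolarizes(tr50, tr50$protocol, config))
    reasons <- c(reasons, "no_repolarization_50pA")
  tr500 <- sims$depol_block
  p500 <- tr500$protocol
  sp500 <- detect_spikes(tr500, config)
  t_off <- p500$pulses$onset[1] + p500$pulses$dur[1]
  if (any(sp500$time >= t_off - 700 & sp500$time < t_off))
    reasons <- c(reasons, "late_spikes_500pA")
  if (any(sp500$time >= t_off))
    reasons <- c(reasons, "recovery_spikes_500pA")
  if (!repolarizes(tr500, p500, config))
    reasons <- c(reasons, "no_repolarization_500pA")
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "ns_elimination")
}

#' Reference measurement constants for the IS3 cell
#'
#' The selected experimental measurement values used as the screening
#' reference for the real cell (packaged as immutable constants): e.g.
#' spike rate 35.0044 Hz, 28 spikes, potential sag 6.7865 mV.  For fixture
#' work, references are generated from a known model instead
#' (\code{\link{make_reference}}).
#'
#' @return named list of per-CIP-class reference vectors.
#' @export
is3_reference <- function() {
  list(
    hyperpolarizing = c(hyperpol_vm_diff = -34.2649,
                        min_potential_time = 58.9,
                        min_potential = -112.6709,
                        potential_sag = 6.7865,
                        sag_time_constant = 14.3),
    passive_depol = c(passive_vm_diff = 12.4910),
    active_depol = c(active_vm_diff = 29.4174,
                     interspike_interval = 36.6898,
                     first_spike_time = 33.1,
                     spike_threshold_mean = -44.3428,
                     spike_halfwidth_mean = 1.0301,
                     spike_amplitude_mean = 61.7296,
                     spike_rate = 35.0044,
                     spike_ahp_mean = 6.8820,
                     n_spikes = 28,
                     spike_freq_adaptation = 1.3305),
    depol_block = c(depol_block_vm_diff = 62.6461,
                    initial_rate_100ms = 60))
}
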