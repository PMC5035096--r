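# ---------------------------------------------------------------------------
# Downstream characterization of accepted models: passive electrotonic
# attenuation, backpropagating action potential amplitude profiles,
# synaptic threshold-weight scans, and conductance unit conversions.
# ---------------------------------------------------------------------------

# steady-state passive conductance system: full transfer matrix Z (MOhm)
passive_transfer_matrix <- function(model) {
  cc <- model$cmodel$comps
  n <- nrow(cc)
  A <- matrix(0, n, n)
  diag(A) <- model$g_pas_uS
  for (i in seq_len(n)) {
    p <- cc$parent[i]
    if (p > 0) {
      g <- cc$g_ax[i]
      A[i, i] <- A[i, i] + g
      A[p, p] <- A[p, p] + g
      A[i, p] <- A[i, p] - g
      A[p, i] <- A[p, i] - g
    }
  }
  solve(A)   # V = Z I (mV per nA)
}

#' Electrotonic distance map of a passive model
#'
#' Applies a 1 mV steady signal at the upstream point and measures the
#' downstream response; the electrotonic distance is L = log(A) with
#' attenuation A = upstream voltage / downstream voltage.  Direction
#' \code{"away_from_soma"} (Vout) applies the signal at the soma and reads
#' every compartment; \code{"toward_soma"} (Vin) applies the signal at each
#' compartment in turn and reads the soma.
#'
#' @param model a passive \code{ns_biomodel} (all active densities zero).
#' @param direction \code{"away_from_soma"} or \code{"toward_soma"}.
#' @param log_base logarithm base for L (default natural log).
#' @return data.frame: compartment, section id, tree label, region, path
#'   distance (um), attenuation A, electrotonic distance L.
#' @export
electrotonic_map <- function(model,
                             direction = c("away_from_soma", "toward_soma"),
                             log_base = exp(1)) {
  direction <- match.arg(direction)
  if (!is_passive_model(model))
    stop("electrotonic analysis requires a passive model")
  cc <- model$cmodel$comps
  Z <- passive_transfer_matrix(model)
  s <- soma_comp(model$cmodel)
  A <- if (direction == "away_from_soma") {
    # clamp soma at 1 mV: V_i = Z_is / Z_ss; attenuation = 1 / V_i
    Z[s, s] / Z[, s]
  } else {
    # clamp compartment i at 1 mV: V_soma = Z_si / Z_ii
    diag(Z) / Z[s, ]
  }
  data.frame(comp = seq_len(nrow(cc)), sec_id = cc$sec_id,
             label = cc$label, region = cc$region,
             path_dist_um = cc$path_dist_um,
             attenuation = A,
             L = log(A) / log(log_base),
             direction = direction)
}

#' Backpropagating spike amplitude profile along a dendritic tree
#'
#' Simulates a somatic pulse train (default three 2 ms, 800 pA steps),
#' records the voltage at every compartment of the tree, and reports the
#' per-location spike amplitude (peak voltage minus pre-train baseline)
#' against path distance.
#'
#' @param model an \code{ns_biomodel}.
#' @param tree tree label (e.g. "1").
#' @param protocol the pulse-train protocol.
#' @param config simulation configuration.
#' @param init_state optional precomputed resting state.
#' @return data.frame: path_distance_um, bap_amplitude_mV, sec_id, comp.
#' @export
bap_profile <- function(model, tree, protocol = bap_protocol(),
                        config = sim_config(), init_state = NULL) {
  cc <- model$cmodel$comps
  in_tree <- which(cc$label == tree)
  if (!length(in_tree)) stop("no tree labelled '", tree, "'")
  sites <- lapply(in_tree, function(i) c(cc$sec_id[i], (cc$a[i] + cc$b[i]) / 2))
  cfg <- config
  cfg$record <- sites
  trs <- simulate_model(model, protocol, config = cfg,
                        init_state = init_state)
  t_on <- protocol$pulses$onset[1]
  out <- lapply(seq_along(trs), function(k) {
    tr <- trs[[k]]
    base <- mean(tr$V[tr$t < t_on])
    data.frame(path_distance_um = cc$path_dist_um[in_tree[k]],
               bap_amplitude_mV = max(tr$V[tr$t >= t_on]) - base,
               sec_id = cc$sec_id[in_tree[k]],
               comp = in_tree[k])
  })
  out <- do.call(rbind, out)
  out[order(out$path_distance_um), ]
}

#' Synaptic threshold-weight scan along a dendritic tree
#'
#' At each sampled location a single-spike double-exponential synapse is
#' activated and its weight increased until the somatic membrane potential
#' surpasses the spike criterion (default -20 mV).  The minimal (threshold)
#' weight is refined by bisection to ~3 significant figures.  At the
#' threshold weight the local depolarization in the first 1 ms after the
#' presynaptic spike is recorded; locations where it approaches the driving
#' force ceiling |V_rest - e| are flagged saturated.
#'
#' @param model an \code{ns_biomodel}.
#' @param tree tree label.
#' @param w_min,w_max weight schedule bounds, uS.
#' @param soma_crit somatic voltage criterion for a spike, mV.
#' @param sat_frac fraction of the driving-force ceiling that counts as
#'   saturation.
#' @param tau1,tau2,e synapse kinetics (ms, ms, mV).
#' @param sim_ms simulated window per trial, ms (synapse fires at 5 ms).
#' @param config simulation configuration.
#' @param locations optional compartment indices; default: every
#'   compartment of the tree.
#' @return data.frame: path_distance_um, threshold_weight_uS (NA where no
#'   spike is achievable at w_max), local_dV_mV, saturated, reachable.
#' @export
threshold_weight_scan <- function(model, tree, w_min = 1e-4, w_max = 10,
                                  soma_crit = -20, sat_frac = 0.9,
                                  tau1 = 0.2, tau2 = 2, e = 0, sim_ms = 60,
                                  config = sim_config(), locations = NULL) {
  cc <- model$cmodel$comps
  if (is.null(locations)) locations <- which(cc$label == tree)
  if (!length(locations)) stop("no tree labelled '", tree, "'")
  rest <- resting_state(model, config)
  soma <- soma_comp(model$cmodel)
  onset <- 5
  proto <- structure(list(pulses = data.frame(onset = numeric(0),
                                              dur = numeric(0),
                                              amp_pA = numeric(0)),
                          baseline = onset, pulse = 0, recovery = 0,
                          total_ms = sim_ms, amp_pA = 0,
                          cip_class = "synaptic", site = NULL),
                     class = "ns_protocol")
  trial <- function(comp_i, w) {
    site <- c(cc$sec_id[comp_i], (cc$a[comp_i] + cc$b[comp_i]) / 2)
    syn <- synapse_spec(site, w, onsets = onset, tau1 = tau1, tau2 = tau2,
                        e = e)
    cfg <- config
    cfg$record <- list(NULL, site)
    cfg$settle_ms <- 0
    trs <- simulate_model(model, proto, synapses = list(syn), config = cfg,
                          init_state = rest)
    vsoma <- trs[[1]]$V
    vloc <- trs[[2]]$V
    tt <- trs[[1]]$t
    w1 <- tt >= onset & tt <= onset + 1
    list(spike = max(vsoma) > soma_crit,
         dv = max(vloc[w1]) - min(vloc[w1]))
  }
  v_rest <- rest$V[soma]
  ceiling_dv <- abs(v_rest - e)
  rows <- list()
  for (comp_i in locations) {
    hi_res <- trial(comp_i, w_max)
    if (!hi_res$spike) {
      rows[[length(rows) + 1L]] <- data.frame(
        path_distance_um = cc$path_dist_um[comp_i],
        threshold_weight_uS = NA_real_,
        local_dV_mV = hi_res$dv,
        saturated = hi_res$dv >= sat_frac * ceiling_dv,
        reachable = FALSE, comp = comp_i)
      next
    }
    # coarse geometric bracket, then bisection in log-weight
    lo <- w_min; hi <- w_max
    w <- w_min
    while (w < w_max) {
      res <- trial(comp_i, w)
      if (res$spike) { hi <- w; break }
      lo <- w
      w <- w * 2
    }
    if (w >= w_max) hi <- w_max
    while (hi / lo > 1.001) {
      mid <- sqrt(lo * hi)
      if (trial(comp_i, mid)$spike) hi <- mid else lo <- mid
    }
    thr_res <- trial(comp_i, hi)
    rows[[length(rows) + 1L]] <- data.frame(
      path_distance_um = cc$path_dist_um[comp_i],
      threshold_weight_uS = hi,
      local_dV_mV = thr_res$dv,
      saturated = thr_res$dv >= sat_frac * ceiling_dv,
      reachable = TRUE, comp = comp_i)
  }
  out <- do.call(rbind, rows)
  out[order(out$path_distance_um), ]
}

#' Point conductance of a density over a spherical soma
#'
#' Converts a conductance density into the total conductance of a sphere of
#' the given radius: G = density * 4 pi r^2, returned in nS (e.g.
#' 0.25 S/cm^2 over a 10 um sphere gives pi uS = 3141.59 nS).
#'
#' @param density conductance density, S/cm^2 (>= 0).
#' @param radius_um sphere radius, um (> 0).
#' @return conductance in nS.
#' @export
gmax_from_density <- function(density, radius_um) {
  if (any(density < 0)) stop("density must be >= 0")
  if (any(radius_um <= 0)) stop("radius must be > 0")
  r_cm <- radius_um * 1e-4
  density * 4 * pi * r_cm^2 * 1e9
}
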