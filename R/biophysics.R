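# ---------------------------------------------------------------------------
# Passive membrane parameters, voltage-gated channel kinetics, and spatial
# conductance distributions.
#
# Channel kinetics are data, not code: each channel is a set of gating
# variables with sigmoid steady states and bell-shaped voltage-dependent time
# constants, read from a YAML parameter file shipped with the package
# (inst/extdata/channels.yml).  Reversal potentials are fixed at E_Na = 50 mV
# and E_K = -77 mV.
# ---------------------------------------------------------------------------

#' Passive membrane parameters
#'
#' @param cm specific capacitance, uF/cm^2.
#' @param ra axial resistivity, Ohm cm.
#' @param gm leak conductance density, S/cm^2.
#' @param e_leak leak reversal potential, mV (by construction the passive
#'   resting potential of a model with uniform e_leak).
#' @return a list of class \code{ns_passive}.
#' @export
passive_params <- function(cm = 0.9, ra = 255, gm = 0.000019, e_leak = -69.7) {
  stopifnot(cm > 0, ra > 0, gm > 0)
  structure(list(cm = cm, ra = ra, gm = gm, e_leak = e_leak),
            class = "ns_passive")
}

#' Default region passive map
#'
#' Soma and dendrites use Cm = 0.9 uF/cm^2, Ra = 255 Ohm cm,
#' Gm = 1.9e-5 S/cm^2; the trimmed axon stub carries the compensating
#' override Cm = 4 uF/cm^2, Ra = 300 Ohm cm, Gm = 1.85e-4 S/cm^2.  The leak
#' reversal defaults to the target resting potential, -69.7 mV.
#'
#' @param e_leak leak reversal, mV, applied to all regions.
#' @return named list (soma, dendrite, axon) of \code{ns_passive}.
#' @export
default_passive <- function(e_leak = -69.7) {
  list(soma = passive_params(0.9, 255, 0.000019, e_leak),
       dendrite = passive_params(0.9, 255, 0.000019, e_leak),
       axon = passive_params(4, 300, 0.000185, e_leak))
}

# ---------------------------------------------------------------------------
# Channel kinetics
# ---------------------------------------------------------------------------

# steady state: 1 / (1 + exp(-(V - vhalf)/k)); k < 0 gives inactivation
gate_inf <- function(gate, V) {
  1 / (1 + exp(-(V - gate$inf$vhalf) / gate$inf$k))
}

# time constant: base + amp / (exp((V-vpeak)/kl) + exp(-(V-vpeak)/kr)), ms
gate_tau <- function(gate, V) {
  tp <- gate$tau
  if (is.null(tp$amp) || tp$amp == 0) return(rep(tp$base, length(V)))
  tp$base + tp$amp / (exp((V - tp$vpeak) / tp$kl) + exp(-(V - tp$vpeak) / tp$kr))
}

#' Load voltage-gated channel definitions from a YAML parameter file
#'
#' The packaged file defines transient sodium (na_t), persistent sodium
#' (na_p), fast and faster delayed-rectifier potassium (kdrf, kdrf_faster),
#' slow delayed-rectifier potassium (kdrs) and A-type potassium (ka)
#' channels in Hodgkin-Huxley form.
#'
#' @param path YAML file; defaults to the packaged channel library.
#' @return named list of channel definitions (class \code{ns_channelset}).
#' @export
load_channels <- function(path = system.file("extdata", "channels.yml",
                                             package = "neuroscreen")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    ch <- raw[[nm]]
    gates <- lapply(names(ch$gates), function(g) {
      gg <- ch$gates[[g]]
      gg$name <- g
      if (is.null(gg$exponent) || gg$exponent < 1)
        stop("channel ", nm, " gate ", g, ": exponent must be >= 1")
      gg
    })
    list(name = nm, erev = ch$erev, gates = gates)
  })
  structure(setNames(out, names(raw)), class = "ns_channelset")
}

#' Evaluate gating steady states and time constants
#'
#' @param channel a channel definition from \code{\link{load_channels}}.
#' @param V membrane potential(s), mV.
#' @return list with matrices \code{inf} and \code{tau} (rows = voltages,
#'   columns = gates, ms for tau).
#' @export
gating_rates <- function(channel, V) {
  stopifnot(all(is.finite(V)))
  gn <- vapply(channel$gates, `[[`, character(1), "name")
  inf <- vapply(channel$gates, function(g) gate_inf(g, V), numeric(length(V)))
  tau <- vapply(channel$gates, function(g) gate_tau(g, V), numeric(length(V)))
  inf <- matrix(inf, nrow = length(V), dimnames = list(NULL, gn))
  tau <- matrix(tau, nrow = length(V), dimnames = list(NULL, gn))
  if (any(tau <= 0)) stop("non-positive time constant in channel ", channel$name)
  list(inf = inf, tau = tau)
}

# ---------------------------------------------------------------------------
# Spatial conductance distributions
# ---------------------------------------------------------------------------

#' Boltzmann proximal conductance profile
#'
#' Distance-dependent conductance density
#' \code{f(p) = G - G/(1 + exp(k (d - p)))}: uniform at G near the soma,
#' falling sharply to 0 around path distance d.
#'
#' @param G plateau density, S/cm^2 (>= 0).
#' @param k steepness, 1/um (default 10).
#' @param d midpoint distance, um (e.g. 55, 75 or 95).
#' @param p path distance(s) from the soma, um (>= 0).
#' @return density at p, S/cm^2.
#' @export
boltzmann_density <- function(G, k = 10, d = 75, p = 0) {
  stopifnot(G >= 0, k > 0, d > 0)
  if (any(p < 0)) stop("negative path distance")
  G - G / (1 + exp(k * (d - p)))
}

# density at a compartment for a given profile kind
profile_density <- function(kind, G, k, d, region, p) {
  base <- switch(kind,
    soma_only = ifelse(region == "soma", G, 0),
    uniform_everywhere = ,
    soma_and_dendrites = ifelse(region %in% c("soma", "dendrite"), G, 0),
    boltzmann_proximal = ifelse(region %in% c("soma", "dendrite"),
                                boltzmann_density(G, k, d, p), 0),
    stop("unknown spatial profile kind: ", kind))
  base
}

#' Channel placement for a distribution scenario
#'
#' Returns the per-channel spatial profile kinds implied by a scenario
#' label: S.1 and S.2 restrict all channels to the soma (S.1 uses kdrf +
#' kdrs, S.2 the faster kdrf without kdrs); SD distributes na_t, ka and the
#' faster kdrf uniformly over soma and dendrites; SDprox.1 confines them to
#' the soma and proximal dendrites via the Boltzmann profile; SDprox.2
#' additionally restricts ka to the soma.  Persistent sodium (na_p) is
#' soma-only in every scenario.  The label \code{"passive"} places no
#' channels at all.
#'
#' @param label one of "S.1", "S.2", "SD", "SDprox.1", "SDprox.2", "passive".
#' @return named character vector: channel name -> profile kind.
#' @export
scenario_channels <- function(label) {
  switch(label,
    "S.1" = c(na_t = "soma_only", na_p = "soma_only", ka = "soma_only",
              kdrf = "soma_only", kdrs = "soma_only"),
    "S.2" = c(na_t = "soma_only", na_p = "soma_only", ka = "soma_only",
              kdrf_faster = "soma_only"),
    "SD" = c(na_t = "soma_and_dendrites", na_p = "soma_only",
             ka = "soma_and_dendrites", kdrf_faster = "soma_and_dendrites"),
    "SDprox.1" = c(na_t = "boltzmann_proximal", na_p = "soma_only",
                   ka = "boltzmann_proximal",
                   kdrf_faster = "boltzmann_proximal"),
    "SDprox.2" = c(na_t = "boltzmann_proximal", na_p = "soma_only",
                   ka = "soma_only", kdrf_faster = "boltzmann_proximal"),
    "passive" = character(0),
    stop("unknown scenario label: ", label))
}

# ---------------------------------------------------------------------------
# Model assembly
# ---------------------------------------------------------------------------

#' Assemble a biophysical model on a compartmentalized morphology
#'
#' Every compartment carries the regional leak; active channels are placed
#' according to the scenario's spatial profiles with the given maximal
#' conductance densities, evaluated at each compartment's path distance for
#' Boltzmann profiles.
#'
#' @param cmodel an \code{ns_cmodel} from \code{\link{compartmentalize}}.
#' @param scenario distribution scenario label (see
#'   \code{\link{scenario_channels}}).
#' @param densities named numeric vector/list of maximal conductance
#'   densities, S/cm^2, one per scenario channel (ignored for "passive").
#' @param d Boltzmann cutoff midpoint, um (55, 75 or 95 in screening grids).
#' @param k Boltzmann steepness, 1/um.
#' @param channels channel definitions (default: packaged library).
#' @param e_leak optional uniform leak reversal override, mV.
#' @return an object of class \code{ns_biomodel}.
#' @export
build_model <- function(cmodel, scenario = "passive", densities = numeric(0),
                        d = 75, k = 10, channels = load_channels(),
                        e_leak = NULL) {
  placement <- scenario_channels(scenario)
  densities <- unlist(densities)
  if (length(placement)) {
    missing <- setdiff(names(placement), names(densities))
    if (length(missing))
      stop("missing densities for channels: ", paste(missing, collapse = ", "))
    if (any(densities < 0)) stop("densities must be non-negative")
  }
  cc <- cmodel$comps
  area_factor <- cc$area_um2 * 1e-2   # S/cm^2 * um^2 -> uS
  pas <- cmodel$passive
  cm <- vapply(cc$region, function(r) pas[[r]]$cm, numeric(1))
  gm <- vapply(cc$region, function(r) pas[[r]]$gm, numeric(1))
  ep <- if (is.null(e_leak))
    vapply(cc$region, function(r) pas[[r]]$e_leak, numeric(1))
  else rep(e_leak, nrow(cc))
  gbar <- matrix(0, nrow(cc), length(placement),
                 dimnames = list(NULL, names(placement)))
  for (ch in names(placement)) {
    gbar[, ch] <- profile_density(placement[[ch]], densities[[ch]], k, d,
                                  cc$region, cc$path_dist_um) * area_factor
  }
  structure(list(
    cmodel = cmodel, scenario = scenario,
    densities = densities, d = d, k = k,
    channels = channels[names(placement)],
    cap_nF = cm * cc$area_um2 * 1e-5,
    g_pas_uS = gm * area_factor,
    e_pas_mV = ep,
    gbar_uS = gbar), class = "ns_biomodel")
}

#' @export
print.ns_biomodel <- function(x, ...) {
  cat("Biophysical model (scenario ", x$scenario, "): ",
      nrow(x$cmodel$comps), " compartments, channels: ",
      if (length(x$channels)) paste(names(x$channels), collapse = ", ")
      else "none (passive)", "\n", sep = "")
  invisible(x)
}

is_passive_model <- function(model) {
  length(model$channels) == 0 || all(model$gbar_uS == 0)
}
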