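# ---------------------------------------------------------------------------
# Synthetic fixtures: stylized interneuron morphologies and ground-truth
# references, so the whole screening strategy is testable without any
# external reconstruction.  The generated cell is a stand-in for a small
# vertically oriented bipolar interneuron: one long sparsely branched
# dendritic tree, one larger heavily branched tree, one small thin branched
# tree, and a short axon stub.  Deterministic given a seed.
# ---------------------------------------------------------------------------

#' Specification for a synthetic fixture morphology
#'
#' @param seed integer seed controlling the small geometric jitter.
#' @param soma_len,soma_diam soma cylinder dimensions, um.
#' @param diam_scale multiplier on all dendritic diameters (controls input
#'   resistance).
#' @param axon_len axon stub length, um.
#' @param jitter relative length jitter (0 disables).
#' @return list of class \code{ns_fixture_spec}.
#' @export
fixture_morph_spec <- function(seed = 1, soma_len = 15, soma_diam = 15,
                               diam_scale = 1.8, axon_len = 30, jitter = 0.03) {
  structure(list(seed = as.integer(seed), soma_len = soma_len,
                 soma_diam = soma_diam, diam_scale = diam_scale,
                 axon_len = axon_len, jitter = jitter),
            class = "ns_fixture_spec")
}

# straight 2-point section between 3D points with linear taper
fixture_section <- function(id, region, label, p0, p1, d0, d1, parent) {
  pts <- rbind(c(p0, d0), c(p1, d1))
  colnames(pts) <- c("x", "y", "z", "diam")
  new_section(id, region, label, pts, parent)
}

#' Generate a synthetic fixture morphology
#'
#' Builds a connected stylized interneuron: soma (3-point cylinder), tree
#' "1" (long, 2 branch points), tree "2" (5 branch points, larger), tree "3"
#' (3 branch points, thin), and a short axon stub.  Total dendritic path
#' length exceeds 200 um so distal analyses are meaningful.  The same seed
#' always yields byte-identical geometry (and SWC output).
#'
#' @param spec an \code{ns_fixture_spec}.
#' @param swc_path optional path; if given the morphology is also written
#'   as SWC.
#' @return an \code{ns_morphology}.
#' @export
make_fixture_morphology <- function(spec = fixture_morph_spec(),
                                    swc_path = NULL) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  jit <- function(x) x * (1 + spec$jitter * (2 * runif(length(x)) - 1))
  ds <- spec$diam_scale
  hs <- spec$soma_len / 2
  soma_pts <- cbind(x = c(0, 0, 0), y = c(-hs, 0, hs), z = 0,
                    diam = spec$soma_diam)
  secs <- list(new_section(1L, "soma", "soma", soma_pts, NULL))
  nid <- 1L
  add <- function(region, label, p0, p1, d0, d1, parent) {
    nid <<- nid + 1L
    secs[[length(secs) + 1L]] <<-
      fixture_section(nid, region, label, p0, p1, d0 * ds, d1 * ds, parent)
    nid
  }
  dir_point <- function(p0, ang_deg, len) {
    a <- ang_deg * pi / 180
    p0 + len * c(sin(a), cos(a), 0)
  }
  top <- c(0, hs, 0); bot <- c(0, -hs, 0)

  # tree 1: long, sparsely branched (root + 1 bifurcation + 1 deeper pair)
  L <- jit(c(100, 80, 80, 70, 70))
  r1 <- add("dendrite", "1", top, dir_point(top, 0, L[1]), 2.0, 1.6,
            list(id = 1L, frac = 1))
  e1 <- dir_point(top, 0, L[1])
  c1 <- add("dendrite", "1", e1, dir_point(e1, -25, L[2]), 1.6, 1.0,
            list(id = r1, frac = 1))
  c2 <- add("dendrite", "1", e1, dir_point(e1, 25, L[3]), 1.6, 1.0,
            list(id = r1, frac = 1))
  e2 <- dir_point(e1, -25, L[2])
  g1 <- add("dendrite", "1", e2, dir_point(e2, -45, L[4]), 1.0, 0.6,
            list(id = c1, frac = 1))
  add("dendrite", "1", e2, dir_point(e2, -5, L[5]), 1.0, 0.6,
      list(id = c1, frac = 1))
  # thin distal extension: strong transient attenuation at the far tip
  e4 <- dir_point(e2, -45, L[4])
  L2 <- jit(c(90, 90))
  gg <- add("dendrite", "1", e4, dir_point(e4, -60, L2[1]), 0.6, 0.35,
            list(id = g1, frac = 1))
  add("dendrite", "1", dir_point(e4, -60, L2[1]),
      dir_point(dir_point(e4, -60, L2[1]), -70, L2[2]), 0.35, 0.3,
      list(id = gg, frac = 1))

  # tree 2: heavily branched, larger area (5 branch points)
  L <- jit(c(50, 45, 45, 45, 45, 45, 45, 40, 40, 40, 40))
  r2 <- add("dendrite", "2", bot, dir_point(bot, 180, L[1]), 1.8, 1.2,
            list(id = 1L, frac = 0))
  e0 <- dir_point(bot, 180, L[1])
  ch <- integer(2); ech <- list()
  for (k in 1:2) {
    ang <- 180 + c(-30, 30)[k]
    ech[[k]] <- dir_point(e0, ang, L[1 + k])
    ch[k] <- add("dendrite", "2", e0, ech[[k]], 1.2, 0.9,
                 list(id = r2, frac = 1))
  }
  gidx <- 0L; gch <- integer(4); egch <- list()
  for (k in 1:2) for (j in 1:2) {
    gidx <- gidx + 1L
    ang <- 180 + c(-45, -15, 15, 45)[gidx]
    egch[[gidx]] <- dir_point(ech[[k]], ang, L[3 + gidx])
    gch[gidx] <- add("dendrite", "2", ech[[k]], egch[[gidx]], 0.9, 0.6,
                     list(id = ch[k], frac = 1))
  }
  for (k in c(1, 4)) for (j in 1:2) {
    ang <- 180 + c(-50, -30, 30, 50)[2 * (k == 4) + j]
    add("dendrite", "2", egch[[k]], dir_point(egch[[k]], ang, L[7 + j]),
        0.6, 0.4, list(id = gch[k], frac = 1))
  }

  # tree 3: small, thin, branched (3 branch points)
  L <- jit(c(45, 40, 40, 40, 40, 40, 40))
  r3 <- add("dendrite", "3", top, dir_point(top, 60, L[1]), 1.2, 0.8,
            list(id = 1L, frac = 1))
  e3 <- dir_point(top, 60, L[1])
  ch3 <- integer(2); ech3 <- list()
  for (k in 1:2) {
    ang <- 60 + c(-20, 20)[k]
    ech3[[k]] <- dir_point(e3, ang, L[1 + k])
    ch3[k] <- add("dendrite", "3", e3, ech3[[k]], 0.8, 0.6,
                  list(id = r3, frac = 1))
  }
  gidx <- 0L
  for (k in 1:2) for (j in 1:2) {
    gidx <- gidx + 1L
    ang <- 60 + c(-30, -10, 10, 30)[gidx]
    add("dendrite", "3", ech3[[k]], dir_point(ech3[[k]], ang, L[3 + gidx]),
        0.6, 0.4, list(id = ch3[k], frac = 1))
  }

  # axon stub
  add("axon", "axon", bot, dir_point(bot, 240, spec$axon_len), 1.0, 0.6,
      list(id = 1L, frac = 0))

  m <- new_morphology(secs, name = sprintf("fixture_seed%d", spec$seed))
  if (!is.null(swc_path)) write_swc(m, swc_path)
  m
}

#' Default compartmentalized fixture model
#'
#' Convenience wrapper: fixture morphology discretized under the default
#' lambda rule.
#'
#' @param spec an \code{ns_fixture_spec}.
#' @param ... passed to \code{\link{compartmentalize}}.
#' @return an \code{ns_cmodel}.
#' @export
fixture_cmodel <- function(spec = fixture_morph_spec(), ...) {
  compartmentalize(make_fixture_morphology(spec), ...)
}

#' Ground truth for recovery experiments
#'
#' Describes the generating model for a synthetic reference: scenario,
#' densities, Boltzmann cutoff, and the CIP set.
#'
#' @param scenario distribution scenario label.
#' @param densities named densities, S/cm^2.
#' @param d Boltzmann cutoff, um.
#' @param amps_pA CIP amplitudes.
#' @return list of class \code{ns_groundtruth}.
#' @export
ground_truth <- function(scenario = "SDprox.2",
                         densities = fixture_truth_densities(scenario),
                         d = 75, amps_pA = c(-100, 20, 50, 500)) {
  structure(list(scenario = scenario, densities = unlist(densities), d = d,
                 amps_pA = amps_pA), class = "ns_groundtruth")
}

#' Reference measurements from a known generating model
#'
#' Simulates the ground-truth model under the four CIPs and extracts its
#' feature vectors; these stand in for measurements from a selected
#' experimental trace.  Errors if the generating model is eliminated by its
#' own criteria (a reference must itself be a valid model).
#'
#' @param truth an \code{ns_groundtruth}.
#' @param cmodel compartmentalized morphology (default: fixture).
#' @param channels channel definitions.
#' @param config simulation configuration.
#' @return named list of per-CIP-class feature vectors (a reference
#'   measurement set), with the truth stored in attribute \code{"truth"}.
#' @export
make_reference <- function(truth, cmodel = fixture_cmodel(),
                           channels = load_channels(),
                           config = sim_config()) {
  model <- build_model(cmodel, truth$scenario, truth$densities,
                       d = truth$d, channels = channels)
  sims <- run_cips(model, truth$amps_pA, config = config)
  elim <- eliminate_model(sims)
  if (!elim$passed)
    stop("ground-truth model eliminated by its own criteria: ",
         paste(elim$reasons, collapse = ", "))
  ref <- lapply(sims, function(tr) measure_cip(tr))
  attr(ref, "truth") <- truth
  ref
}

#' Default fixture screening densities and grids
#'
#' The ground-truth densities for the fixture cell, per scenario, chosen in
#' the conductance regime of soma-and-proximal-dendrite interneuron models;
#' \code{fixture_grid} spans each varied conductance with three values (a
#' deliberately broad bracket around the truth, factors 0.5/1/1.75, so
#' screening grids contain both passing models and models that fail the
#' elimination criteria, as broad starting grids do).  Persistent sodium is
#' held fixed.
#'
#' @param scenario distribution scenario label.
#' @return named density vector (S/cm^2) or a named list of grid values.
#' @export
fixture_truth_densities <- function(scenario = "SDprox.2") {
  switch(scenario,
    "SDprox.2" = c(na_t = 0.15, na_p = 0.00005, ka = 0.07,
                   kdrf_faster = 0.295),
    "SDprox.1" = c(na_t = 0.15, na_p = 0.00005, ka = 0.07,
                   kdrf_faster = 0.295),
    "S.2" = c(na_t = 0.45, na_p = 0.00005, ka = 0.07, kdrf_faster = 0.6),
    "SD" = c(na_t = 0.05, na_p = 0.00005, ka = 0.08, kdrf_faster = 0.13),
    stop("no fixture truth for scenario ", scenario))
}

#' @rdname fixture_truth_densities
#' @param vary channels to vary in the grid (others held at truth).
#' @param factors multiplicative bracket around the truth values.
#' @param d_values optional Boltzmann cutoff axis (adds a "d" grid column).
#' @export
fixture_grid <- function(scenario = "SDprox.2",
                         vary = c("na_t", "ka", "kdrf_faster"),
                         factors = c(0.5, 1, 1.75), d_values = NULL) {
  tr <- fixture_truth_densities(scenario)
  grid <- lapply(names(tr), function(ch) {
    if (ch %in% vary) sort(tr[[ch]] * factors) else tr[[ch]]
  })
  names(grid) <- names(tr)
  if (!is.null(d_values)) grid$d <- d_values
  grid
}

#' Parameter-recovery harness
#'
#' Full screening run on a grid containing the ground truth: generates the
#' reference from the truth, screens every grid member, and reports whether
#' the truth is recovered at rank 1 with distance 0, along with survivor
#' counts.
#'
#' @param grid named list of grid values (see \code{\link{fixture_grid}}).
#' @param truth an \code{ns_groundtruth}.
#' @param cmodel compartmentalized morphology.
#' @param channels channel definitions.
#' @param config simulation configuration.
#' @param reference optional precomputed reference (default: from truth).
#' @return list of class \code{ns_recovery}: the database, the rank-1
#'   parameters, recovery flag, survivor count, and the truth distance.
#' @export
recovery_harness <- function(grid, truth, cmodel = fixture_cmodel(),
                             channels = load_channels(),
                             config = sim_config(), reference = NULL) {
  if (is.null(reference))
    reference <- make_reference(truth, cmodel, channels, config)
  db <- generate_database(cmodel, truth$scenario, grid, reference,
                          channels = channels, config = config,
                          amps_pA = truth$amps_pA)
  rec <- db$records
  top <- rec[rec$rank == 1, , drop = FALSE]
  pnames <- names(grid)
  truth_vec <- c(truth$densities[setdiff(pnames, "d")],
                 if ("d" %in% pnames) c(d = truth$d))
  top_vec <- unlist(top[1, pnames])
  matched <- all(abs(top_vec - truth_vec[pnames]) <
                   1e-12 + 1e-9 * abs(truth_vec[pnames]))
  truth_row <- which(apply(rec[pnames], 1, function(r)
    all(abs(r - truth_vec[pnames]) < 1e-12 + 1e-9 * abs(truth_vec[pnames]))))
  structure(list(
    db = db,
    recovered = matched,
    top_params = top_vec,
    truth_params = truth_vec[pnames],
    truth_distance = if (length(truth_row)) rec$distance[truth_row[1]] else NA,
    n_models = nrow(rec),
    n_survivors = sum(!rec$eliminated)), class = "ns_recovery")
}

#' @export
print.ns_recovery <- function(x, ...) {
  cat("Recovery harness: ", x$n_models, " models, ", x$n_survivors,
      " survivors\n", sep = "")
  cat("  truth ", if (x$recovered) "recovered at rank 1" else "NOT recovered",
      "; truth distance = ", signif(x$truth_distance, 4), "\n", sep = "")
  invisible(x)
}
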