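test_that("density-to-point-conductance conversion is exact", {
  expect_equal(gmax_from_density(0.25, 10), pi * 1000, tolerance = 1e-9)
  expect_equal(round(gmax_from_density(0.25, 10)), 3142)
  expect_gte(gmax_from_density(0.25, 10) / 140, 22)
  expect_identical(gmax_from_density(0, 10), 0)
  expect_error(gmax_from_density(-1, 10), "density")
  expect_error(gmax_from_density(0.1, 0), "radius")
  # linear in density, quadratic in radius
  expect_equal(gmax_from_density(0.5, 10), 2 * gmax_from_density(0.25, 10))
  expect_equal(gmax_from_density(0.25, 20), 4 * gmax_from_density(0.25, 10))
})

test_that("electrotonic distance is zero at the reference and matches the cable form", {
  m <- make_cylinder_morph(soma_len = 10, soma_diam = 10,
                           dend_len = 400, dend_diam = 1.5)
  cmod <- compartmentalize(m, policy = "fixed", max_len = 5)
  mod <- build_model(cmod, "passive")
  em <- electrotonic_map(mod, "away_from_soma")
  soma_rows <- em[em$region == "soma", ]
  expect_lt(abs(soma_rows$L[which.min(abs(soma_rows$path_dist_um))]), 1e-9)
  # analytic: clamped proximal end, sealed distal end
  lambda_um <- sqrt(1.5e-4 / (4 * 255 * 1.9e-5)) * 1e4
  Ltot <- 400 / lambda_um
  dend <- em[em$region == "dendrite", ]
  x <- (dend$path_dist_um - 5) / 400   # arc fraction along the dendrite
  L_exp <- -log(cosh(Ltot * (1 - x)) / cosh(Ltot))
  expect_equal(dend$L, L_exp, tolerance = 0.01)
  # configurable logarithm base
  em10 <- electrotonic_map(mod, "away_from_soma", log_base = 10)
  expect_equal(em10$L, em$L / log(10), tolerance = 1e-9)
  expect_error(electrotonic_map(fx_truth_model()), "passive")
})

test_that("electrotonic distance is additive along an unbranched passive path", {
  m <- make_cylinder_morph(soma_len = 10, soma_diam = 10,
                           dend_len = 400, dend_diam = 1.5)
  cmod <- compartmentalize(m, policy = "fixed", max_len = 10)
  mod <- build_model(cmod, "passive")
  Z <- ns_internal("passive_transfer_matrix")(mod)
  cc <- cmod$comps
  dend <- which(cc$region == "dendrite")
  a <- dend[3]; b <- dend[15]; c3 <- dend[30]
  L_ab <- log(Z[a, a] / Z[a, b])
  L_bc <- log(Z[b, b] / Z[b, c3])
  L_ac <- log(Z[a, a] / Z[a, c3])
  expect_equal(L_ac, L_ab + L_bc, tolerance = 0.01)
})

test_that("more branched, smaller-area trees attenuate more at matched distance", {
  pm <- fx("passive_model", function() build_model(fx_cmodel(), "passive"))
  st <- tree_stats(fx_morph())
  expect_gt(st$n_branch_points[st$tree_label == "3"],
            st$n_branch_points[st$tree_label == "1"])
  expect_lt(st$surface_area_um2[st$tree_label == "3"],
            st$surface_area_um2[st$tree_label == "1"])
  # signal attenuation toward the soma (synaptic efficacy direction)
  em <- electrotonic_map(pm, "toward_soma")
  band <- em$path_dist_um > 100 & em$path_dist_um < 140
  L1 <- mean(em$L[band & em$label == "1"])
  L3 <- mean(em$L[band & em$label == "3"])
  expect_gt(L3, L1)
})

test_that("bAP amplitudes decay passively but not with uniform dendritic channels", {
  cm <- fx_cmodel()
  sd_mod <- fx("sd_model", function()
    build_model(cm, "SD", fixture_truth_densities("SD")))
  s2_mod <- fx("s2_model", function()
    build_model(cm, "S.2", fixture_truth_densities("S.2")))
  bp_sd <- bap_profile(sd_mod, "1")
  bp_s2 <- bap_profile(s2_mod, "1")
  # uniform dendritic channels: distal amplitude at least 80% of proximal
  n <- nrow(bp_sd)
  expect_gte(bp_sd$bap_amplitude_mV[n], 0.8 * bp_sd$bap_amplitude_mV[1])
  # passive dendrites: strictly decreasing along a single root-to-tip path
  cc <- cm$comps
  tip_sec <- cc$sec_id[which.max(cc$path_dist_um * (cc$label == "1"))]
  path_secs <- tip_sec
  repeat {
    s <- ns_internal("get_section")(fx_morph(), path_secs[1])
    if (is.null(s$parent) || s$parent$id == 1) break
    path_secs <- c(s$parent$id, path_secs)
  }
  on_path <- bp_s2[bp_s2$sec_id %in% path_secs, ]
  expect_true(all(diff(on_path$bap_amplitude_mV) < 0))
  # and the passive profile decays overall while SD does not
  expect_lt(on_path$bap_amplitude_mV[nrow(on_path)],
            0.6 * on_path$bap_amplitude_mV[1])
})

test_that("Boltzmann-confined models plateau then decay with the cutoff", {
  cm <- fx_cmodel()
  dens <- fixture_truth_densities("SDprox.2")
  m55 <- build_model(cm, "SDprox.2", dens, d = 55)
  m95 <- build_model(cm, "SDprox.2", dens, d = 95)
  bp55 <- bap_profile(m55, "1")
  bp95 <- bap_profile(m95, "1")
  # between the two cutoffs the wider distribution sustains larger spikes
  mid <- bp55$path_distance_um > 55 & bp55$path_distance_um < 110
  expect_true(all(bp95$bap_amplitude_mV[mid] >=
                    bp55$bap_amplitude_mV[mid] - 1))
  expect_gt(mean(bp95$bap_amplitude_mV[mid] - bp55$bap_amplitude_mV[mid]), 5)
  # well inside both plateaus the profiles agree closely
  prox <- bp55$path_distance_um < 30
  expect_equal(bp55$bap_amplitude_mV[prox], bp95$bap_amplitude_mV[prox],
               tolerance = 0.1)
})

test_that("threshold weights are smallest at the soma and zero weight does nothing", {
  cm <- fx_cmodel()
  s2_mod <- fx("s2_model", function()
    build_model(cm, "S.2", fixture_truth_densities("S.2")))
  cc <- cm$comps
  tree1 <- which(cc$label == "1")
  locs <- c(ns_internal("soma_comp")(cm),
            tree1[c(2, 8, length(tree1) - 6)])
  sc <- threshold_weight_scan(s2_mod, "1", locations = locs)
  expect_true(all(diff(sc$threshold_weight_uS[!is.na(sc$threshold_weight_uS)])
                  >= 0))
  expect_equal(which.min(sc$threshold_weight_uS), 1)  # soma row sorts first

  # zero-weight synapse: no spike, no local deflection
  site <- c(cc$sec_id[tree1[5]], 0.5)
  syn <- synapse_spec(site, 0, onsets = 20)
  p <- cip_protocol(0, baseline = 10, pulse = 40, recovery = 0,
                    cip_class = "passive_depol")
  tr <- simulate_model(s2_mod, p, synapses = list(syn),
                       config = sim_config(record = list(site)))[[1]]
  expect_lt(max(tr$V) - min(tr$V), 0.01)
})

test_that("saturation co-locates with the reference-weight crossover on passive dendrites", {
  cm <- fx_cmodel()
  s2_mod <- fx("s2_model", function()
    build_model(cm, "S.2", fixture_truth_densities("S.2")))
  cc <- cm$comps
  # distal half of tree 1, where saturation emerges
  locs <- which(cc$label == "1" & cc$path_dist_um > 180)
  sc <- fx("s2_scan", function()
    threshold_weight_scan(s2_mod, "1", locations = locs))
  expect_true(any(sc$saturated))
  expect_true(any(!sc$saturated))
  w_ref <- 0.1  # fixture-scale analogue of the 0.5 uS reference line
  cross_i <- which(!is.na(sc$threshold_weight_uS) &
                     sc$threshold_weight_uS > w_ref)[1]
  sat_i <- which(sc$saturated)[1]
  expect_lt(abs(cross_i - sat_i), 2)
  # local depolarization approaches the driving-force ceiling distally
  expect_gt(max(sc$local_dV_mV), 0.9 * 69)
})

test_that("threshold weight does not increase with dendritic sodium density", {
  cm <- fx_cmodel()
  cc <- cm$comps
  tree1 <- which(cc$label == "1")
  locs <- tree1[c(10, 16)]
  base <- fixture_truth_densities("SDprox.2")
  thr <- matrix(NA_real_, 3, length(locs))
  for (k in 1:3) {
    dens <- base
    dens["na_t"] <- base[["na_t"]] * c(0.75, 1, 1.3)[k]
    m <- build_model(cm, "SDprox.2", dens, d = 75)
    sc <- threshold_weight_scan(m, "1", locations = locs)
    thr[k, ] <- sc$threshold_weight_uS
  }
  for (j in seq_along(locs)) expect_true(all(diff(thr[, j]) <= 1e-6))
})

test_that("removing dendritic A-type channels shifts the crossover distally", {
  cm <- fx_cmodel()
  cc <- cm$comps
  locs <- which(cc$label == "1" & cc$path_dist_um > 180)
  m1 <- build_model(cm, "SDprox.1", fixture_truth_densities("SDprox.1"),
                    d = 75)
  m2 <- build_model(cm, "SDprox.2", fixture_truth_densities("SDprox.2"),
                    d = 75)
  s1 <- fx("sp1_scan", function()
    threshold_weight_scan(m1, "1", locations = locs))
  s2 <- fx("sp2_scan", function()
    threshold_weight_scan(m2, "1", locations = locs))
  cross <- function(sc, w) {
    ok <- !is.na(sc$threshold_weight_uS) & sc$threshold_weight_uS > w
    if (any(ok)) min(sc$path_distance_um[ok]) else Inf
  }
  for (w in c(0.05, 0.1, 0.2)) {
    expect_gt(cross(s2, w), cross(s1, w))
  }
})
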