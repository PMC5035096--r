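test_that("the normalized distance is the sigma-scaled mean absolute deviation", {
  x <- c(1, 2, 3)
  expect_identical(normalized_distance(x, x), 0)
  y <- x + c(1, -1, 1)
  expect_equal(normalized_distance(x, y), 1)
  expect_equal(normalized_distance(x, y), normalized_distance(y, x))
  # hand-computed example on the hyperpolarizing reference vector
  ref <- is3_reference()$hyperpolarizing
  shifted <- ref + c(1, -2, 3, -4, 5)
  expect_equal(normalized_distance(shifted, ref), 15 / 5)
  # sigma scaling and the L2 variant
  expect_equal(normalized_distance(x, y, sigma = 2), 0.5)
  expect_equal(normalized_distance(x, y, type = "l2"), 1)
  expect_error(normalized_distance(x, y[1:2]), "length mismatch")
  expect_error(normalized_distance(x, y, sigma = 0), "sigma")
})

test_that("model distance averages the four CIP distances with a 100 sentinel", {
  expect_equal(model_distance(c(0, 0, 0, 0)), 0)
  expect_equal(model_distance(c(1, 2, 3, 4)), 2.5)
  expect_equal(model_distance(c(1, 2, 3, 4), eliminated = TRUE), 100)
  expect_error(model_distance(c(1, 2, 3)), "4 per-CIP")
})

test_that("the fixture screening database recovers its generator at rank 1", {
  db <- fx_db()
  rec <- db$records
  expect_equal(nrow(rec), 27)
  top <- rec[rec$rank == 1, ]
  truth <- fx_truth()
  expect_equal(top$na_t, unname(truth$densities["na_t"]))
  expect_equal(top$ka, unname(truth$densities["ka"]))
  expect_equal(top$kdrf_faster, unname(truth$densities["kdrf_faster"]))
  expect_equal(top$distance, 0, tolerance = 1e-9)
  # ranking is a permutation with eliminated models last
  expect_setequal(rec$rank, seq_len(27))
  expect_true(max(rec$rank[!rec$eliminated]) < min(rec$rank[rec$eliminated]))
  # every eliminated model carries the sentinel distance exactly
  expect_true(all(rec$distance[rec$eliminated] == 100))
  expect_true(all(rec$distance[!rec$eliminated] < 100))
})

test_that("survivor count equals an independent recount from the stored traces", {
  db <- fx_db()
  recount <- vapply(db$traces, function(sims) eliminate_model(sims)$passed,
                    logical(1))
  expect_equal(sum(recount), sum(!db$records$eliminated))
})

test_that("an off-grid reference resolves to a bracketing grid neighbor", {
  db <- fx_db()
  truth <- fx_truth()
  off <- truth$densities
  off[["kdrf_faster"]] <- off[["kdrf_faster"]] * 1.3
  mod <- build_model(fx_cmodel(), truth$scenario, off, d = truth$d)
  sims <- run_cips(mod)
  expect_true(eliminate_model(sims)$passed)
  ref_off <- lapply(sims, measure_cip)
  db2 <- score_database(db, ref_off)
  top <- db2$records[db2$records$rank == 1, ]
  for (p in c("na_t", "ka", "kdrf_faster")) {
    grid_vals <- sort(db$grid[[p]])
    bracket <- grid_vals[findInterval(off[[p]], grid_vals) + c(0, 1)]
    expect_true(top[[p]] %in% bracket)
  }
})

test_that("a reference perturbed on three measurements still ranks the generator first", {
  db <- fx_db()
  ref <- db$reference
  ref$active_depol["spike_rate"] <- ref$active_depol["spike_rate"] + 1
  ref$active_depol["first_spike_time"] <-
    ref$active_depol["first_spike_time"] - 1
  ref$hyperpolarizing["min_potential"] <-
    ref$hyperpolarizing["min_potential"] + 1
  db2 <- score_database(db, ref)
  top <- db2$records[db2$records$rank == 1, ]
  truth <- fx_truth()
  expect_equal(top$na_t, unname(truth$densities["na_t"]))
  expect_equal(top$kdrf_faster, unname(truth$densities["kdrf_faster"]))
  expect_gt(top$distance, 0)
})

# a synthetic database with known structure, for layout tests
make_synthetic_db <- function(grid, dist_fun, eliminated_fun = NULL) {
  grid_df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  rec <- grid_df
  rec$distance <- apply(grid_df, 1, dist_fun)
  rec$eliminated <- if (is.null(eliminated_fun)) FALSE
    else apply(grid_df, 1, eliminated_fun)
  rec$distance[rec$eliminated] <- 100
  rec$model_id <- seq_len(nrow(rec))
  structure(list(grid = grid, records = rec), class = "ns_modeldb")
}

test_that("CBDR layout is a pixel-model bijection with impact-ordered axes", {
  grid <- list(a = c(1, 2, 3), b = c(10, 20, 30))
  db <- make_synthetic_db(grid, function(r) r[["a"]] + 0.01 * r[["b"]])
  lay <- cbdr_layout(db)
  expect_equal(dim(lay$image), c(3, 3))
  expect_setequal(as.vector(lay$map), 1:9)
  # every pixel's value matches its mapped record
  for (r in 1:3) for (cc in 1:3)
    expect_equal(lay$image[r, cc],
                 db$records$distance[lay$map[r, cc]])
  # distance dominated by parameter a: a is outermost (highest impact)
  expect_equal(lay$order[1], "a")

  # distance depending on only one parameter gives axis-aligned bands
  db1 <- make_synthetic_db(grid, function(r) r[["a"]])
  lay1 <- cbdr_layout(db1)
  expect_equal(lay1$y_params, "a")
  for (r in 1:3) expect_equal(length(unique(lay1$image[r, ])), 1)

  # degenerate all-equal distances: deterministic tie-break by name
  db0 <- make_synthetic_db(grid, function(r) 1)
  expect_equal(cbdr_layout(db0)$order, c("a", "b"))
})

test_that("CBDR layouts of larger grids decode every pixel to its parameters", {
  grid <- list(a = c(0.1, 0.2, 0.3), b = c(1, 2), c = c(5, 6, 7))
  db <- make_synthetic_db(grid,
                          function(r) r[["c"]] + 0.1 * r[["a"]] + 0.01 * r[["b"]],
                          eliminated_fun = function(r) r[["b"]] == 1 & r[["a"]] < 0.15)
  lay <- cbdr_layout(db)
  expect_equal(prod(dim(lay$image)), nrow(db$records))
  expect_setequal(as.vector(lay$map), db$records$model_id)
  expect_true(all(lay$image[lay$eliminated] == 100))
})

test_that("CBDR rendering writes a PNG raster and a pixel sidecar table", {
  db <- fx_db()
  lay <- cbdr_layout(db)
  png_path <- withr::local_tempfile(fileext = ".png")
  plot_cbdr(lay, png_path)
  expect_true(file.exists(png_path))
  img <- png::readPNG(png_path)
  expect_equal(dim(img)[1:2], 12 * dim(lay$image))
  side <- read.table(sub("\\.png$", ".map.tsv", png_path), header = TRUE)
  expect_equal(nrow(side), length(lay$map))
  expect_setequal(side$model_id, db$records$model_id)
})

test_that("databases and feature tables export as delimited text", {
  db <- fx_db()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_database(db, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 27)
  expect_true(all(c("na_t", "ka", "kdrf_faster", "eliminated", "distance",
                    "rank") %in% names(back)))
  ft <- feature_table(db)
  expect_true(all(measurement_names("active_depol") %in% names(ft)))
  expect_equal(sum(ft$cip_class == "depol_block"), 27)
})
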