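test_that("climate generation is deterministic and satisfies monthly invariants", {
  c1 <- gen_climate(rows = 12, cols = 12, seed = 4)
  c2 <- gen_climate(rows = 12, cols = 12, seed = 4)
  for (m in c(1, 6, 12)) {
    expect_identical(c1$monthly$tmin[[m]]$values, c2$monthly$tmin[[m]]$values)
    expect_identical(c1$monthly$prec[[m]]$values, c2$monthly$prec[[m]]$values)
    d <- c1$monthly$tmax[[m]]$values - c1$monthly$tmin[[m]]$values
    expect_true(all(d[!is.na(d)] > 0))
    expect_true(all(c1$monthly$prec[[m]]$values >= 0, na.rm = TRUE))
  }
  c3 <- gen_climate(rows = 12, cols = 12, seed = 5)
  expect_false(identical(c1$monthly$tmin[[1]]$values,
                         c3$monthly$tmin[[1]]$values))
  expect_error(gen_climate(rows = 2, cols = 12), "degenerate")
})

test_that("infinite smoothness gives latitude-band-only temperature structure", {
  cl <- gen_climate(rows = 10, cols = 8, seed = 1, smoothness = Inf)
  st <- derive_bioclim(cl$monthly)
  nat <- which(!is.na(cl$native_region$values) & cl$native_region$values == 1)
  temps <- st$layers$TEMPS$values[, 1:8]
  # constant within every row, strictly varying across rows
  expect_equal(max(apply(temps, 1, function(r) diff(range(r)))), 0)
  expect_gt(diff(range(temps[, 1])), 0)
})

test_that("derived stacks from generated climate satisfy all invariants across seeds", {
  for (seed in c(1, 7, 23, 40, 99)) {
    cl <- gen_climate(rows = 10, cols = 10, seed = seed)
    # bioclim_stack() itself asserts the ordering invariants on build
    expect_silent(st <- suppressMessages(derive_bioclim(cl$monthly)))
    expect_s3_class(st, "nm_stack")
  }
})

test_that("truth occupancy hits the target fraction within one cell", {
  sc <- cached("sc_eval_small", gen_scenario(list(rows = 24, cols = 24,
                                                  seed = 3)))
  n_native <- sum(sc$native_region$values == 1, na.rm = TRUE)
  n_occ <- length(mask_cells(sc$historical_mask))
  expect_lte(abs(n_occ - 0.2 * n_native), 1)
  # historical occupancy sits above the threshold by construction
  occ <- mask_cells(sc$historical_mask)
  expect_true(all(sc$truth$values[occ] >= sc$occ_threshold))
})

test_that("a single positive weight makes truth monotone in that variable", {
  cl <- gen_climate(rows = 16, cols = 16, seed = 6)
  st <- suppressMessages(derive_bioclim(cl$monthly))
  tr <- gen_truth(st, c(MTEMP = 2), cl$native_region, seed = 6)
  nat <- which(!is.na(cl$native_region$values) & cl$native_region$values == 1)
  mt <- st$layers$MTEMP$values[nat]
  su <- tr$suitability$values[nat]
  expect_equal(order(mt), order(su))
  # all-zero weights give the uniform truth
  tru <- gen_truth(st, c(MTEMP = 0, PREC = 0), cl$native_region, seed = 6)
  expect_equal(diff(range(tru$suitability$values[nat])), 0)
})

test_that("contraction removes the right cells under both biases", {
  sc <- cached("sc_eval_small", gen_scenario(list(rows = 24, cols = 24,
                                                  seed = 3)))
  hist <- sc$historical_mask
  # fraction 0: modern == historical
  m0 <- contract_range(hist, sc$stack, 0, "cold_edge")
  expect_identical(mask_cells(m0), mask_cells(hist))
  # cold-edge: removed cells are all colder than retained ones
  m5 <- contract_range(hist, sc$stack, 0.5, "cold_edge")
  removed <- setdiff(mask_cells(hist), mask_cells(m5))
  retained <- mask_cells(m5)
  mt <- sc$stack$layers$MTEMP$values
  expect_lte(max(mt[removed]), min(mt[retained]))
  expect_true(all(retained %in% mask_cells(hist)))
  # random bias keeps exact counts
  n <- length(mask_cells(hist))
  mr <- contract_range(hist, sc$stack, 0.5, "random", seed = 9)
  expect_equal(length(mask_cells(mr)), n - ceiling(0.5 * n))
  expect_error(contract_range(hist, sc$stack, 1, "random"), "fraction")
})

test_that("cold-biased contraction truncates the presence temperature distribution", {
  sc <- cached("sc_canon_seed1", gen_scenario(list(seed = 1)))
  d <- sample_design(n_points = 100, seed = 1)
  hp <- sample_presence(sc$historical_mask, d, 1)
  mp <- sample_presence(sc$modern_mask, d, 1)
  ht <- suppressMessages(extract_values(sc$stack, hp))$MTEMP
  mt <- suppressMessages(extract_values(sc$stack, mp))$MTEMP
  # modern presences are warm-shifted: one-sided rank test
  p <- stats::wilcox.test(mt, ht, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("the canonical scenario satisfies its structural invariants", {
  sc <- cached("sc_canon_seed1", gen_scenario(list(seed = 1)))
  expect_true(check_nested(sc$modern_mask, sc$historical_mask))
  # regions disjoint
  both <- sc$native_region$values == 1 & sc$transfer_region$values == 1
  expect_false(any(both, na.rm = TRUE))
  # introduction points clear the occupancy threshold and sit on transfer cells
  rc <- locate_cell(sc$truth, sc$intro_points$x, sc$intro_points$y)
  idx <- cbind(rc$row, rc$col)
  expect_true(all(sc$truth$values[idx] >= sc$occ_threshold))
  expect_true(all(sc$transfer_region$values[idx] == 1))
})

test_that("scenario serialization round-trips and regenerates bit-identically", {
  sc <- gen_scenario(list(rows = 12, cols = 12, seed = 21))
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  sc2 <- suppressMessages(read_scenario(dir))
  expect_equal(sc2$truth$values, sc$truth$values, tolerance = 1e-12)
  expect_identical(mask_cells(sc2$modern_mask), mask_cells(sc$modern_mask))
  expect_equal(sc2$occ_threshold, sc$occ_threshold, tolerance = 1e-12)
  expect_equal(sc2$intro_points, sc$intro_points)
  expect_equal(sc2$true_weights, sc$true_weights)
  # regeneration from the stored config reproduces the scenario exactly
  sc3 <- gen_scenario(sc2$config)
  expect_identical(sc3$truth$values, sc$truth$values)
  expect_identical(sc3$intro_points, sc$intro_points)
})

test_that("truth-distributed presences land on high-suitability cells", {
  sc <- cached("sc_eval_small", gen_scenario(list(rows = 24, cols = 24,
                                                  seed = 3)))
  pts <- sample_from_truth(sc, 500, seed = 3)
  rc <- locate_cell(sc$truth, pts$x, pts$y)
  vals <- sc$truth$values[cbind(rc$row, rc$col)]
  nat <- which(sc$native_region$values == 1 & !is.na(sc$truth$values))
  # mean sampled suitability well above the uniform average
  expect_gt(mean(vals), 1.3 * mean(sc$truth$values[nat]))
  expect_identical(sample_from_truth(sc, 500, seed = 3), pts)
})
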