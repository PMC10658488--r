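test_that("an all-zero mask yields an empty graph and all-zero metrics", {
  m <- blank_mask()
  g <- skeletonize_and_graph(m)
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$segments), 0)
  mm <- measure_morphology(m)
  expect_true(all(unlist(mm) == 0))
})

test_that("non-binary rasters are rejected", {
  m <- blank_mask(10, 10)
  m$pixels[5, 5] <- 2L
  expect_error(measure_morphology(m), "mask not binary")
  expect_error(vessel_mask(matrix(c(0, 0.5, 1, 1), 2), 1), "mask not binary")
})

test_that("a single bar reduces to two endpoints and one segment", {
  m <- bar_mask(200, 200, width = 3, len = 100)
  g <- skeletonize_and_graph(m)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "branchpoint"), 0)
  expect_equal(nrow(g$segments), 1)
  # brute-force check: the skeleton must be a simple open curve
  census <- degree_census(m)
  expect_equal(unname(census["1"]), 2L)
  expect_equal(sum(census[c("0", as.character(3:8))]), 0)
})

test_that("a plus sign has one branchpoint, four segments, four endpoints", {
  m <- plus_mask(200, 200, width = 3, len = 120)
  g <- skeletonize_and_graph(m)
  expect_equal(sum(g$nodes$kind == "branchpoint"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4)
  expect_equal(nrow(g$segments), 4)
  census <- degree_census(m)
  expect_equal(unname(census["1"]), 4L)
  expect_gte(sum(census[as.character(3:8)]), 1)
})

test_that("bar metrics match closed-form pixel accounting", {
  m <- bar_mask(200, 200, width = 3, len = 100, pitch = 1)
  mm <- measure_morphology(m)
  expect_equal(mm$vessel_coverage, 300 / 40000)
  expect_equal(mm$segment_count, 1)
  expect_equal(mm$branchpoint_count, 0)
  # diameter: 2 x distance transform on the medial axis, +/- 1 px on width 3
  expect_gte(mm$mean_segment_diameter, 2)
  expect_lte(mm$mean_segment_diameter, 4)
  # skeleton of a 100 px bar: length within a few eroded end pixels
  expect_gte(mm$total_vessel_length, 90)
  expect_lte(mm$total_vessel_length, 101)
})

test_that("an all-ones mask has coverage exactly 1", {
  m <- vessel_mask(matrix(1L, 100, 100), 1)
  expect_equal(measure_morphology(m)$vessel_coverage, 1.0)
})

test_that("metrics are invariant to translation and 90-degree rotation", {
  base <- generate_mask(generator_config(n_seed_points = 60, rng_seed = 11L))
  mm <- measure_morphology(base)

  # whole-pixel translation on a padded canvas so nothing falls off
  pad <- matrix(0L, 300, 300)
  pad[23:278, 31:286] <- base$pixels
  mt <- measure_morphology(vessel_mask(pad, base$pixel_pitch))
  expect_equal(mt$segment_count, mm$segment_count)
  expect_equal(mt$branchpoint_count, mm$branchpoint_count)
  expect_equal(mt$total_vessel_length, mm$total_vessel_length, tolerance = 1e-8)

  # construction-based shapes rotate exactly
  for (shape in list(bar_mask(200, 200, 3, 100), plus_mask(200, 200, 3, 120))) {
    ms <- measure_morphology(shape)
    rot <- vessel_mask(t(shape$pixels)[ncol(shape$pixels):1, ],
                       shape$pixel_pitch)
    mr <- measure_morphology(rot)
    expect_equal(mr$vessel_coverage, ms$vessel_coverage)
    expect_equal(mr$segment_count, ms$segment_count)
    expect_equal(mr$branchpoint_count, ms$branchpoint_count)
    expect_equal(mr$total_vessel_length, ms$total_vessel_length,
                 tolerance = 0.01)
  }

  # random networks: thinning is not exactly rotation-equivariant, so counts
  # agree closely but not identically
  rot <- vessel_mask(t(base$pixels)[ncol(base$pixels):1, ], base$pixel_pitch)
  mr <- measure_morphology(rot)
  expect_equal(mr$vessel_coverage, mm$vessel_coverage)
  expect_lte(abs(mr$segment_count - mm$segment_count),
             0.04 * mm$segment_count)
  expect_lte(abs(mr$branchpoint_count - mm$branchpoint_count),
             0.04 * max(mm$branchpoint_count, 1))
  expect_equal(mr$total_vessel_length, mm$total_vessel_length,
               tolerance = 0.01)
  expect_equal(mr$mean_segment_length, mm$mean_segment_length,
               tolerance = 0.05)
})

test_that("dilation never decreases coverage or mean diameter", {
  for (s in c(2L, 9L)) {
    m <- generate_mask(generator_config(n_seed_points = 50, rng_seed = s))
    mm <- measure_morphology(m)
    grown <- m$pixels
    nr <- nrow(grown); nc <- ncol(grown)
    for (dr in -1:1) for (dc in -1:1) {
      src_r <- max(1, 1 - dr):min(nr, nr - dr)
      src_c <- max(1, 1 - dc):min(nc, nc - dc)
      grown[src_r + dr, src_c + dc] <-
        pmax(grown[src_r + dr, src_c + dc], m$pixels[src_r, src_c])
    }
    md <- measure_morphology(vessel_mask(grown, m$pixel_pitch))
    expect_gte(md$vessel_coverage, mm$vessel_coverage)
    expect_gte(md$mean_segment_diameter, mm$mean_segment_diameter)
  }
})

test_that("cohort measurement returns one labelled row per mask", {
  coh <- generate_cohort(generator_config(n_seed_points = 30), n = 3,
                         master_seed = 2L)
  tab <- measure_cohort(coh$masks, coh$manifest$sample_id)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$sample_id, coh$manifest$sample_id)
  expect_true(all(morphology_columns() %in% names(tab)))
})
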