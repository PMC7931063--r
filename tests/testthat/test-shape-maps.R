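test_that("bundled stimuli load and validate", {
  stim <- stimulus_set()
  expect_named(stim, c("beck_gibson_1", "beck_gibson_2", "beck_gibson_3",
                       "watanabe_left", "watanabe_right", "fig3_text_small",
                       "fig3_caption_small", "fig3_large"))
  for (s in stim) expect_s3_class(s, "retinal_image")
  expect_equal(unlist(stim$watanabe_left), c(theta_BC = 41.19,
                                             theta_CA = 27.68,
                                             theta_AB = 31.01))
  expect_equal(stim$beck_gibson_1$theta_AB, 6.573)
})

test_that("map grid and validity marking follow the shape constraints", {
  # default: full shape simplex, invalid only where omega_C degenerates
  m <- compute_shape_map(retinal_image(9, 10, 11), grid_step = 4)
  expect_equal(m$omega_A[1], 2)
  expect_true(all(m$omega_A > 0 & m$omega_A < 180))
  gA <- rep(m$omega_A, times = length(m$omega_B))
  gB <- rep(m$omega_B, each = length(m$omega_A))
  gC <- 180 - gA - gB
  expect_identical(is.na(as.vector(m$counts)), !(gC > 0))
  v <- m$counts[!is.na(m$counts)]
  expect_true(all(v >= 0 & v <= 4))
  # study-range restriction
  mr <- compute_shape_map(retinal_image(9, 10, 11), grid_step = 4,
                          omega_range = c(10, 170))
  expect_equal(mr$omega_A[1], 12)
  gA <- rep(mr$omega_A, times = length(mr$omega_B))
  gB <- rep(mr$omega_B, each = length(mr$omega_A))
  gC <- 180 - gA - gB
  expect_identical(is.na(as.vector(mr$counts)), !(gC > 10 & gC < 170))
  expect_error(compute_shape_map(retinal_image(9, 10, 11), grid_step = 500),
               "grid_step")
  expect_error(compute_shape_map(retinal_image(9, 10, 11), 0.5,
                                 omega_range = c(170, 10)), "omega_range")
})

test_that("maps are deterministic and symmetric for isoceles images", {
  # theta_BC = theta_CA: relabeling A and B leaves the image fixed and
  # swaps omega_A with omega_B, so the count matrix must be symmetric
  img <- stimulus_set()$beck_gibson_1
  m1 <- compute_shape_map(img, grid_step = 4)
  m2 <- compute_shape_map(img, grid_step = 4)
  expect_identical(m1$counts, m2$counts)
  expect_identical(m1$counts, t(m1$counts))
})

test_that("small images are consistent with almost any shape", {
  st <- map_statistics(compute_shape_map(stimulus_set()$beck_gibson_1,
                                         grid_step = 2))
  expect_equal(sum(st$fractions), 1, tolerance = 1e-12)
  expect_equal(st$fractions[["3"]], 0)
  expect_equal(st$fractions[["4"]], 0)
  expect_gt(st$fraction_projectable, 0.99)
  # the small-image map is dominated by two-solution shapes
  st2 <- map_statistics(compute_shape_map(stimulus_set()$fig3_text_small,
                                          grid_step = 2))
  expect_gt(st2$fractions[["2"]], 0.5)
})

test_that("the large image restricts the projectable shapes", {
  st <- map_statistics(compute_shape_map(stimulus_set()$fig3_large,
                                         grid_step = 2))
  expect_lt(st$fraction_projectable, 0.5)
})

test_that("grid refinement moves the fractions only slightly", {
  img <- stimulus_set()$watanabe_left
  f2 <- map_statistics(compute_shape_map(img, grid_step = 2))$fractions
  f1 <- map_statistics(compute_shape_map(img, grid_step = 1))$fractions
  expect_lt(max(abs(f2 - f1)), 0.02)
})

test_that("binocular combination obeys its identities", {
  stim <- stimulus_set()
  left <- compute_shape_map(stim$watanabe_left, grid_step = 2)
  right <- compute_shape_map(stim$watanabe_right, grid_step = 2)
  bin <- binocular_combine(left, right)
  s <- bin$statistics
  expect_lte(s$fraction_binocular, min(s$fraction_left, s$fraction_right))
  expect_gt(s$fraction_binocular, 0.5)
  # idempotence: an eye combined with itself
  self <- binocular_combine(left, left)
  expect_equal(self$statistics$fraction_binocular, s$fraction_left)
  # grid mismatch
  coarse <- compute_shape_map(stim$watanabe_right, grid_step = 4)
  expect_error(binocular_combine(left, coarse), "identical grid")
})

test_that("map long-format export is lossless", {
  m <- compute_shape_map(retinal_image(10, 15, 20), grid_step = 8)
  tab <- p3ptriangle:::shape_map_to_table(m)
  expect_equal(nrow(tab), length(m$omega_A)^2)
  expect_identical(tab$valid, !is.na(tab$n_solutions))
  expect_equal(matrix(tab$n_solutions, nrow = length(m$omega_A)), m$counts)
})
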