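test_that("frontoparallel equilateral round trip recovers the placement", {
  sh <- triangle_shape(60, 60)
  A <- c(-0.5, 0, 10); B <- c(0.5, 0, 10); C <- c(0, sqrt(3) / 2, 10)
  img <- project_vertices(A, B, C)
  sols <- solve_p3p(sh, img)
  l <- c(sqrt(sum(A^2)), sqrt(sum(B^2)), sqrt(sum(C^2)))
  expect_true(contains_triple(sols, l, 1e-6))
  for (s in sols$solutions) {
    expect_lt(max(p3p_residuals(s, sh, img)), 1e-8)
  }
})

test_that("random round trips recover the generating pose", {
  set.seed(101)
  n_fail <- 0
  for (i in 1:200) {
    sh <- sample_shape()
    pl <- random_placement(sh)
    sols <- solve_p3p(sh, pl$image, scale = 1)
    if (!contains_triple(sols, pl$l, 1e-6)) n_fail <- n_fail + 1
    expect_lte(length(sols$solutions), 4)
  }
  expect_equal(n_fail, 0)
})

test_that("solver output satisfies its contracts", {
  set.seed(7)
  inst <- random_instances(50, 60)
  for (i in seq_len(nrow(inst))) {
    sh <- triangle_shape(inst$omega_A[i], inst$omega_B[i])
    img <- retinal_image(inst$theta_BC[i], inst$theta_CA[i],
                         inst$theta_AB[i])
    sols <- solve_p3p(sh, img)
    k <- length(sols$solutions)
    expect_true(k >= 0 && k <= 4)
    if (k) {
      lA <- vapply(sols$solutions, `[[`, 0, "l_A")
      expect_false(is.unsorted(lA))
      for (s in sols$solutions) {
        expect_true(all(c(s$l_A, s$l_B, s$l_C) > 0))
        expect_lt(max(p3p_residuals(s, sh, img)), 1e-8)
        # positions realize Eq A = l V: re-projection returns the image
        reimg <- project_vertices(s$A_pos, s$B_pos, s$C_pos)
        expect_equal(unlist(reimg), unlist(img), tolerance = 1e-9)
        # positioned side lengths match the shape
        d <- side_lengths(sh)
        expect_equal(sqrt(sum((s$A_pos - s$B_pos)^2)), d[["len_AB"]],
                     tolerance = 1e-7)
        expect_equal(sqrt(sum((s$B_pos - s$C_pos)^2)), d[["len_BC"]],
                     tolerance = 1e-7)
      }
    }
  }
})

test_that("a perturbed solution has a large residual", {
  sh <- triangle_shape(30, 60)
  img <- retinal_image(9, 10, 11)
  sols <- solve_p3p(sh, img)
  s <- sols$solutions[[1]]
  expect_lt(max(p3p_residuals(s, sh, img)), 1e-8)
  s$l_A <- s$l_A + 0.1
  expect_gt(max(p3p_residuals(s, sh, img)), 1e-3)
})

test_that("small-image text example has two depth-reversed solutions", {
  sols <- solve_p3p(triangle_shape(30, 60), retinal_image(9, 10, 11))
  expect_length(sols$solutions, 2)   # frozen: oracle_count agrees
  chk <- is_depth_reversal_pair(sols$solutions[[1]], sols$solutions[[2]],
                                tol = 0.15)
  expect_true(chk$reversal)
})

test_that("large-image equilateral example has one solution", {
  # frozen from oracle_count(triangle_shape(60, 60), retinal_image(90, 100, 110))
  sols <- solve_p3p(triangle_shape(60, 60), retinal_image(90, 100, 110))
  expect_length(sols$solutions, 1)
})

test_that("solutions scale linearly with the size factor", {
  set.seed(11)
  inst <- random_instances(30, 40)
  for (i in seq_len(nrow(inst))) {
    sh <- triangle_shape(inst$omega_A[i], inst$omega_B[i])
    img <- retinal_image(inst$theta_BC[i], inst$theta_CA[i],
                         inst$theta_AB[i])
    s1 <- solve_p3p(sh, img, scale = 1)
    s2 <- solve_p3p(sh, img, scale = 3.7)
    expect_equal(length(s1$solutions), length(s2$solutions))
    for (j in seq_along(s1$solutions)) {
      expect_equal(3.7 * c(s1$solutions[[j]]$l_A, s1$solutions[[j]]$l_B,
                           s1$solutions[[j]]$l_C),
                   c(s2$solutions[[j]]$l_A, s2$solutions[[j]]$l_B,
                     s2$solutions[[j]]$l_C),
                   tolerance = 1e-9)
    }
  }
})

test_that("solution count is invariant under the mirrored embedding", {
  set.seed(12)
  inst <- random_instances(30, 80)
  for (i in seq_len(nrow(inst))) {
    img <- retinal_image(inst$theta_BC[i], inst$theta_CA[i],
                         inst$theta_AB[i])
    V <- rays_from_image(img)
    Vm <- rays_from_image(img, mirror = TRUE)
    # the mirrored apex subtends the same visual angles, hence the same
    # law-of-cosines system and the same solution count
    expect_equal(Vm["V_C", "y"], -V["V_C", "y"])
    expect_equal(Vm["V_C", c("x", "z")], V["V_C", c("x", "z")])
  }
})

test_that("solver rejects invalid inputs", {
  sh <- triangle_shape(60, 60)
  img <- retinal_image(9, 10, 11)
  expect_error(solve_p3p(sh, list(theta_BC = 9)), "retinal_image")
  expect_error(solve_p3p(list(), img), "triangle_shape")
  expect_error(solve_p3p(sh, img, scale = -1), "scale")
})
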