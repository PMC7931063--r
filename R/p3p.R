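#' Enumerate all 3D interpretations of a triangle's retinal image
#'
#' Solves the Perspective-3-Point (P3P) problem for the tetrahedron `EABC`:
#' given the shape of triangle `ABC` (hence its side lengths, with
#' `||AB|| = scale`) and the visual angles of its retinal image, find every
#' triple of positive distances `(l_A, l_B, l_C)` along the sight rays that
#' satisfies the three law-of-cosines constraints
#' \deqn{l_i^2 + l_j^2 - 2 l_i l_j \cos\theta_{ij} = d_{ij}^2.}
#' There are between 0 and 4 such triples. The solver reduces the system to
#' a degree-4 polynomial (resultant of two quadratics in the distance ratio
#' `l_B/l_A`, eliminating the other ratio), extracts roots from the companion
#' matrix, back-substitutes, and keeps candidates that are strictly positive
#' and verify against the original system to within `resid_tol`.
#'
#' @param shape A [triangle_shape()].
#' @param image A [retinal_image()].
#' @param scale Size factor `s = ||AB||`; all recovered distances scale
#'   linearly with it while the solution count is unchanged.
#' @param resid_tol Verification tolerance on the law-of-cosines residuals
#'   at `scale = 1` (internally scaled by `scale^2`).
#' @return An object of class `p3p_solutions`: a list with fields `shape`,
#'   `image`, `scale`, and `solutions`, the latter a list of 0 to 4
#'   interpretations sorted by `l_A` (ties by `l_B`). Each interpretation
#'   carries `l_A`, `l_B`, `l_C` and vertex positions `A_pos`, `B_pos`,
#'   `C_pos` in the canonical frame of [rays_from_image()].
#' @examples
#' sols <- solve_p3p(triangle_shape(30, 60), retinal_image(9, 10, 11))
#' length(sols$solutions)
#' @export
solve_p3p <- function(shape, image, scale = 1, resid_tol = 1e-8) {
  stopifnot(inherits(shape, "triangle_shape"),
            inherits(image, "retinal_image"),
            is.numeric(scale), length(scale) == 1L, scale > 0)
  d <- side_lengths(shape) * scale
  L <- .p3p_solve_raw(d[["len_BC"]], d[["len_CA"]], d[["len_AB"]],
                      deg2rad(image$theta_BC), deg2rad(image$theta_CA),
                      deg2rad(image$theta_AB),
                      resid_tol * max(1, scale^2))
  rays <- rays_from_image(image)
  sols <- lapply(seq_len(nrow(L)), function(i) {
    interpretation(L[i, 1], L[i, 2], L[i, 3], rays, scale)
  })
  structure(list(shape = shape, image = image, scale = scale,
                 solutions = sols),
            class = "p3p_solutions")
}

# one recovered 3D placement: distances along the sight rays and the
# implied vertex positions A = l_A V_A etc.
interpretation <- function(l_A, l_B, l_C, rays, scale = 1) {
  structure(list(l_A = l_A, l_B = l_B, l_C = l_C,
                 A_pos = l_A * rays["V_A", ],
                 B_pos = l_B * rays["V_B", ],
                 C_pos = l_C * rays["V_C", ],
                 scale = scale),
            class = "p3p_interpretation")
}

#' @export
print.p3p_solutions <- function(x, ...) {
  cat(sprintf("P3P solutions: %d interpretation(s)\n", length(x$solutions)))
  cat(sprintf("  shape (%g, %g, %g) deg, image (%g, %g, %g) deg, s = %g\n",
              x$shape$omega_A, x$shape$omega_B, x$shape$omega_C,
              x$image$theta_BC, x$image$theta_CA, x$image$theta_AB, x$scale))
  for (s in x$solutions) {
    cat(sprintf("  l_A = %.9g, l_B = %.9g, l_C = %.9g\n",
                s$l_A, s$l_B, s$l_C))
  }
  invisible(x)
}

#' Law-of-cosines residuals of a candidate interpretation
#'
#' Measures how far a distance triple is from solving the P3P system for a
#' given shape and image: `|l_i^2 + l_j^2 - 2 l_i l_j cos(theta_ij) -
#' d_ij^2|` for the three vertex pairs. All three vanish exactly on a true
#' solution.
#'
#' @param interp A `p3p_interpretation` (e.g. an element of
#'   `solve_p3p(...)$solutions`).
#' @param shape,image The instance the interpretation is checked against.
#' @return Named numeric vector `c(res_BC, res_CA, res_AB)`.
#' @export
p3p_residuals <- function(interp, shape, image) {
  stopifnot(inherits(interp, "p3p_interpretation"),
            inherits(shape, "triangle_shape"),
            inherits(image, "retinal_image"))
  if (any(c(interp$l_A, interp$l_B, interp$l_C) <= 0)) {
    stop("interpretation distances must be positive")
  }
  d <- side_lengths(shape) * interp$scale
  lc <- function(li, lj, th) li^2 + lj^2 - 2 * li * lj * cos(deg2rad(th))
  c(res_BC = abs(lc(interp$l_B, interp$l_C, image$theta_BC) -
                   d[["len_BC"]]^2),
    res_CA = abs(lc(interp$l_C, interp$l_A, image$theta_CA) -
                   d[["len_CA"]]^2),
    res_AB = abs(lc(interp$l_A, interp$l_B, image$theta_AB) -
                   d[["len_AB"]]^2))
}

#' Recover a triangle's shape from its image and a given plane
#'
#' When the orientation of the triangle's plane is known, the shape is
#' determined uniquely: intersect the three sight rays with the plane
#' `normal . x = distance` and read off the vertex angles of the triangle so
#' cut. The plane's distance from the eye only sets the size.
#'
#' @param image A [retinal_image()].
#' @param plane_normal Numeric 3-vector, need not be unit length.
#' @param plane_distance Positive distance of the plane from the origin
#'   along the (normalized) normal.
#' @return List with `shape` (a [triangle_shape()]) and `size` (`||AB||`).
#' @export
shape_from_orientation <- function(image, plane_normal, plane_distance) {
  stopifnot(inherits(image, "retinal_image"),
            is.numeric(plane_normal), length(plane_normal) == 3L,
            is.numeric(plane_distance), plane_distance > 0)
  n <- plane_normal / sqrt(sum(plane_normal^2))
  rays <- rays_from_image(image)
  dots <- as.numeric(rays %*% n)
  if (any(abs(dots) < 1e-10)) {
    stop("plane normal is perpendicular to a line of projection")
  }
  t <- plane_distance / dots
  if (any(t <= 0)) {
    stop("plane intersects a sight ray behind the center of projection")
  }
  P <- rays * t   # rows: A, B, C positions
  ab <- P["V_B", ] - P["V_A", ]
  ac <- P["V_C", ] - P["V_A", ]
  bc <- P["V_C", ] - P["V_B", ]
  omega_A <- angle_between(ab, ac)
  omega_B <- angle_between(-ab, bc)
  list(shape = triangle_shape(omega_A, omega_B),
       size = sqrt(sum(ab^2)))
}

#' Test whether two interpretations are approximate depth reversals
#'
#' For small retinal images the perspective projection is close to
#' orthographic and the two dominant P3P solutions mirror each other in
#' depth, like the two percepts of a Necker cube. This predicate compares
#' the per-vertex depth offsets from each interpretation's mean depth: in an
#' exact reversal the offsets of one are the negation of the other's. The
#' discrepancy metric is `||e1 + e2|| / (||e1|| + ||e2||)` where `e_k` is
#' the centered depth-offset vector of interpretation `k`; it is 0 for an
#' exact reversal and 1 when the profiles are identical (a frontoparallel
#' triangle has zero offsets and counts as an exact, degenerate reversal).
#'
#' @param s1,s2 Two `p3p_interpretation` objects for the same instance.
#' @param tol Acceptance threshold on the discrepancy metric.
#' @return List with `reversal` (logical) and `discrepancy` (numeric in
#'   `[0, 1]`).
#' @export
is_depth_reversal_pair <- function(s1, s2, tol = 0.15) {
  stopifnot(inherits(s1, "p3p_interpretation"),
            inherits(s2, "p3p_interpretation"))
  e1 <- c(s1$l_A, s1$l_B, s1$l_C)
  e2 <- c(s2$l_A, s2$l_B, s2$l_C)
  e1 <- e1 - mean(e1)
  e2 <- e2 - mean(e2)
  denom <- sqrt(sum(e1^2)) + sqrt(sum(e2^2))
  disc <- if (denom < 1e-12) 0 else sqrt(sum((e1 + e2)^2)) / denom
  list(reversal = disc <= tol, discrepancy = disc)
}

#' Brute-force count of P3P solutions by 1D scanning
#'
#' Independent verification oracle for [solve_p3p()]. The system is
#' parameterized by the ratio `u = l_B/l_A`: the `AB` equation fixes
#' `l_A(u)` in closed form, the `BC` equation then gives up to two branches
#' `l_C(u)`, and what remains is a single residual function `f(u)` per
#' branch from the `CA` equation. Roots of `f` are located by scanning a
#' dense grid (uniform in `atan(u)` so that the whole ray `u > 0` is
#' covered), bracketing sign changes, refining with [stats::uniroot()], and
#' polishing near-zero local minima of `|f|` (tangential roots). Distinct
#' positive solutions are counted after deduplication.
#'
#' @param shape A [triangle_shape()].
#' @param image A [retinal_image()].
#' @param scan_step Grid step in `atan(u)` (radians); the default gives
#'   about 15,700 grid points.
#' @return Integer solution count.
#' @export
oracle_count <- function(shape, image, scan_step = 1e-4) {
  stopifnot(inherits(shape, "triangle_shape"),
            inherits(image, "retinal_image"))
  if (!is.numeric(scan_step) || length(scan_step) != 1L || scan_step <= 0) {
    stop("scan_step must be a positive number")
  }
  d <- side_lengths(shape)
  dBC <- d[["len_BC"]]; dCA <- d[["len_CA"]]; dAB <- d[["len_AB"]]
  ca <- cos(deg2rad(image$theta_BC))
  cb <- cos(deg2rad(image$theta_CA))
  cg <- cos(deg2rad(image$theta_AB))
  sa2 <- 1 - ca^2

  # per-branch CA residual as a function of u; NA where the branch is
  # infeasible (complex or non-positive l_C)
  fbranch <- function(u, sign) {
    g <- 1 + u^2 - 2 * u * cg
    lA <- dAB / sqrt(g)
    lB <- u * lA
    disc <- dBC^2 - lB^2 * sa2
    lC <- lB * ca + sign * sqrt(pmax(disc, 0))
    out <- lC^2 + lA^2 - 2 * lC * lA * cb - dCA^2
    out[disc < -1e-9 * dBC^2 | lC <= 0] <- NA_real_
    out
  }

  tgrid <- seq(scan_step / 2, pi / 2 - scan_step / 2, by = scan_step)
  ugrid <- tan(tgrid)
  # the two l_C branches meet where the BC discriminant vanishes; roots can
  # hide in the grid cell next to a junction, so junction points (roots of a
  # quadratic in u) are inserted as exact evaluation points on both branches
  jq <- c(-dBC^2, 2 * dBC^2 * cg, dAB^2 * sa2 - dBC^2)
  jdisc <- jq[2]^2 - 4 * jq[1] * jq[3]
  if (abs(jq[3]) > 1e-14 && jdisc >= 0) {
    uj <- (-jq[2] + c(1, -1) * sqrt(jdisc)) / (2 * jq[3])
    ugrid <- sort(c(ugrid, uj[uj > 0]))
  }
  roots <- list()
  for (sgn in c(1, -1)) {
    f <- fbranch(ugrid, sgn)
    ok <- !is.na(f)
    # sign changes between consecutive feasible points
    idx <- which(ok[-length(ok)] & ok[-1] &
                   f[-length(f)] * f[-1] < 0)
    for (i in idx) {
      r <- uniroot(function(u) fbranch(u, sgn), lower = ugrid[i],
                   upper = ugrid[i + 1], tol = 1e-13)
      roots[[length(roots) + 1L]] <- c(r$root, sgn)
    }
    # tangential roots: local minima of |f| that polish to ~0
    af <- abs(f)
    n <- length(af)
    is_min <- ok & c(FALSE, af[-1] < af[-n]) & c(af[-n] < af[-1], FALSE)
    for (i in which(is_min)) {
      if (af[i] > 1e-3) next
      op <- optimize(function(u) abs(fbranch(u, sgn)),
                     c(ugrid[max(1, i - 1)], ugrid[min(n, i + 1)]),
                     tol = 1e-14)
      if (op$objective < 1e-10) {
        roots[[length(roots) + 1L]] <- c(op$minimum, sgn)
      }
    }
  }
  if (!length(roots)) return(0L)
  triples <- do.call(rbind, lapply(roots, function(rs) {
    u <- rs[1]; sgn <- rs[2]
    g <- 1 + u^2 - 2 * u * cg
    lA <- dAB / sqrt(g)
    lB <- u * lA
    disc <- dBC^2 - lB^2 * sa2
    lC <- lB * ca + sgn * sqrt(max(disc, 0))
    c(lA, lB, lC)
  }))
  keep <- triples[, 1] > 1e-9 & triples[, 2] > 1e-9 & triples[, 3] > 1e-9
  triples <- triples[keep, , drop = FALSE]
  if (!nrow(triples)) return(0L)
  # dedup by max relative component difference (same rule as the solver)
  uniq <- triples[1, , drop = FALSE]
  for (i in seq_len(nrow(triples))[-1]) {
    dup <- FALSE
    for (j in seq_len(nrow(uniq))) {
      rel <- abs(triples[i, ] - uniq[j, ]) / pmax(abs(triples[i, ]),
                                                  abs(uniq[j, ]))
      if (max(rel) < 1e-5) { dup <- TRUE; break }
    }
    if (!dup) uniq <- rbind(uniq, triples[i, ])
  }
  nrow(uniq)
}

# vectorized solution counting used by the Monte-Carlo experiments and the
# shape-space maps; inputs are plain numeric vectors in degrees
count_solutions_batch <- function(omega_A, omega_B, theta_BC, theta_CA,
                                  theta_AB, resid_tol = 1e-8) {
  omega_C <- 180 - omega_A - omega_B
  sC <- sin(deg2rad(omega_C))
  .p3p_count_batch(sin(deg2rad(omega_A)) / sC,
                   sin(deg2rad(omega_B)) / sC,
                   rep(1, length(omega_A)),
                   deg2rad(theta_BC), deg2rad(theta_CA), deg2rad(theta_AB),
                   resid_tol)
}
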