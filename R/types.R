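#' Triangle shape given by its vertex angles
#'
#' A planar triangle's shape is fully characterized by two vertex angles
#' `omega_A` and `omega_B` (degrees); the third is
#' `omega_C = 180 - omega_A - omega_B`. Side `AB` has unit length by
#' convention, so the shape fixes all three side lengths.
#'
#' @param omega_A,omega_B Vertex angles at `A` and `B`, degrees, each strictly
#'   inside (0, 180).
#' @param omega_C Optional vertex angle at `C`; when supplied it must equal
#'   `180 - omega_A - omega_B` to within 1e-9 degrees.
#' @return An object of class `triangle_shape` with fields `omega_A`,
#'   `omega_B`, `omega_C` (degrees).
#' @examples
#' triangle_shape(60, 60)
#' triangle_shape(30, 60, 90)
#' @export
triangle_shape <- function(omega_A, omega_B, omega_C = NULL) {
  stopifnot(is.numeric(omega_A), length(omega_A) == 1L,
            is.numeric(omega_B), length(omega_B) == 1L)
  third <- 180 - omega_A - omega_B
  if (!is.null(omega_C) && abs(omega_C - third) > 1e-9) {
    stop("vertex angles must sum to 180 degrees (got sum ",
         format(omega_A + omega_B + omega_C), ")")
  }
  ang <- c(omega_A, omega_B, third)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("each vertex angle must lie strictly in (0, 180) degrees")
  }
  structure(list(omega_A = omega_A, omega_B = omega_B, omega_C = third),
            class = "triangle_shape")
}

#' @export
print.triangle_shape <- function(x, ...) {
  cat(sprintf("triangle shape: omega_A = %g, omega_B = %g, omega_C = %g deg\n",
              x$omega_A, x$omega_B, x$omega_C))
  invisible(x)
}

#' Does a shape satisfy the study constraint on vertex angles?
#'
#' The simulation experiments restrict triangle shapes to those whose three
#' vertex angles all lie strictly between 10 and 170 degrees.
#'
#' @param shape A [triangle_shape()].
#' @return `TRUE` if all three vertex angles are strictly in (10, 170).
#' @export
shape_in_study_range <- function(shape) {
  stopifnot(inherits(shape, "triangle_shape"))
  ang <- c(shape$omega_A, shape$omega_B, shape$omega_C)
  all(ang > 10 & ang < 170)
}

#' Retinal image of a triangle given by three visual angles
#'
#' The retinal image of triangle `ABC` is characterized by the visual angles
#' (degrees) that each pair of vertices subtends at the eye's center of
#' projection `E`: `theta_BC`, `theta_CA`, `theta_AB`. For the three sight
#' rays to form the apex of a tetrahedron the angles must each lie in
#' (0, 180), sum to less than 360, and satisfy all pairwise triangle
#' inequalities.
#'
#' @param theta_BC,theta_CA,theta_AB Visual angles in degrees.
#' @return An object of class `retinal_image`.
#' @examples
#' retinal_image(9, 10, 11)
#' @export
retinal_image <- function(theta_BC, theta_CA, theta_AB) {
  th <- c(theta_BC, theta_CA, theta_AB)
  stopifnot(is.numeric(th), length(th) == 3L)
  if (any(!is.finite(th)) || any(th <= 0) || any(th >= 180)) {
    stop("each visual angle must lie strictly in (0, 180) degrees")
  }
  if (sum(th) >= 360) {
    stop("visual angles must sum to less than 360 degrees")
  }
  if (th[1] + th[2] <= th[3] || th[2] + th[3] <= th[1] ||
      th[3] + th[1] <= th[2]) {
    stop("visual angles must satisfy the pairwise triangle inequalities")
  }
  structure(list(theta_BC = theta_BC, theta_CA = theta_CA,
                 theta_AB = theta_AB),
            class = "retinal_image")
}

#' @export
print.retinal_image <- function(x, ...) {
  cat(sprintf(
    "retinal image: theta_BC = %g, theta_CA = %g, theta_AB = %g deg\n",
    x$theta_BC, x$theta_CA, x$theta_AB))
  invisible(x)
}

#' Side lengths of a triangle from its vertex angles
#'
#' With `||AB|| = 1` fixed by convention, the law of sines gives the two
#' remaining sides: `||BC|| = sin(omega_A)/sin(omega_C)` and
#' `||CA|| = sin(omega_B)/sin(omega_C)`.
#'
#' @param shape A [triangle_shape()].
#' @return Named numeric vector `c(len_BC, len_CA, len_AB)`.
#' @examples
#' side_lengths(triangle_shape(60, 60))   # c(1, 1, 1)
#' @export
side_lengths <- function(shape) {
  stopifnot(inherits(shape, "triangle_shape"))
  sC <- sin(deg2rad(shape$omega_C))
  c(len_BC = sin(deg2rad(shape$omega_A)) / sC,
    len_CA = sin(deg2rad(shape$omega_B)) / sC,
    len_AB = 1)
}

#' Unit sight rays realizing a retinal image
#'
#' Embeds the apex of the tetrahedron `EABC` in a fixed coordinate frame:
#' `E` at the origin, `V_A` along +z, `V_B` in the x-z half-plane with
#' positive x, and `V_C` with positive y (the mirror image would carry the
#' same solution structure).
#'
#' @param image A [retinal_image()].
#' @param mirror If `TRUE`, choose the mirrored embedding with `V_C` below
#'   the x-z plane; the P3P solution count is invariant to this choice.
#' @return A 3 x 3 matrix with rows `V_A`, `V_B`, `V_C` (unit vectors).
#' @export
rays_from_image <- function(image, mirror = FALSE) {
  stopifnot(inherits(image, "retinal_image"))
  thAB <- deg2rad(image$theta_AB)
  thBC <- deg2rad(image$theta_BC)
  thCA <- deg2rad(image$theta_CA)
  vA <- c(0, 0, 1)
  vB <- c(sin(thAB), 0, cos(thAB))
  z <- cos(thCA)
  x <- (cos(thBC) - cos(thCA) * cos(thAB)) / sin(thAB)
  y2 <- 1 - x^2 - z^2
  if (y2 <= 0) {
    stop("retinal image admits no real sight-ray embedding (degenerate apex)")
  }
  vC <- c(x, if (mirror) -sqrt(y2) else sqrt(y2), z)
  rays <- rbind(V_A = vA, V_B = vB, V_C = vC)
  colnames(rays) <- c("x", "y", "z")
  rays
}

# angle (degrees) between two 3-vectors, numerically clamped
angle_between <- function(u, v) {
  d <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  rad2deg(acos(min(1, max(-1, d))))
}

#' Visual angles subtended by three vertex positions
#'
#' Forward projection: given the positions of the triangle's vertices with
#' the center of projection `E` at the origin, return the retinal image they
#' generate. Angles depend only on directions, so the image is invariant
#' under a global rescaling of the positions.
#'
#' @param A_pos,B_pos,C_pos Numeric 3-vectors; each must be at strictly
#'   positive distance from the origin and no two may be collinear with it.
#' @return A [retinal_image()].
#' @export
project_vertices <- function(A_pos, B_pos, C_pos) {
  P <- list(A_pos, B_pos, C_pos)
  if (any(vapply(P, function(p) sqrt(sum(p^2)), 0) < 1e-12)) {
    stop("vertex at the center of projection: projection undefined")
  }
  th <- c(angle_between(B_pos, C_pos),
          angle_between(C_pos, A_pos),
          angle_between(A_pos, B_pos))
  if (any(th < 1e-9) || any(th > 180 - 1e-9)) {
    stop("two vertices collinear with the center of projection")
  }
  retinal_image(th[1], th[2], th[3])
}
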