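# shared fixtures built in code

# place a triangle of the given shape at a random rigid position with every
# vertex well in front of the center of projection; returns the vertex
# positions, the generating sight-ray distances and the projected image
random_placement <- function(shape, dist_range = c(2, 30)) {
  d <- side_lengths(shape)
  A <- c(0, 0, 0)
  B <- c(1, 0, 0)
  C <- d[["len_CA"]] * c(cos(shape$omega_A * pi / 180),
                         sin(shape$omega_A * pi / 180), 0)
  # uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  D <- runif(1, dist_range[1], dist_range[2])
  w <- rnorm(3); w <- w / sqrt(sum(w^2))
  P <- lapply(list(A, B, C), function(p) as.numeric(R %*% p + D * w))
  list(A = P[[1]], B = P[[2]], C = P[[3]],
       l = vapply(P, function(p) sqrt(sum(p^2)), 0),
       image = project_vertices(P[[1]], P[[2]], P[[3]]))
}

# does the solution set contain the distance triple within rel tolerance?
contains_triple <- function(sols, l, rel_tol = 1e-6) {
  any(vapply(sols$solutions, function(s) {
    max(abs(c(s$l_A, s$l_B, s$l_C) - l) / l) < rel_tol
  }, TRUE))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# random valid (shape, image) instances as a data frame of degrees
random_instances <- function(n, theta_max, mode = "full") {
  sh <- sample_shapes(n)
  im <- sample_images(n, image_range_for(theta_max, mode))
  cbind(sh, im)
}
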