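#' Visual-angle sampling range
#'
#' The Monte-Carlo experiments draw visual angles uniformly from a box
#' `(theta_lo, theta_hi)^3` intersected with the apex constraints. The two
#' study conditions are `full`, sampling on `(0.1, theta_max)`, and `half`,
#' sampling on `(theta_max/2, theta_max)`.
#'
#' @param theta_lo,theta_hi Bounds in degrees, `0 < theta_lo < theta_hi <= 180`.
#' @return An object of class `image_range`.
#' @export
image_range <- function(theta_lo, theta_hi) {
  stopifnot(is.numeric(theta_lo), is.numeric(theta_hi),
            length(theta_lo) == 1L, length(theta_hi) == 1L)
  if (!(theta_lo > 0 && theta_lo < theta_hi && theta_hi <= 180)) {
    stop("need 0 < theta_lo < theta_hi <= 180")
  }
  structure(list(theta_lo = theta_lo, theta_hi = theta_hi),
            class = "image_range")
}

#' @rdname image_range
#' @param theta_max Upper bound of the sweep condition, degrees.
#' @param mode `"full"` for `(0.1, theta_max)` or `"half"` for
#'   `(theta_max/2, theta_max)`.
#' @export
image_range_for <- function(theta_max, mode = c("full", "half")) {
  mode <- match.arg(mode)
  if (mode == "full") image_range(0.1, theta_max)
  else image_range(theta_max / 2, theta_max)
}

#' Draw random triangle shapes uniformly under the study constraints
#'
#' Vertex angles `(omega_A, omega_B)` are uniform over the region where all
#' three angles lie strictly in (10, 170) degrees and sum to 180,
#' implemented by rejection: draw `omega_A` and `omega_B` independently
#' uniform on (10, 170) and accept iff `10 < 180 - omega_A - omega_B < 170`.
#' Uses R's global random number generator; seed with [set.seed()].
#'
#' @param n Number of shapes to draw.
#' @return Data frame with columns `omega_A`, `omega_B`, `omega_C`
#'   (degrees) and an `acceptance_rate` attribute recording the rejection
#'   bookkeeping.
#' @examples
#' set.seed(1)
#' head(sample_shapes(5))
#' @export
sample_shapes <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  oA <- numeric(n); oB <- numeric(n)
  got <- 0L; drawn <- 0L; accepted <- 0L
  while (got < n) {
    m <- max(64L, as.integer(ceiling((n - got) * 1.4)))
    a <- runif(m, 10, 170)
    b <- runif(m, 10, 170)
    cc <- 180 - a - b
    keep <- cc > 10 & cc < 170 & a > 10 & a < 170 & b > 10 & b < 170
    drawn <- drawn + m
    accepted <- accepted + sum(keep)
    k <- which(keep)
    if (length(k)) {
      k <- k[seq_len(min(length(k), n - got))]
      idx <- got + seq_along(k)
      oA[idx] <- a[k]; oB[idx] <- b[k]
      got <- got + length(k)
    }
  }
  out <- data.frame(omega_A = oA, omega_B = oB, omega_C = 180 - oA - oB)
  attr(out, "acceptance_rate") <- accepted / drawn
  out
}

#' @rdname sample_shapes
#' @return `sample_shape()` draws a single shape and returns a
#'   [triangle_shape()].
#' @export
sample_shape <- function() {
  s <- sample_shapes(1)
  triangle_shape(s$omega_A, s$omega_B)
}

#' Draw random retinal images uniformly under the apex constraints
#'
#' Visual angles `(theta_BC, theta_CA, theta_AB)` are uniform over the box
#' `(theta_lo, theta_hi)^3` intersected with the tetrahedron-apex
#' constraints: the three angles sum to less than 360 degrees and satisfy
#' every pairwise triangle inequality. Implemented by rejection sampling;
#' draws landing exactly on a boundary (measure zero) are rejected.
#'
#' @param n Number of images to draw.
#' @param range An [image_range()].
#' @return Data frame with columns `theta_BC`, `theta_CA`, `theta_AB`
#'   (degrees) and an `acceptance_rate` attribute.
#' @examples
#' set.seed(1)
#' head(sample_images(5, image_range(0.1, 14)))
#' @export
sample_images <- function(n, range) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            inherits(range, "image_range"))
  n <- as.integer(n)
  lo <- range$theta_lo; hi <- range$theta_hi
  t1 <- numeric(n); t2 <- numeric(n); t3 <- numeric(n)
  got <- 0L; drawn <- 0L; tries <- 0L; accepted <- 0L
  while (got < n) {
    m <- max(256L, as.integer(ceiling((n - got) * 2.5)))
    a <- runif(m, lo, hi); b <- runif(m, lo, hi); cc <- runif(m, lo, hi)
    keep <- (a + b + cc < 360) & (a + b > cc) & (b + cc > a) & (cc + a > b)
    drawn <- drawn + m
    accepted <- accepted + sum(keep)
    k <- which(keep)
    if (!length(k)) {
      tries <- tries + 1L
      if (tries > 50L) {
        stop("acceptance probability numerically zero for this range")
      }
    } else {
      tries <- 0L
      k <- k[seq_len(min(length(k), n - got))]
      idx <- got + seq_along(k)
      t1[idx] <- a[k]; t2[idx] <- b[k]; t3[idx] <- cc[k]
      got <- got + length(k)
    }
  }
  out <- data.frame(theta_BC = t1, theta_CA = t2, theta_AB = t3)
  attr(out, "acceptance_rate") <- accepted / drawn
  out
}

#' @rdname sample_images
#' @return `sample_image()` draws a single image and returns a
#'   [retinal_image()].
#' @export
sample_image <- function(range) {
  s <- sample_images(1, range)
  retinal_image(s$theta_BC, s$theta_CA, s$theta_AB)
}

# deterministic per-condition substream seed derived from a master seed;
# kept below 2^31 - 1 so it is always a valid R integer seed
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 10007 + 7919 * as.numeric(index)) %%
               2147483647)
}
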