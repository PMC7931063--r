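#' Bundled triangle stimuli from two classic shape-constancy studies
#'
#' Returns the visual-angle triples of the triangle stimuli analyzed by the
#' package: the three orientations of Beck & Gibson's (1955) Experiment 1
#' triangle, the left- and right-eye images of Watanabe's (2004) Condition 3
#' triangle, and three reference images (a small image in two published
#' variants that disagree between the running text and the figure caption,
#' and a large image).
#'
#' @return Named list of [retinal_image()] objects.
#' @examples
#' stimulus_set()$watanabe_left
#' @export
stimulus_set <- function() {
  path <- system.file("extdata", "stimuli.csv", package = "p3ptriangle",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    retinal_image(tab$theta_BC[i], tab$theta_CA[i], tab$theta_AB[i])
  })
  names(out) <- tab$name
  out
}

#' Solution-count map over triangle shape space for a fixed image
#'
#' Grids the shape space `(omega_A, omega_B)` at `grid_step` degrees (cell
#' centers offset by `grid_step/2` from the lower bound) and records, for
#' each valid shape, the number of P3P solutions for the given retinal
#' image. A cell is valid when all three vertex angles lie strictly inside
#' `omega_range`; other cells are marked `NA`. The default range is the
#' full shape simplex (every proper triangle); pass `c(10, 170)` to
#' restrict the map to the shapes admitted by the Monte-Carlo samplers.
#'
#' @param image A [retinal_image()].
#' @param grid_step Grid spacing in degrees.
#' @param omega_range Length-2 numeric: open bounds on all three vertex
#'   angles defining a valid cell.
#' @return An object of class `solution_count_map`: list with `image`,
#'   `grid_step`, `omega_range`, axis vectors `omega_A`, `omega_B` (cell
#'   centers, degrees) and an integer `counts` matrix (`omega_A` on rows)
#'   with `NA` at invalid cells.
#' @examples
#' m <- compute_shape_map(retinal_image(9, 10, 11), grid_step = 8)
#' map_statistics(m)$fraction_projectable
#' @export
compute_shape_map <- function(image, grid_step = 0.5,
                              omega_range = c(0, 180)) {
  stopifnot(inherits(image, "retinal_image"),
            is.numeric(grid_step), length(grid_step) == 1L, grid_step > 0,
            is.numeric(omega_range), length(omega_range) == 2L)
  lo <- omega_range[1]; hi <- omega_range[2]
  if (!(lo >= 0 && lo < hi && hi <= 180)) {
    stop("omega_range must satisfy 0 <= lo < hi <= 180")
  }
  if (lo + grid_step / 2 >= hi) stop("grid_step too large: no valid cells")
  centers <- seq(lo + grid_step / 2, hi, by = grid_step)
  centers <- centers[centers < hi]
  gA <- rep(centers, times = length(centers))
  gB <- rep(centers, each = length(centers))
  gC <- 180 - gA - gB
  valid <- gC > lo & gC < hi
  if (!any(valid)) stop("grid_step too large: no valid cells")
  counts <- rep(NA_integer_, length(gA))
  counts[valid] <- count_solutions_batch(
    gA[valid], gB[valid],
    rep(image$theta_BC, sum(valid)), rep(image$theta_CA, sum(valid)),
    rep(image$theta_AB, sum(valid)))
  structure(list(image = image, grid_step = grid_step,
                 omega_range = c(lo, hi),
                 omega_A = centers, omega_B = centers,
                 counts = matrix(counts, nrow = length(centers))),
            class = "solution_count_map")
}

#' @export
print.solution_count_map <- function(x, ...) {
  st <- map_statistics(x)
  cat(sprintf(
    "solution-count map: image (%g, %g, %g) deg, step %g deg, %d valid cells\n",
    x$image$theta_BC, x$image$theta_CA, x$image$theta_AB, x$grid_step,
    st$n_valid))
  cat(sprintf("  projectable fraction: %.4f\n", st$fraction_projectable))
  invisible(x)
}

#' Summary statistics of a solution-count map
#'
#' @param map A `solution_count_map`.
#' @return List with `n_valid` (number of valid grid shapes), `fractions`
#'   (named vector: fraction of valid cells at each count 0-4, summing to
#'   1) and `fraction_projectable` (count >= 1).
#' @export
map_statistics <- function(map) {
  stopifnot(inherits(map, "solution_count_map"))
  v <- map$counts[!is.na(map$counts)]
  fr <- tabulate(v + 1L, nbins = 5L) / length(v)
  names(fr) <- as.character(0:4)
  list(n_valid = length(v), fractions = fr,
       fraction_projectable = sum(fr[-1]))
}

#' Combine the left- and right-eye maps of a binocularly viewed triangle
#'
#' A shape is monocularly projectable to an eye when it has at least one
#' P3P solution for that eye's image; it is binocularly projectable when it
#' is projectable to both. No epipolar or vergence consistency between the
#' two eyes is imposed — the combination is a per-shape conjunction of the
#' two monocular maps.
#'
#' @param left,right Two `solution_count_map` objects on identical grids.
#' @return An object of class `binocular_map`: list with `left`, `right`,
#'   `binocular` (logical matrix, `NA` at invalid cells) and `statistics`
#'   (fractions projectable monocularly per eye and binocularly).
#' @export
binocular_combine <- function(left, right) {
  stopifnot(inherits(left, "solution_count_map"),
            inherits(right, "solution_count_map"))
  if (left$grid_step != right$grid_step ||
      !identical(left$omega_range, right$omega_range) ||
      length(left$omega_A) != length(right$omega_A) ||
      any(abs(left$omega_A - right$omega_A) > 1e-12)) {
    stop("left and right maps must share an identical grid")
  }
  bino <- (left$counts >= 1L) & (right$counts >= 1L)
  v <- !is.na(bino)
  stats <- list(
    fraction_left = map_statistics(left)$fraction_projectable,
    fraction_right = map_statistics(right)$fraction_projectable,
    fraction_binocular = sum(bino[v]) / sum(v))
  structure(list(left = left, right = right, binocular = bino,
                 statistics = stats),
            class = "binocular_map")
}

#' @export
print.binocular_map <- function(x, ...) {
  s <- x$statistics
  cat(sprintf(paste0("binocular map: projectable left %.4f, right %.4f, ",
                     "both %.4f\n"),
              s$fraction_left, s$fraction_right, s$fraction_binocular))
  invisible(x)
}

# long-format data frame for CSV export and plotting
shape_map_to_table <- function(map) {
  stopifnot(inherits(map, "solution_count_map"))
  gA <- rep(map$omega_A, times = length(map$omega_B))
  gB <- rep(map$omega_B, each = length(map$omega_A))
  data.frame(omega_A = gA, omega_B = gB, omega_C = 180 - gA - gB,
             valid = !is.na(as.vector(map$counts)),
             n_solutions = as.vector(map$counts))
}
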