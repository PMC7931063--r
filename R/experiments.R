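#' Monte-Carlo experiment on the number of 3D interpretations
#'
#' For each value of `theta_max`, draws random (shape, image) pairs with the
#' constrained uniform samplers — shapes with all vertex angles in
#' (10, 170) degrees, visual angles in the mode's range under the apex
#' constraints — solves the P3P problem for every pair, and tallies how
#' often 0, 1, 2, 3, or 4 interpretations occur.
#'
#' Each `theta_max` condition runs on its own random substream derived from
#' the master seed and the condition's position in the grid, so conditions
#' are reproducible independently of one another; within a condition the
#' shape stream and the image stream are also separated.
#'
#' @param theta_max_values Numeric vector of `theta_max` values in degrees
#'   (the study sweep is `seq(2, 120, by = 2)`).
#' @param trials Trials per condition. Default `1e5` keeps a full sweep at
#'   desk scale; the original study used `4e8`.
#' @param mode `"full"` (angles in `(0.1, theta_max)`) or `"half"`
#'   (`(theta_max/2, theta_max)`).
#' @param seed Master integer seed.
#' @return List of `frequency_record` objects, one per `theta_max`. Each
#'   has fields `theta_max`, `mode`, `trials`, `counts` (named integer
#'   vector for solution numbers 0-4) and `frequencies`.
#' @examples
#' rec <- run_frequency_experiment(14, trials = 200, mode = "full", seed = 1)
#' rec[[1]]$frequencies
#' @export
run_frequency_experiment <- function(theta_max_values, trials = 1e5,
                                     mode = c("full", "half"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(theta_max_values), length(theta_max_values) >= 1,
            all(theta_max_values > 0), all(theta_max_values <= 180),
            is.numeric(trials), trials >= 1)
  trials <- as.integer(trials)
  records <- vector("list", length(theta_max_values))
  for (i in seq_along(theta_max_values)) {
    tmax <- theta_max_values[i]
    rng <- image_range_for(tmax, mode)
    set.seed(derive_seed(seed, 2L * i))
    shapes <- sample_shapes(trials)
    set.seed(derive_seed(seed, 2L * i + 1L))
    images <- sample_images(trials, rng)
    ns <- count_solutions_batch(shapes$omega_A, shapes$omega_B,
                                images$theta_BC, images$theta_CA,
                                images$theta_AB)
    counts <- tabulate(ns + 1L, nbins = 5L)
    names(counts) <- as.character(0:4)
    records[[i]] <- structure(
      list(theta_max = tmax, mode = mode, trials = trials,
           counts = counts, frequencies = counts / trials),
      class = "frequency_record")
  }
  records
}

#' @export
print.frequency_record <- function(x, ...) {
  cat(sprintf("frequency record: theta_max = %g deg, mode = %s, %d trials\n",
              x$theta_max, x$mode, x$trials))
  print(round(x$frequencies, 5))
  invisible(x)
}

#' Convert frequency records to and from a long-format table
#'
#' `frequency_records_to_table()` flattens a list of records into one row
#' per (theta_max, solution count); `frequency_table_to_records()` is its
#' lossless inverse.
#'
#' @param records List of `frequency_record` objects.
#' @return A data frame with columns `theta_max`, `mode`, `n_solutions`,
#'   `count`, `frequency`, `trials`.
#' @export
frequency_records_to_table <- function(records) {
  if (!length(records)) {
    return(data.frame(theta_max = numeric(0), mode = character(0),
                      n_solutions = integer(0), count = integer(0),
                      frequency = numeric(0), trials = integer(0)))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(theta_max = r$theta_max, mode = r$mode, n_solutions = 0:4,
               count = as.integer(r$counts), frequency = r$frequencies,
               trials = r$trials, row.names = NULL)
  }))
}

#' @rdname frequency_records_to_table
#' @param table A data frame as produced by `frequency_records_to_table()`.
#' @export
frequency_table_to_records <- function(table) {
  if (!nrow(table)) return(list())
  keys <- unique(table[c("theta_max", "mode")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$theta_max == keys$theta_max[i] &
                   table$mode == keys$mode[i], ]
    sub <- sub[order(sub$n_solutions), ]
    counts <- as.integer(sub$count)
    names(counts) <- as.character(0:4)
    structure(list(theta_max = keys$theta_max[i], mode = keys$mode[i],
                   trials = sub$trials[1], counts = counts,
                   frequencies = counts / sub$trials[1]),
              class = "frequency_record")
  })
}
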