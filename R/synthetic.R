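#' Specification for a synthetic descriptor matrix
#'
#' Describes a compounds-by-descriptors matrix with a planted sparse linear
#' retention signal: descriptors are standard normal (optionally sharing a
#' within-block correlation), and the response is a linear combination of a
#' few informative descriptors plus Gaussian noise. The default shape is
#' 26 compounds by 200 descriptors -- the library size of a typical
#' biomimetic-chromatography campaign, with the descriptor count kept small
#' enough that exhaustive-search oracles remain feasible.
#'
#' @param n_compounds number of rows.
#' @param n_descriptors number of columns.
#' @param informative named numeric vector: true coefficients, names are
#'   descriptor indices (as integers or \code{"d<i>"} names).
#' @param intercept response intercept.
#' @param noise_sd response noise standard deviation (>= 0).
#' @param descriptor_correlation within-block correlation in [0, 1).
#' @param seed integer seed.
#' @return A list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_compounds = 26, n_descriptors = 200,
                           informative = c(`3` = 4, `7` = -2),
                           intercept = 0, noise_sd = 0.5,
                           descriptor_correlation = 0, seed = 1) {
  idx <- as.integer(gsub("^d", "", names(informative)))
  stopifnot(all(is.finite(informative)), all(idx >= 1),
            all(idx <= n_descriptors), noise_sd >= 0,
            descriptor_correlation >= 0, descriptor_correlation < 1)
  structure(list(n_compounds = n_compounds, n_descriptors = n_descriptors,
                 informative = stats::setNames(as.numeric(informative), idx),
                 intercept = intercept, noise_sd = noise_sd,
                 descriptor_correlation = descriptor_correlation,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a descriptor matrix with a planted linear signal
#'
#' Draws the descriptor matrix and response described by a
#' [synthetic_spec()]. With \code{descriptor_correlation = rho > 0} every
#' descriptor shares a latent factor, giving pairwise correlation rho in
#' expectation. Pure function of the spec (including its seed).
#'
#' @param spec a [synthetic_spec()].
#' @return List with \code{matrix} (named columns \code{d1..dD}),
#'   \code{response}, and \code{truth} (the informative indices and
#'   coefficients, the intercept and the noise level).
#' @export
gen_descriptor_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds; d <- spec$n_descriptors
  rho <- spec$descriptor_correlation
  Z <- matrix(stats::rnorm(n * d), n, d)
  if (rho > 0) {
    f <- stats::rnorm(n)
    Z <- sqrt(rho) * f + sqrt(1 - rho) * Z
  }
  colnames(Z) <- paste0("d", seq_len(d))
  idx <- as.integer(names(spec$informative))
  signal <- drop(Z[, idx, drop = FALSE] %*% spec$informative)
  y <- spec$intercept + signal + stats::rnorm(n, sd = spec$noise_sd)
  list(matrix = Z, response = y,
       truth = list(informative = stats::setNames(spec$informative,
                                                  paste0("d", idx)),
                    intercept = spec$intercept, noise_sd = spec$noise_sd))
}

#' Generate a noisy calibration run
#'
#' Emulates a fast-gradient calibration mixture: \code{n_standards}
#' retention times spread uniformly over \code{rt_range}, with literature
#' index values on a known line plus Gaussian noise.
#'
#' @param slope,intercept the true calibration line (index units per
#'   minute; index units).
#' @param n_standards number of standards, >= 2.
#' @param rt_range retention-time window in minutes (positive width).
#' @param noise_sd index-unit noise standard deviation.
#' @param seed integer seed.
#' @return Data frame with columns \code{id}, \code{rt_min},
#'   \code{literature_index}.
#' @export
gen_calibration_run <- function(slope, intercept, n_standards = 10,
                                rt_range = c(0.5, 5.5), noise_sd = 0,
                                seed = 1) {
  stopifnot(n_standards >= 2, length(rt_range) == 2)
  if (diff(rt_range) <= 0)
    stop("degenerate design: rt_range must have positive width")
  set.seed(seed)
  rt <- sort(stats::runif(n_standards, rt_range[1], rt_range[2]))
  data.frame(id = paste0("std", seq_len(n_standards)),
             rt_min = rt,
             literature_index = slope * rt + intercept +
               stats::rnorm(n_standards, sd = noise_sd))
}

#' Generate an index table with correlated column groups
#'
#' Emulates a set of lipophilicity scales that fall into families: columns
#' within a group share a latent factor so that their pairwise correlation
#' is \code{within_r} in expectation; groups are independent. Useful for
#' testing whether clustering recovers a planted two-family structure.
#'
#' @param n_compounds number of rows.
#' @param column_groups list of \code{c(n_columns, within_r)} pairs with
#'   \code{within_r} in [0, 1).
#' @param seed integer seed.
#' @return Data frame with columns \code{g<k>_c<j>} plus attribute
#'   \code{"groups"} giving the planted group of each column.
#' @export
gen_index_table <- function(n_compounds = 26,
                            column_groups = list(c(10, 0.9), c(4, 0.9)),
                            seed = 1) {
  set.seed(seed)
  cols <- list(); groups <- integer(0)
  for (k in seq_along(column_groups)) {
    nc <- column_groups[[k]][1]; r <- column_groups[[k]][2]
    stopifnot(r >= 0, r < 1, nc >= 1)
    f <- stats::rnorm(n_compounds)
    for (j in seq_len(nc)) {
      cols[[paste0("g", k, "_c", j)]] <-
        sqrt(r) * f + sqrt(1 - r) * stats::rnorm(n_compounds)
      groups <- c(groups, k)
    }
  }
  out <- as.data.frame(cols)
  attr(out, "groups") <- stats::setNames(groups, names(cols))
  out
}
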