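#' Monte Carlo stability analysis of the ordination
#'
#' Re-runs the anchored ordination repeatedly with random noise added to
#' every real-entity score (references and anchors are never perturbed),
#' and compares the per-entity median Monte Carlo index against the
#' deterministic MDS index.  Small differences indicate a stable
#' ordination: differences under 5 index points are conventionally taken
#' as sufficient, under 1 point as tolerable error.
#'
#' @param scores score matrix as for \code{\link{rapbeef}}.
#' @param dimension dimension to analyse.
#' @param reps number of Monte Carlo replicates (default 25).
#' @param noise noise half-width (uniform) or standard deviation
#'   (gaussian) in score units; default 0.25, half a scale step.
#' @param noise_dist "uniform" (on \code{[-noise, +noise]}) or
#'   "gaussian" (sd = \code{noise}); perturbed scores are clipped to
#'   \code{[1, 6]}.
#' @param attributes optional attribute-to-dimension map.
#' @param config a \code{\link{rapbeef_config}}; its seed drives the
#'   noise streams (one derived seed per replicate).
#' @return Object of class \code{rapbeef_mc}: list with \code{mds_index},
#'   \code{mc_index} (per-entity median over replicates), \code{diff}
#'   (absolute difference), \code{sufficient} (diff < 5) and
#'   \code{tolerable} (diff < 1) flags, the replicate index matrix
#'   \code{reps_index}, and the run parameters.
#' @export
monte_carlo <- function(scores, dimension = "multi", reps = 25L,
                        noise = 0.25, noise_dist = c("uniform", "gaussian"),
                        attributes = NULL, config = rapbeef_config()) {
  noise_dist <- match.arg(noise_dist)
  stopifnot(reps >= 1L, noise >= 0)
  sel <- select_dimension(as.matrix(scores), dimension, attributes)
  base <- rapbeef(sel, dimension = "multi", config = config)
  n <- nrow(sel)
  p <- ncol(sel)
  reps_index <- matrix(NA_real_, reps, n,
                       dimnames = list(NULL, rownames(sel)))
  for (r in seq_len(reps)) {
    eps <- with_seed(derive_seed(config$seed, 1000 + r), {
      if (noise_dist == "uniform") {
        stats::runif(n * p, -noise, noise)
      } else {
        stats::rnorm(n * p, sd = noise)
      }
    })
    pert <- pmin(pmax(sel + matrix(eps, n, p), 1), 6)
    reps_index[r, ] <- rapbeef(pert, dimension = "multi",
                               config = config)$index
  }
  mc_index <- apply(reps_index, 2, stats::median)
  diff <- abs(base$index - mc_index)
  structure(
    list(dimension = dimension,
         reps = as.integer(reps),
         noise = noise,
         noise_dist = noise_dist,
         seed = config$seed,
         mds_index = base$index,
         mc_index = mc_index,
         diff = diff,
         sufficient = diff < 5,
         tolerable = diff < 1,
         reps_index = reps_index),
    class = "rapbeef_mc"
  )
}

#' @export
print.rapbeef_mc <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo ordination stability (dimension '%s', %d reps, %s noise %.2f)\n",
    x$dimension, x$reps, x$noise_dist, x$noise))
  df <- data.frame(MDS = round(x$mds_index, 2),
                   MonteCarlo = round(x$mc_index, 2),
                   diff = round(x$diff, 2),
                   sufficient = x$sufficient,
                   tolerable = x$tolerable)
  print(df)
  invisible(x)
}
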