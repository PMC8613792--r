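#' Attribute leverage (RMS) analysis
#'
#' Quantifies how much each attribute drives the sustainability index by
#' re-running the anchored ordination without it and summarising the
#' per-entity index change as a root mean square:
#' \deqn{RMS_j = \sqrt{\mathrm{mean}_e (index_{-j}(e) - index(e))^2}}
#' computed over the real entities only (references and anchors are
#' excluded).  The higher the RMS, the greater the attribute's effect on
#' the sustainability level.  Both the full and the drop-one ordinations
#' use the identical configuration and seed.
#'
#' @param scores score matrix as for \code{\link{rapbeef}}.
#' @param dimension dimension to analyse (needs at least 3 attributes so
#'   each drop leaves a valid ordination).
#' @param attributes optional attribute-to-dimension map, see
#'   \code{\link{rapbeef}}.
#' @param config a \code{\link{rapbeef_config}}.
#' @param replicates if > 1, the RMS is averaged over this many seeds
#'   (derived from \code{config$seed}); default 1 (deterministic
#'   recomputation at the configured seed).
#' @return Object of class \code{rapbeef_leverage}: data frame with
#'   columns \code{attribute}, \code{RMS} and \code{rank}, sorted by
#'   decreasing RMS (ties broken by attribute id), plus the full-fit
#'   indices as attribute \code{index_full}.
#' @export
leverage <- function(scores, dimension = "multi", attributes = NULL,
                     config = rapbeef_config(), replicates = 1L) {
  sel <- select_dimension(as.matrix(scores), dimension, attributes)
  if (ncol(sel) < 3L) {
    stop("leverage analysis for dimension '", dimension,
         "' needs at least 3 attributes, got ", ncol(sel))
  }
  seeds <- if (replicates > 1L) {
    vapply(seq_len(replicates), function(r) derive_seed(config$seed, 100 + r),
           integer(1))
  } else {
    config$seed
  }
  rms_mat <- matrix(NA_real_, length(seeds), ncol(sel),
                    dimnames = list(NULL, colnames(sel)))
  index_full <- NULL
  for (s in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- seeds[s]
    full <- rapbeef(sel, dimension = "multi", config = cfg)
    if (s == 1L) index_full <- full$index
    for (j in seq_len(ncol(sel))) {
      drop_fit <- rapbeef(sel[, -j, drop = FALSE], dimension = "multi",
                          config = cfg)
      rms_mat[s, j] <- sqrt(mean((drop_fit$index - full$index)^2))
    }
  }
  rms <- colMeans(rms_mat)
  ord <- order(-rms, names(rms))
  out <- data.frame(attribute = names(rms)[ord],
                    RMS = unname(rms[ord]),
                    rank = seq_along(rms),
                    stringsAsFactors = FALSE)
  attr(out, "dimension") <- dimension
  attr(out, "index_full") <- index_full
  class(out) <- c("rapbeef_leverage", "data.frame")
  out
}

#' @export
print.rapbeef_leverage <- function(x, ...) {
  cat(sprintf("Attribute leverage (RMS of index change, dimension '%s')\n",
              attr(x, "dimension")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
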