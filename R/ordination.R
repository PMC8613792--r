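#' Ordination configuration
#'
#' Collects the tunable parameters of the anchored MDS ordination.  A
#' single integer seed drives every stochastic component (random restart
#' configurations, Monte Carlo noise streams) through deterministic
#' counter-based derived seeds, so whole runs are reproducible from one
#' number.
#'
#' @param n_anchor_pairs number of synthetic anchor pairs (complementary
#'   half-good/half-bad profiles) added beside the good/bad references to
#'   stabilise the second ordination axis.  Default 2.
#' @param max_iter maximum majorization iterations per restart.
#' @param tolerance relative stress-decrease threshold stopping the
#'   majorization.
#' @param n_restarts number of starting configurations per ordination:
#'   one classical-scaling start plus \code{n_restarts - 1} seeded random
#'   starts.
#' @param seed integer master seed.
#' @param stress_formula which badness-of-fit is reported as \code{S}:
#'   \code{"stress1"} (Kruskal stress-1, the default) or
#'   \code{"sstress"} (on squared distances, the ALSCAL tradition).
#'   Both are always computed; see the methods vignette for why the
#'   Kruskal form is the reported one.
#' @return A list of class \code{rapbeef_config}.
#' @export
rapbeef_config <- function(n_anchor_pairs = 2L, max_iter = 500L,
                           tolerance = 1e-10, n_restarts = 3L,
                           seed = 20210923L,
                           stress_formula = c("stress1", "sstress")) {
  stopifnot(n_anchor_pairs >= 0L, max_iter >= 1L, tolerance > 0,
            n_restarts >= 1L, is.numeric(seed), length(seed) == 1L)
  structure(
    list(n_anchor_pairs = as.integer(n_anchor_pairs),
         max_iter = as.integer(max_iter),
         tolerance = tolerance,
         n_restarts = as.integer(n_restarts),
         seed = as.integer(seed),
         stress_formula = match.arg(stress_formula)),
    class = "rapbeef_config"
  )
}

# Evaluate `expr` under a derived seed without disturbing the caller's RNG
# stream.  Derived seeds stay below 2^31 - 1.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 16807) %% 2147483629)
}

#' Augment a score matrix with good/bad references and anchors
#'
#' Appends the reference profiles that anchor the ordination: a GOOD row
#' (every attribute at its best score, 6), a BAD row (every attribute at
#' 1) and \code{n_anchor_pairs} pairs of complementary half-good/half-bad
#' profiles.  Anchor patterns are deterministic functions of the
#' attribute set: the first pair splits the attributes in half (first
#' half best / rest worst, and the complement); further pairs alternate
#' attributes with a shifting phase.  Patterns are assigned in sorted
#' attribute-name order, so reordering columns never changes the
#' geometry.  Anchors stabilise the second MDS axis but are never
#' counted as entities in indices or leverage.
#'
#' @param scores numeric matrix of scores in \code{[1, 6]}, one row per
#'   real entity, named columns.
#' @param config a \code{\link{rapbeef_config}}.
#' @return Numeric matrix with the entity rows followed by the reference
#'   rows, plus attribute \code{reference} (logical row flags).
#' @export
build_reference_set <- function(scores, config = rapbeef_config()) {
  scores <- as.matrix(scores)
  p <- ncol(scores)
  if (p < 2L) stop("at least 2 attributes are required for ordination")
  if (any(scores < 1 | scores > 6)) stop("scores must lie in [1, 6]")
  refs <- matrix(0, 0, p)
  rn <- character(0)
  refs <- rbind(refs, rep(6, p), rep(1, p))
  rn <- c("GOOD", "BAD")
  if (config$n_anchor_pairs >= 1L) {
    # position of each column in sorted-name order (stable for unnamed)
    pos <- if (is.null(colnames(scores))) seq_len(p) else
      rank(colnames(scores), ties.method = "first")
    for (k in seq_len(config$n_anchor_pairs)) {
      best <- if (k == 1L) {
        pos <= ceiling(p / 2)
      } else {
        (pos + k) %% 2L == 0L
      }
      pat <- ifelse(best, 6, 1)
      refs <- rbind(refs, pat, 7 - pat)
      rn <- c(rn, sprintf("ANCHOR%d%s", k, c("a", "b")))
    }
  }
  rownames(refs) <- rn
  colnames(refs) <- colnames(scores)
  out <- rbind(scores, refs)
  attr(out, "reference") <- c(rep(FALSE, nrow(scores)), rep(TRUE, nrow(refs)))
  out
}

#' Linearly rescale 1-6 scores to a 0-100 axis
#'
#' Maps the worst score (1) to 0 and the best (6) to 100 on every
#' attribute, so Euclidean distances weight all attributes equally.
#' Fractional scores (e.g. Monte Carlo perturbed) map linearly.
#'
#' @param rows numeric matrix of scores in \code{[1, 6]}.
#' @return Matrix of the same shape on the 0-100 scale.
#' @export
normalize_scores <- function(rows) {
  rows <- as.matrix(rows)
  if (any(rows < 1 | rows > 6)) stop("scores must lie in [1, 6]")
  (rows - 1) / 5 * 100
}

stress_raw <- function(d_obs, d_fit) sum((d_obs - d_fit)^2)

stress_1 <- function(d_obs, d_fit) {
  sqrt(sum((d_obs - d_fit)^2) / sum(d_obs^2))
}

s_stress <- function(d_obs, d_fit) {
  sqrt(sum((d_fit^2 - d_obs^2)^2) / sum(d_obs^4))
}

# One SMACOF majorization run from a fixed starting configuration.
# Guttman transform; raw stress is non-increasing at every step.
smacof_run <- function(delta, x0, max_iter, tolerance) {
  n <- nrow(x0)
  x <- x0
  d <- as.matrix(stats::dist(x))
  sig <- stress_raw(delta, d)
  trace <- sig
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    b <- matrix(0, n, n)
    pos <- d > 0
    b[pos] <- -delta[pos] / d[pos]
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x_new <- b %*% x / n
    d_new <- as.matrix(stats::dist(x_new))
    sig_new <- stress_raw(delta, d_new)
    trace <- c(trace, sig_new)
    drop <- sig - sig_new
    x <- x_new
    d <- d_new
    sig <- sig_new
    if (sig < 1e-24 || (drop >= 0 && drop <= tolerance * max(sig, 1e-24))) {
      converged <- TRUE
      break
    }
  }
  list(coords = x, dist = d, raw = sig, trace = trace, converged = converged)
}

#' Two-dimensional metric MDS of a dissimilarity matrix
#'
#' Embeds a symmetric dissimilarity matrix in the plane by iterative
#' stress majorization (the Guttman transform), which guarantees a
#' non-increasing raw-stress trace.  The best of \code{n_restarts}
#' configurations is returned: one start from classical scaling
#' (Torgerson double-centering) and the rest from seeded random
#' configurations.
#'
#' @param distances symmetric, zero-diagonal, non-negative matrix (or a
#'   \code{\link[stats]{dist}} object).
#' @param config a \code{\link{rapbeef_config}}.
#' @return List with \code{coords} (n x 2), \code{stress1},
#'   \code{sstress}, \code{S} (the one named by
#'   \code{config$stress_formula}), \code{R2} (squared Pearson correlation
#'   of fitted and observed distances), \code{converged} and
#'   \code{trace} (raw-stress trace of the winning restart).
#' @export
mds_ordinate <- function(distances, config = rapbeef_config()) {
  delta <- as.matrix(distances)
  n <- nrow(delta)
  if (!isSymmetric(unname(delta), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(delta < 0) || any(abs(diag(delta)) > 1e-12)) {
    stop("distances must be non-negative with a zero diagonal")
  }
  if (n < 2L) stop("need at least 2 points")
  starts <- vector("list", config$n_restarts)
  cs <- suppressWarnings(stats::cmdscale(delta, k = min(2L, n - 1L)))
  if (ncol(cs) < 2L) cs <- cbind(cs, 0)
  starts[[1L]] <- cs
  if (config$n_restarts > 1L) {
    for (r in 2:config$n_restarts) {
      starts[[r]] <- with_seed(derive_seed(config$seed, r),
                               matrix(stats::rnorm(n * 2, sd = stats::sd(delta) + 1),
                                      n, 2))
    }
  }
  best <- NULL
  for (r in seq_along(starts)) {
    run <- smacof_run(delta, starts[[r]], config$max_iter, config$tolerance)
    if (is.null(best) || run$raw < best$raw) best <- run
  }
  low <- lower.tri(delta)
  d_fit <- best$dist
  # R2 degenerates to a perfect fit when there is at most one pair or no
  # spread in either distance set
  r2 <- if (sum(low) < 2 || stats::sd(delta[low]) == 0 ||
            stats::sd(d_fit[low]) == 0) {
    1
  } else {
    stats::cor(delta[low], d_fit[low])^2
  }
  s1 <- stress_1(delta[low], d_fit[low])
  ss <- s_stress(delta[low], d_fit[low])
  rownames(best$coords) <- rownames(delta)
  list(coords = best$coords,
       stress1 = s1,
       sstress = ss,
       S = if (config$stress_formula == "sstress") ss else s1,
       R2 = r2,
       converged = best$converged,
       trace = best$trace)
}

#' Rotate an ordination so the bad-good line is the index axis
#'
#' Applies the rigid motion (rotation about the good/bad midpoint plus
#' translation of that midpoint to the origin) that places BAD and GOOD
#' on the horizontal axis with GOOD at the larger x.  Distances are
#' unchanged.
#'
#' @param coords n x 2 coordinate matrix.
#' @param good,bad row indices (or names) of the GOOD and BAD reference
#'   points.
#' @return Rotated coordinate matrix.
#' @export
align_axes <- function(coords, good = "GOOD", bad = "BAD") {
  coords <- as.matrix(coords)
  g <- coords[good, , drop = TRUE]
  b <- coords[bad, , drop = TRUE]
  v <- g - b
  len <- sqrt(sum(v^2))
  if (len < 1e-10) stop("degenerate configuration: GOOD and BAD coincide")
  centre <- (g + b) / 2
  u <- v / len
  rot <- rbind(c(u[1], u[2]), c(-u[2], u[1]))  # maps u onto (1, 0)
  out <- sweep(coords, 2, centre) %*% t(rot)
  dimnames(out) <- dimnames(coords)
  out
}

#' Project aligned coordinates onto the 0-100 sustainability index
#'
#' The index of a row is its position along the horizontal (bad-good)
#' axis, linearly rescaled so BAD scores 0 and GOOD scores 100, and
#' clipped to \code{[0, 100]} for rows ordinating slightly beyond the
#' anchors.
#'
#' @param coords aligned coordinate matrix (see \code{\link{align_axes}}).
#' @param good,bad row names of the reference points.
#' @return Named numeric vector of indices for every row.
#' @export
sustainability_index <- function(coords, good = "GOOD", bad = "BAD") {
  x <- coords[, 1]
  xg <- coords[good, 1]
  xb <- coords[bad, 1]
  idx <- 100 * (x - xb) / (xg - xb)
  pmin(pmax(idx, 0), 100)
}

#' Anchored MDS ordination of a sustainability score matrix
#'
#' The central fitting function of the rapid-appraisal pipeline.  The
#' selected attribute columns are augmented with good/bad reference
#' profiles and anchors, rescaled to a common 0-100 axis, converted to
#' Euclidean distances and embedded in the plane by metric MDS; the
#' configuration is rotated so the bad-to-good direction is horizontal
#' and every entity is projected onto the 0-100 sustainability index.
#'
#' @param scores numeric matrix of 1-6 scores; rows are entities (named),
#'   columns are attributes (named).  Matrices from
#'   \code{\link{score_entities}} carry their definitions and need no
#'   \code{attributes} argument.
#' @param dimension which attributes to ordinate: "economic", "social",
#'   "environmental" or "multi" (all attributes jointly).  Default
#'   "multi".
#' @param attributes optional data frame with columns \code{id} and
#'   \code{dimension} mapping score columns to dimensions; defaults to
#'   the definitions attached to \code{scores}, or to all columns for
#'   \code{dimension = "multi"}.
#' @param config a \code{\link{rapbeef_config}}.
#' @return An object of class \code{rapbeef}: list with
#'   \code{index} (per-entity 0-100 index), \code{band} (status band per
#'   entity), \code{coordinates} (aligned, entities + references),
#'   \code{S}, \code{stress1}, \code{sstress}, \code{R2},
#'   \code{dimension}, \code{entities}, \code{reference} flags,
#'   \code{distances}, \code{converged} and the \code{config}.
#' @examples
#' fix <- load_fixture("region_evaluation")
#' m <- fix$scores[fix$level == "farm", , drop = FALSE]
#' @export
rapbeef <- function(scores, dimension = "multi", attributes = NULL,
                    config = rapbeef_config()) {
  scores <- select_dimension(scores, dimension, attributes)
  if (nrow(scores) < 1L) stop("no entities to ordinate")
  aug <- build_reference_set(scores, config)
  is_ref <- attr(aug, "reference")
  norm <- normalize_scores(aug)
  delta <- as.matrix(stats::dist(norm))
  fit <- mds_ordinate(delta, config)
  coords <- align_axes(fit$coords)
  idx_all <- sustainability_index(coords)
  entities <- rownames(scores)
  idx <- idx_all[entities]
  structure(
    list(index = idx,
         band = classify_status(idx),
         index_all = idx_all,
         coordinates = coords,
         S = fit$S,
         stress1 = fit$stress1,
         sstress = fit$sstress,
         R2 = fit$R2,
         dimension = dimension,
         entities = entities,
         reference = is_ref,
         scores = scores,
         distances = delta,
         converged = fit$converged,
         trace = fit$trace,
         config = config,
         call = match.call()),
    class = "rapbeef"
  )
}

# Resolve the attribute subset for one ordinated dimension.
select_dimension <- function(scores, dimension, attributes = NULL) {
  scores <- as.matrix(scores)
  dimension <- match.arg(dimension,
                         c("multi", "economic", "social", "environmental"))
  if (dimension == "multi") return(scores)
  if (is.null(attributes)) {
    defs <- attr(scores, "definitions")
    if (!is.null(defs)) {
      attributes <- data.frame(
        id = names(defs),
        dimension = vapply(defs, `[[`, character(1), "dimension"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(attributes)) {
    stop("dimension filtering needs an 'attributes' map ",
         "(columns id, dimension) or a score matrix from score_entities()")
  }
  keep <- attributes$id[attributes$dimension == dimension]
  keep <- intersect(colnames(scores), keep)
  if (length(keep) < 2L) {
    stop("dimension '", dimension, "' selects fewer than 2 attributes")
  }
  scores[, keep, drop = FALSE]
}

#' @export
print.rapbeef <- function(x, ...) {
  cat("Anchored MDS sustainability ordination\n")
  cat(sprintf("dimension: %s   attributes: %d   entities: %d\n",
              x$dimension, ncol(x$scores), length(x$entities)))
  cat(sprintf("S (%s) = %.4f   stress-1 = %.4f   R2 = %.4f%s\n",
              x$config$stress_formula, x$S, x$stress1, x$R2,
              if (x$converged) "" else "   [not converged]"))
  df <- data.frame(index = round(x$index, 2), status = as.character(x$band))
  print(df)
  invisible(x)
}

#' @export
summary.rapbeef <- function(object, ...) {
  out <- list(
    dimension = object$dimension,
    n_entities = length(object$entities),
    n_attributes = ncol(object$scores),
    index = object$index,
    band = object$band,
    S = object$S,
    stress1 = object$stress1,
    sstress = object$sstress,
    R2 = object$R2,
    fit_acceptable = object$S < 0.25,
    converged = object$converged
  )
  class(out) <- "summary.rapbeef"
  out
}

#' @export
print.summary.rapbeef <- function(x, ...) {
  cat(sprintf("Ordination of %d entities on %d '%s' attributes\n",
              x$n_entities, x$n_attributes, x$dimension))
  cat(sprintf("goodness of fit: S = %.4f (%s), R2 = %.4f\n",
              x$S, if (x$fit_acceptable) "acceptable, < 0.25" else ">= 0.25",
              x$R2))
  df <- data.frame(index = round(x$index, 2), status = as.character(x$band))
  print(df)
  invisible(x)
}

#' @export
coef.rapbeef <- function(object, ...) object$index

#' Residuals of the distance fit
#'
#' Differences between the configuration distances and the input
#' dissimilarities over all row pairs, the quantity whose sum of squares
#' the majorization minimises.
#'
#' @param object a \code{rapbeef} fit.
#' @param ... unused.
#' @return Numeric vector (lower-triangle pairs).
#' @export
residuals.rapbeef <- function(object, ...) {
  d_fit <- as.matrix(stats::dist(object$coordinates))
  low <- lower.tri(d_fit)
  d_fit[low] - object$distances[low]
}

#' Plot an anchored ordination
#'
#' Draws the aligned two-dimensional configuration: entities as filled
#' points, the GOOD/BAD references and anchors as open symbols, with the
#' horizontal axis carrying the 0-100 sustainability index.
#'
#' @param x a \code{rapbeef} fit.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.rapbeef <- function(x, ...) {
  co <- x$coordinates
  ref <- x$reference
  graphics::plot(co, type = "n", xlab = "bad - good axis", ylab = "axis 2",
                 main = sprintf("Anchored ordination (%s)", x$dimension), ...)
  graphics::points(co[ref, , drop = FALSE], pch = 1, col = "grey40")
  graphics::points(co[!ref, , drop = FALSE], pch = 19)
  graphics::text(co, labels = rownames(co), pos = 3, cex = 0.7)
  invisible(x)
}
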