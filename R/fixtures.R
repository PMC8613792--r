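#' Load a packaged fixture
#'
#' The package ships three small plain-text fixtures used throughout the
#' examples and tests:
#' \describe{
#'   \item{\code{"indicators"}}{the 20 indicator definitions with their
#'     six-bin scales (same content as
#'     \code{\link{indicator_definitions}}).}
#'   \item{\code{"region_evaluation"}}{the published performance
#'     evaluation of the three Central Java regencies (Semarang, Boyolali,
#'     Sragen): the actual value of every indicator as printed (mixed
#'     decimal-comma and decimal-point styles, parsed locale-correctly),
#'     the printed 1-6 score, and a \code{consistent} flag marking cells
#'     whose printed score agrees with the bin scales.  Returned with
#'     ready-made farm and slaughterhouse score matrices.}
#'   \item{\code{"delphi_round2"}}{the second-round Delphi rating matrix:
#'     3 experts rating 13 candidate policies on a 1-5 priority scale.}
#' }
#'
#' @param name one of \code{"indicators"}, \code{"region_evaluation"},
#'   \code{"delphi_round2"}.
#' @return See Description; \code{region_evaluation} is a list with
#'   elements \code{values} (long data frame with parsed \code{value}),
#'   \code{farm_scores} and \code{slaughterhouse_scores} (entity x
#'   indicator integer matrices of the printed scores, carrying their
#'   indicator definitions).
#' @export
load_fixture <- function(name) {
  available <- c("indicators", "region_evaluation", "delphi_round2")
  if (length(name) != 1L || !name %in% available) {
    stop("unknown fixture '", name, "'; available: ",
         paste(available, collapse = ", "))
  }
  ext <- function(f) system.file("extdata", f, package = "rapbeef",
                                 mustWork = TRUE)
  switch(name,
    indicators = read_indicator_definitions(ext("indicators.json")),
    delphi_round2 = {
      df <- utils::read.csv(ext("delphi_round2.csv"), check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      storage.mode(m) <- "integer"
      rownames(m) <- df[[1]]
      m
    },
    region_evaluation = {
      df <- utils::read.csv(ext("region_evaluation.csv"),
                            stringsAsFactors = FALSE)
      df$value <- parse_number(df$value_raw, df$locale)
      df$printed_score <- as.integer(df$printed_score)
      defs <- indicator_definitions()
      score_mat <- function(level) {
        sub <- df[df$level == level, ]
        ids <- unique(sub$indicator)
        ents <- unique(sub$entity)
        m <- matrix(NA_integer_, length(ents), length(ids),
                    dimnames = list(ents, ids))
        m[cbind(sub$entity, sub$indicator)] <- sub$printed_score
        attr(m, "definitions") <- defs[ids]
        m
      }
      list(values = df,
           farm_scores = score_mat("farm"),
           slaughterhouse_scores = score_mat("slaughterhouse"))
    }
  )
}

#' Generate a synthetic score matrix with known ground truth
#'
#' Emulates an appraisal score matrix in which each entity has a latent
#' sustainability level in \code{[0, 1]} and every attribute is an
#' independent noisy reading of it: the expected score is
#' \code{1 + 5 * latent}, observation noise is added, and the result is
#' rounded half-up and clipped to the 1-6 scale.  The latent vector is
#' returned so ordination output can be checked against the generating
#' ordering (parameter recovery).
#'
#' @param n_entities number of entities (>= 2).
#' @param n_attributes number of attributes; default 9.
#' @param latent optional numeric vector of latent levels in
#'   \code{[0, 1]}; by default drawn uniformly (reproducibly from
#'   \code{seed}).
#' @param sd standard deviation of the gaussian scoring noise in score
#'   units; default 0.5.
#' @param seed integer seed making the draw reproducible.
#' @return List with \code{scores} (integer matrix, entities x
#'   attributes, values in 1-6), \code{latent}, and the generator
#'   parameters.
#' @examples
#' syn <- generate_synthetic(10, seed = 42)
#' cor(rowMeans(syn$scores), syn$latent, method = "spearman")
#' @export
generate_synthetic <- function(n_entities, n_attributes = 9L, latent = NULL,
                               sd = 0.5, seed = 1L) {
  stopifnot(n_entities >= 2L, n_attributes >= 2L, sd >= 0)
  with_seed(seed, {
    if (is.null(latent)) latent <- stats::runif(n_entities)
    stopifnot(length(latent) == n_entities, all(latent >= 0 & latent <= 1))
    expected <- 1 + 5 * latent
    noise <- matrix(stats::rnorm(n_entities * n_attributes, sd = sd),
                    n_entities, n_attributes)
    m <- round_half_up(expected + noise)
    m <- pmin(pmax(m, 1), 6)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(sprintf("E%02d", seq_len(n_entities)),
                        sprintf("A%02d", seq_len(n_attributes)))
    list(scores = m, latent = latent, sd = sd, seed = seed)
  })
}
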