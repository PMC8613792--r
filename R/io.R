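#' Read a score matrix from CSV
#'
#' Expects a header of indicator ids, a first column of entity ids, and
#' integer scores 1-6 in the body.  Validation failures report the
#' offending (entity, indicator) cells.
#'
#' @param path CSV file path.
#' @return Integer score matrix (entities x indicators).
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("score file needs an entity column and >= 2 indicators")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  num <- suppressWarnings(apply(m, 2, as.numeric))
  num <- matrix(num, nrow(m), ncol(m), dimnames = dimnames(m))
  bad <- which(is.na(num) | num != round(num) | num < 1 | num > 6,
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid score cells (must be integers 1-6): ",
         paste(sprintf("(%s, %s)", rownames(m)[bad[, 1]],
                       colnames(m)[bad[, 2]]), collapse = ", "))
  }
  storage.mode(num) <- "integer"
  num
}

#' Read a raw indicator value matrix from CSV
#'
#' Same shape as \code{\link{read_scores}} but with real-valued cells,
#' optionally printed in decimal-comma style.
#'
#' @param path CSV file path.
#' @param locale decimal style of the file, "point" or "comma"; see
#'   \code{\link{parse_number}}.
#' @return Numeric matrix (entities x indicators).
#' @export
read_values <- function(path, locale = "point") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  num <- matrix(parse_number(m, locale), nrow(m), ncol(m),
                dimnames = dimnames(m))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("unparseable value cells: ",
         paste(sprintf("(%s, %s)", rownames(m)[bad[, 1]],
                       colnames(m)[bad[, 2]]), collapse = ", "))
  }
  num
}

#' Write an appraisal report
#'
#' Serialises a set of results (ordinations, leverage profiles, Monte
#' Carlo analyses, Delphi rounds) to a versioned JSON report, and writes
#' the per-entity per-dimension indices to a companion "kite" CSV (one
#' row per entity and dimension) ready for external kite-diagram
#' plotting.
#'
#' @param results named list whose elements are \code{rapbeef},
#'   \code{rapbeef_leverage}, \code{rapbeef_mc} or \code{delphi_round}
#'   objects.
#' @param path output JSON path; the kite CSV is written next to it with
#'   suffix \code{_kite.csv} (only if any ordination is present).
#' @return Invisibly, the report list that was serialised.
#' @export
write_report <- function(results, path) {
  if (!is.list(results) || length(results) == 0L) {
    stop("no results to report")
  }
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a fully named list")
  }
  report <- list(schema = "rapbeef-report/1",
                 package_version = as.character(utils::packageVersion("rapbeef")),
                 results = lapply(results, serialize_result))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  kite <- kite_rows(results)
  if (nrow(kite) > 0L) {
    utils::write.csv(kite, sub("\\.json$", "_kite.csv", path),
                     row.names = FALSE)
  }
  invisible(report)
}

serialize_result <- function(x) {
  if (inherits(x, "rapbeef")) {
    list(type = "ordination",
         dimension = x$dimension,
         seed = x$config$seed,
         index = as.list(x$index),
         band = as.list(stats::setNames(as.character(x$band),
                                        names(x$index))),
         S = x$S, stress1 = x$stress1, sstress = x$sstress, R2 = x$R2,
         converged = x$converged)
  } else if (inherits(x, "rapbeef_leverage")) {
    list(type = "leverage",
         dimension = attr(x, "dimension"),
         attribute = x$attribute, RMS = x$RMS, rank = x$rank)
  } else if (inherits(x, "rapbeef_mc")) {
    list(type = "monte_carlo",
         dimension = x$dimension, reps = x$reps, noise = x$noise,
         noise_dist = x$noise_dist, seed = x$seed,
         mds_index = as.list(x$mds_index),
         mc_index = as.list(x$mc_index),
         diff = as.list(x$diff),
         max_diff = max(x$diff),
         sufficient = all(x$sufficient),
         tolerable = all(x$tolerable))
  } else if (inherits(x, "delphi_round")) {
    list(type = "delphi_round",
         means = as.list(x$means),
         ranking = x$ranking,
         below_cut = x$below_cut,
         W = if (is.null(x$kendall)) NA else x$kendall$W,
         chi2 = if (is.null(x$kendall)) NA else x$kendall$chi2,
         df = if (is.null(x$kendall)) NA else x$kendall$df,
         p = if (is.null(x$kendall)) NA else x$kendall$p,
         consensus = if (is.null(x$kendall)) "indeterminate"
                     else x$kendall$consensus,
         stop = x$stop)
  } else {
    stop("cannot serialise result of class ", paste(class(x), collapse = "/"))
  }
}

kite_rows <- function(results) {
  rows <- lapply(results, function(x) {
    if (!inherits(x, "rapbeef")) return(NULL)
    data.frame(entity = names(x$index),
               dimension = x$dimension,
               index = unname(x$index),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(entity = character(0), dimension = character(0),
                      index = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
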