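#' Mid-ranks of one rater's ratings
#'
#' Converts a vector of ratings into ranks where tied values share the
#' average of the rank positions they span, so ranks always sum to
#' \code{n(n+1)/2}.  This is the rank assignment required by the
#' tie-corrected Kendall concordance statistic.
#'
#' @param x numeric vector of ratings.
#' @return Numeric vector of mid-ranks.
#' @examples
#' rank_with_ties(c(3, 4, 4, 5))  # 1, 2.5, 2.5, 4
#' @export
rank_with_ties <- function(x) {
  if (length(x) == 0L) stop("empty rating vector")
  rank(x, ties.method = "average")
}

#' Tie-corrected Kendall coefficient of concordance
#'
#' Measures agreement among \eqn{m} raters rating \eqn{n} items:
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum T_r}}
#' where \eqn{S} is the sum of squared deviations of the item rank sums
#' from their mean \eqn{m(n+1)/2}, and \eqn{T_r = \sum (t^3 - t)} over
#' the tie groups of rater \eqn{r}.  The associated chi-squared statistic
#' is \eqn{\chi^2 = m (n - 1) W} on \eqn{n - 1} degrees of freedom.
#'
#' @param ratings numeric matrix, raters in rows, items in columns;
#'   complete, at least 2 raters and 2 items.
#' @return Object of class \code{kendall_w}: list with \code{W},
#'   \code{S}, \code{tie_correction} (\eqn{\sum T_r}), \code{chi2},
#'   \code{df}, \code{p}, \code{m}, \code{n} and \code{consensus} (see
#'   \code{\link{consensus_level}}).  If every rater rates all items
#'   identically the denominator vanishes: \code{W} is \code{NA} and the
#'   consensus is flagged indeterminate.
#' @examples
#' r <- load_fixture("delphi_round2")
#' kendall_w(r)
#' @export
kendall_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  m <- nrow(ratings)
  n <- ncol(ratings)
  if (n < 2L) stop("need at least 2 items")
  if (m < 2L) stop("need at least 2 raters")
  if (anyNA(ratings)) stop("rating matrix must be complete")
  ranks <- t(apply(ratings, 1, rank_with_ties))
  r_i <- colSums(ranks)
  s <- sum((r_i - m * (n + 1) / 2)^2)
  tie <- sum(apply(ratings, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie
  if (denom <= 0) {
    w <- NA_real_
    chi2 <- NA_real_
    p <- NA_real_
    consensus <- "indeterminate"
  } else {
    w <- 12 * s / denom
    chi2 <- m * (n - 1) * w
    p <- stats::pchisq(chi2, df = n - 1, lower.tail = FALSE)
    consensus <- consensus_level(w)
  }
  structure(
    list(W = w, S = s, tie_correction = tie, chi2 = chi2, df = n - 1L,
         p = p, m = m, n = n, consensus = consensus),
    class = "kendall_w"
  )
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf("Kendall's W = %s  (%d raters, %d items, %s consensus)\n",
              format(x$W, digits = 4), x$m, x$n, x$consensus))
  cat(sprintf("chi-squared = %s, df = %d, p = %s\n",
              format(x$chi2, digits = 5), x$df, format(x$p, digits = 3)))
  invisible(x)
}

#' Chi-squared significance of a concordance coefficient
#'
#' For \eqn{m} raters and \eqn{n} items, \eqn{\chi^2 = m (n - 1) W} is
#' asymptotically chi-squared distributed on \eqn{n - 1} degrees of
#' freedom under the null of no agreement.
#'
#' @param W concordance coefficient in \code{[0, 1]}.
#' @param m number of raters (>= 2).
#' @param n number of items (>= 2).
#' @return List with \code{chi2}, \code{df} and \code{p}.
#' @examples
#' kendall_chi_square(0.795, m = 3, n = 15)
#' @export
kendall_chi_square <- function(W, m, n) {
  stopifnot(W >= 0, W <= 1, m >= 2, n >= 2)
  chi2 <- m * (n - 1) * W
  df <- n - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Consensus band of a concordance coefficient
#'
#' Bands the coefficient into the conventional Delphi consensus levels:
#' strong (\eqn{W > 0.7}), moderate (\eqn{0.5 \le W \le 0.7}), weak
#' (\eqn{W < 0.3}); the unlabelled range \eqn{[0.3, 0.5)} is reported
#' explicitly as indeterminate rather than silently extended into a
#' neighbouring band.
#'
#' @param W concordance coefficient in \code{[0, 1]} (NA allowed).
#' @return Character: "strong", "moderate", "weak" or "indeterminate".
#' @export
consensus_level <- function(W) {
  if (is.na(W)) return("indeterminate")
  stopifnot(W >= 0, W <= 1)
  if (W > 0.7) "strong"
  else if (W >= 0.5) "moderate"
  else if (W < 0.3) "weak"
  else "indeterminate"
}

# Round half away from zero, as in printed rating means (3.666... -> 3.7).
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarise one Delphi rating round
#'
#' Computes per-item mean ratings (rounded half-up to one decimal), the
#' descending priority ranking (ties in stable item-id order), the items
#' whose mean falls below the "essential" cut of 3, the concordance of
#' the round and the decision whether another round is needed.  With a
#' single rater the concordance is undefined and the stop decision is
#' flagged indeterminate (\code{NA}).
#'
#' @param ratings rating matrix, raters in rows, items in columns.
#' @param w_stop_threshold stop iterating once \eqn{W \ge} this value;
#'   default 0.5.
#' @return Object of class \code{delphi_round}: list with \code{means},
#'   \code{ranking}, \code{below_cut}, \code{kendall}
#'   (a \code{\link{kendall_w}} or NULL for one rater), \code{stop}
#'   (logical, NA if indeterminate) and \code{w_stop_threshold}.
#' @export
summarize_round <- function(ratings, w_stop_threshold = 0.5) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("rating matrix must be complete")
  raw_means <- colMeans(ratings)
  means <- round_half_up(raw_means, 1)
  names(means) <- colnames(ratings)
  ord <- order(-raw_means, colnames(ratings))
  ranking <- data.frame(item = colnames(ratings)[ord],
                        mean = means[ord],
                        rank = seq_along(ord),
                        stringsAsFactors = FALSE,
                        row.names = NULL)
  below <- colnames(ratings)[raw_means < 3]
  kw <- if (nrow(ratings) >= 2L) kendall_w(ratings) else NULL
  stop_now <- if (is.null(kw) || is.na(kw$W)) NA else kw$W >= w_stop_threshold
  structure(
    list(means = means, ranking = ranking, below_cut = below,
         kendall = kw, stop = stop_now,
         w_stop_threshold = w_stop_threshold),
    class = "delphi_round"
  )
}

#' @export
print.delphi_round <- function(x, ...) {
  cat("Delphi round summary\n")
  print(x$ranking, row.names = FALSE)
  if (length(x$below_cut)) {
    cat("items below the essential cut (mean < 3):",
        paste(x$below_cut, collapse = ", "), "\n")
  } else {
    cat("no item falls below the essential cut (mean < 3)\n")
  }
  if (!is.null(x$kendall)) print(x$kendall)
  cat(sprintf("stop after this round (W >= %.2f): %s\n",
              x$w_stop_threshold,
              if (is.na(x$stop)) "indeterminate" else x$stop))
  invisible(x)
}
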