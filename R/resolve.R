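#' Merging parameters
#'
#' The four user parameters of the merger, with the defaults used throughout:
#' context k-mer size `k = 17`, minimum overlap `omega = 10` bp, give-up
#' mismatch ratio `gamma = 0.5`, and quality-difference threshold
#' `delta = 19`. A mismatch whose quality scores differ by more than `delta`
#' is settled by qualities alone; otherwise the k-mer context vote decides.
#'
#' `quality_weighted_vote` switches on a variant in which each side's window
#' count is scaled by that side's base error probability
#' (`10^(-Q/10)`) before the per-window comparison. It is off by default; in
#' practice it changes very few decisions.
#'
#' @param k Context k-mer size, in `[1, 31]`.
#' @param omega Minimum overlap length (bp), `>= 1`.
#' @param gamma Give-up mismatch-ratio threshold in `[0, 1]`.
#' @param delta Quality-difference threshold, `>= 0`.
#' @param quality_weighted_vote Logical; see above.
#' @return An object of class `merge_params`.
#' @export
merge_params <- function(k = 17, omega = 10, gamma = 0.5, delta = 19,
                         quality_weighted_vote = FALSE) {
  k <- as.integer(k); omega <- as.integer(omega); delta <- as.integer(delta)
  stopifnot(k >= 1L, k <= 31L, omega >= 1L, gamma >= 0, gamma <= 1,
            delta >= 0L, is.logical(quality_weighted_vote))
  structure(list(k = k, omega = omega, gamma = gamma, delta = delta,
                 quality_weighted_vote = isTRUE(quality_weighted_vote)),
            class = "merge_params")
}

#' @export
print.merge_params <- function(x, ...) {
  cat(sprintf("merge_params: k = %d, omega = %d, gamma = %g, delta = %d, quality_weighted_vote = %s\n",
              x$k, x$omega, x$gamma, x$delta, x$quality_weighted_vote))
  invisible(x)
}

#' Quality-score pass over an accepted overlap
#'
#' First resolution pass. Scanning overlap positions left to right: matching
#' bases are untouched; when the forward base's quality exceeds the reverse
#' base's by more than `delta`, the forward base and its quality overwrite
#' the reverse base (and symmetrically). Differences of at most `delta` are
#' left for the context pass. If exactly one of the two bases is `N`, the
#' informative base overwrites it regardless of `delta`; two `N`s are
#' skipped.
#'
#' @param x,y Forward and (reverse-complemented) reverse sequences.
#' @param qx,qy Their Phred quality vectors.
#' @param b 1-based overlap start in `x`.
#' @param delta Quality-difference threshold.
#' @return A list with updated `x`, `qx`, `y`, `qy`.
#' @export
quality_pass <- function(x, qx, y, qy, b, delta = 19) {
  cpp_quality_pass(as_sequence(x), as.integer(qx), as_sequence(y),
                   as.integer(qy), as.integer(b), as.integer(delta))
}

#' Collect k-mer context votes for one unresolved mismatch
#'
#' For a mismatch at position `i` of `x` (`ip` of `y`), up to `k`
#' progressively shifted windows of length `k` covering the position are
#' compared between the two reads via their table counts. Window `j` spans
#' `x(i-k+j : i+j-1)` and `y(ip-k+j : ip+j-1)`. A window underrunning the
#' left boundary of either read is skipped; the scan stops at the first
#' window overrunning the right boundary of either read, or at the first
#' `j > 1` whose rightmost position is itself an uncorrected mismatch.
#' Windows containing `N` look up as count 0.
#'
#' @inheritParams quality_pass
#' @param i,ip 1-based mismatch positions in `x` and `y`.
#' @param table A [kmer_table()] built from the whole preprocessed input.
#' @param k Context window size (defaults to the table's `k`).
#' @param quality_weighted_vote Scale each side's count by its base error
#'   probability `10^(-Q/10)` before comparing.
#' @return A data frame with one row per evaluated window: `j`,
#'   `forward_count`, `reverse_count` and `vote`
#'   (`"forward"`, `"reverse"` or `"none"`).
#' @export
collect_context_votes <- function(x, y, i, ip, table, k = table$k,
                                  qx = NULL, qy = NULL,
                                  quality_weighted_vote = FALSE) {
  stopifnot(inherits(table, "kmer_table"))
  x <- as_sequence(x); y <- as_sequence(y)
  if (is.null(qx)) qx <- integer(nchar(x))
  if (is.null(qy)) qy <- integer(nchar(y))
  res <- cpp_collect_votes(x, as.integer(qx), y, as.integer(qy),
                           as.integer(i), as.integer(ip), table$ptr,
                           as.integer(k), isTRUE(quality_weighted_vote))
  data.frame(j = res$j,
             forward_count = res$forward_count,
             reverse_count = res$reverse_count,
             vote = c("reverse", "none", "forward")[res$vote + 2L],
             stringsAsFactors = FALSE)
}

#' Decide a mismatch from its context votes
#'
#' Majority vote: the forward base wins if and only if it collected strictly
#' more window votes than the reverse base. Ties -- including an empty vote
#' set -- go to the reverse read. This is the 0.5-thresholded linear opinion
#' pool over the per-window decisions.
#'
#' @param votes A data frame from [collect_context_votes()] (only the `vote`
#'   column is used), or a character vector of votes.
#' @return `"forward"` or `"reverse"`.
#' @export
decide_votes <- function(votes) {
  v <- if (is.data.frame(votes)) votes$vote else as.character(votes)
  if (sum(v == "forward") > sum(v == "reverse")) "forward" else "reverse"
}

#' Context pass over an accepted overlap
#'
#' Second resolution pass, run after [quality_pass()]. Remaining mismatches
#' are visited left to right; each is decided by
#' [collect_context_votes()] + [decide_votes()], and the winner's base and
#' quality overwrite the loser's in the other read, so that downstream
#' context windows see corrected bases. After this pass every overlap
#' position agrees between the two reads (or is `N` on both).
#'
#' @inheritParams quality_pass
#' @inheritParams collect_context_votes
#' @param params A [merge_params()] object supplying `k` and
#'   `quality_weighted_vote`.
#' @return A list with updated `x`, `qx`, `y`, `qy`.
#' @export
context_pass <- function(x, qx, y, qy, b, table, params = merge_params()) {
  stopifnot(inherits(table, "kmer_table"), inherits(params, "merge_params"))
  cpp_context_pass(as_sequence(x), as.integer(qx), as_sequence(y),
                   as.integer(qy), as.integer(b), table$ptr,
                   params$k, params$quality_weighted_vote)
}
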