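#' Count mismatches between a forward read and a shifted reverse read
#'
#' Position `j` of `x` (for `j >= b`) is compared with position `j - b + 1`
#' of `y` over the overlap of length `min(nchar(x) - b + 1, nchar(y))`.
#' Positions where either base is `N` are not comparable and do not count as
#' mismatches.
#'
#' @param x,y Sequences (character scalars or `seq_read`s); `y` must already
#'   be the reverse-complemented reverse mate.
#' @param b 1-based offset of the overlap start within `x`.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(x, y, b) {
  cpp_count_mismatches(as_sequence(x), as_sequence(y), as.integer(b))
}

as_sequence <- function(x) {
  if (inherits(x, "seq_read")) return(x$sequence)
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

overlap_statuses <- c("accepted", "abandoned_mismatch_ratio", "no_valid_offset")

#' Find the best overlap between a read pair
#'
#' Scans every candidate offset `b` in `[1, nchar(x) - omega + 1]` and keeps
#' the one with the lowest mismatch ratio (mismatches divided by overlap
#' length). The update is a strict improvement, so ties keep the smallest
#' `b`, i.e. the longest overlap. The returned status is `"accepted"`
#' pending the give-up check ([apply_giveup()]), or `"no_valid_offset"` when
#' no candidate of length at least `omega` exists.
#'
#' @inheritParams count_mismatches
#' @param omega Minimum overlap length in bp.
#' @return An `overlap_result` with fields `offset`, `overlap_length`,
#'   `mismatch_count`, `mismatch_ratio`, `status`.
#' @examples
#' find_best_overlap("AAAATTTT", "TTTTCCCC", omega = 4)  # offset 5, ratio 0
#' @export
find_best_overlap <- function(x, y, omega = 10) {
  res <- cpp_find_best_overlap(as_sequence(x), as_sequence(y),
                               as.integer(omega))
  out <- structure(list(
    offset = if (res$status == 2L) NA_integer_ else res$offset,
    overlap_length = if (res$status == 2L) NA_integer_ else res$overlap_length,
    mismatch_count = res$mismatch_count,
    mismatch_ratio = res$mismatch_ratio,
    status = overlap_statuses[res$status + 1L]), class = "overlap_result")
  out
}

#' Apply the give-up threshold to an overlap result
#'
#' The merge is abandoned when the best mismatch ratio strictly exceeds
#' `gamma`; a ratio exactly equal to `gamma` is still accepted.
#'
#' @param result An `overlap_result` from [find_best_overlap()].
#' @param gamma Give-up mismatch-ratio threshold in `[0, 1]`.
#' @return The result with `status` updated.
#' @export
apply_giveup <- function(result, gamma = 0.5) {
  stopifnot(inherits(result, "overlap_result"), gamma >= 0, gamma <= 1)
  if (result$status == "no_valid_offset") return(result)
  result$status <- if (result$mismatch_ratio > gamma)
    "abandoned_mismatch_ratio" else "accepted"
  result
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: offset %s, length %s, %d mismatches (ratio %.4g), %s\n",
              x$offset, x$overlap_length, x$mismatch_count,
              x$mismatch_ratio, x$status))
  invisible(x)
}
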