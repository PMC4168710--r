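#' Merge evaluation counts
#'
#' The accounting used to score a merging run against truth: `total` input
#' pairs, `merges` pairs that were merged, and `correct` merges whose
#' elongated read is identical (length and bases) to the true fragment.
#'
#' @param total,merges,correct Non-negative counts with
#'   `correct <= merges <= total`.
#' @return An object of class `eval_counts`.
#' @export
eval_counts <- function(total, merges, correct) {
  stopifnot(correct >= 0, correct <= merges, merges <= total)
  structure(list(total = total, merges = merges, correct = correct),
            class = "eval_counts")
}

#' Classify one merge outcome against its truth record
#'
#' @param outcome A `merge_outcome` from [merge_pair()].
#' @param truth One row of a truth table (needs `fragment_sequence`).
#' @return `"correct"`, `"incorrect"` or `"unmerged"`.
#' @export
classify_merge <- function(outcome, truth) {
  stopifnot(inherits(outcome, "merge_outcome"))
  if (is.null(truth) || !nrow(as.data.frame(truth)))
    stop("missing truth record for pair ", outcome$pair_id)
  if (outcome$status != "merged") return("unmerged")
  if (identical(outcome$merged$sequence, truth$fragment_sequence))
    "correct" else "incorrect"
}

#' Score a set of merge results against a truth table
#'
#' A merge is correct if and only if the merged sequence equals the true
#' fragment exactly.
#'
#' @param merged_seq Character vector of merged sequences (`NA` for
#'   unmerged pairs), aligned with `ids`.
#' @param ids Pair identifiers aligned with `merged_seq`.
#' @param truth Truth table with columns `pair_id` and `fragment_sequence`.
#' @return An [eval_counts()].
#' @export
score_merges <- function(merged_seq, ids, truth) {
  frag <- truth$fragment_sequence[match(ids, truth$pair_id)]
  if (anyNA(frag)) stop("missing truth records for ",
                        sum(is.na(frag)), " pairs")
  merged <- !is.na(merged_seq)
  eval_counts(total = length(ids), merges = sum(merged),
              correct = sum(merged & merged_seq == frag))
}

#' Accuracy, precision, recall and F1 for merge outcomes
#'
#' With `TP` the correct merges, `FP` the incorrect merges
#' (`merges - correct`) and `FN` the unmerged pairs (`total - merges`):
#' `accuracy = TP / total`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)` and `F1` their harmonic mean (0 when `TP = 0`).
#'
#' @param counts An [eval_counts()].
#' @return A list with `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' compute_metrics(eval_counts(1e6, 989960, 732040))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  if (counts$total == 0) stop("total must be positive")
  tp <- counts$correct
  fp <- counts$merges - counts$correct
  fn <- counts$total - counts$merges
  accuracy <- tp / counts$total
  if (tp == 0) {
    precision <- 0; recall <- 0; f1 <- 0
  } else {
    precision <- tp / (tp + fp)
    recall <- tp / (tp + fn)
    f1 <- 2 * precision * recall / (precision + recall)
  }
  list(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Relative change between two counts, in percent
#'
#' `100 * (b - a) / a`: the percentage by which `b` exceeds baseline `a`.
#'
#' @param a Baseline count, strictly positive.
#' @param b Comparison count.
#' @return Percentage (negative when `b < a`).
#' @export
percent_change <- function(a, b) {
  if (any(a <= 0)) stop("baseline count must be positive")
  100 * (b - a) / a
}

#' Evaluate a merged FASTQ file against a simulated truth table
#'
#' @param merged_fastq Path to the merged FASTQ produced by [merge_fastq()].
#' @param truth_tsv Path to the truth TSV produced by [simulate_dataset()].
#' @param total Total number of input pairs (the truth table's row count is
#'   used when omitted).
#' @param offset Phred offset of the merged FASTQ.
#' @return A list with the `counts` ([eval_counts()]) and `metrics`
#'   ([compute_metrics()]).
#' @export
evaluate_merged <- function(merged_fastq, truth_tsv, total = NULL,
                            offset = 33L) {
  truth <- read.delim(truth_tsv, stringsAsFactors = FALSE)
  if (is.null(total)) total <- nrow(truth)
  con <- open_maybe_gz(merged_fastq, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  batch <- parse_fastq_chunk(lines, offset, 0L, merged_fastq)
  frag <- truth$fragment_sequence[match(batch$id, truth$pair_id)]
  if (anyNA(frag)) stop("merged reads without truth records in ", merged_fastq)
  counts <- eval_counts(total = total, merges = batch_size(batch),
                        correct = sum(batch$seq == frag))
  list(counts = counts, metrics = compute_metrics(counts))
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("eval_counts: %d total, %d merged, %d correct\n",
              x$total, x$merges, x$correct))
  invisible(x)
}
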