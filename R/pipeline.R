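merge_statuses <- c("merged", "abandoned_mismatch_ratio", "no_valid_offset")

#' Merge one read pair against a k-mer table
#'
#' Runs the whole per-pair procedure: reverse-complement preprocessing of the
#' reverse mate, best-overlap search, give-up check, quality pass, context
#' pass, and assembly of the elongated read `Z` (`X(1 : b-1)` followed by the
#' corrected reverse read, whose post-resolution qualities are kept).
#' Failures are reported as statuses, not errors.
#'
#' @param pair A [read_pair()]; the reverse mate is in original (unflipped)
#'   orientation.
#' @param table A [kmer_table()] built from the same preprocessed read
#'   population.
#' @param params A [merge_params()].
#' @return A `merge_outcome`: list with `pair_id`, `status` (one of
#'   `"merged"`, `"abandoned_mismatch_ratio"`, `"no_valid_offset"`),
#'   `merged` (a `seq_read`, or `NULL`), `offset`, `overlap_length`.
#' @examples
#' fwd <- seq_read("p1/1", "ACGTTGCA", rep(30, 8))
#' rev <- seq_read("p1/2", reverse_complement("TTGCAACG"), rep(30, 8))
#' tab <- build_kmer_table(c(fwd$sequence, "TTGCAACG"), k = 3)
#' merge_pair(read_pair(fwd, rev), tab)
#' @export
merge_pair <- function(pair, table, params = merge_params()) {
  stopifnot(inherits(pair, "read_pair"), inherits(table, "kmer_table"),
            inherits(params, "merge_params"))
  y <- reverse_complement_read(pair$reverse)
  res <- cpp_merge_pairs(pair$forward$sequence, list(pair$forward$qualities),
                         y$sequence, list(y$qualities),
                         table$ptr, params$k, params$omega, params$gamma,
                         params$delta, params$quality_weighted_vote)
  id <- strip_mate_suffix(pair$forward$identifier)
  status <- merge_statuses[res$status[1L] + 1L]
  merged <- NULL
  if (status == "merged")
    merged <- seq_read(id, res$merged_seq[1L], res$merged_qual[[1L]])
  structure(list(pair_id = id, status = status, merged = merged,
                 offset = if (status == "merged") res$offset[1L] else NA_integer_,
                 overlap_length = if (status == "merged") res$overlap_length[1L]
                                  else NA_integer_),
            class = "merge_outcome")
}

#' @export
print.merge_outcome <- function(x, ...) {
  cat(sprintf("merge_outcome %s: %s", x$pair_id, x$status))
  if (x$status == "merged")
    cat(sprintf(" (offset %d, overlap %d, merged length %d)",
                x$offset, x$overlap_length, nchar(x$merged$sequence)))
  cat("\n")
  invisible(x)
}

## merge a preprocessed batch (y already reverse-complemented), optionally in
## parallel over sub-batches; output order always equals input order
merge_batch_core <- function(fseq, fqual, yseq, yqual, table, params,
                             threads = 1L) {
  run_one <- function(idx) {
    cpp_merge_pairs(fseq[idx], fqual[idx], yseq[idx], yqual[idx],
                    table$ptr, params$k, params$omega, params$gamma,
                    params$delta, params$quality_weighted_vote)
  }
  n <- length(fseq)
  threads <- max(1L, as.integer(threads))
  if (threads == 1L || n < 2L * threads ||
      .Platform$OS.type != "unix") {
    return(run_one(seq_len(n)))
  }
  splits <- split(seq_len(n), cut(seq_len(n), threads, labels = FALSE))
  parts <- parallel::mclapply(splits, run_one, mc.cores = threads)
  list(status = unlist(lapply(parts, `[[`, "status"), use.names = FALSE),
       offset = unlist(lapply(parts, `[[`, "offset"), use.names = FALSE),
       overlap_length = unlist(lapply(parts, `[[`, "overlap_length"),
                               use.names = FALSE),
       mismatch_count = unlist(lapply(parts, `[[`, "mismatch_count"),
                               use.names = FALSE),
       mismatch_ratio = unlist(lapply(parts, `[[`, "mismatch_ratio"),
                               use.names = FALSE),
       merged_seq = unlist(lapply(parts, `[[`, "merged_seq"),
                           use.names = FALSE),
       merged_qual = do.call(c, lapply(parts, `[[`, "merged_qual")))
}

#' Merge an in-memory set of read pairs
#'
#' In-memory variant of the full pipeline: builds the k-mer table from all
#' preprocessed reads, then merges every pair against it. Used by the
#' simulator-driven evaluations; [merge_fastq()] is the file-based
#' equivalent.
#'
#' @param forward,reverse Lists with character vector `seq` and
#'   list-of-integer-vectors `qual` (as produced by [simulate_pairs()]);
#'   `reverse` is in original orientation.
#' @param ids Optional pair identifiers.
#' @param params A [merge_params()].
#' @param threads Worker count for the merge phase; the output is identical
#'   for any value.
#' @param table Optional pre-built [kmer_table()]; when supplied, the table
#'   build is skipped (useful for parameter sweeps over the same input).
#' @return A list with per-pair vectors `id`, `status`, `offset`,
#'   `overlap_length`, `merged_seq` (`NA` when unmerged), `merged_qual`
#'   (list; `NULL` when unmerged), and the `table` used.
#' @export
merge_read_pairs <- function(forward, reverse, ids = NULL,
                             params = merge_params(), threads = 1L,
                             table = NULL) {
  stopifnot(length(forward$seq) == length(reverse$seq))
  n <- length(forward$seq)
  if (is.null(ids)) ids <- sprintf("pair%06d", seq_len(n))
  yseq <- reverse_complement(reverse$seq)
  yqual <- lapply(reverse$qual, rev)
  if (is.null(table)) {
    table <- build_kmer_table(c(forward$seq, yseq), params$k)
  } else {
    stopifnot(inherits(table, "kmer_table"))
    if (table$k != params$k)
      stop("table k (", table$k, ") differs from params k (", params$k, ")")
  }
  res <- merge_batch_core(forward$seq, forward$qual, yseq, yqual,
                          table, params, threads)
  list(id = ids,
       status = merge_statuses[res$status + 1L],
       offset = ifelse(res$status == 0L, res$offset, NA_integer_),
       overlap_length = ifelse(res$status == 0L, res$overlap_length,
                               NA_integer_),
       merged_seq = res$merged_seq,
       merged_qual = res$merged_qual,
       table = table)
}

#' Merge paired FASTQ files end to end
#'
#' The full five-step pipeline over files, in two streaming passes: pass A
#' reads both files in chunks and accumulates the k-mer count table from all
#' preprocessed reads; pass B re-reads the input, merges each pair against
#' the completed table, and writes results as it goes. Outputs are
#' `PREFIX.merged.fastq` (elongated reads), `PREFIX.unmerged_1.fastq` /
#' `PREFIX.unmerged_2.fastq` (unmergeable pairs, original orientation) and
#' `PREFIX.log` (parameter echo and summary). Output order equals input
#' order for any `threads` value.
#'
#' @param forward,reverse Paths to the synchronized FASTQ files (optionally
#'   gzipped).
#' @param out_prefix Output path prefix.
#' @param params A [merge_params()].
#' @param threads Worker count for the merge phase (results are identical
#'   for any value).
#' @param phred_offset FASTQ quality encoding offset (33 or 64).
#' @param strict_pairing Error on mate-identifier mismatch instead of
#'   warning.
#' @param chunk_size Pairs per streamed chunk.
#' @param gzip_output Compress the three output FASTQ files.
#' @return A `run_summary`: list with `total_pairs`, `merged_count`,
#'   `abandoned_count`, `no_valid_offset_count`, `elapsed` (seconds),
#'   `params` and the output `paths`.
#' @export
merge_fastq <- function(forward, reverse, out_prefix,
                        params = merge_params(), threads = 1L,
                        phred_offset = 33L, strict_pairing = FALSE,
                        chunk_size = 5000L, gzip_output = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(inherits(params, "merge_params"))
  ext <- if (gzip_output) ".fastq.gz" else ".fastq"
  paths <- list(merged = paste0(out_prefix, ".merged", ext),
                unmerged_1 = paste0(out_prefix, ".unmerged_1", ext),
                unmerged_2 = paste0(out_prefix, ".unmerged_2", ext),
                log = paste0(out_prefix, ".log"))

  # pass A: k-mer table over all preprocessed reads
  table <- kmer_table(params$k)
  reader <- fastq_pair_reader(forward, reverse, phred_offset, strict_pairing)
  repeat {
    chunk <- read_pair_chunk(reader, chunk_size)
    if (is.null(chunk)) break
    add_reads(table, c(chunk$forward$seq, reverse_complement(chunk$reverse$seq)))
  }
  close_reader(reader)

  # pass B: merge each pair against the completed table, stream outputs
  con_m <- open_maybe_gz(paths$merged, "wt")
  con_1 <- open_maybe_gz(paths$unmerged_1, "wt")
  con_2 <- open_maybe_gz(paths$unmerged_2, "wt")
  on.exit({ close(con_m); close(con_1); close(con_2) }, add = TRUE)
  counts <- c(merged = 0L, abandoned = 0L, no_offset = 0L)
  reader <- fastq_pair_reader(forward, reverse, phred_offset, strict_pairing)
  repeat {
    chunk <- read_pair_chunk(reader, chunk_size)
    if (is.null(chunk)) break
    yseq <- reverse_complement(chunk$reverse$seq)
    yqual <- lapply(chunk$reverse$qual, rev)
    res <- merge_batch_core(chunk$forward$seq, chunk$forward$qual,
                            yseq, yqual, table, params, threads)
    ok <- res$status == 0L
    counts["merged"] <- counts["merged"] + sum(ok)
    counts["abandoned"] <- counts["abandoned"] + sum(res$status == 1L)
    counts["no_offset"] <- counts["no_offset"] + sum(res$status == 2L)
    if (any(ok))
      writeLines(fastq_lines(chunk$id[ok], res$merged_seq[ok],
                             res$merged_qual[ok], phred_offset), con_m)
    if (any(!ok)) {
      writeLines(fastq_lines(chunk$forward$id[!ok], chunk$forward$seq[!ok],
                             chunk$forward$qual[!ok], phred_offset), con_1)
      writeLines(fastq_lines(chunk$reverse$id[!ok], chunk$reverse$seq[!ok],
                             chunk$reverse$qual[!ok], phred_offset), con_2)
    }
  }
  close_reader(reader)

  elapsed <- proc.time()[["elapsed"]] - t0
  summary <- structure(list(
    total_pairs = sum(counts),
    merged_count = unname(counts["merged"]),
    abandoned_count = unname(counts["abandoned"]),
    no_valid_offset_count = unname(counts["no_offset"]),
    elapsed = elapsed, params = params, paths = paths),
    class = "run_summary")
  writeLines(c(
    sprintf("contextmerge run: %s + %s -> %s", forward, reverse, out_prefix),
    sprintf("parameters: k = %d, omega = %d, gamma = %g, delta = %d, quality_weighted_vote = %s, phred_offset = %d, threads = %d",
            params$k, params$omega, params$gamma, params$delta,
            params$quality_weighted_vote, as.integer(phred_offset),
            as.integer(threads)),
    sprintf("total_pairs: %d", summary$total_pairs),
    sprintf("merged: %d", summary$merged_count),
    sprintf("abandoned_mismatch_ratio: %d", summary$abandoned_count),
    sprintf("no_valid_offset: %d", summary$no_valid_offset_count),
    sprintf("elapsed_sec: %.2f", elapsed)), paths$log)
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("run_summary: %d pairs, %d merged, %d abandoned, %d without valid offset (%.2f s)\n",
              x$total_pairs, x$merged_count, x$abandoned_count,
              x$no_valid_offset_count, x$elapsed))
  invisible(x)
}
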