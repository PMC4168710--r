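#' Configuration for the paired-end amplicon read simulator
#'
#' The simulator emulates high-coverage amplicon sequencing: a small set of
#' reference sequences, short fragments sampled from them, and a pair of
#' equal-length reads per fragment whose substitution error rate rises
#' linearly from the 5' to the 3' end of each read -- the characteristic
#' degradation of Illumina-style platforms. Per-base qualities are Phred
#' scores implied by the local error rate (`Q = -10 log10 p`), plus an
#' optional integer jitter, clipped to `[2, 41]`.
#'
#' Two presets are provided via [sim_preset()]: `"harsh"`
#' (`error_rate_start = 1e-4`, `error_rate_end = 0.015`, jitter 3), a noisy
#' regime whose per-base quality decays from about Q40 at the 5' end to
#' about Q18 at the 3' end, and `"mild"` (`5e-5` to `0.005`, jitter 2), a
#' cleaner regime decaying to about Q23. The harsh rates are the default.
#'
#' @param n_pairs Number of read pairs.
#' @param read_length Read length `n` (both mates).
#' @param fragment_length_range Integer `c(min, max)` for the fragment length
#'   `m`, sampled uniformly; must satisfy `max < 2 * read_length` so every
#'   pair overlaps.
#' @param error_rate_start,error_rate_end Per-base substitution probability
#'   at the 5' and 3' read ends; linearly interpolated in between, each in
#'   `[0, 0.75]`.
#' @param quality_jitter Integer spread: a uniform integer in
#'   `[-quality_jitter, quality_jitter]` added to each implied Phred score.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param n_references,reference_length Number and length of random
#'   references (`reference_mode = "random"`).
#' @param reference_mode `"random"` or `"user_fasta"`.
#' @param references Named character vector of reference sequences (used
#'   when `reference_mode = "user_fasta"`, e.g. from [read_reference_fasta()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 10000L, read_length = 100L,
                       fragment_length_range = c(160L, 190L),
                       error_rate_start = 1e-4, error_rate_end = 0.015,
                       quality_jitter = 3L, seed = NULL,
                       n_references = 23L, reference_length = 1500L,
                       reference_mode = c("random", "user_fasta"),
                       references = NULL) {
  reference_mode <- match.arg(reference_mode)
  fragment_length_range <- as.integer(fragment_length_range)
  stopifnot(n_pairs >= 0, read_length >= 1,
            length(fragment_length_range) == 2L,
            fragment_length_range[1] <= fragment_length_range[2],
            error_rate_start >= 0, error_rate_start <= 0.75,
            error_rate_end >= 0, error_rate_end <= 0.75,
            quality_jitter >= 0)
  if (fragment_length_range[2] >= 2L * read_length)
    stop("max fragment length must be < 2 * read_length so the mates overlap")
  if (fragment_length_range[1] < read_length)
    stop("min fragment length must be >= read_length")
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 fragment_length_range = fragment_length_range,
                 error_rate_start = error_rate_start,
                 error_rate_end = error_rate_end,
                 quality_jitter = as.integer(quality_jitter),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 n_references = as.integer(n_references),
                 reference_length = as.integer(reference_length),
                 reference_mode = reference_mode,
                 references = references),
            class = "sim_config")
}

#' @rdname sim_config
#' @param name Preset name, `"harsh"` or `"mild"`.
#' @param ... Overrides passed on to [sim_config()].
#' @export
sim_preset <- function(name = c("harsh", "mild"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    harsh = list(error_rate_start = 1e-4, error_rate_end = 0.015,
                 quality_jitter = 3L),
    mild  = list(error_rate_start = 5e-5, error_rate_end = 0.005,
                 quality_jitter = 2L))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Generate random reference sequences
#'
#' Uniform-random A/C/G/T sequences standing in for a small amplicon
#' reference panel.
#'
#' @param n_references Number of references.
#' @param length_range Integer `c(min, max)` reference length (must be at
#'   least the longest fragment to be sampled).
#' @param seed Optional integer seed.
#' @return Named character vector (`ref01`, `ref02`, ...).
#' @export
simulate_references <- function(n_references, length_range, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(length_range) == 1L) length_range <- rep(length_range, 2L)
  lens <- sample_uniform_int(length_range[1], length_range[2], n_references)
  refs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(refs) <- sprintf("ref%02d", seq_len(n_references))
  refs
}

## uniform integers in [lo, hi], safe against sample()'s scalar expansion
sample_uniform_int <- function(lo, hi, n) {
  vals <- seq.int(lo, hi)
  vals[sample.int(length(vals), n, replace = TRUE)]
}

## position-dependent error profile along a read (5' -> 3')
error_profile <- function(config) {
  n <- config$read_length
  if (n == 1L) return(config$error_rate_start)
  config$error_rate_start +
    (config$error_rate_end - config$error_rate_start) * (seq_len(n) - 1) / (n - 1)
}

## inject substitutions into equal-length reads and derive qualities;
## returns list(seq = chr vector, qual = list of int vectors)
corrupt_reads <- function(seqs, config) {
  n <- config$read_length
  np <- length(seqs)
  p <- error_profile(config)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = n)
  err <- matrix(runif(n * np), nrow = n) < p
  if (any(err)) {
    idx <- which(err)
    bases <- c("A", "C", "G", "T")
    code <- match(mat[idx], bases) - 1L
    # shift by 1..3 mod 4: uniform over the three alternative bases
    shift <- sample.int(3L, length(idx), replace = TRUE)
    mat[idx] <- bases[((code + shift) %% 4L) + 1L]
  }
  q_true <- pmin(41L, as.integer(round(-10 * log10(pmax(p, 1e-9)))))
  qmat <- matrix(rep(q_true, np), nrow = n)
  if (config$quality_jitter > 0L) {
    jit <- sample.int(2L * config$quality_jitter + 1L, n * np,
                      replace = TRUE) - config$quality_jitter - 1L
    qmat <- qmat + matrix(jit, nrow = n)
  }
  qmat <- pmin(pmax(qmat, 2L), 41L)
  list(seq = apply(mat, 2L, paste, collapse = ""),
       qual = lapply(seq_len(np), function(j) qmat[, j]))
}

#' Simulate paired-end reads with known truth
#'
#' For each pair a reference and a fragment (uniform start, uniform length in
#' range) are sampled; the forward read is the fragment prefix of length `n`
#' and the reverse read is the reverse complement of the fragment suffix of
#' length `n`. Substitutions are injected per position with the linearly
#' interpolated error probability (erroneous bases replaced uniformly by one
#' of the three alternatives), and qualities follow the local error rate as
#' described in [sim_config()].
#'
#' @param references Named character vector of reference sequences.
#' @param config A [sim_config()].
#' @return A list with `ids`, read sets `forward` and `reverse` (each with
#'   `seq` and `qual`), and a `truth` data frame (`pair_id`, `reference_id`,
#'   `fragment_start`, `fragment_length`, `fragment_sequence`; 1-based
#'   inclusive coordinates). The true overlap offset is
#'   `fragment_length - read_length + 1`.
#' @export
simulate_pairs <- function(references, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$n_pairs
  n <- config$read_length
  reflen <- nchar(references)
  if (any(reflen < config$fragment_length_range[2]))
    stop("all references must be at least as long as the longest fragment")
  ref_idx <- sample.int(length(references), np, replace = TRUE)
  m <- sample_uniform_int(config$fragment_length_range[1],
                          config$fragment_length_range[2], np)
  start <- floor(runif(np) * (reflen[ref_idx] - m + 1)) + 1L
  frag <- substr(references[ref_idx], start, start + m - 1L)
  fwd_true <- substr(frag, 1L, n)
  rev_true <- reverse_complement(substr(frag, m - n + 1L, m))
  ids <- sprintf("pair%06d", seq_len(np))
  fwd <- corrupt_reads(fwd_true, config)
  rev <- corrupt_reads(rev_true, config)
  truth <- data.frame(pair_id = ids,
                      reference_id = names(references)[ref_idx],
                      fragment_start = start,
                      fragment_length = m,
                      fragment_sequence = unname(frag),
                      stringsAsFactors = FALSE)
  list(ids = ids, forward = fwd, reverse = rev, truth = truth)
}

#' Simulate a dataset and write it to disk
#'
#' Writes `PREFIX.refs.fasta` (the references), `PREFIX_1.fastq` /
#' `PREFIX_2.fastq` (the read pairs, mate suffixes `/1` and `/2`) and
#' `PREFIX.truth.tsv` (tab-separated truth table with header).
#'
#' @param out_prefix Output path prefix.
#' @param config A [sim_config()].
#' @param references Optional pre-built references; generated per the config
#'   otherwise.
#' @return Invisibly, a list with the output `paths`, the `truth` table and
#'   the `references`.
#' @export
simulate_dataset <- function(out_prefix, config, references = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(references)) {
    references <- if (config$reference_mode == "user_fasta") {
      if (is.null(config$references))
        stop("reference_mode = 'user_fasta' needs config$references")
      config$references
    } else {
      simulate_references(config$n_references, config$reference_length,
                          seed = config$seed)
    }
  }
  sim <- simulate_pairs(references, config)
  paths <- list(refs = paste0(out_prefix, ".refs.fasta"),
                forward = paste0(out_prefix, "_1.fastq"),
                reverse = paste0(out_prefix, "_2.fastq"),
                truth = paste0(out_prefix, ".truth.tsv"))
  seqinr::write.fasta(as.list(unname(references)), names(references),
                      paths$refs)
  write_fastq(read_batch(paste0(sim$ids, "/1"), sim$forward$seq,
                         sim$forward$qual), paths$forward)
  write_fastq(read_batch(paste0(sim$ids, "/2"), sim$reverse$seq,
                         sim$reverse$qual), paths$reverse)
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(paths = paths, truth = sim$truth, references = references))
}

#' Read a reference FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercased sequences.
#' @export
read_reference_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- toupper(vapply(fa, as.character, character(1)))
  names(out) <- names(fa)
  out
}
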