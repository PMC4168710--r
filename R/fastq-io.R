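#' A sequencing read with per-base qualities
#'
#' Bundles an identifier, a base sequence over `{A,C,G,T,N}` and one integer
#' Phred quality per base. Sequences are uppercased on construction; any other
#' character is rejected.
#'
#' @param identifier Read name (without a leading `@`).
#' @param sequence Character scalar over `A`, `C`, `G`, `T`, `N`
#'   (lowercase accepted).
#' @param qualities Integer vector of Phred scores, one per base, each in
#'   `[0, 93]`.
#' @return An object of class `seq_read`.
#' @examples
#' r <- seq_read("r1", "ACGTN", c(30, 30, 30, 30, 2))
#' reverse_complement_read(r)
#' @export
seq_read <- function(identifier, sequence, qualities) {
  stopifnot(is.character(identifier), length(identifier) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}: ", identifier)
  qualities <- as.integer(qualities)
  if (length(qualities) != nchar(sequence))
    stop("sequence and qualities differ in length for read ", identifier)
  if (length(qualities) && (min(qualities) < 0L || max(qualities) > 93L))
    stop("quality values must lie in [0, 93] for read ", identifier)
  structure(list(identifier = identifier, sequence = sequence,
                 qualities = qualities),
            class = "seq_read")
}

#' @export
print.seq_read <- function(x, ...) {
  cat("seq_read", x$identifier, "(", nchar(x$sequence), "bp )\n")
  cat(" ", x$sequence, "\n")
  cat(" ", encode_quality(x$qualities), "\n")
  invisible(x)
}

#' A synchronized forward/reverse read pair
#'
#' @param forward,reverse `seq_read` objects for the two mates. Identifiers
#'   must agree after stripping a trailing `/1` / `/2` mate suffix or a
#'   space-delimited mate field; a mismatch raises a warning (or an error when
#'   `strict = TRUE`).
#' @param strict Turn the identifier-mismatch warning into an error.
#' @return An object of class `read_pair`.
#' @export
read_pair <- function(forward, reverse, strict = FALSE) {
  stopifnot(inherits(forward, "seq_read"), inherits(reverse, "seq_read"))
  idf <- strip_mate_suffix(forward$identifier)
  idr <- strip_mate_suffix(reverse$identifier)
  if (idf != idr) {
    msg <- sprintf("mate identifiers disagree: '%s' vs '%s'",
                   forward$identifier, reverse$identifier)
    if (strict) stop(msg) else warning(msg)
  }
  structure(list(forward = forward, reverse = reverse), class = "read_pair")
}

strip_mate_suffix <- function(id) {
  sub("/[12]$", "", sub("\\s.*$", "", id))
}

#' Decode and encode Phred quality characters
#'
#' FASTQ stores one quality per base as `intToUtf8(q + offset)`. The default
#' offset 33 is the Sanger / Illumina 1.8+ convention; pass 64 for legacy
#' Illumina 1.3--1.7 files.
#'
#' @param chars A quality string (or vector of single characters).
#' @param offset ASCII offset, 33 (default) or 64.
#' @return `decode_quality`: integer vector of Phred scores.
#' @examples
#' decode_quality("II!")       # 40 40 0
#' encode_quality(c(40, 0))    # "I!"
#' @export
decode_quality <- function(chars, offset = 33L) {
  codes <- utf8ToInt(paste(chars, collapse = "")) - as.integer(offset)
  bad <- which(codes < 0L | codes > 93L)
  if (length(bad))
    stop(sprintf("malformed FASTQ quality character at position %d (Phred %d out of [0, 93])",
                 bad[1L], codes[bad[1L]]))
  codes
}

#' @rdname decode_quality
#' @param q Integer vector of Phred scores in `[0, 93]`.
#' @return `encode_quality`: a single quality string.
#' @export
encode_quality <- function(q, offset = 33L) {
  q <- as.integer(q)
  if (length(q) && (min(q) < 0L || max(q) > 93L))
    stop("Phred scores must lie in [0, 93]")
  if (!length(q)) return("")
  intToUtf8(q + as.integer(offset))
}

#' Convert a Phred score to an error probability
#'
#' The Phred convention is `Q = -10 log10(p)` with `p` the probability that
#' the base call is wrong, so `p = 10^(-Q/10)`.
#'
#' @param q Non-negative Phred score(s).
#' @return Error probabilities in `(0, 1]`.
#' @examples
#' phred_to_error_prob(c(0, 19, 40))
#' @export
phred_to_error_prob <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  10^(-q / 10)
}

#' Reverse-complement sequences or reads
#'
#' The preprocessing step of the merger: the reverse mate `W` is turned into
#' `Y` with `Y(i)` the complement of `W(n-i+1)` and the quality vector
#' reversed, so that both mates read along the same fragment strand.
#' The complement of `N` is `N`.
#'
#' @param x Character vector of sequences.
#' @return `reverse_complement`: character vector of the same length.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), character(1))
}

#' @rdname reverse_complement
#' @param read A `seq_read`.
#' @return `reverse_complement_read`: a `seq_read` with complemented,
#'   reversed bases and reversed qualities.
#' @export
reverse_complement_read <- function(read) {
  stopifnot(inherits(read, "seq_read"))
  seq_read(read$identifier, reverse_complement(read$sequence),
           rev(read$qualities))
}

## ------------------------------------------------------------------ batches
## Internally reads travel as a "read batch": a list with character vector
## `id`, character vector `seq` and list-of-integer-vectors `qual`. This keeps
## per-chunk work vectorized and maps directly onto the C++ batch interface.

read_batch <- function(id, seq, qual) {
  structure(list(id = id, seq = seq, qual = qual), class = "read_batch")
}

batch_size <- function(batch) length(batch$id)

#' @export
print.read_batch <- function(x, ...) {
  cat("read_batch of", batch_size(x), "reads\n")
  invisible(x)
}

## -------------------------------------------------------------- FASTQ input

open_maybe_gz <- function(path, mode) {
  # gzfile() reads plain text transparently and writes gzip only when the
  # path says so; use it for reading always and for writing *.gz
  if (mode == "rt") return(gzfile(path, open = "rt"))
  if (grepl("\\.gz$", path)) gzfile(path, open = mode) else file(path, open = mode)
}

parse_fastq_chunk <- function(lines, offset, lines_before, path) {
  nl <- length(lines)
  if (nl %% 4L != 0L)
    stop(sprintf("truncated FASTQ record in '%s' near line %d",
                 path, lines_before + nl))
  n <- nl %/% 4L
  heads <- lines[seq(1L, nl, by = 4L)]
  seqs <- toupper(lines[seq(2L, nl, by = 4L)])
  quals <- lines[seq(4L, nl, by = 4L)]
  bad <- which(substr(heads, 1L, 1L) != "@")
  if (length(bad))
    stop(sprintf("malformed FASTQ header in '%s' at line %d",
                 path, lines_before + (bad[1L] - 1L) * 4L + 1L))
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad))
    stop(sprintf("non-ACGTN base in '%s' at line %d",
                 path, lines_before + (bad[1L] - 1L) * 4L + 2L))
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stop(sprintf("sequence/quality length mismatch in '%s' at line %d",
                 path, lines_before + (bad[1L] - 1L) * 4L + 4L))
  qual <- vector("list", n)
  for (i in seq_len(n)) {
    qual[[i]] <- tryCatch(decode_quality(quals[i], offset),
                          error = function(e)
                            stop(sprintf("%s [file '%s', line %d]",
                                         conditionMessage(e), path,
                                         lines_before + (i - 1L) * 4L + 4L),
                                 call. = FALSE))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", heads))
  read_batch(ids, seqs, qual)
}

#' Stream synchronized paired FASTQ files
#'
#' `fastq_pair_reader()` opens both mate files (gzip detected transparently)
#' and returns a reader from which [read_pair_chunk()] pulls batches of
#' record-synchronized pairs. Mate `i` of file 1 is paired with mate `i` of
#' file 2; identifier agreement (after stripping the mate suffix) is checked
#' and warned about, or rejected under `strict_pairing`.
#'
#' @param forward_path,reverse_path Paths to the two FASTQ files.
#' @param offset Phred ASCII offset (33 or 64).
#' @param strict_pairing Error (rather than warn) on identifier mismatch.
#' @return A reader object; pass it to [read_pair_chunk()] and
#'   [close_reader()].
#' @export
fastq_pair_reader <- function(forward_path, reverse_path, offset = 33L,
                              strict_pairing = FALSE) {
  for (p in c(forward_path, reverse_path))
    if (!file.exists(p)) stop("no such file: ", p)
  env <- new.env(parent = emptyenv())
  env$con_f <- open_maybe_gz(forward_path, "rt")
  env$con_r <- open_maybe_gz(reverse_path, "rt")
  env$path_f <- forward_path
  env$path_r <- reverse_path
  env$offset <- as.integer(offset)
  env$strict <- isTRUE(strict_pairing)
  env$records <- 0L
  env$warned <- FALSE
  class(env) <- "fastq_pair_reader"
  env
}

#' @rdname fastq_pair_reader
#' @param reader A reader from `fastq_pair_reader()`.
#' @param n Maximum number of pairs per chunk.
#' @return `read_pair_chunk`: a list with read batches `forward` and
#'   `reverse` plus the pair identifiers `id`, or `NULL` at end of input.
#' @export
read_pair_chunk <- function(reader, n = 5000L) {
  lf <- readLines(reader$con_f, n = n * 4L)
  lr <- readLines(reader$con_r, n = n * 4L)
  if (!length(lf) && !length(lr)) return(NULL)
  fb <- parse_fastq_chunk(lf, reader$offset, reader$records * 4L, reader$path_f)
  rb <- parse_fastq_chunk(lr, reader$offset, reader$records * 4L, reader$path_r)
  if (batch_size(fb) != batch_size(rb))
    stop(sprintf("unequal record counts: '%s' and '%s' diverge after record %d",
                 reader$path_f, reader$path_r,
                 reader$records + min(batch_size(fb), batch_size(rb))))
  idf <- strip_mate_suffix(fb$id)
  idr <- strip_mate_suffix(rb$id)
  bad <- which(idf != idr)
  if (length(bad)) {
    msg <- sprintf("mate identifiers disagree at record %d: '%s' vs '%s'",
                   reader$records + bad[1L], fb$id[bad[1L]], rb$id[bad[1L]])
    if (reader$strict) stop(msg)
    if (!reader$warned) { warning(msg); reader$warned <- TRUE }
  }
  reader$records <- reader$records + batch_size(fb)
  list(id = idf, forward = fb, reverse = rb)
}

#' @rdname fastq_pair_reader
#' @export
close_reader <- function(reader) {
  close(reader$con_f)
  close(reader$con_r)
  invisible(NULL)
}

#' Read two synchronized FASTQ files into read pairs
#'
#' Convenience wrapper over the streaming reader; materializes every pair.
#' Intended for modest inputs (tests, examples); [merge_fastq()] streams
#' chunks instead.
#'
#' @inheritParams fastq_pair_reader
#' @return A list of [read_pair()] objects.
#' @export
read_paired_fastq <- function(forward_path, reverse_path, offset = 33L,
                              strict_pairing = FALSE) {
  reader <- fastq_pair_reader(forward_path, reverse_path, offset, strict_pairing)
  on.exit(close_reader(reader))
  pairs <- list()
  repeat {
    chunk <- read_pair_chunk(reader)
    if (is.null(chunk)) break
    new <- lapply(seq_along(chunk$id), function(i) {
      structure(list(
        forward = seq_read(chunk$forward$id[i], chunk$forward$seq[i],
                           chunk$forward$qual[[i]]),
        reverse = seq_read(chunk$reverse$id[i], chunk$reverse$seq[i],
                           chunk$reverse$qual[[i]])), class = "read_pair")
    })
    pairs <- c(pairs, new)
  }
  pairs
}

## ------------------------------------------------------------- FASTQ output

fastq_lines <- function(ids, seqs, quals, offset) {
  qstr <- vapply(quals, encode_quality, character(1), offset = offset)
  as.vector(rbind(paste0("@", ids), seqs, "+", qstr))
}

#' Write reads to a FASTQ file
#'
#' @param reads A list of `seq_read` objects, a single `seq_read`, or an
#'   internal read batch.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param offset Phred ASCII offset used for encoding.
#' @return The number of records written.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  if (inherits(reads, "seq_read")) reads <- list(reads)
  if (inherits(reads, "read_batch")) {
    ids <- reads$id; seqs <- reads$seq; quals <- reads$qual
  } else {
    ids <- vapply(reads, `[[`, character(1), "identifier")
    seqs <- vapply(reads, `[[`, character(1), "sequence")
    quals <- lapply(reads, `[[`, "qualities")
  }
  con <- open_maybe_gz(path, "wt")
  on.exit(close(con))
  if (length(ids)) writeLines(fastq_lines(ids, seqs, quals, offset), con)
  length(ids)
}
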