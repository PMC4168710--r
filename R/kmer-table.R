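#' Exact k-mer count tables
#'
#' The table counts every length-`k` window over `{A,C,G,T}` across all
#' preprocessed input reads (forward reads plus reverse-complemented reverse
#' reads, pooled: after preprocessing both mates represent the same fragment
#' strand). Windows containing `N` are skipped; lookups of windows containing
#' `N` return 0. Counting is non-canonical: a k-mer and its reverse
#' complement are distinct keys.
#'
#' `k` is capped at 31 so each k-mer packs into a 64-bit word.
#'
#' @param k K-mer length, in `[1, 31]`.
#' @return `kmer_table()`: an empty table of class `kmer_table`.
#' @examples
#' tab <- build_kmer_table(c("ACGT", "ANGT"), k = 2)
#' kmer_count(tab, c("AC", "GT", "AN"))
#' @export
kmer_table <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be an integer in [1, 31]")
  structure(list(ptr = kmer_map_new(), k = k), class = "kmer_table")
}

#' @rdname kmer_table
#' @param table A `kmer_table`.
#' @param sequences Character vector of reads (uppercased internally).
#' @return `add_reads()`: the table, invisibly (counts are updated in place).
#' @export
add_reads <- function(table, sequences) {
  stopifnot(inherits(table, "kmer_table"))
  kmer_map_add(table$ptr, toupper(as.character(sequences)), table$k)
  invisible(table)
}

#' @rdname kmer_table
#' @return `build_kmer_table()`: a populated `kmer_table`. The result is
#'   independent of the order of `sequences`.
#' @export
build_kmer_table <- function(sequences, k) {
  tab <- kmer_table(k)
  add_reads(tab, sequences)
  tab
}

#' @rdname kmer_table
#' @param kmers Character vector of queries, each exactly `k` long.
#' @return `kmer_count()`: numeric vector of counts (0 for absent keys and
#'   for any query containing `N`).
#' @export
kmer_count <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_table"))
  kmers <- toupper(as.character(kmers))
  if (any(nchar(kmers) != table$k))
    stop("all queries must have length k = ", table$k)
  kmer_map_lookup(table$ptr, kmers, table$k)
}

#' @rdname kmer_table
#' @return `kmer_table_size()`: number of distinct stored k-mers;
#'   `kmer_table_total()`: total count over all stored k-mers.
#' @export
kmer_table_size <- function(table) kmer_map_size(table$ptr)

#' @rdname kmer_table
#' @export
kmer_table_total <- function(table) kmer_map_total(table$ptr)

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k = %d, %d distinct k-mers, total count %g\n",
              x$k, kmer_table_size(x), kmer_table_total(x)))
  invisible(x)
}

#' Dump or restore a k-mer table as plain text
#'
#' Debugging aid: the pipeline itself never serializes tables. The dump is a
#' two-column tab-separated file (`kmer`, `count`) sorted by k-mer.
#'
#' @param table A `kmer_table`.
#' @param path Optional output path; when `NULL` the dump is returned as a
#'   data frame only.
#' @return A data frame with columns `kmer` and `count`, invisibly when
#'   written to `path`.
#' @export
dump_kmer_table <- function(table, path = NULL) {
  stopifnot(inherits(table, "kmer_table"))
  d <- kmer_map_dump(table$ptr, table$k)
  df <- data.frame(kmer = as.character(d$kmer), count = as.numeric(d$count),
                   stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname dump_kmer_table
#' @param k K-mer length of the dumped table.
#' @return `load_kmer_table()`: a `kmer_table` rebuilt from the dump.
#' @export
load_kmer_table <- function(path, k) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tab <- kmer_table(k)
  kmer_map_set(tab$ptr, df$kmer, as.numeric(df$count), tab$k)
  tab
}
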