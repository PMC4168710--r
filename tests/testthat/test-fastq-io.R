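test_that("quality decoding and encoding follow the Phred ASCII conventions", {
  expect_identical(decode_quality("I", 33L), 40L)
  expect_identical(decode_quality("!", 33L), 0L)
  expect_identical(decode_quality("@", 64L), 0L)
  expect_identical(decode_quality("II!"), c(40L, 40L, 0L))
  # decode . encode is the identity on the whole legal range, both offsets
  for (off in c(33L, 64L)) {
    q <- 0:93
    expect_identical(decode_quality(encode_quality(q, off), off), q)
  }
  expect_error(decode_quality(" ", 64L), "malformed FASTQ")
  expect_error(encode_quality(94L), "\\[0, 93\\]")
})

test_that("Phred scores convert to error probabilities by the closed form", {
  expect_equal(phred_to_error_prob(40), 1e-4)
  expect_equal(phred_to_error_prob(0), 1.0)
  expect_equal(phred_to_error_prob(19), 10^(-1.9))
  expect_equal(phred_to_error_prob(19), 0.012589, tolerance = 1e-4)
  expect_error(phred_to_error_prob(-1), "non-negative")
})

test_that("reverse complement flips bases and qualities and is an involution", {
  r <- seq_read("r", "ACGT", c(10, 20, 30, 40))
  rc <- reverse_complement_read(r)
  expect_identical(rc$sequence, "ACGT")  # palindrome
  expect_identical(rc$qualities, c(40L, 30L, 20L, 10L))
  r2 <- reverse_complement_read(seq_read("r", "AACC", 1:4))
  expect_identical(r2$sequence, "GGTT")
  expect_identical(r2$qualities, c(4L, 3L, 2L, 1L))
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    r <- seq_read("r", rand_seq(n, n_prob = 0.1),
                  sample(0:41, n, replace = TRUE))
    expect_identical(reverse_complement_read(reverse_complement_read(r)), r)
  }
  # complement of N is N
  expect_identical(reverse_complement("ANT"), "ANT")
})

test_that("seq_read enforces its invariants", {
  expect_error(seq_read("r", "ACGX", rep(30, 4)), "outside")
  expect_error(seq_read("r", "ACGT", rep(30, 3)), "differ in length")
  expect_error(seq_read("r", "ACGT", c(30, 30, 30, 95)), "\\[0, 93\\]")
  r <- seq_read("r", "acgtn", rep(5, 5))
  expect_identical(r$sequence, "ACGTN")  # case-normalized
})

test_that("paired FASTQ round-trips exactly, plain and gzipped", {
  set.seed(7)
  n <- 25L
  make <- function(mate) {
    lens <- sample(5:60, n, replace = TRUE)
    read_batch_list <- lapply(seq_len(n), function(i)
      seq_read(sprintf("read%03d/%d", i, mate), rand_seq(lens[i], n_prob = 0.05),
               sample(0:41, lens[i], replace = TRUE)))
    read_batch_list
  }
  f <- make(1); r <- make(2)
  for (ext in c(".fastq", ".fastq.gz")) {
    pf <- tempfile(fileext = ext); pr <- tempfile(fileext = ext)
    expect_identical(write_fastq(f, pf), n)
    write_fastq(r, pr)
    pairs <- read_paired_fastq(pf, pr)
    expect_length(pairs, n)
    expect_identical(lapply(pairs, `[[`, "forward"), f)
    expect_identical(lapply(pairs, `[[`, "reverse"), r)
  }
})

test_that("malformed paired input is reported with file and position", {
  pf <- tempfile(fileext = ".fastq"); pr <- tempfile(fileext = ".fastq")
  writeLines(c("@a/1", "ACGT", "+", "IIII", "@b/1", "ACGT"), pf)
  writeLines(c("@a/2", "ACGT", "+", "IIII"), pr)
  expect_error(read_paired_fastq(pf, pr), "truncated.*line 6")

  writeLines(c("@a/1", "ACGT", "+", "IIII", "@b/1", "ACGT", "+", "IIII"), pf)
  expect_error(read_paired_fastq(pf, pr), "unequal record counts")

  writeLines(c("@a/1", "ACQT", "+", "IIII"), pf)
  writeLines(c("@a/2", "ACGT", "+", "IIII"), pr)
  expect_error(read_paired_fastq(pf, pr), "non-ACGTN.*line 2")

  writeLines(c("@a/1", "ACGT", "+", "II I"), pf)
  expect_error(read_paired_fastq(pf, pr), "line 4")

  # identifier desynchronization: warn by default, error under strict pairing
  writeLines(c("@a/1", "ACGT", "+", "IIII"), pf)
  writeLines(c("@zz/2", "ACGT", "+", "IIII"), pr)
  expect_warning(read_paired_fastq(pf, pr), "record 1")
  expect_error(
    suppressWarnings(read_paired_fastq(pf, pr, strict_pairing = TRUE)),
    "record 1")
})

test_that("mate identifiers match after stripping suffixes", {
  f <- seq_read("p7/1", "ACGT", rep(30, 4))
  r <- seq_read("p7/2", "ACGT", rep(30, 4))
  expect_silent(read_pair(f, r))
  r2 <- seq_read("p8/2", "ACGT", rep(30, 4))
  expect_warning(read_pair(f, r2), "disagree")
  expect_error(read_pair(f, r2, strict = TRUE), "disagree")
  # space-delimited mate fields are ignored too
  f3 <- seq_read("p9 1:N:0:ATC", "ACGT", rep(30, 4))
  r3 <- seq_read("p9 2:N:0:ATC", "ACGT", rep(30, 4))
  expect_silent(read_pair(f3, r3))
})
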