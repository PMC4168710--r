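test_that("the quality pass overwrites only decisively weaker bases", {
  # forward quality wins by more than delta: Y takes X's base and quality
  r <- quality_pass("A", 40, "C", 10, b = 1, delta = 19)
  expect_identical(r$y, "A")
  expect_identical(r$qy, 40L)
  # difference exactly delta: untouched, left for the context pass
  r <- quality_pass("A", 30, "C", 11, b = 1, delta = 19)
  expect_identical(r$x, "A"); expect_identical(r$y, "C")
  # symmetric direction
  r <- quality_pass("A", 10, "C", 40, b = 1, delta = 19)
  expect_identical(r$x, "C"); expect_identical(r$qx, 40L)
  # one-sided N is always overwritten by the informative base
  r <- quality_pass("N", 2, "C", 3, b = 1, delta = 19)
  expect_identical(r$x, "C"); expect_identical(r$qx, 3L)
  r <- quality_pass("G", 2, "N", 40, b = 1, delta = 19)
  expect_identical(r$y, "G"); expect_identical(r$qy, 2L)
  # both N: skipped
  r <- quality_pass("N", 2, "N", 2, b = 1, delta = 19)
  expect_identical(r$x, "N"); expect_identical(r$y, "N")
  # matching bases untouched even with a large quality gap
  r <- quality_pass("AC", c(40, 40), "AC", c(2, 2), b = 1, delta = 19)
  expect_identical(r$qy, c(2L, 2L))
})

test_that("context windows honor boundaries and stop at downstream mismatches", {
  tab <- build_kmer_table(c("ACGTA", "ACGTA", "ACCTA"), 3)
  # k = 1: one degenerate window, the mismatching base itself
  t1 <- build_kmer_table(c("G", "G", "C"), 1)
  v <- collect_context_votes("G", "C", 1, 1, t1, k = 1)
  expect_identical(nrow(v), 1L)
  expect_identical(v$vote, "forward")

  # adjacent uncorrected mismatch: only j = 1 is evaluated
  x <- "ACGTAA"; y <- "ACCTTA"  # mismatches at 3 and 5
  v <- collect_context_votes(x, y, 3, 3, tab, k = 3)
  expect_true(all(v$j <= 2))

  # j = 1 underruns the left boundary of Y: skipped, later j still evaluated
  x <- "TTACGTACGTAC"
  y <- substr(x, 4, 12)               # y(t) = x(t + 3)
  xx <- x; substr(xx, 5, 5) <- "A"    # mismatch at x position 5 / y position 2
  v <- collect_context_votes(xx, y, 5, 2, tab, k = 3)
  # with k = 3 the j = 1 window needs y(0:2): skipped; j = 2 and 3 survive
  expect_identical(v$j, c(2L, 3L))
})

test_that("votes match a brute-force window enumerator on random mismatches", {
  set.seed(31)
  for (rep in 1:200) {
    k <- sample(1:6, 1)
    reads <- replicate(8, rand_seq(sample(12:25, 1), n_prob = 0.04))
    tab <- build_kmer_table(reads, k)
    counts <- naive_kmer_counts(reads, k)
    nx <- sample(10:20, 1); ny <- sample(10:20, 1)
    x <- rand_seq(nx, n_prob = 0.05); y <- rand_seq(ny, n_prob = 0.05)
    i <- sample(1:nx, 1); ip <- sample(1:ny, 1)
    got <- collect_context_votes(x, y, i, ip, tab, k = k)
    want <- bf_votes(x, y, i, ip, k, counts)
    expect_equal(got$j, want$j)
    expect_equal(got$forward_count, want$forward_count)
    expect_equal(got$reverse_count, want$reverse_count)
    expect_identical(got$vote, want$vote)
  }
})

test_that("the final decision is a majority vote with ties to the reverse read", {
  expect_identical(decide_votes(c("forward", "forward", "reverse")), "forward")
  expect_identical(decide_votes(c("forward", "reverse")), "reverse")
  expect_identical(decide_votes(character(0)), "reverse")
  expect_identical(decide_votes(c("none", "none", "forward")), "forward")
  # equivalent to the 0.5-thresholded mean when all k votes are cast
  set.seed(32)
  for (rep in 1:100) {
    k <- sample(1:9, 1)
    d <- sample(0:1, k, replace = TRUE)
    votes <- c("reverse", "forward")[d + 1]
    expect_identical(decide_votes(votes),
                     if (mean(d) > 0.5) "forward" else "reverse")
  }
})

test_that("the context pass corrects an isolated error against clean coverage", {
  frag <- "ACGTACGTACGT"
  reads <- rep(frag, 5)
  # one pair carries a single error in the overlap, equal qualities
  x <- frag; substr(x, 6, 6) <- "A"   # true base C
  y <- frag
  tab <- build_kmer_table(c(reads, x, y), 3)
  r <- context_pass(x, rep(30, 12), y, rep(30, 12), b = 1, tab,
                    merge_params(k = 3))
  expect_identical(r$x, frag)
  expect_identical(r$y, frag)
})

test_that("left-to-right resolution unlocks later windows for adjacent mismatches", {
  frag <- "ACGTACGTACGTACG"
  reads <- rep(frag, 6)
  x <- frag
  substr(x, 7, 7) <- "A"; substr(x, 8, 8) <- "C"  # true bases G, T
  y <- frag
  tab <- build_kmer_table(c(reads, x, y), 4)
  r <- context_pass(x, rep(30, 15), y, rep(30, 15), b = 1, tab,
                    merge_params(k = 4))
  expect_identical(r$x, frag)
  # after resolving, a second pass changes nothing (idempotence)
  r2 <- context_pass(r$x, r$qx, r$y, r$qy, b = 1, tab, merge_params(k = 4))
  expect_identical(r2, r)
})

test_that("a huge delta routes every mismatch to the context pass", {
  set.seed(33)
  frag <- rand_seq(30)
  x <- frag; substr(x, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                          substr(frag, 20, 20))[1]
  qx <- rep(40, 30); qy <- rep(2, 30)
  r <- quality_pass(x, qx, frag, qy, b = 1, delta = 1000)
  expect_identical(r$x, x)   # untouched despite the 38-point gap
  expect_identical(r$y, frag)
})

test_that("quality weighting scales each side's counts by its error probability", {
  tab <- build_kmer_table(c(rep("G", 100), "C"), 1)
  # unweighted: forward count 100 beats reverse count 1
  v <- collect_context_votes("G", "C", 1, 1, tab, k = 1)
  expect_identical(v$vote, "forward")
  # weighted with qx = 40 (p = 1e-4) and qy = 10 (p = 0.1):
  # 100 * 1e-4 = 0.01 < 1 * 0.1, so the vote flips to reverse
  v <- collect_context_votes("G", "C", 1, 1, tab, k = 1,
                             qx = 40, qy = 10, quality_weighted_vote = TRUE)
  expect_identical(v$vote, "reverse")
  # equal qualities: weighting cannot change any vote
  set.seed(34)
  for (rep in 1:50) {
    k <- sample(1:4, 1)
    reads <- replicate(6, rand_seq(15))
    tab <- build_kmer_table(reads, k)
    x <- rand_seq(12); y <- rand_seq(12)
    i <- sample(1:12, 1); ip <- sample(1:12, 1)
    q <- sample(2:41, 1)
    v0 <- collect_context_votes(x, y, i, ip, tab, k = k)
    v1 <- collect_context_votes(x, y, i, ip, tab, k = k,
                                qx = rep(q, 12), qy = rep(q, 12),
                                quality_weighted_vote = TRUE)
    expect_identical(v0$vote, v1$vote)
  }
})

test_that("after both passes every overlap position agrees", {
  set.seed(35)
  refs <- simulate_references(3, 600, seed = 35)
  cfg <- sim_preset("harsh", n_pairs = 60, seed = 35)
  sim <- simulate_pairs(refs, cfg)
  yseq <- reverse_complement(sim$reverse$seq)
  yqual <- lapply(sim$reverse$qual, rev)
  tab <- build_kmer_table(c(sim$forward$seq, yseq), 17)
  params <- merge_params()
  checked <- 0
  for (i in seq_along(sim$ids)) {
    ov <- apply_giveup(find_best_overlap(sim$forward$seq[i], yseq[i],
                                         params$omega), params$gamma)
    if (ov$status != "accepted") next
    qp <- quality_pass(sim$forward$seq[i], sim$forward$qual[[i]],
                       yseq[i], yqual[[i]], ov$offset, params$delta)
    cp <- context_pass(qp$x, qp$qx, qp$y, qp$qy, ov$offset, tab, params)
    len <- min(nchar(cp$x) - ov$offset + 1, nchar(cp$y))
    expect_identical(substr(cp$x, ov$offset, ov$offset + len - 1),
                     substr(cp$y, 1, len))
    checked <- checked + 1
  }
  expect_gt(checked, 40)
})
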