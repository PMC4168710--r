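test_that("error-free simulation yields exact substrings of the fragments", {
  refs <- simulate_references(3, c(400, 500), seed = 51)
  cfg <- sim_config(n_pairs = 150, read_length = 80,
                    fragment_length_range = c(120, 150),
                    error_rate_start = 0, error_rate_end = 0,
                    quality_jitter = 0, seed = 51)
  sim <- simulate_pairs(refs, cfg)
  m <- sim$truth$fragment_length
  expect_identical(sim$forward$seq, substr(sim$truth$fragment_sequence, 1, 80))
  expect_identical(sim$reverse$seq,
                   reverse_complement(substr(sim$truth$fragment_sequence,
                                             m - 80 + 1, m)))
  # truth coordinates point back into the reference
  expect_identical(sim$truth$fragment_sequence,
                   unname(substr(refs[sim$truth$reference_id],
                                 sim$truth$fragment_start,
                                 sim$truth$fragment_start + m - 1)))
  # with zero error rate every quality is the clipped maximum
  expect_true(all(unlist(sim$forward$qual) == 41L))
})

test_that("identical config and seed reproduce the dataset byte for byte", {
  dir <- tempfile(); dir.create(dir)
  cfg <- sim_preset("harsh", n_pairs = 80, seed = 52, n_references = 2,
                    reference_length = 400)
  a <- simulate_dataset(file.path(dir, "a"), cfg)
  b <- simulate_dataset(file.path(dir, "b"), cfg)
  for (f in c("forward", "reverse", "truth", "refs"))
    expect_identical(readLines(a$paths[[f]]), readLines(b$paths[[f]]))
})

test_that("the per-position substitution rate follows the linear profile", {
  refs <- simulate_references(1, 2000, seed = 53)
  cfg <- sim_config(n_pairs = 20000, read_length = 100,
                    fragment_length_range = c(160, 190),
                    error_rate_start = 0.001, error_rate_end = 0.05,
                    quality_jitter = 0, seed = 53)
  sim <- simulate_pairs(refs, cfg)
  truth_fwd <- substr(sim$truth$fragment_sequence, 1, 100)
  obs <- matrix(unlist(strsplit(sim$forward$seq, ""), use.names = FALSE),
                nrow = 100)
  tru <- matrix(unlist(strsplit(truth_fwd, ""), use.names = FALSE), nrow = 100)
  rate <- rowMeans(obs != tru)
  p <- 0.001 + (0.05 - 0.001) * (0:99) / 99
  z <- abs(rate - p) / sqrt(p * (1 - p) / 20000)
  # per-position binomial tolerance with an allowance for testing 100
  # positions at once: ~0.3 excursions beyond 3 sd are expected by chance
  expect_lte(sum(z > 3), 3)
  expect_true(all(z <= 4))
})

test_that("qualities are consistent with the local error rate", {
  refs <- simulate_references(1, 2000, seed = 54)
  cfg <- sim_config(n_pairs = 20000, read_length = 100,
                    fragment_length_range = c(160, 190),
                    error_rate_start = 0.001, error_rate_end = 0.05,
                    quality_jitter = 0, seed = 54)
  sim <- simulate_pairs(refs, cfg)
  truth_fwd <- substr(sim$truth$fragment_sequence, 1, 100)
  obs <- matrix(unlist(strsplit(sim$forward$seq, ""), use.names = FALSE),
                nrow = 100)
  tru <- matrix(unlist(strsplit(truth_fwd, ""), use.names = FALSE), nrow = 100)
  err <- obs != tru
  q <- do.call(cbind, sim$forward$qual)
  # mean observed error within a factor of 2 of 10^(-Q/10) per Phred bin
  for (qq in unique(as.vector(q))) {
    sel <- q == qq
    if (sum(sel) < 5000) next  # skip sparsely populated bins
    ratio <- mean(err[sel]) / 10^(-qq / 10)
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(read_length = 100,
                          fragment_length_range = c(150, 200)),
               "< 2 \\* read_length")
  expect_error(sim_config(read_length = 100,
                          fragment_length_range = c(90, 150)),
               ">= read_length")
  expect_error(sim_config(error_rate_end = 0.8), "error_rate_end")
  refs <- c(ref1 = "ACGT")
  expect_error(simulate_pairs(refs, sim_config(n_pairs = 1)),
               "at least as long")
})
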