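# Brute-force reference implementations used as independent oracles, plus
# the published benchmark counts the metric module must reproduce.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T"), n_prob = 0) {
  b <- sample(alphabet, n, replace = TRUE)
  if (n_prob > 0) b[runif(n) < n_prob] <- "N"
  paste(b, collapse = "")
}

# naive k-mer counter: enumerate every window, drop those containing N
naive_kmer_counts <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  wins <- wins[!grepl("N", wins, fixed = TRUE)]
  if (!length(wins)) return(numeric(0))
  tab <- table(wins)
  structure(as.numeric(tab), names = names(tab))
}

naive_lookup <- function(counts, s) {
  if (grepl("N", s, fixed = TRUE)) return(0)
  v <- counts[s]
  if (is.na(v)) 0 else as.numeric(v)
}

# all-offsets overlap scan; strict-< update keeps the smallest offset
bf_best_overlap <- function(x, y, omega) {
  xv <- strsplit(x, "", fixed = TRUE)[[1]]
  yv <- strsplit(y, "", fixed = TRUE)[[1]]
  nx <- length(xv); ny <- length(yv)
  best <- list(offset = NA_integer_, overlap_length = NA_integer_,
               mismatch_count = 0L, mismatch_ratio = Inf,
               status = "no_valid_offset")
  if (omega < 1 || nx - omega + 1 < 1 || ny < omega) return(best)
  acgt <- c("A", "C", "G", "T")
  for (b in 1:(nx - omega + 1)) {
    len <- min(nx - b + 1, ny)
    xs <- xv[b:(b + len - 1)]
    ys <- yv[1:len]
    m <- sum(xs != ys & xs %in% acgt & ys %in% acgt)
    ratio <- m / len
    if (ratio < best$mismatch_ratio)
      best <- list(offset = b, overlap_length = len, mismatch_count = m,
                   mismatch_ratio = ratio, status = "accepted")
  }
  best
}

# window-by-window vote enumerator for one mismatch at (i, ip)
bf_votes <- function(x, y, i, ip, k, counts) {
  nx <- nchar(x); ny <- nchar(y)
  out <- data.frame(j = integer(0), forward_count = numeric(0),
                    reverse_count = numeric(0), vote = character(0),
                    stringsAsFactors = FALSE)
  for (j in 1:k) {
    if (i - k + j < 1 || ip - k + j < 1) next
    if (i + j - 1 > nx || ip + j - 1 > ny) break
    if (j > 1 && substr(x, i + j - 1, i + j - 1) !=
                 substr(y, ip + j - 1, ip + j - 1)) break
    cx <- naive_lookup(counts, substr(x, i - k + j, i + j - 1))
    cy <- naive_lookup(counts, substr(y, ip - k + j, ip + j - 1))
    vote <- if (cx > cy) "forward" else if (cy > cx) "reverse" else "none"
    out <- rbind(out, data.frame(j = j, forward_count = cx, reverse_count = cy,
                                 vote = vote, stringsAsFactors = FALSE))
  }
  out
}

# published per-tool merging benchmark: counts and the printed accuracy / F1
# (simulated datasets of 1e6 pairs; real 16S runs of varying size)
benchmark_rows <- local({
  r <- function(tool, dataset, total, merges, correct, accuracy, f1)
    data.frame(tool = tool, dataset = dataset, total = total, merges = merges,
               correct = correct, accuracy = accuracy, f1 = f1,
               stringsAsFactors = FALSE)
  rbind(
    r("context",   "A4", 1000000,  999936, 967842, 0.968, 0.984),
    r("cope",     "A4", 1000000,  262661, 241630, 0.242, 0.389),
    r("flash",    "A4", 1000000,  989960, 732040, 0.732, 0.845),
    r("pandaseq", "A4", 1000000,  991698, 807691, 0.808, 0.894),
    r("context",   "A5", 1000000,  999973, 997201, 0.997, 0.999),
    r("cope",     "A5", 1000000,  924634, 915981, 0.916, 0.956),
    r("flash",    "A5", 1000000,  999578, 977355, 0.977, 0.989),
    r("pandaseq", "A5", 1000000,  999101, 978527, 0.979, 0.989),
    r("context",   "S4", 1000000, 1000000, 960986, 0.961, 0.980),
    r("cope",     "S4", 1000000,  262107, 230595, 0.231, 0.375),
    r("flash",    "S4", 1000000,  999964, 697867, 0.698, 0.822),
    r("pandaseq", "S4", 1000000,  999976, 785919, 0.786, 0.880),
    r("context",   "S5", 1000000, 1000000, 997303, 0.997, 0.999),
    r("cope",     "S5", 1000000,  974219, 961366, 0.961, 0.980),
    r("flash",    "S5", 1000000,  999921, 977431, 0.977, 0.989),
    r("pandaseq", "S5", 1000000,  999947, 976701, 0.977, 0.988),
    r("context",   "C1",  716366,  713782, 667421, 0.932, 0.965),
    r("cope",     "C1",  716366,  603357, 572885, 0.800, 0.889),
    r("flash",    "C1",  716366,  688730, 601561, 0.840, 0.913),
    r("pandaseq", "C1",  716366,  693518, 590898, 0.825, 0.904),
    r("context",   "C2", 1350602, 1345759, 1233831, 0.914, 0.955),
    r("cope",     "C2", 1350602, 1105743, 1046420, 0.775, 0.873),
    r("flash",    "C2", 1350602, 1282916, 1101436, 0.816, 0.898),
    r("pandaseq", "C2", 1350602, 1298903, 1080593, 0.800, 0.889),
    r("context",   "PA",  673845,  671877, 658631, 0.977, 0.989),
    r("flash",    "PA",  673845,  660984, 634261, 0.941, 0.970),
    r("pandaseq", "PA",  673845,  660593, 635663, 0.943, 0.971))
})

# published quality-weighted-vote ablation: correct merges without / with the
# weighting and the printed percentage increase (6 decimal places)
qweight_rows <- data.frame(
  dataset = c("A4", "A5", "S4", "S5", "C1", "C2", "PA"),
  without = c(967842, 997201, 960986, 997303, 667421, 1233831, 658631),
  with    = c(967875, 997211, 960984, 997303, 667165, 1233012, 658648),
  increase = c(0.003410, 0.001003, -0.000208, 0.000000, -0.038357,
               -0.066379, 0.002581),
  stringsAsFactors = FALSE)

# small in-memory pipeline run + scoring, shared by trend tests
run_and_score <- function(sim, params, table = NULL) {
  r <- merge_read_pairs(sim$forward, sim$reverse, ids = sim$ids,
                        params = params, table = table)
  score_merges(r$merged_seq, r$id, sim$truth)
}
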