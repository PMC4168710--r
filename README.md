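# contextmerge

Merging the forward and reverse reads of overlapping paired-end sequencing
fragments into virtually elongated reads, for high-coverage amplicon data
(e.g. 16S rRNA surveys) where read ends — and therefore the overlap — are
noisy.

For a fragment of length *m* read from both ends with reads of length *n*
(*m* < 2*n*), the reverse read is reverse-complemented into *Y* and slid
against the forward read *X*; the offset *b* minimizing the overlap mismatch
ratio is kept (minimum overlap ω, give-up threshold γ on the ratio).
Mismatches inside the overlap are then resolved in two passes:

1. **quality pass** — if the Phred scores differ by more than δ, the
   higher-quality base (and its score) overwrites the other;
2. **context pass** — otherwise up to *k* sliding k-mer windows covering
   the mismatch are compared between the two reads via an exact k-mer count
   table *T<sub>k</sub>* built from the whole input, each window voting for
   the side whose context is more frequent:

   d<sub>j</sub> = 1 if T<sub>k</sub>[X(i−k+j : i+j−1)] >
   T<sub>k</sub>[Y(i′−k+j : i′+j−1)], else 0,

   with the final call the majority vote (a 0.5-thresholded linear opinion
   pool); ties go to the reverse read.

The merged read is X(1 : b−1) followed by the corrected *Y* (length
b − 1 + n). Defaults: k = 17, ω = 10, γ = 0.5, δ = 19.

The package also ships a paired-end amplicon read **simulator** (linear
5'→3' substitution-rate profile with matching Phred qualities, known truth)
and the **evaluation metrics** (accuracy, precision, recall, F1 with
TP = correct merges, FP = incorrect merges, FN = unmerged pairs), so the
whole method is testable end to end without external data.

## Worked example

Simulate 2,000 noisy pairs (per-base error rising from 10⁻⁴ at the 5' end
to 1.5% at the 3' end), merge them, and score against the known fragments:

```r
library(contextmerge)

cfg <- sim_preset("harsh", n_pairs = 2000, seed = 1)
ds  <- simulate_dataset(tempfile("sim"), cfg)
run <- merge_fastq(ds$paths$forward, ds$paths$reverse, tempfile("run"))
run
#> run_summary: 2000 pairs, 2000 merged, 0 abandoned, 0 without valid offset (0.64 s)

ev <- evaluate_merged(run$paths$merged, ds$paths$truth)
ev$counts
#> eval_counts: 2000 total, 2000 merged, 817 correct
round(unlist(ev$metrics), 4)
#>  accuracy precision    recall        f1
#>    0.4085    0.4085    1.0000    0.5800
```

Every pair merges (all true overlaps are ≥ 10 bp and γ = 0.5 is permissive);
a merge counts as *correct* only when the elongated read equals the true
fragment exactly, so accuracy is bounded by the substitution errors that
fall **outside** the overlap and cannot be repaired by any merger — see the
methods vignette (`vignettes/context-aware-merging.Rmd`) for that ceiling
and for the parameter response. Individual steps are exposed too:

```r
find_best_overlap("AAAATTTT", "TTTTCCCC", omega = 4)
#> overlap_result: offset 5, length 4, 0 mismatches (ratio 0), accepted
```

A shell interface covering `simulate`, `merge` and `evaluate` is installed
at `system.file("scripts", "contextmerge", package = "contextmerge")`:

```sh
contextmerge merge --forward R1.fastq.gz --reverse R2.fastq.gz --out run \
    -k 17 --min-overlap 10 --giveup 0.5 --delta 19 --threads 4
```

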