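---
title: "Context-aware merging of overlapping paired-end reads: methods and design"
author: "contextmerge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware merging of overlapping paired-end reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextmerge)
```

## The problem

In paired-end sequencing a DNA fragment of length $m$ is read from both
ends, giving a forward read $X$ and a reverse read $W$, each of length $n$.
When $m < 2n$ the two reads overlap, and merging them yields a virtually
elongated read covering the whole fragment — valuable for amplicon studies
(e.g. 16S rRNA surveys), assembly and mapping. The difficulty is that
base-calling error rates rise sharply toward the 3' end of a read, which is
exactly where the overlap sits, so the two reads frequently disagree inside
the overlap and the disagreements must be resolved base by base.

Most mergers resolve a mismatch by keeping the base with the higher Phred
quality ($Q = -10\log_{10} p$, $p$ the probability the call is wrong). That
works when the two qualities differ a lot; when they are similar, the higher
score carries almost no information and quality-only resolution degenerates
into a noisy coin flip. This package implements a context-aware scheme: a
quality decision where the score difference is decisive, and otherwise an
ensemble vote over k-mer contexts drawn from the entire input.

## The procedure

Five steps, the first two over the whole input, the rest per pair:

1. **Preprocessing.** Each reverse read $W$ is reverse-complemented into
   $Y$ ($y_i = \bar w_{n-i+1}$, qualities reversed) so both mates run along
   the same fragment strand.
2. **k-mer table.** An exact table $T_k$ counts every k-length window over
   $\{A,C,G,T\}$ in all preprocessed reads (forward and reverse pooled —
   after step 1 the two mates are replicates of the same strand, which is
   why a single table is used). Windows containing `N` are skipped;
   counting is non-canonical. The implementation packs k-mers two bits per
   base into a 64-bit word (hence $k \le 31$) inside a C++ hash map;
   correctness does not depend on the packing.
3. **Overlap search.** For each candidate offset $b \in [1, n-\omega+1]$ the
   mismatch ratio (mismatching positions / overlap length) is computed, and
   the smallest ratio wins; the update is a strict improvement, so ties keep
   the smallest $b$, i.e. the longest overlap. If the best ratio exceeds the
   give-up threshold $\gamma$ the pair is left unmerged.
4. **Mismatch resolution**, two left-to-right passes over the overlap:
   * *Quality pass.* If the two qualities differ by more than $\delta$, the
     higher-quality base and its quality overwrite the other read's. If
     exactly one base is `N`, the informative base wins regardless of
     $\delta$; two `N`s are skipped.
   * *Context pass.* Each remaining mismatch at $(i, i')$ is judged by up to
     $k$ progressively shifted windows of length $k$ covering it. Window $j$
     compares $T_k[X(i-k+j:i+j-1)]$ against $T_k[Y(i'-k+j:i'+j-1)]$ and
     casts a vote for the side with the larger count. The final call is the
     0.5-thresholded linear opinion pool — a majority vote — with ties and
     empty vote sets going to the reverse read. Windows that underrun the
     left boundary of either read are skipped; the scan stops at the right
     boundary of either read, or at the first window whose rightmost
     position is itself a still-unresolved mismatch (those bases may be
     wrong). Because resolution proceeds left to right, bases to the left of
     the current mismatch are already consistent between the reads, so
     corrected bases feed later windows.
5. **Merge.** The elongated read $Z$ takes $X(1:b-1)$ followed by the full
   corrected $Y$; its length is $b - 1 + n$ (equal-length mates), i.e. the
   fragment length $m = 2n - \text{overlap}$. Overlap positions keep the
   post-resolution reverse-read qualities; qualities untouched by
   resolution remain unchanged; positions that stayed `N` on both reads are
   written as `N` with quality 0.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `k` | 17 | bp | context window size; 17 is a common assembly choice, and accuracy plateaus well below it on amplicon-scale fragments |
| `omega` | 10 | bp | minimum admissible overlap length |
| `gamma` | 0.5 | — | give-up threshold on the overlap mismatch ratio (strictly greater abandons) |
| `delta` | 19 | Phred | quality differences of at most `delta` are routed to the context pass |

`quality_weighted_vote` (default off) scales each side's window count by
that side's base *error* probability $10^{-Q/10}$ before each comparison.
This direction — weighting by error rather than correctness probability —
is implemented literally as the variant is described; with equal qualities
it reduces to the unweighted vote, and in practice it changes very few
decisions. It is exposed as an ablation flag, not a recommended setting.

## What the simulator emulates

`simulate_pairs()` generates the regime the merger is designed for:
high-coverage amplicon sequencing. Defaults: 23 random references of
1500 bp, fragments of 160–190 bp drawn uniformly, read length 100, so true
overlaps span 10–40 bp; substitution-only errors (indels are rare on the
Illumina-style platforms this models and are out of scope) whose per-base
probability rises **linearly** from the 5' to the 3' read end; per-base
qualities equal to the Phred score implied by the local error rate, plus a
uniform integer jitter in $[-j, j]$, clipped to $[2, 41]$.

Two presets fix the error regime:

* `"harsh"`: $10^{-4} \to 0.015$ (≈ Q40 at the 5' end decaying to ≈ Q18),
  jitter 3 — a noisy early-platform profile under which merging is
  genuinely hard;
* `"mild"`: $5\times10^{-5} \to 0.005$ (≈ Q23 at the end), jitter 2.

These rates were chosen once, as follows. Evaluation counts a merge as
correct only when the merged read equals the true fragment *exactly*, and
errors outside the overlap can never be repaired by merging; with a linear
profile the expected number of such residual errors is roughly
$2\,(75\,p_{5'} + 28\,(p_{3'}-p_{5'}))$ for the default geometry, so
accuracy is capped near $e^{-E}$ no matter how well the overlap is
resolved. End rates much above ~2% therefore make *every* configuration
score near zero and would leave nothing to compare; the chosen harsh rates
put the ceiling near 0.5 while still producing ~1 overlap mismatch per pair
(about 60% of pairs carry at least one), which is where the quality-pass /
context-pass interplay is actually exercised.

Features of real data the simulator does **not** model: indels, chimeric
fragments, PCR duplicates, motif-dependent errors, quality-model
miscalibration, adapter read-through. Passing tests therefore demonstrate
algorithmic correctness and the expected parameter response on an idealized
error model, not field performance on any particular instrument.

## Numerical and design choices

* **Tie-breaking** in the overlap search is the strict-improvement update:
  earliest offset (longest overlap) wins ratio ties. Deterministic, and
  important because ratio ties across different overlap lengths are common.
* **`N` handling**: `N` never counts as a mismatch in the ratio numerator
  (the denominator stays purely positional); k-mer windows containing `N`
  are neither stored nor looked up (count 0); a one-sided `N` in the
  overlap is overwritten by the informative base during the quality pass.
* **Boundary checks** in the context pass apply to *both* reads' windows,
  although only the forward-read check is usually written out: the
  reverse-read index can underrun even when the forward index is valid.
* **Ties and empty vote sets** go to the reverse read — the else-branch of
  the voting step; no randomization anywhere in the merge path, which gives
  byte-identical outputs across repeated runs and any worker count
  (parallelism is an optional `mclapply` over ordered sub-batches).
* **Unequal read lengths** are supported by generalizing the index
  arithmetic: candidate offsets are $[1, n_X - \omega + 1]$ and the overlap
  length is $\min(n_X - b + 1, n_Y)$; for equal lengths this reduces to the
  standard formulas.
* **Degenerate inputs**: empty files produce valid empty outputs; reads
  shorter than $\omega$ give status `no_valid_offset`; merge failures are
  statuses, never errors.
* The per-decision error bound $\varepsilon_j = \min(P\{X(i)\mid C_j\},
  P\{Y(i')\mid C_j\})$ that motivates the Bayesian decision rule is never
  needed operationally and is not computed.

## Problem sizes used in the checks

The shipped tests run the full pipeline on 10,000 simulated pairs for the
error-free reconstruction check (100% merged, 100% exact), 10,000-pair
harsh-regime sweeps for the $\delta$/$\gamma$/$\omega$ response, 10,000
random pairs against a brute-force all-offsets overlap oracle, and 1,000
constructed mismatches against a brute-force window enumerator. These sizes
keep the whole suite around a minute on one core while leaving the
stochastic assertions with comfortable margins (binomial SE
$\approx 0.005$ on an accuracy at $n = 10^4$).

Because short overlaps can match by chance (probability $\sim 4^{-L}$ for
an overlap of length $L$), lowering $\omega$ below ~10 admits rare spurious
best overlaps; the $\omega$ sweep therefore asserts a spread below 0.01
rather than exact equality, and the $\delta$ sweep asserts a non-decreasing
trend (within binomial noise) followed by a plateau.

## Known limitations

* Substitution-only: indel sequencing errors shift the overlap and are not
  recognized.
* Non-overlapping pairs (fragment longer than $2n$) are out of scope; they
  surface as abandoned pairs.
* The k-mer context is informative in proportion to coverage; on
  low-coverage whole-genome data the vote degenerates toward the
  reverse-read tie-break.
* Overlap search and resolution run once, in that order; a suboptimal
  overlap is never revisited after correction.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_preset("harsh", n_pairs = 2000, seed = 1)
ds <- simulate_dataset(tempfile("sim"), cfg)
run <- merge_fastq(ds$paths$forward, ds$paths$reverse, tempfile("run"))
run
evaluate_merged(run$paths$merged, ds$paths$truth)$metrics
```
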