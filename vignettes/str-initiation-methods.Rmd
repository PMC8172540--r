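---
title: "Methods: quantifying and modelling transcription initiation at STRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and modelling transcription initiation at STRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the statistics it
computes, the model it fits, the choices that were genuinely open, and what
the synthetic-data tests do and do not establish.

## Coordinates and orientation

All interval storage is BED-style 0-based half-open; human-facing 3'-end
coordinates are 1-based, converted only at the reporting boundary. One
internal convention avoids an entire class of off-by-one errors; the
worked consequence is that an STR stored as `[10001, 10468)` has 3' ends
10468 on the (+) strand and 10002 on the (−) strand.

STR catalogs are (+)-strand normalized, so each locus is evaluated in both
orientations: the (−) orientation reads the reverse-complement motif
(which is also its class key) and anchors at the first catalog base. This
near-doubles the records per class and is what makes directionality
scoring well-defined.

## The initiation-signal statistic

For coverage `cov` (1-bp binned mean tag counts, one strand) and an STR of
length $L$,

$$S = \frac{\sum_{p \in [start-5,\; end+5)} cov[p]}{L + 10}.$$

The window is the STR extended by 5 bp on each side — 10 extra bases,
which fixes the denominator — and is clipped at chromosome edges while the
nominal denominator is retained. Low scattered counts (single tags) occur
along repeat bodies and would otherwise make raw sums grow with $L$;
dividing by the window length makes $S$ equal to the mean per-base
coverage, so a uniform track of height $c$ scores exactly $c$ at any
length. That invariance is asserted in the test suite.

Directionality is $D = (S^+ - S^-)/(S^+ + S^-)$. The score is computed
whenever either strand has signal and marked undefined only when both are
zero; restricting it to loci with signal on *both* strands would make the
boundary values $\pm 1$ — which are meaningful, strictly-one-strand
observations — unrepresentable. Binomial proportions are given Wilson 95%
intervals (the interval type was an open choice; Wilson behaves well at
the small per-class counts and at 0/1 fractions).

## Cap validation

Reverse transcription of the 5' cap adds a template-mismatched G at the 5'
end of a tag. On the (+) strand this shows as an MD descriptor starting
with a zero-length match (`MD:Z:0...`); on the (−) strand, symmetrically,
as a descriptor ending in a substitution. Both are handled; a strict
plus-only mode reproduces the one-liner form of the check. Records with
indels in the descriptor, or flags other than 0/16, are skipped and
counted rather than guessed at. Whether the mismatch fraction should be
reported over all intersecting tags or over mismatched tags only was
ambiguous; the report carries both.

## The sequence-to-signal network

Input is a one-hot 4×101 matrix (rows A, C, G, T; `N` and masked bases are
zero columns) centered on the 3'-end base — "centered" is pinned to
*center column = the 3'-end base*, which makes interpretation offsets
(e.g. a −15/+30 window) well-defined relative to column 51. The default
architecture is one convolution stage of **50 filters × 12 bp**, rectifier
activation, max-pooling of width 4, fully-connected stages of 64 and 16
units with **dropout 0.30**, and a single output unit — linear for signal
regression, sigmoid for pairwise classification; the two tasks differ only
in that unit, so parameter counts match. Loss is mean squared error /
binary cross-entropy, optimized by Adam (learning rate 1e-3, batch 256) for
at most 100 epochs with **early stopping at patience 5**: training stops
after five consecutive epochs without improvement on the best validation
loss, and the best-validation weights are kept. The literal reading of
"stop when the validation loss drops" would halt exactly when learning
works; patience-on-no-improvement is the only sensible interpretation and
is what is implemented.

The engine (im2col convolution, pooling with tie-sharing subgradients,
backpropagation, Adam) is written in vectorised base R with examples
stored column-wise so the hot path is plain BLAS matrix multiplication;
backpropagation is verified against numerical gradients to ~1e-10.
Training is bit-reproducible given the seed. Models persist as a
versioned JSON archive of spec + weights; no foreign-format compatibility
is promised.

Splits are seeded 70/15/15 (fractions were an open choice; these are
conventional and configurable) with largest-remainder rounding, persisted
through a manifest that reproduces the identical partition. Identical
windows are *not* deduplicated before splitting. For pairwise
classification the majority class is seeded-downsampled to the minority
size, since plain AUCs are reported without class weighting.

Regression targets default to the natural signal scale — the 0.2
prediction-error threshold used downstream lives on that scale — with a
`log1p` training transform available as a config switch, stored in the
model and inverted at prediction time. The analysis and acceptance runs
use `log1p`: the signal is lognormal-like, squared error on the log scale
is better conditioned, and every downstream quantity used here (Spearman
ρ, delta signs) is monotone-invariant while error stratification is
computed on the natural scale after back-transformation.

### Masking layouts

* `downstream7`: the 7 bases immediately 3' of the STR end become `N` —
  they can contain repeat bases, a trivially learnable give-away for
  classification.
* `flank_only`: 50 bp upstream flank + 9 `N` (the whole repeat, regardless
  of its true length) + 7 `N` + 43 bp downstream flank = 109 positions,
  with the `N` block exactly at positions 51–66. The upstream flank is
  taken upstream of the STR 5' boundary (not of the window), so long STRs
  do not leak repeat sequence into the "flank".

## Interpretation

Filter influence ablates one first-layer filter at a time — its activation
map is zeroed, with no retraining and no renormalization — and recomputes
the test metric; influence = baseline − ablated. A filter whose ablation
leaves a constant predictor has an undefined rank metric, which is scored
0. The chance-level threshold retrains the model $k$ times (reference
protocol: 10), takes the **t-based 95% CI of the mean accuracy** (the
interval type was unstated; the t-interval is the standard choice at
$n = 10$) and sets $\tau = \log_2(\text{CI length}/2)$, reading "CI
length" as the full interval width. Influences are reported raw and as
log2 with non-positive values floored at a configurable epsilon.

PWMs are column frequencies with pseudocount 0.5 and log-odds against a
uniform background; scanning keeps the per-sequence maximum with `N`
contributing zero. No p-value machinery is reproduced — downstream use
needs only per-sequence max scores.

Random mutagenesis draws positions uniformly over the window and
alternative bases uniformly over the three non-reference bases; deltas
(reference − mutated) are pooled by position relative to the 3'-end column
and summarized by variance. Draws are keyed to (seed, window content), so
the pooled profile is exactly invariant to input order. Positional
distributions are compared with the two-sample KS test on raw offsets.

## Variant analyses

Only SNVs are scored (indels would unalign the windows; they are counted
and reported). Alleles are given on the (+) strand; (−) orientations see
the complement automatically through reverse-complemented window
extraction. Reference-allele mismatches against the genome are flagged and
skipped — on self-generated data this rate is exactly zero, which the
suite asserts. The eQTL concordance pipeline keeps STRs within 1 kb of a
gene start, keeps eQTL SNVs within −15/+30 bp of the 3' end in transcript
orientation, compares `sign(predict(alt) − predict(ref))` with the slope
sign, stratifies by reference-genome prediction error at 0.2 (natural
scale), and applies a binomial test against 0.5 per stratum — one-sided by
default, since the claim under test is directional excess concordance;
two-sided is available. Cases are deduplicated on (variant, STR, gene).
Benjamini–Hochberg is used wherever an "fdr" adjustment is called for.

## The synthetic world

The generator exists to give every stage a ground truth. Expected signal
is $\exp(\mu)$ with

$$\mu = \text{baseline}(\text{class key}) + \sum_m \beta_m \,
        \mathbf{1}[\text{motif } m \text{ in window}],$$

observed signal multiplies it by $\exp(\mathcal N(0, \sigma^2))$,
$\sigma = 0.3$, and unit counts scatter along the repeat body at 0.02/bp —
emulating the single-tag noise seen along real repeats. Coverage mass is
deposited in five bins around the 3' end (weights .6/.15/.1/.1/.05 at
transcript offsets 0/−1/+1/−2/+2). Because $\mu$ is a function of the
window sequence and class key only, the Bayes-optimal predictor is
available in closed form (`bayes_predictor()`), and with zero noise and
zero scatter the quantified signal equals the truth table exactly — both
are asserted.

Design choices, each made once:

* **Scale.** Baselines (AC −0.5, AT −1.2, AG −0.9, AAAG −1.6 on the log
  scale; −3.3 for unlisted antisense keys) put expected signals at
  O(0.03–1), where a natural-scale error cut of 0.2 is a meaningful
  stratifier, as it is on real CAGE signal.
* **Directionality by construction.** AC/AG/AAAG read a low-baseline
  antisense key (directional); AT is its own reverse complement
  (balanced). The two planted effect motifs (`TTATATAA`, +1.5 at offset
  −45; `ACGCGCGT`, −1.2 at offset +20) are reverse-complement palindromes,
  so both orientations of a locus see them and directionality remains a
  pure class property.
* **Flank composition.** Class-specific base composition (GC 0.62 / 0.38 /
  0.50 / 0.50) in the ±50 bp flanks makes flank-only classification
  learnable for distinct pairs and chance-level for the identically
  generated AG/AAAG pair. This is a base-composition bias, not a full
  dinucleotide chain — one acknowledged simplification.
* **Geometry.** 20,000 STRs of length 12–36 bp on 2 × 1.8 Mb (slot-based
  placement so flanks never collide), motif instances planted at fixed
  offsets so positional attribution is testable.
* **Variants.** 70% of generated variants target planted downstream-motif
  instances (the motif inside the −15/+30 eQTL window); the rest follow
  $P(o) \propto e^{-|o|/10}$. Slopes equal the closed-form effect; a
  variant with zero expression effect is, by definition, not an eQTL and
  carries an `NA` slope.

What passing on this world shows — and what it does not: recovery of a
planted, additive, motif-driven signal demonstrates that the
quantification, encoding, training, interpretation and concordance
machinery is correct end to end. Real CAGE data have mappability
artifacts, cell-type structure, correlated noise, repeat-induced
multi-mapping and regulatory grammar far beyond additive motifs; no test
here speaks to those.

## Problem sizes and numerical choices

The analysis drivers use a 6,000-STR world (2 × 550 kb); the acceptance
run uses the 20,000-STR default, trains on a 12,000-example subsample for
at most 15 epochs, evaluates on the full 6,000-example test split, and
runs each null (label-shuffled) model for fewer epochs — sizes chosen so
the whole study runs in minutes on one CPU while the held-out ρ sits
within ~0.1 of the Bayes ceiling. Other numerics: early-stopping
improvement tolerance 1e-12; pooled max-gradients shared equally among
ties; dropout masks are inverted (scaled at train time); the mean is the
first validation epoch's loss reference; window extraction skips and logs
loci whose window leaves the chromosome.

## Known limitations

* The signal statistic consumes a single (mean) track; per-library
  matrices are out of scope.
* The CNN is deliberately small and cell-type agnostic; no GPU path, no
  attribution methods beyond ablation and mutagenesis.
* `shuffle_intervals` matches the semantics of length-preserving excluded
  placement, not any external tool's random stream.
* BigWig and BAM are not parsed; bedGraph and SAM text are the contracts,
  with conversion left to standard tooling.
* Filter–PWM correlation is informative when a filter specializes; with
  50 redundant filters the representation is distributed and single-filter
  ablation effects are small — the influence threshold exists precisely to
  make that honest.
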