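---
title: "Methods: models and design choices behind ncatsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices behind ncatsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncatsr)
```

This vignette is the package's own account of what it computes and why the
open design choices were resolved the way they were. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## What the pipeline models

Nanopore Cas9-targeted sequencing (nCATS) enriches a small panel —
here the *MGMT* promoter/exon-1/intron-1 CpG island region and the *IDH1*
and *IDH2* exon-4 hotspots — without amplification, so native
5-methylcytosine survives to be read directly from the current signal.
This package starts where signal-level tools stop: its inputs are per-read,
per-CpG log-likelihood ratios (LLRs) for methylation, base-count pileups at
the variant loci, and qRT-PCR Ct tables. Basecalling, alignment and the
signal-level HMMs themselves are out of scope; their *outputs* are the
modelled interface, which is what the synthetic generators emulate.

## Methylation aggregation

A call with LLR `l` is treated as follows (`meth_filter_params()`):

* `|l| < llr_cutoff` (default **2.5**, natural-log units): ambiguous. The
  call is removed from both numerator and denominator. A site-level
  mean-LLR reading of the same cutoff was rejected because it would leave
  "frequency = methylated/called" ill-defined; the per-call magnitude
  filter matches the semantics of the frequency-aggregation scripts that
  accompany signal-level callers.
* qualifying and `l > 0`: methylated; qualifying and `l < 0`: unmethylated.
* a site is reported only with at least `min_reads` (default **10**)
  qualifying calls. The depth gate counts *reads*, while
  `called_sites` accumulates `num_motifs` per qualifying read so that a
  call spanning a CpG group contributes its state once per motif.

Strand handling: CpGs are palindromic and 5mC is symmetric, so both strands
are one site, keyed by the position of the plus-strand C (0-based
internally; 1-based only in rendered reports). Panel CpG numbering starts
at 1 from the 5′ end of the captured interval, so the literature numbering
of the *MGMT* island is reproduced by configuring the captured interval,
not by hard-coding genome coordinates — which genomic CpG is
"literature CpG #1" therefore stays a configuration concern.

The clinical three-bin readout is `< 10%` → not detected, `10–30%`
(both edges inclusive) → low, `> 30%` → detected. The band edges follow
the strict `<`/`>` phrasing of the outer bins; edge membership is exposed
as an argument (`boundaries`) rather than hard-coded.

Read QC (`qc_filter_reads()`) passes a read iff mean quality
strictly exceeds Phred 8 **and** length strictly exceeds 200 bases; the
mean is taken on the error-probability scale,
$-10\log_{10}\overline{10^{-Q/10}}$, the convention of long-read QC tools.
A read of uniform Q8 therefore fails.

## The synthetic LLR model

Per-read calls are simulated as a signed Gaussian (`llr_model()`): a truly
methylated call draws magnitude $|N(\mu_m, \sigma)|$ with positive sign, an
unmethylated call $|N(\mu_u, \sigma)|$ with negative sign, and the sign is
flipped with probability `miscall_rate`. Positive LLR is evidence for 5mC,
matching the sign convention of the callers whose output is filtered at
2.5. Defaults — $\mu_m = \mu_u = 4$, $\sigma = 1.5$, miscall 0.03 — were
chosen once so that the simulated assay behaves like a usable real one:
roughly 84 % of calls clear the 2.5 cutoff, so 10–20X yields measurable
frequencies with visible replicate dispersion, fully methylated /
unmethylated controls aggregate near 95 % / 5 %, and depth 5 cells fall
below the read gate entirely. Real standards' LLR distributions were not
estimated from deposited raw data; the model is a modelling choice, and
every parameter is overridable.

Reads are simulated per site, with `read_name` linking the calls of one
molecule across the sites of a region; no read-length or quality model is
attached because the downstream consumers only use per-site call sets.

## Standards, panel and pileups

`generate_standard()` builds the control-molecule geometry exactly: a
897-bp sequence with 52 disjoint CG dinucleotides by default, placed
uniformly at random among feasible disjoint slots (the stars-and-bars
bijection), seeded; free bases are filled so that no accidental CG arises.
The generators only receive CpG *counts*, not positions, so uniform seeded
placement is the neutral choice.

`generate_panel()` applies the same construction per subregion: 98 CpGs in
a 1500-bp promoter/exon-1 portion and 121 in a 2000-bp 5′ intron-1 portion
of one *MGMT* region, plus 300-bp IDH exon-4 amplicons. Region lengths are
not dictated by the assay's published coordinates; they were fixed once at
values giving realistic CpG densities (island-like ~6.5/100 bp for MGMT).
Planted motifs pin the biologically meaningful contexts: `CGT` at the
IDH1 codon-132 offset (its C→G substitution is the R132G allele), `AGG` at
IDH2 codon 172 (G→A gives R172K), and a `GGGGGG` run inside *MGMT*
mirroring the 6-guanine homopolymer that makes one assayed locus
error-prone on current pores.

`simulate_pileup()` corrupts `depth` reads per column with an
`error_profile()`: substitutions at `sub_rate` (default 0.05), uniform over
the three other bases, inflated by `homopolymer_sub_multiplier` inside runs
of ≥ 5 identical bases; deletions remove a read from the column; insertions
do not alter column counts (a pileup column only carries A/C/G/T counts, so
indel reads either vanish from it or contribute their base as usual).

## Limit-of-detection titration

Mixtures are assembled per CpG by drawing `round(p·d)` calls without
replacement from the 100 % pool and the rest from the 0 % pool. The
replicate statistic is the mean frequency across all reported CpGs — the
titration summarises a standard, not a single site; a per-CpG pooling is
available by working with the replicate table directly. Because the mixture
composition is exact by construction, replicate dispersion comes from
miscalls and the qualifying filter, so the simple binomial closed form
$\mathrm{CV} \approx \sqrt{(1-p)/(p\,d)}$ is an upper-bound-shaped
reference: the tests check that observed CV falls with depth as that oracle
predicts (monotone trend), not that it equals it.

Distinguishability uses two-sided **Welch** t-tests — variances differ
strongly across levels, and the unequal-variance form is the conservative
reading of an unspecified "pairwise t-test" — with Bonferroni correction
over the 10 pairs of the canonical levels {0, 25, 50, 75, 100} %. The 10 %
mixture is titrated but excluded from that family, since the
distinguishability claim is stated for the five canonical levels; its
pairs are reported with raw p-values. Replicates use independent RNG
streams fanned out from one master seed, so a full titration is
bit-reproducible. Cells whose replicates all fall below the read gate are
marked unusable rather than dropped silently, and CV is undefined (missing,
never 0) when the cell mean is 0.

## Diploid genotyping

The signal-level re-evaluation a nanopore variant caller performs is
replaced by a base-count binomial model, which suffices because the
quantities consumed downstream are genotype and allele fraction only.
Gates come first: columns under `min_candidate_depth` (10) are no-calls
with a reason code; the most frequent non-reference base is a candidate
only at frequency ≥ `min_candidate_frequency` (0.15). The genotype is then
$\arg\max_{g \in \{0/0,\,0/1,\,1/1\}} \mathrm{Bin}(k \mid n, p_g)$ with
$p_g \in \{e, \tfrac12, 1-e\}$, $e = \text{error\_rate}/3$ directed at the
candidate alt; priors are uniform, `error_rate` defaults to 0.05 as a
generic long-read substitution rate, and the call's quality is the
log-likelihood margin to the runner-up. Note the gates and the likelihood
are separate: an alt at exactly 15 % passes the candidate gate yet is still
called 0/0 when the likelihood favours it. Indels and multi-allelic sites
are out of scope (the panel's targets are SNVs).

Methylation-awareness: at a known panel CpG, C→T (and reverse-strand G→A)
candidates are excluded, since 5mC-induced miscalls concentrate there.
The homopolymer flag (within or immediately adjacent to a run of ≥ 5) is
advisory metadata mirroring the known error hotspot — it never suppresses
a call. Somatic classification is the four-way contract
somatic / germline / absent / inconsistent from a tumor/normal genotype
pair, and cross-platform allele-frequency agreement is a plain Pearson
chi-squared on the 2×2 ref/alt count table without continuity correction.

## Expression association

Relative expression is $2^{-\Delta Ct}$ with
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{ACTB}$, averaging the
technical triplicates on the Ct scale. The normalization formula is the
standard relative-quantification choice; correlations are taken against
log2 expression because that is the scale on which the planted cohort model
is linear (raw-scale correlation is available via `log2_expression =
FALSE`). Per-CpG Pearson r uses pairwise-complete observations with a
minimum of 4 pairs; zero-variance CpGs are flagged, never selected.
Selection is strictly `|r| > 0.7`; no multiple-testing correction is
applied because selection is on r, not p — p-values are reported for
transparency only.

Clustering is agglomerative on Euclidean distance with average linkage,
the common heatmap default (linkage is an argument; the planted-block tests
also verify single linkage gives the same 2-cut). Leaf ordering is the
deterministic `hclust` order with ties broken by input order.

The cohort generator plants the structure the locus shows across samples:
sample-level exon-1 and intron-1 methylation means drawn U(0.05, 0.95),
per-CpG jitter (sd 0.05), and log2 expression
$= 2 - 3\,m_{exon} + 3\,m_{intron} + N(0, 0.75)$ by default, over 12 exon
and 34 intron CpGs (the counts the clustering analysis works with). These
defaults were fixed once to produce aggregate correlations of magnitude
around 0.6 — the realm reported for small glioma cohorts — and are the
conditions under which the sign-recovery tests run; they were not revisited
afterwards.

## Numerical and degenerate-input choices

* Ambiguity and emptiness are signalled, not coerced: an empty site list
  gives an empty call table; a window with no reported site gives an `NA`
  mean with `n_sites_used = 0`, distinct from 0.0; a chi-squared with a
  zero margin, a zero-variance aggregate correlation, and a distance over
  an all-missing pair are errors.
* Welch tests with zero variance in both groups (the noiseless degenerate
  case) are resolved exactly: p = 1 for identical means, 0 otherwise.
* Bonferroni is `min(1, raw × n_pairs)` over the explicit claim family.
* Ties in the candidate-alt choice break deterministically in base order
  A < C < G < T; `which.max` semantics are pinned by the oracle tests.
* All stochastic entry points take a seed and restore the caller's RNG
  state; one master seed fans out to child streams
  (`sample.int(2^31 - 1, n)`) so stages are independently reproducible.

## Scale of the shipped analyses

The test suite and acceptance script run the titration at 100 replicates
per (level, depth) cell over depths {5, 10, 15, 20, 25, 50} and six levels
with 52-CpG standards and 200-deep pools; genotype recovery uses 1000
seeded trials at depth 60; association recovery uses 200 cohorts of 50
samples. These sizes were chosen so a full run completes in a couple of
minutes on one CPU while keeping Monte-Carlo error well below the decision
margins (e.g. the titration's replicate SE is ~0.001 at 20X).

## What passing tests do and do not show

The generators emulate the *interfaces* of real data, not their physics:
LLRs are exchangeable within a site (no per-read covariance from signal
quality), errors are independent across positions apart from the
homopolymer multiplier, read length and quality are not jointly modelled,
and mixtures are composition-exact where a wet-lab dilution is itself
binomial. Parameter-recovery results on these cohorts therefore validate
the estimators and filters — unbiasedness, gate enforcement, selection and
clustering behaviour — but say nothing about basecaller-specific biases,
CpG-density-dependent calling accuracy, or tumor purity, and the
correlation magnitudes on real cohorts are expected to differ from the
planted ones. Homopolymer flagging marks known-unreliable loci; it does
not correct them.
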