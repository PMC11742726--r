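---
title: "Host filtration and re-identification auditing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host filtration and re-identification auditing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmlfilter)
```

# The problem

Shotgun metagenomes of human-associated samples carry host reads. If they
are not removed before data sharing, the residual human reads can be
matched against genotype databases and the sample donor re-identified.
`pmlfilter` implements (i) a per-read host classifier built on
pseudo-matching lengths against a pangenome index, (ii) three composable
filtration pipelines, (iii) a labeled synthetic benchmark for measuring
what a pipeline removes and what it costs, and (iv) a likelihood-based
re-identification audit for quantifying the privacy risk that remains.

# Matching statistics as the classification signal

For a read $x$ of length $L$ and a reference collection indexed on both
strands, the package computes at every position $i$ the *matching
statistic*: the length of the longest prefix of $x[i:]$ occurring anywhere
in the collection. We refer to the resulting vector as the read's PML
(pseudo-matching-length) profile. Compressed-index tools report fast
approximations of this quantity; `pmlfilter` computes it exactly, with a
suffix automaton over the separator-joined concatenation of all references
and their reverse complements. Exact values are deterministic, reproduce
the analytic threshold calibration below, and are verified in the test
suite against an independent brute-force substring-scan oracle,
position-exact over thousands of random and planted reads.

Two representation choices matter:

* **Both strands are indexed.** Sequencers read either strand; indexing
  reverse complements makes classification strand-symmetric.
* **`N` matches nothing.** Ambiguous bases in reads or references are
  treated as universal mismatches (reference `N`s become segment
  separators). This is conservative: runs of `N` can never inflate a host
  score.

The profile obeys two invariants used throughout: $0 \le v_i \le L - i + 1$
and $v_{i+1} \ge v_i - 1$ (a match of length $m$ at $i$ implies one of at
least $m-1$ at $i+1$).

# Score metrics and threshold calibration

All three metrics are calibrated on a *theoretical* minimal host read: 150
bp containing a single contiguous matching run of 31 bases, whose profile
decays $31, 30, \dots, 1$ and is zero elsewhere.

* maximum: $\max_i v_i$; calibration value $31$.
* average: $\tfrac1L \sum_i v_i$; calibration value $496/150 = 3.3067$
  (conventionally printed as 3.306).
* custom:
  $$s(v) = \frac{1}{2L}\Big(\max_i v_i + \big(\textstyle\sum_{r \in R} r\big)\,
  \ln(|R| + 1)\Big),$$
  where $R$ is the set of matching *runs* strictly longer than $w$ bases.
  For the theoretical read, $s = (31 + 31\ln 2)/300 = 0.1750$.

A read is called host when its score is $\ge$ the threshold: the
calibration read defines the threshold and is intended to be caught, so
the boundary is inclusive.

## Run decomposition

A run is a maximal segment over which the profile decreases by exactly 1,
beginning at an entry point (position 1, or any position whose value
exceeds the previous value minus 1); zero values belong to no run. An
uninterrupted exact match decays fully, so its segment length equals the
profile value at its start. When a longer fresh match supersedes a decaying
one, the earlier segment is truncated.

The weight $r$ each run contributes is its **segment length**, and
membership in $R$ requires segment length $> w$. This choice is forced by
discriminative behavior. Against any realistically sized index, random
(non-host) reads carry per-position matching statistics around
$\log_4(\text{index size})$ — 8-11 for the fixtures used here — so their
*starting values* routinely exceed $w = 5$. But those runs are superseded
within one to three positions, because a fresh random match almost always
beats a continuation that has decayed toward the noise floor. Weighting by
segment length therefore cleanly separates the two classes: measured on
random 150-mers against a 30 kb two-strand index, segment-length weighting
yields scores around 0.06 (never near 0.175 in our tests), while
one-mismatch host reads score above 0.7. Weighting runs by their starting
value instead would hand every random read several qualifying runs and
scores orders of magnitude above any usable threshold. Both conventions
coincide on fully decaying runs, including the calibration read.

## Other numerical conventions

* **Natural logarithm** in the custom metric: $\ln$ uniquely reproduces
  the 0.175 calibration ($\log_{10}$ would give 0.134).
* **Strict run-length inequality**: $w = 5$ admits runs of length $\ge 6$.
* **Read length enters as $1/(2L)$** with the actual post-trim length;
  thresholds are held fixed across lengths, matching how one threshold is
  applied to real libraries whose read lengths vary after trimming.
* **Degenerate profiles**: an all-zero profile has no runs, scores 0 under
  every metric, and is non-host for any positive threshold.

The default grid search explores thresholds 0.145-0.200 in steps of 0.005
and $w$ from 2 to 12, i.e. $12 \times 11 = 132$ combinations, reporting
host recall/precision and microbial loss per combination.

# Filtration pipelines

Alignment stages remove a pair when **either** mate maps (equivalently, a
pair survives only if both mates are unmapped); index stages remove a pair
when **either** mate classifies host. The either-mate removal rule at the
index stage mirrors the alignment-stage semantics and is the
privacy-conservative choice for paired data, where mates come from one
fragment.

Two aligner implementations satisfy one contract (deterministic per-pair
mapped/unmapped):

* an **internal seed-and-extend aligner** (exact 15-mer seeds, ungapped
  extension along the seed diagonal, mapped at $\ge 90\%$ identity over
  $\ge 60$ bp). It is hermetic — the package and its tests need no external
  binaries — and deterministic by construction;
* an **external adapter** driving `minimap2 -2 -ax sr` with unmapped-pair
  extraction via `samtools fastq -f 12 -F 256 -N` (single-end:
  `-f 4 -F 256`), for users who want the production aligner.

Preset Method 1 is align(primary), align(secondary), index(aggregate);
Method 2 inserts one alignment pass per pangenome haplotype before the
index stage (sequential per-genome passes, matching the stepwise
discard-as-you-go design); Method 3 is the index stage alone. Because the
stage sets are nested, survivor sets are nested on any input, and reports
telescope: removed + survivors equals input at every stage.

Pre-filtration follows the standard recipe: adapters are clipped from the
3' end by exact suffix-overlap against an explicit adapter list (bundled
TruSeq/Nextera set; minimum overlap 8 bp, longest overlap wins, iterated
to a fixed point so the operation is idempotent), then any pair with a
mate shorter than 45 bp is dropped entirely. Quality-window trimming is
deliberately out of scope: the classifier uses sequence content only, and
an explicit adapter list keeps the step deterministic and testable,
whereas production trimmers bundle hard-coded lists and heuristics.

# The synthetic benchmark

The generator emulates the structure of the validation design — a base
"human" genome, derived haplotypes standing in for pangenome assemblies,
unrelated "microbial" genomes, and 50/50 labeled read mixtures — at desk
scale. Defaults, chosen once as field-plausible values:

| parameter | default | rationale |
|---|---|---|
| read length | 150 bp | standard short-read length; matches the calibration read |
| mixture | 50% human / 50% microbial pairs | the benchmark's mixing design |
| substitution error | 0.005/base | short-read scale error; substitution-only |
| insert | 350 ± 35 bp | typical paired-end library |
| haplotype SNP rate | 0.001/base | human-scale per-haplotype divergence |
| haplotype indel rate | 1e-4/base, 1-3 bp events | minor indel component |
| GC | 0.41 human-side, 0.5 microbial | human-like vs neutral composition |

Reads are drawn uniformly from either strand; mate 2 is the reverse
complement of the fragment's far end; qualities are constant Phred 35
(the classifier never reads them). All randomness flows from one explicit
seed through fixed sub-streams, so every artifact is reproducible
bit-for-bit. Ground truth (origin, source genome, fragment placement,
strand) travels with every pair, which also gives reference-oriented
placements for pileups and coverage profiles without re-alignment.

What the generator does *not* emulate — and what passing tests therefore
do not show: real pangenome haplotype structure (segmental duplication,
structural variation, repeat families), empirical sequencing-error and
quality profiles, indel sequencing errors, GC-coverage bias, and genome
sizes beyond tens of kilobases. The benchmark demonstrates the
*mechanics* (nesting, recovery, conservation, privacy restoration) under
controlled conditions; absolute removal counts on real pangenome-scale
data are outside what a desk-scale fixture can certify.

Benchmark fixtures in the test suite use 10 kb genomes, 10 held-out
haplotypes for read simulation with 3 held-in references for filtration,
10 microbial genomes and 5,000 read pairs — sizes chosen so the full
three-method comparison runs in seconds while leaving binomial headroom
(at these sizes the recovery properties pass with removal margins far from
their bounds).

The coverage diagnostic summarizes read placements into breadth (covered
fraction), mean depth and the ratio of the densest 1 kb window to the mean
depth; a genome is flagged artifactual at breadth < 0.01 and peak ratio
> 10 (configurable). With no reads the flag is reported as not-evaluable
rather than false.

# The re-identification model

At SNP site $i$ covered by $n_i$ reads of which $k_i$ carry the reference
allele, the likelihood that a genotype with $g$ alternative alleles
produced the reads is

$$L(g, n_i, k_i) = \frac{1}{2^{n_i}}\,[(2-g)\varepsilon + g(1-\varepsilon)]^{\,n_i - k_i}\,
[g\varepsilon + (2-g)(1-\varepsilon)]^{\,k_i},$$

with per-base error $\varepsilon = 10^{-6}$. Heterozygotes give exactly
$2^{-n_i}$ regardless of $k_i$. The per-sample likelihood score is the sum
of natural-log likelihoods over the usable sites; its background mean and
variance come from the Hardy–Weinberg genotype distribution
$\{(1-p_i)^2,\, 2p_i(1-p_i),\, p_i^2\}$ at the panel's allele frequencies,
summed over sites under an independence assumption. The standardized score
is tested two-sided against the standard normal, but a *match* is declared
only for positive deviations — a candidate must be more likely than a
random population member, not less. All products are evaluated in log
space; scores stay finite to site depths of $10^4$.

Usable sites are selected by **cover-then-clump**: sites covered by at
least one read passing the quality filters (mapping quality $\ge 40$, base
quality $\ge 20$) are LD-pruned greedily in sliding windows of 100 sites
advanced by 30, dropping, from any pair with squared Pearson
genotype-dosage correlation above 0.1, the site with the lower minor
allele frequency (ties drop the later position). The dosage-correlation
definition of $r^2$ and the MAF-based drop rule follow the common
convention of genotype-pruning tools; the exact tie-breaking of those
tools is not documented, so the rule here is stated explicitly and
verified by an exhaustive pairwise check in the tests. Pruning after
coverage restriction (rather than before) matches the order in which the
inputs become available in the audit; sites the reads never touch cannot
influence which sites are retained.

An all-vs-all audit of $J$ genotype samples against $M$ metagenomes
performs $J \times M$ tests with Bonferroni lines at $0.05/(J M)$
(study-wide) and $0.05/J$ (per panel). Read sets with no usable site — or
a degenerate (zero-variance) background, as happens when every covered
site is monomorphic — are reported not-evaluable rather than assigned a
p-value. A $343 \times 343$ design yields 117,649 tests; the exact
study-wide line is $0.05/117{,}649 = 4.25 \times 10^{-7}$ (conventionally
printed rounded up to $4.3 \times 10^{-7}$), the per-panel line
$1.5 \times 10^{-4}$.

The synthetic audit experiment mirrors the full loop: a 500-sample HWE
panel over a 20 kb base genome (300 sites, frequencies uniform on
[0.05, 0.95]), a designated donor whose two haplotypes carry their
genotypes (random phasing), leaked reads simulated from those haplotypes
at error rate $10^{-3}$, then (i) the donor attains the minimum p-value,
below $0.05/J$, from a few thousand leaked bases, while at least 99% of
non-donors stay above the line, and (ii) after a Method-1-style filtration
whose references include the donor's haplotypes, the surviving read set
supports no call below $0.05/J$ — typically because nothing survives and
the audit reports not-evaluable, which is precisely the privacy goal.

# Known limitations

* Exact matching statistics are an idealization of compressed-index
  pseudo-matching lengths; the two can differ on reads whose matches
  straddle index-internal boundaries. The calibration thresholds are
  analytic and unaffected, but per-read scores from a production
  compressed index may differ slightly.
* The internal aligner is a stand-in contract implementation: ungapped
  extension does not model indel alignment, so its mapped set differs from
  a production aligner's near indels. The external adapter exists for
  exactly that reason.
* The simulator's i.i.d. substitution model understates the structured
  errors of real instruments; recovery bounds measured on it are
  mechanics checks, not performance claims for real data.
* Allele frequencies default to panel-derived estimates; with small
  panels these are noisy, and an external frequency table is the better
  choice when available.
* Multi-allelic sites are excluded from genotype panels by construction.
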