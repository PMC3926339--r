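---
title: "Simulating diploid variants and quality-profiled short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diploid variants and quality-profiled short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diploidsim)
```

# Purpose and model overview

Developers of variant callers need datasets where the truth is known
exactly. `diploidsim` builds such datasets in three steps: it spikes SNVs,
small indels and allele-specific copy-number variants (CNVs) into a diploid
realization of a reference genome, writes every simulated variant to truth
logs, and generates Illumina-like short reads from the two mutated allele
sequences using an empirical per-cycle Phred quality model. Because reads
are drawn from the *post-variant* alleles, heterozygous allele fractions and
CNV read-depth signal emerge naturally rather than being painted on.

The three variant modules are independent and can run alone or chained
(SNV, then indel, then CNV, which must know the indel coordinates).

## SNV placement

The SNV density is controlled by a rate $r$ interpreted as the fraction of
genome bases carrying an SNV. Placement is a random walk along each
chromosome: successive gaps are drawn from a Gaussian with mean

$$D_{\mathrm{avg}} = \mathrm{clamp}\!\left(\mathrm{round}(1/r),\ 300,\ 1000\right)$$

bases, the range supported by population-scale human resequencing. The walk
keeps SNVs well distributed instead of clumped Poisson-fashion. Two filters
follow: a positional filter removes any SNV closer than 15 bases to the last
kept one (distances of exactly 15 survive; the earlier member of a close
pair is kept), and SNVs landing in N-regions (assembly gaps, or any
non-ACGT base after normalization) are discarded outright, not relocated.
The clamp means the *realized* rate deviates from the requested rate outside
$[10^{-3}, 3.3\times10^{-3}]$; this is documented behaviour, not corrected.

The Gaussian's standard deviation is not fixed by the density argument
alone; we default to $D_{\mathrm{avg}}/4$ (gaps floored at the 15-base
minimum), which keeps the walk overwhelmingly positive while giving visible
spacing variability. It is exposed as `spacing_sd`.

Alternate bases follow the transition/transversion constraint: with
probability $R/(R+1)$ the unique transition partner is chosen
(A$\leftrightarrow$G, C$\leftrightarrow$T), otherwise one of the two
transversion partners uniformly, so the expected Ti/Tv count ratio is $R$.
The human-genome default is $R = 2.1$; setting $R = 0.5$ makes all three
alternatives equally likely, the signature of random (artifactual)
substitution. Zygosity is heterozygous with probability 0.20 by default;
heterozygous SNVs land on allele 1 or 2 with a fair coin.

## Indel simulation

Indels of 1-100 bases are simulated in four categories with the
literature-based human mix: 30% single-base, 20% repeat expansions,
49% mid-size (2-20 bp) and 1% long (21-100 bp). Counts are apportioned by
largest remainder so they are exact and deterministic. Because 2-5% of
candidates are typically lost to duplicate and overlap removal, the
algorithm over-generates by 5% (`ceiling(1.05 n)`) and trims the
coordinate-sorted survivors back to the requested count.

Two choices here were genuinely open:

* **Repeat expansions.** The mechanism is realized as a tandem-motif
  insertion: a motif of 1-5 bases is read immediately left of the anchor
  and inserted again as 2-4 adjacent copies. Motif length and copy count
  are exposed as knobs.
* **Insertion:deletion balance.** Repeat expansions are insertions by
  construction, so if the other categories used a fair coin the overall
  insertion fraction would be $0.2 + 0.8 \times 0.5 = 0.6$, breaking the
  documented 1:1 insertion:deletion ratio. The package therefore
  compensates: non-repeat candidates are insertions with probability
  $(f_{\mathrm{ins}} - f_{\mathrm{rep}})/(1 - f_{\mathrm{rep}})$
  (0.375 under defaults), making the *overall* ratio hit the
  `ins_del_ratio` target.

Deletions take their sequence from the reference and must not touch
N-regions; insertions only need a non-N anchor. Deletions also require an
anchor base to their left so the truth set can always be rendered as a
left-anchored VCF. Heterozygous:homozygous is 1:1 by default, and the truth
set is written as two allele-specific logs (homozygous records appear in
both), reflecting the bi-allelic genome.

## CNV simulation

CNV size and location are generated dynamically by rejection sampling: the
user sets only the count and the size range. A candidate is accepted when
its span lies inside the chromosome, is disjoint from every accepted CNV,
and neither boundary falls inside an indel span on either allele — indels
*fully contained* in a CNV are allowed. Gains are tandem duplications
(copy number 2-4 adjacent copies; each copy carries the contained indels),
losses remove the span (erasing contained indels). Tandem realization is the
simplest mechanism that produces the correct read-depth signal for
depth-based CNV callers. Copy numbers are stored per allele (1 = unchanged,
0 = loss, $\geq 2$ = gain), so the single tabular truth file fully
determines both allele sequences; a BED rendering (0-based half-open) is
written alongside for visualization tools.

A retry budget (`retry_factor` $\times$ count, default 1000$\times$) makes
the rejection loop terminate: unplaceable configurations fail with an
explicit capacity error naming how many CNVs were placed.

## Quality profile and read generation

The error model is empirical: a training FASTQ pair (real Illumina data, or
the synthetic trainer described below) is reduced to one probability vector
over Phred scores Q0-Q41 per mate and per cycle. Sampling a read's quality
string draws each cycle independently from its distribution; dependence of
quality across cycles, or on base identity and GC, is deliberately not
modelled. Sequencing errors are substitution-only: position $i$ is replaced
by one of the other three bases with its own Phred error probability
$10^{-q_i/10}$; N bases pass through untouched.

Read counts come from the coverage identity
$N_{\mathrm{pairs}} = \mathrm{round}(c \cdot L_{\mathrm{alleles}} / (2\ell))$
with $L_{\mathrm{alleles}}$ the summed length of *both* allele sequences and
$\ell$ the read length. **Insert size means inner distance** — the gap
between the two mates, so fragment length $= 2\ell + d$ with
$d \sim \mathrm{round}(\mathcal{N}(\mu, \sigma))$ floored at 0. Tools
disagree on this convention; this package takes the stated one literally.
Fragments are placed uniformly on the allele sequences, alleles weighted by
length; each fragment is sequenced from a random strand by default
(`strand_flip`) so variant strands are balanced. Single-end mode simply
draws read-length fragments.

Read names encode the complete ground truth
(`frag<i>:<chrom>:<allele>:<start>:<end>`, allele coordinates), so
coverage, allele balance and CNV depth can be verified without an aligner.

### Deterministic parallelism

Output is always partitioned into 4 fixed blocks, each with a random stream
derived from the global seed; the `workers` setting (1-4, matching a
quad-core desktop) only chooses how many blocks execute concurrently.
Blocks are written in order, so the FASTQ bytes are identical for any
worker count — parallelism never changes results.

## Truth-set rediscovery

`match_variants()` scores a caller's VCF against the truth logs. SNVs must
match chromosome, position and alternate allele exactly. Indels match on
chromosome, kind and exact length, with a position tolerance (default 10
bases, exposed as a flag) absorbing left/right alignment ambiguity; each
truth record greedily takes the nearest unused call. Reports stratify by
SNV zygosity and by the indel size bins 1-6, 7-10, 11-20 and 21-100 bases.
External aligners and callers are intentionally out of scope: the harness
evaluates their output, it does not run them.

# The synthetic data generators

`simulate_reference_genome()` produces uniform-random ACGT chromosomes with
N-runs (uniform length 100-1000 by default) placed until a target N
fraction is reached; `simulate_training_fastq()` produces training reads
whose per-cycle quality distributions follow a discretized normal whose
mean decays linearly along the read (Q37 to Q25 for mate 1, 2 points lower
for mate 2, SD 4) — an Illumina-like decay profile. The exact generating
distribution is available from `training_quality_model()`, which is what
lets the test suite check profile recovery quantitatively (total-variation
distance below 0.02 at $10^5$ reads).

These generators emulate base composition, assembly gaps and quality decay
— and nothing else. Real genomes have repeats, GC structure and
context-dependent error; passing tests on these fixtures demonstrates the
correctness of the simulation machinery, not caller performance on real
data.

# Numerical and edge-case choices

* Internal coordinates are 0-based half-open; all emitted logs are 1-based
  inclusive except the BED file, which keeps BED's own convention.
* Insertions anchor *after* their stated base (VCF-style), deletions start
  *at* their stated base; the truth VCF re-anchors deletions on the
  previous base.
* The reference-to-allele coordinate map is piecewise: positions inside
  deleted spans map to the deletion's left edge; gains map reference
  positions into their first copy.
* Duplicate-position candidates keep the first after sorting; the
  over-generation excess is trimmed from the sorted tail. Both choices are
  deterministic and order-stable.
* An all-N chromosome yields zero SNVs; indel sampling re-draws colliding
  positions a bounded number of rounds (default 100) and then errors.
* Every module takes an explicit seed; one pipeline seed derives all module
  and worker seeds, so a configuration reproduces byte-identical outputs.

# Test problem sizes

The empirical checks in the test suite use a 10 Mb two-chromosome fixture
genome: pooled SNV sets of $\geq 10^5$ records for the Ti/Tv, zygosity and
spacing checks, $10^4$-$10^5$ indels for the category and ratio checks
(all at 3-standard-error tolerances), and $10^5$ reads for the emitted
quality and error-rate checks. The per-cycle mismatch check compares 100
cycles simultaneously, so it allows up to 3 single-cycle excursions past 3
SE alongside a pooled 3-SE bound — the family-wise false-alarm rate of 100
independent 3-SE tests would otherwise be about 24%.

# Known limitations

* Substitution-only errors: no sequencing indels, optical duplicates,
  adapter read-through, GC bias or chimeras.
* Quality cycles are independent; other platforms are supported only by
  swapping in their profile.
* No mutation-signature or context-dependent substitution model; no
  population allele frequencies.
* CNVs are tandem gains or full losses: no dispersed duplications,
  inversions or translocations.
* The clamp on $D_{\mathrm{avg}}$ makes extreme SNV rates saturate.
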