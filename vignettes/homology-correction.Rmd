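---
title: "Correcting sex-chromosome mapping artifacts and inferring the sex chromosome complement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting sex-chromosome mapping artifacts and inferring the sex chromosome complement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Therian X and Y chromosomes descend from one autosome pair and still share
large blocks of homologous ("gametologous") sequence. Two kinds matter most
for short-read work:

* **Pseudoautosomal regions (PARs)** — identical in sequence between X and Y.
  A reference genome that carries both sex chromosomes therefore contains the
  PARs *twice*. A read from a PAR matches both copies equally well, so the
  aligner assigns mapping quality ~0 and places it on either chromosome at
  random.
* **Recent X→Y duplications** such as the human X-transposed region (XTR),
  still >98% identical. Reads whose span happens to contain no divergent site
  behave like PAR reads; the rest map uniquely, so mean MAPQ is depressed but
  not zeroed.

The consequences are concrete: an XX individual accumulates reads and variant
calls on a Y chromosome she does not have; PAR variants in any sample lose
half their supporting reads to the other gametolog and fail depth or quality
filters; and windowed MAPQ collapses in homologous regions. The fix exploited
here is equally concrete: genotype-aware **hard masking**. For a homogametic
(XX) sample, mask the entire Y with `N`s so nothing can map there; for a
heterogametic (XY) sample, mask only the Y copies of the PARs so PAR reads map
uniquely to the X. Masking (rather than deleting sequence) keeps the sequence
dictionary — the ordered (name, length) contig list — identical between the
two reference versions, so BAMs and VCFs produced against either can be
processed jointly downstream.

Both moves require knowing each sample's sex chromosome complement, which is
itself inferred from the data. The package therefore provides one connected
tool chain: reference preparation, BAM/VCF metrics, complement inference,
and read stripping/remapping, plus a simulator that makes all of it testable
without external data.

## The statistics

**Windowed depth heuristic.** A chromosome is tiled with non-overlapping
windows (default 5 kb; the final window is truncated at the chromosome end).
Each primary alignment is assigned to exactly one window — the one containing
its leftmost aligned position — and window depth is approximated as

$$\hat d_w = \frac{\sum_{r \in w} \ell_r}{|w|},$$

the total read length over the window length. The approximation equals exact
per-base depth whenever reads lie wholly inside one window and converges to
it as windows grow; assigning whole reads by start position keeps
$\sum_w n_w$ equal to the chromosome's primary read count, which the tests
assert. Read length $\ell_r$ is the query length by default; a CIGAR
reference-span mode is available (`length_mode = "reference"`). Mean window
MAPQ is the arithmetic mean over the assigned reads; empty windows report 0
with an explicit `empty` flag rather than a silent 0, and always fail
filtering.

**Window filtering.** A window passes when mean MAPQ ≥ `min_mapq` (default
30) and its depth lies within `depth_bounds` (default 0.25–4) times the
chromosome's mean window depth; all comparisons are inclusive. A `"strict"`
preset raises the MAPQ cut to 55, the level needed to suppress residual XTR
homology when false positives are costly. Thresholds are deliberately plain
and exposed: they are data-dependent choices, not constants of nature.

**Depth comparison.** For a chromosome pair, threshold-passing window depths
are compared three ways:

1. *Bootstrap*: percentile confidence intervals of each chromosome's mean
   window depth (default 10,000 resamples, $\alpha = 0.05$), with an overlap
   check;
2. *Permutation*: the absolute difference in means under label shuffling,
   with the add-one Monte-Carlo correction $p = (b+1)/(m+1)$ so $p$ is never
   exactly 0; an exact mode enumerates all label assignments when
   $\binom{n}{n_a} \le 2 \times 10^5$ and then equals the exhaustive p-value
   by construction;
3. *Two-sample Kolmogorov–Smirnov*: $D = \sup_x |\hat F_a(x) - \hat F_b(x)|$
   with the asymptotic p-value (`stats::ks.test`; an independent brute-force
   ECDF oracle checks $D$ in the tests).

Only the bootstrap drives the default complement decision; the permutation
and KS results are reported as supporting evidence.

**Decision rule.** Let $r_Y$ be the ratio of mean Y window depth to mean
autosome window depth, with a bootstrap interval obtained by resampling both
window sets independently. The Y is called *absent* when the interval's upper
bound is below `t_absent` (default 0.10), *present* when its lower bound
exceeds `t_present` (default 0.25), otherwise *indeterminate*. The X ratio
$r_X$ is *haploid-like* when its interval lies inside (0.3, 0.7) and
*diploid-like* when it overlaps [0.8, 1.2]. "XX" requires absent Y +
diploid-like X; "XY" requires present Y + haploid-like X; anything else is
reported indeterminate and never remapped silently. The thresholds are
engineering defaults — no universal cut separates complements across
organisms, library types and coverages, which is why they sit in
`sex_call_thresholds()` rather than in code. For ZW systems the same
machinery applies with roles swapped (the W plays the Y).

One degenerate case needs a policy: after filtering, the Y of an XX sample
usually retains *no* passing windows (every Y window is either empty or
MAPQ 0). The bootstrap cannot run on an empty vector, so a chromosome with
zero passing windows contributes mean depth 0 with a degenerate (0, 0)
interval and a warning — evidence of absence, which is exactly what it is.

**Read balance.** At a variant site, balance is
$b = \mathrm{alt}/(\mathrm{ref} + \mathrm{alt})$ from the allelic-depth
field (or a BAM pileup when AD is absent; multi-allelic records are reduced
to the highest-count alt). Diploid chromosomes show peaks near 0.5
(heterozygotes) and 1.0 (fixed differences); a haploid X shows a single peak
near 1.0. The "heterozygous view" histogram keeps only $0.05 < b < 1.0$
(strict inequalities) to hide fixed sites and low-balance noise. Variant
filters are inclusive ≥ thresholds: site QUAL ≥ 30 and MQ ≥ 30 (the
standard artifact-analysis filter), GQ ≥ 30, depth ≥ 8 (the depth default is
ours — callers vary too much for a universal value). A missing MQ annotation
passes with a warning (caller-specific extra), a missing GQ fails
(conservative on genotype confidence).

## Strip, remap, merge

Read correction is deliberately surgical. Primary reads are exported per
read group (absent RG headers degenerate to one `"default"` group) as
re-paired FASTQs: a pair is exported when *either* mate maps to a target
chromosome, so FASTQs stay valid for paired remapping; reverse-strand
records are reverse-complemented back to their sequenced orientation;
orphaned mates go to a singles file with a warning. Remapping runs either
through user-editable command templates (`{ref} {fq1} {fq2} {out} {rg}`,
e.g. `bwa mem` + a sort) or through the package's built-in seed-and-extend
aligner: exact 32-mer seeds from both read ends propose loci, full-length
mismatch counting (≤ 8 mismatches) verifies them, a unique best locus maps
at MAPQ 60, tied loci give MAPQ 0 with a uniform choice, and all-`N` masked
regions admit no seeds at all — which is precisely how the masked reference
redirects gametologous reads. Remapped records carry a `ZR:i:1` tag. The
final merge is a chromosome partition, never a read-identity merge:
non-target chromosomes come byte-for-byte from the original BAM, target
chromosomes only from the remap; identical sequence dictionaries are
checked first.

The naive pileup caller used in tests (any position with ≥ 1 alt read;
QUAL = phred of a binomial error test at 1% per-base error; 1/1 above 90%
balance; site MQ = mean MAPQ of covering reads) is a dependency-free
test instrument, not a production caller.

## What the simulator emulates — and what it does not

`simulate_genome()` builds a three-chromosome toy genome: a 120 kb autosome,
a 120 kb X and a 60 kb Y, with 5 kb PARs copied byte-identically onto both
ends of X and Y and a 10 kb XTR copied at 98% identity. Sequence is uniform
ACGT; all outputs are pure functions of (spec, seed).

`simulate_alignments()` draws 100 bp paired reads (300 bp inserts) uniformly
per chromosome copy number (XX: A2 X2 Y0; XY: A2 X1 Y1), so expected
depth(X)/depth(autosome) is 1.0 for XX and 0.5 for XY. Placement encodes the
homology mechanism rather than wrapping an aligner: under a reference that
carries both gametologs, a read wholly inside a PAR — or inside the XTR with
no divergent site in its span — is placed on either copy with equal
probability at MAPQ 0; everything else maps uniquely at MAPQ 60. Truth
variants can be written into the reads (heterozygous alleles on one of two
haplotypes), which is what makes an XX sample's mismapped PAR reads produce
spurious Y-chromosome variant calls — the before/after contrast the
correction removes.

The simulator does **not** model sequencing-error profiles, GC or insert-size
bias, duplicates, indels, or the Y's ampliconic repeats (whose anomalous
~0.2 read-balance peak in real data remains unexplained and is out of
scope). Passing tests therefore demonstrate that the machinery is correct
under the stated homology model at desk scale — not that any particular
real dataset will show effects of the same magnitude.

## Problem sizes and numerical choices

Test and acceptance runs use 1 kb windows for general metrics and 500 bp
windows for complement recovery, giving 120–240 windows per chromosome —
comfortably above the ~100 windows per chromosome at which the bootstrap
intervals become reliable at 20× coverage; the complement-recovery property
runs 20 XX and 20 XY replicates at those conditions and requires 40/40
correct. Statistical checks scale the defaults down where exactness is not
at stake (2,000 bootstrap resamples in tests versus the 10,000 default).
Bootstrap and permutation draws all flow through R's RNG behind explicit
seeds; identical seeds reproduce intervals and p-values bit for bit, and
the pipeline derives per-sample, per-test seeds from one master seed.
Quantiles use R's default type-7 definition; permutation ties are compared
with a relative 10⁻¹² tolerance so floating-point noise cannot flip a
tie into an exceedance.

## Limitations

* Depth-based inference assumes roughly uniform coverage; capture designs
  (exomes) shift the ratios, and thresholds must be recalibrated per
  experiment. The quick read-count classifier assumes at least one sample of
  each complement when it splits a cohort at the largest ratio gap; uniform
  cohorts are reported indeterminate rather than guessed.
* Heterogametic samples keep both sex chromosomes in their reference, so
  X–Y homology outside the PARs (notably the XTR) is mitigated only by
  MAPQ/window filtering, not eliminated — hence the strict 55 MAPQ preset.
* The package detects chromosome-scale depth signals; it is not a CNV or
  structural-variant caller, and partial aneuploidies or mosaicism are
  outside its decision rule.
* The built-in aligner and caller are exact, deterministic test instruments;
  real data should flow through production tools via the command templates.
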