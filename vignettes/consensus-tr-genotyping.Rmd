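---
title: "Consensus genotyping of tandem repeats: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus genotyping of tandem repeats: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusTR)
```

Short-read tandem-repeat (TR) genotypers disagree with one another far more
than SNP callers do. Sequence-resolved callers (HipSTR-style) and
copy-number callers (GangSTR-, ExpansionHunter- and adVNTR-style) genotype
overlapping but unequal locus spans, represent the same underlying allele
differently, and attach incomparable quality scores. consensusTR merges
their multi-sample VCFs into a single scored consensus callset and provides
the downstream quality-control and population-genetics toolkit that a
cohort-scale TR study needs.

## The consensus model

**Mergeable sets.** After restricting all callsets to their mutual samples,
records from different callers are grouped when their spans overlap by at
least 1 bp and their repeat units are identical as strings (uppercased; no
cyclic rotation and no reverse complement — unit-representation mismatches
such as a pentamer versus a dodecamer annotation of the same locus are a
known failure mode of literal comparison and are deliberately left
unmerged). At most one record per caller joins a set; a second overlapping
record from the same caller opens a new set, greedily in position order.
Loci seen by a single caller pass through untouched.

**Allele unification.** Every allele in a set is extended to the union span
by prepending/appending reference flank sequence (sequence-resolved
alleles) or by adding the flank lengths (length-only alleles). When a
sequence-resolved record is present, its sequences represent each length
class; two same-length, different-sequence alleles are both kept, and a
length-only allele of that length maps to the more frequently called
variant. Without a sequence-resolved record, consensus alleles are
length-only and caller metadata follows a fixed priority
(GangSTR > ExpansionHunter > adVNTR) rather than a random choice, for
reproducibility.

**Scoring.** Let `M` be the methods that called a sample and `Q[g, m]`
method `m`'s quality when its genotype (an unordered pair of consensus
allele indices) equals `g`, else 0. The score of `g` is

$$ S_g \;=\; \frac{\sum_m Q_{g,m}}{\sum_{g'} \sum_m Q_{g',m}}
   \cdot \max_m Q_{g,m}, $$

a fractional quality-weighted vote times the strongest supporting quality.
The consensus genotype is the argmax; exact ties (scores equal after
rounding to 9 decimals) resolve by caller priority
HipSTR > GangSTR > ExpansionHunter > adVNTR, and the call is annotated with
its score and the supporting methods. A method that made no call
contributes zero to every candidate, and a sample with zero total quality
is a no-call.

Qualities are the callers' own `Q` in [0, 1] where available. For
ExpansionHunter-style calls, each allele is scored
$1/\exp(4\,\mathrm{CI}/\mathrm{CN})$ from its copy number and
confidence-interval width (in copies), and the genotype quality is
`0.8 * min + 0.2 * max` of the two allele scores, so one poor allele
dominates. A zero copy number scores 0 (such genotypes win only when
unopposed), and calls without a confidence interval are treated as absent
rather than given an invented default.

```{r scoring}
# two agreeing callers and one dissenter
score_diploid_genotypes(list(
  list(method = "HIPSTR",  g = c(1, 2), q = 0.9),
  list(method = "GANGSTR", g = c(1, 2), q = 0.6),
  list(method = "EH",      g = c(1, 1), q = 0.5)))
```

## Motif-complexity filtering

VNTR units with internal repeat structure (e.g. `TTTTTCTT`, essentially an
interrupted homopolymer) produce unreliable copy-number calls. The filter
masks `k = ceiling(n/10)` positions of the length-`n` unit at a time
(`k = 1` for `n > 40`), compares each masked unit against all shifted
windows of its own doubling, wildcard-aware, and scores the best match
count over masks and shifts, normalized by `n`. Homopolymer-like units
score 1; units scoring strictly above 0.8 are discarded.

Two readings of the comparison direction are possible; the implemented
default maximizes similarity, because the maximal-mismatch reading assigns
0 to perfectly periodic units, contradicting the intended semantics (scores
near 1 must indicate internal repetition). The literal reading remains
available via `motif_score(..., mode = "literal")`. For a single-base unit
no shift in `1..n-1` exists; the score is defined as 1, consistent with the
homopolymer limit.

## Quality control

**Mendelian inheritance.** A trio/locus pair is assessed only when all
three members are called and at least one is not homozygous reference; the
trio score is the minimum consensus score among the three members.
Consistency means one child allele is assignable to each parent, on
consensus allele identity. `mi_by_score_threshold()` sweeps score
thresholds, including only pairs whose trio score passes.

**Locus filters.** Default thresholds: call rate >= 0.75, Hardy-Weinberg
p >= 1e-6, Mendelian error rate <= 5%; each independently toggleable, loci
failing any enabled filter are dropped. Because no standard exact HWE test
covers arbitrarily multiallelic TRs, the p-value comes from a seeded
Monte-Carlo permutation test (alleles shuffled and re-paired; statistic =
heterozygote count; two-sided around the permutation mean; 10^4
permutations by default). This is a stated substitute for an external
tool's unspecified multiallelic test, not a reconstruction of it.

## Population statistics

Allele-frequency spectra are keyed by copy-number offset from the
reference. Heterozygosity is `1 - sum(p_i^2)`; common alleles are those
with frequency >= 1% (inclusive). Spectrum comparison uses the
Jensen-Shannon *distance* with base-2 logarithms, so identical spectra
score 0 and disjoint spectra score 1.

**Expansion outliers.** An expanded allele has copy number strictly above
`Q3 + 3 * IQR`, computed on copies pooled across samples; quartiles use
linear interpolation between order statistics (`stats::quantile` type 7 —
the convention is not dictated by the method, so it is exposed as an
argument). A locus is reported as population-specific when (1) the
threshold exceeds 10 copies, (2) the expansion frequency (over alleles, not
samples) exceeds 0.01 in at least one group, and (3) one group's frequency
is at least 10 times the other's. Homopolymers are excluded. The grouping
is any user bipartition of populations.

A known degenerate mode: when three quarters or more of pooled alleles sit
on a single length, the IQR collapses to 0 and the fence degenerates to Q3
itself, so every longer allele counts as "expanded" in both groups and the
ratio criterion rejects the locus. This is a property of Tukey-style fences
on discrete spectra, not of the implementation.

**Imputation evaluation and LD.** Observed/imputed genotype concordance is
1 for an exact (unordered) match, 0 when no imputed allele matches, 0.5
otherwise, averaged per locus over evaluable samples. The bundled baseline
imputer predicts the most common diploid genotype (ties: smaller total
allele length, then lexicographic) and is evaluated leave-one-out. SNP-TR
LD is the squared Pearson correlation between phased allele vectors of
length 2n; the best tag SNP is the argmax within +/- 50 kb (ties: nearest,
then smallest position). Phasing itself is out of scope: the LD interface
requires pre-phased input, which the synthetic generator provides.

## The synthetic cohort generator

All tests run on cohorts from `simulate_cohort()`, which produces every
input format the pipeline consumes under labeled substreams of one master
seed (byte-identical reruns; adding a generator never perturbs another).

What it emulates, with defaults chosen once as plausible for a polymorphic
STR panel:

* **Reference** — perfect repeats (`unit^copies`, units 1-4 bp, 8-15
  copies) embedded in random flanks, >= 200 bp apart.
* **Spectra** — allele frequencies decay geometrically with copy-number
  offset (decay 0.4 per copy, support +/- 3 copies) with a slight bias
  toward contractions (factor 1.15), mirroring the observed decay of
  frequency with distance from the reference length; populations differ by
  log-normal drift (sd 0.3) on spectrum weights; optional expansion alleles
  are injected at configured frequencies.
* **Trios** — children inherit one allele per parent; with probability
  equal to the configured Mendelian-error rate, one child allele is
  replaced by a spectrum draw restricted to alleles that actually violate
  inheritance, with the raw rate thinned by the expected fraction of
  all-homozygous-reference (hence MI-ineligible) trios, so the configured
  rate is the expected *measured* violation rate among eligible trios.
* **Callers** — per-caller miscall (2%) and no-call (2%) rates, high
  qualities (0.9-1) on correct calls and low (0.1-0.5) on miscalls; the
  HipSTR dialect is sequence-resolved and shifts its span 2 bp into the
  flank (absorbing flank bases into every allele), exercising the
  span-harmonization and flank-extension paths; the ExpansionHunter dialect
  carries copy numbers whose confidence intervals widen on erroneous calls.
* **SNP panel** — per locus, one designated tag SNP coupled to the
  non-reference indicator of each TR haplotype at a configurable strength;
  remaining SNPs independent.

What it does not emulate: read-level noise and stutter, locus-dependent
error profiles, imperfect or compound repeats, indels in flanks, linkage
between loci, and realistic human demography. Passing tests therefore
demonstrate correctness of the algorithms under their stated models, not
end-to-end accuracy on real sequencing data.

Problem sizes used by the test and acceptance suites — chosen as the
smallest cohorts at which the statistical checks have adequate power — are
500 trios across 10 loci for Mendelian-error recovery, 500 samples per
group (20 replicate seeds) for expansion recovery, 1000 loci for the null
false-positive rate, and 10,000 randomized instances for the scoring
oracle. The expansion-recovery experiment uses drift 0 (groups identical
except the injection) and reference copies 12-18, because the outlier rule
only defines detection for loci whose threshold exceeds 10 copies;
recovery at excluded loci is not a meaningful quantity.

## Numerical conventions

* Coordinates are 0-based half-open internally; VCF I/O converts at the
  boundary.
* Genotypes are unordered allele pairs everywhere; phase is carried only by
  the synthetic SNP/TR haplotypes used for LD.
* Allele lengths are stored in base pairs; copy numbers are
  `length / unit length` and may be fractional (the CA10 assay reference
  allele, 66 bp of a CAG unit, counts 22 copies).
* Score ties are compared after rounding to 9 decimals, making
  tie-breaking reproducible across platforms.
* Length-only alleles are serialized in VCF ALT columns as perfect repeats
  of the unit truncated to the allele length — a representation convention,
  not a sequence claim; parsers for the copy-number dialects ignore the
  serialized sequence.
* The VCF writer emits deterministic plain text, so identical inputs and
  seeds give byte-identical outputs end to end.

## Limitations

Repeat units are compared literally, so rotated or reverse-complemented
unit annotations of the same locus do not merge. The consensus vote
prioritizes precisely estimated alleles, which can prefer a confident
short-allele call over an imprecise large expansion — a bias inherited from
the scoring model. The HWE permutation test is a substitute, not a
reconstruction, of any specific external test. The generator's spectra are
single-unit perfect repeats; behavior on compound or imperfect repeats is
untested.
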