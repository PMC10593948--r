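# consensusTR

Consensus genotyping and population analysis of tandem repeats (TRs).

Short-read TR genotypers disagree: sequence-resolved callers (HipSTR-style)
and copy-number callers (GangSTR-, ExpansionHunter- and adVNTR-style)
genotype overlapping but unequal locus spans, represent the same underlying
allele differently, and report incomparable quality scores. consensusTR is
for cohort-scale TR studies that need one callset: it merges multi-caller
VCFs into a single scored consensus, and bundles the quality-control and
population-genetics toolkit around it — a motif-complexity filter for VNTR
units, Mendelian-inheritance analysis over trios, locus filters (call rate,
Hardy–Weinberg, Mendelian error), allele-frequency spectra and
heterozygosity, population-specific repeat-expansion detection, imputation
concordance, SNP–TR LD / tag-SNP search, and a fully seeded synthetic
cohort generator producing every input format the pipeline consumes.

## The model

For each sample at each merged locus, let **M** be the callers that made a
call and `Q[g, m]` caller *m*'s quality when its genotype (an unordered pair
of consensus alleles) equals *g*, else 0. Each candidate genotype is scored

    S_g = ( Σ_m Q[g, m] / Σ_{g'} Σ_m Q[g', m] ) · max_m Q[g, m]

— a fractional quality-weighted vote times the strongest supporting quality
— and the argmax wins, with exact ties resolved by the caller priority
HipSTR > GangSTR > ExpansionHunter > adVNTR. ExpansionHunter-style calls
get per-allele scores `1 / exp(4·CI/CN)` (copy number `CN`,
confidence-interval width `CI` in copies), combined as
`0.8·min + 0.2·max`. Before scoring, all alleles in a mergeable set
(overlapping spans, identical repeat units, at most one record per caller)
are extended to the union span with reference flanks and unified into one
consensus allele table, with sequence-resolved alleles representing each
length class when available. See the methods vignette
(`vignettes/consensus-tr-genotyping.Rmd`) for the full account.

## Worked example

Simulate a two-population cohort with five trios, genotype it with all four
simulated callers, and merge:

```r
library(consensusTR)

cfg <- sim_config(seed = 42, n_loci = 3, n_samples = c(AFR = 25L, EUR = 25L),
                  trios = list(n = 5L, mendelian_error_rate = 0))
sim  <- simulate_cohort(cfg)
cons <- ensemble_call(sim$callsets, sim$ref$genome)
cons
#> <tr_callset: 3 loci x 65 samples>
cons$records[[1]]
#> <tr_record CONSENSUS chrS:253-281 unit=AT alleles=7 called=65/65>

ct   <- calls_table(cons)
loc1 <- ct[ct$locus == 1, ]
sp   <- allele_spectrum(c(loc1$off1, loc1$off2))
heterozygosity(sp)            # 0.757
count_common_alleles(sp)      # 7
mean(ct$score)                # 0.987

mi_by_score_threshold(cons, sim$pedigree, c(0, 0.5))
#>   threshold n_pairs mi_rate
#> 1       0.0      14       1
#> 2       0.5      14       1
```

The first locus is an AT dinucleotide merged across the four callers on the
span `chrS:253-281`; its 7 consensus alleles are all common (frequency
≥ 1%) and give heterozygosity 0.757. The mean consensus score of 0.987
reflects the generator's default 2% miscall rate (miscalled genotypes carry
low caller qualities, which the vote converts into low consensus scores),
and with a zero Mendelian-error rate all 14 eligible trio/locus pairs
follow inheritance at every score threshold.

A command-line front end wraps the same functions
(`inst/cli/trcons.R`; subcommands `simulate`, `merge`, `motif-filter`,
`qc`, `stats`, `expansions`, `impute-eval`, `ld`):

```sh
Rscript inst/cli/trcons.R simulate --seed 42 --outdir fixtures --trios 5
Rscript inst/cli/trcons.R merge \
  --vcfs fixtures/hipstr.vcf:hipstr,fixtures/gangstr.vcf:gangstr \
  --ref fixtures/reference.fa --out consensus.vcf
```

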