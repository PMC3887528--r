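---
title: "Diversity, differentiation and LD from multi-sample SNP data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, differentiation and LD from multi-sample SNP data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vcfpopgen` re-implements, as a tested and reusable pipeline, the
computational chain used to characterize genetic diversity, population
differentiation and linkage disequilibrium (LD) in whole-genome SNP data
from a small panel of resequenced diploids — the kind of survey run on
malaria-vector mosquitoes to judge the feasibility of association mapping.
This vignette is the package's account of the statistical methods, the
tunable parameters, the synthetic-data generator, and the design choices
made where the design was genuinely open.

## The two-tier filter cascade

Variant filtering follows the two-tier strategy used with jointly called
GATK-style VCFs:

1. **High-confidence tier.** From the jointly called *high-coverage*
   samples, keep biallelic SNPs (single-base REF and ALT) that pass the
   standard hard filters — fail when `QD < 2.0`, `MQ < 40`, `FS > 60`,
   `HaplotypeScore > 13`, `MQRankSum < -12.5` or `ReadPosRankSum < -8.0` —
   and additionally satisfy `QUAL > 30` and combined `DP > 30`. All bounds
   are strict, exactly as printed by the recommendations: `MQ = 40` passes,
   `QUAL = 30` fails. An *absent* annotation never fails a filter; the
   caller omits rank-sum tags at homozygous sites and absence carries no
   evidence.
2. **Low-coverage tier.** The jointly called *low-coverage* set is
   hard-filtered with the QUAL bound relaxed to `QUAL > 4` and the depth
   bound removed, and then passed through a four-rule exclusion cascade, in
   fixed order: (1) any sample genotype missing; (2) site not present in the
   high-confidence set; (3) minor allele carried by fewer than 5
   individuals; (4) multiallelic, including sites biallelic for two
   non-reference alleles.

A site failing several rules is charged to the first failing stage only,
so the `filter_ledger` satisfies exact conservation
(input = retained + sum of per-stage exclusions); permuting the rule order
would change per-stage counts but never the retained set, and re-filtering
the retained set excludes nothing. `ledger_report()` refuses ledgers that
violate conservation.

Two points in the cascade were genuinely open:

* **High-confidence matching.** Matching is by the full
  `chrom:pos:ref:alt` key, which blocks allele-swap leakage between call
  sets. For multiallelic low-coverage records the site is considered
  present in the reference set when *any* of its ALT alleles matches a key;
  a literal whole-record match would send every multiallelic site to
  rule 2 and rule 4 could never fire, which contradicts the cascade's own
  enumeration.
* **Minor-allele carriers.** "Carried by at least 5 individuals" counts
  individuals with at least one copy of the minor allele, the minor allele
  being the least frequent allele *observed* among called genotypes. Ties
  (frequency 0.5) pass only if every tied allele meets the threshold. A
  site monomorphic among called genotypes has no detectable minor allele
  and fails the rule. Defining minority over observed alleles (rather than
  the REF/ALT pair) lets sites biallelic for two non-reference alleles —
  which arise when reads are aligned to a sister species' reference —
  reach the multiallelic rule they are meant to be excluded by.

## Nucleotide diversity, SNP density and F~ST~

Per-site diversity uses the unbiased estimator
$\pi = 2 j (n - j) / (n (n - 1))$ for $j$ alternate alleles among $n$
called alleles — the fraction of mismatching pairs among all allele pairs;
missing genotypes are excluded site by site. Windowed $\pi$ divides the
summed per-site values by the *full window length* in bp: monomorphic and
unascertained bases contribute zero to the numerator but remain in the
denominator, matching the windowed-$\pi$ convention of the standard VCF
toolkits. Empty windows are therefore 0, not excluded. SNP density is
reported in the "1 SNP per X bases" form.

Differentiation uses the Weir & Cockerham (1984) variance components for
diploid biallelic sites: $a$ (among populations), $b$ (among individuals
within populations) and $c$ (within individuals), computed from
per-population sample sizes, allele frequencies and observed heterozygote
frequencies, with per-population $n$ recomputed at every site
(complete-case). Aggregation is the weighted ratio of sums
$\hat F_{ST} = \sum_s a_s / \sum_s (a_s + b_s + c_s)$ over sites with a
positive denominator; negative per-site components are retained (no
truncation), preserving the near-unbiasedness of the ratio-of-sums. The
choice of this estimator (the cited toolchains name only the program, not
the estimator) is recorded as an assumption. Sliding-window and per-region
F~ST~ use the same ratio of sums restricted to the window, with windows
holding fewer than 100 usable sites excluded.

## Linkage disequilibrium

LD is the squared Pearson correlation $r^2$ of genotype dosage vectors
(0/1/2) over the complete-case sample intersection of each site pair —
computed directly from genotypes, so phase is irrelevant. Pairs where
either restricted vector is constant are undefined and skipped, not
counted as zero. The decay curve bins all intra-chromosomal pairs up to
`max_dist` (default 5 kb) by separation into `bin_width`-wide bins
(default 10 bp, which resolves decay on the sub-200 bp scale) and reports
binned means with pair counts; whether a decay model should instead be
fitted was open, and binned means were chosen and documented. Windowed LD
takes pairs separated by 1–10 kb, assigns each pair to the window
containing its midpoint (left-anchor selectable), and excludes windows
with fewer than 100 contributing pairs. No additional MAF pruning is
applied: the upstream carrier rule already enforces at least 5 carriers.

## The sliding-window engine

Windows are anchored at coordinate 0 of each chromosome, advance by
`step`, and the terminal window is truncated at the chromosome length so
every base is covered at least once. Coordinates are 0-based half-open
internally and 1-based in reports (the VCF convention on disk), which
keeps window arithmetic free of off-by-one adjustments. A value
contributes to every window overlapping its position, so overlapping
windows (step < bin) share values by design. The default minimum-value
rule is 0; F~ST~ and LD windows pass 100 explicitly.

## Positional classification and region tagging

Sites are classified against GFF3 gene models with precedence
coding > intronic > flank > intergenic, where *flank* means within 5 kb of
a gene span but outside it. The flank is measured from the gene span
(transcript extent), not the CDS, matching common annotator conventions
for upstream/downstream regions, and is strand-symmetric. Exonic non-CDS
(UTR) positions are within-gene non-coding and are folded into the
intronic bucket of the four-class report; codon-level consequences are out
of scope. Region tagging labels each site with all enclosing named
intervals (inversions, centromeres, telomeres) and supports stratified
means of any per-site statistic, e.g. F~ST~ inside versus outside an
inversion.

## The synthetic-data generator

No sequence data are deposited for the study this package re-implements,
so the generator is a first-class module that emulates the *statistical
structure* the analyses assume, at desk scale:

* **Sites and ancestral frequencies.** `n_sites` biallelic SNPs at uniform
  positions; derived-allele counts over `n_founders` ancestral haplotypes
  follow the neutral SFS, $P(i) \propto 1/i$.
* **Population divergence.** Per-population allele frequencies follow the
  Balding–Nichols model,
  $p_k \sim \mathrm{Beta}(p(1-\theta)/\theta,\ (1-p)(1-\theta)/\theta)$,
  whose $\theta$ equals the expected F~ST~.
* **LD.** Each descendant haplotype is a mosaic over a population copying
  panel with per-bp switch probability `switch_rate`; between consecutive
  sites the switch probability is $1-(1-\rho)^{d_\mathrm{eff}}$ with the
  effective distance shortened by the suppression factor inside the
  centromere (all karyotypes) and inside each inversion for
  *heterokaryotypes only* — homokaryotypes recombine freely, emulating the
  lack of crossing over in inversion heterozygotes. A full coalescent
  simulator was deliberately not used: the copying model is desk-scale,
  has few parameters, and has analytically checkable limits
  (`switch_rate = 0` with a two-founder panel gives $r^2 = 1$ for every
  polymorphic pair; $\theta \to 0$ gives $p_k = p$; $\theta \to 1$ gives
  fixation).
* **Filter exercise.** Emitted VCFs carry QUAL and the GATK-style INFO
  tags drawn from configurable laws, with disjoint engineered subsets
  built to fail each hard-filter tag and each cascade rule; the truth
  table records each site's intended first-failing stage, and a matching
  high-confidence call set (three synthetic high-coverage samples) is
  emitted alongside.

Haplotypes start on a random permutation of the panel, each founder used
equally often — exactly once when the panel size equals twice the number
of diploids. In that configuration with `switch_rate = 0`, site-wise
allele counts are exactly binomial in the Balding–Nichols frequencies, so
the Weir–Cockerham estimator is calibrated: at $\theta = 0.05$ with
10,000 sites and 20 + 20 diploids the weighted estimate recovers $\theta$
within $\pm 0.01$.

**What the generator does not emulate.** Finite copying panels create
founder relatedness: once mosaics mix, allele draws behave like sampling
with replacement from the panel, which adds roughly $1/K$ of
divergence-like variance on top of $\theta$ and raises measured F~ST~
accordingly (about +0.07 at the default 20 + 4 design). This is a real
property of small cross-bred panels, not of large outbred field
populations, which is why divergence is *estimated* on the unlinked
configuration and LD on the mosaic configuration — mirroring the original
study, which estimated LD within the local population only to avoid
structure confounding. The generator also has no selection, demography,
gene conversion, or read-level error model, and its short-range $r^2$
plateaus near $1/(K-1)$ rather than rising smoothly to 1; passing tests
therefore demonstrate estimator correctness and pipeline behavior, not
realism of any particular real genome.

**Default conditions.** The defaults are the study design the package
targets, chosen once: 24 diploids split 20/4 over two populations;
$\theta = 0.057$ (the overall between-population F~ST~ scale);
`switch_rate` $4 \times 10^{-3}$/bp so binned mean $r^2$ falls below 0.2
within roughly the first couple of hundred bp; a 1 Mb chromosome with
5,000 SNPs (about 1 SNP per 200 bp, the autosomal density scale); one
polymorphic inversion (30–50% of the arm) with suppression 0 and
arrangement frequency 0.5; a centromere-proximal low-recombination zone;
per-genotype missing rate 0.024, which makes about 44% of sites fail the
called-in-all-samples rule for 24 samples. Determinism is strict: a single
mandatory master seed with fixed per-stage offsets (founders +0,
population +1, annotation/emission +2, depth +3); identical configurations
produce byte-identical files.

## Numerical and degenerate-input choices

* Sites with fewer than two called alleles have undefined $\pi$ and are
  skipped with a notice; sites where a population is entirely missing are
  skipped for F~ST~; per-site components with $a+b+c \le 0$
  (near-monomorphic) are excluded from ratio denominators.
* $r^2$ pair computation uses missing-data-aware cross-products evaluated
  blockwise, which is exact (integer sums) and equals the brute-force
  double loop on every tested instance.
* Coverage percentages are defined over declared chromosome lengths;
  positions absent from the depth table are depth 0, and a base at exactly
  the threshold counts toward the "at or above" bucket.
* Interval semantics: BED and internal windows are 0-based half-open; VCF
  positions and GFF3 intervals are 1-based; a window `[start, end)`
  contains the 1-based position `p` iff `start < p <= end`.

## Problem sizes used by the test and acceptance runs

The shipped suite exercises the estimators against exhaustive oracles on
instances up to 200 sites, parameter recovery on 10,000 sites with 40
diploids, LD properties on 1,500–5,000 sites over 0.1–1 Mb, the cascade
on 100 randomized 30-site call sets, and the end-to-end pipeline on
800–5,000 sites — sizes at which every property is decisive while the
whole suite runs in well under a minute on one core.
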