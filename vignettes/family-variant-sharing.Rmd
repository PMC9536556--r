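---
title: "Family-based variant prioritization and IBD sharing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization and IBD sharing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famshare)
```

## The problem

Family designs turn a whole-genome search for disease-relevant variation
into two complementary questions. First, among millions of called variants,
which rare, protein-altering changes do *all* affected members of a family
carry — and which of those recur across unrelated families with the same
phenotype? Second, which chromosomal intervals do affected relatives share
*identically by descent* (IBD), so that genes inside recurrently shared
intervals become positional candidates even without a coding hit?

famshare implements both analyses for small pedigrees (the motivating
design is two unrelated families, each containing a monozygotic twin pair
with non-contact anterior cruciate ligament rupture), together with
cross-population descriptive statistics and a gene-drop simulator that
provides ground truth for every stage.

## The casting-vote consensus

Individual deleteriousness predictors (SIFT, PolyPhen-2, FATHMM, CADD, ...)
disagree often enough that any single tool is a poor gatekeeper. The
consensus rule used here is deliberately blunt: each of a configured,
ordered set of predictors (default: 21 ANNOVAR-style tools) casts one
categorical vote per variant —

* `D` (deleterious / probably damaging / disease_causing),
* `A` (disease_causing_automatic),
* `T` (tolerated), or
* `U` (unknown / missing),

and a variant is retained iff at least `min_votes` (default 17) of the
statuses are `D` or `A`. Two properties are worth stating explicitly:

* `U` never qualifies, and the denominator never shrinks: a variant scored
  by only 18 tools still needs 17 qualifying votes out of the configured
  21. Missing evidence weakens a variant, it never helps it.
* The rule is monotone: adding a qualifying status or lowering the
  threshold can only grow the retained set (this is property-tested).

Predictors that emit numeric scores without a categorical call (CADD,
GERP++, PhyloP, SiPhy) must be thresholded to participate; the default
maps score ≥ 20 (the conventional CADD "likely deleterious" band) to `D`
and anything below to `T`. This mapping is an explicit, logged assumption
of every run — there is no canonical published conversion — and lives in
`tool_config()` where it can be replaced wholesale.

## The per-family filter cascade

`prioritize_family()` applies four per-variant predicates in sequence:
rarity, consequence, the casting vote, and the affected-carrier pattern.
All four are pure per-variant predicates, so they commute; the order is
fixed only for logging consistency (and is verified by permutation in the
test suite). Choices that were genuinely open:

* **Rarity scope.** The default retains a variant whose alternate-allele
  frequency is ≤ `max_af` (default 0.01) in *at least one* scoped
  population (`scope_mode = "any"`). A strict all-population rule would be
  incoherent with the motivating data, where a shared candidate variant
  (rs970547) has frequency 0.0026 in an African reference panel but 0.73
  in a European one; "rare somewhere relevant" is the weakest rule
  consistent with such a record, and both scope and mode are configurable.
* **Unknown frequencies.** Variants absent from the panel count as
  frequency 0, with a logged tally. Novel family-private variants are
  exactly the interesting case; silently dropping them would invert the
  analysis.
* **Consequence classes.** The default whitelist is nonsynonymous,
  stopgain and stoploss: exonic, protein-altering point classes. The
  filter requires `region == "exonic"`, so UTR/intronic/intergenic
  variants never pass regardless of consequence annotation.
* **Carrier mode.** `all_affected_carry` (≥ 1 alternate allele in every
  affected, the default) is the permissive choice;
  `all_affected_homozygous` reproduces the stricter pattern in which every
  affected individual is homozygous for the candidate — the pattern of
  the motivating study's shared candidates — and is what the acceptance
  fixtures use. Missing genotypes fail either test: absence of evidence
  is not carriage.

`intersect_families()` then reports the genes present in every family's
candidate list, the union with per-family membership flags, and the
supporting variants per family. Multi-gene variants support every
overlapped symbol.

## IBD sharing

Pairwise IBD segments arrive either from an external haplotype-based
detector (Refined-IBD-style text is parsed directly) or from the package's
own `detect_ibd_segments()`. Segments are filtered on LOD (default
`min_lod = 3`, chosen below the weakest segment a haplotype detector
typically reports, so published-scale records survive intact; the bound is
closed), annotated with overlapping gene models (1-based closed intervals,
≥ 1 bp overlap by default, full containment as an option), and assembled
into within-family sharing tables and cross-family interval intersections.
Gene lists keep duplicate symbols as listed — reference annotation
genuinely contains same-symbol multi-copy models — and a `dedup` flag
collapses them; counts follow entries as listed.

The bundled worked-example record preserves, rather than reconciles, the
known quirks of its source: prose gene counts exceed the listed entries in
three places, one ~3 Mb chromosome 2 locus carries two different band
labels (coordinates are trusted, labels are not), and one symbol is listed
twice. The record pairing a twin *pair* against a third sibling is encoded
as a single pair — monozygotic twins are genetically identical, so nothing
is lost.

### The built-in detector

`detect_ibd_segments()` exists so synthetic studies run end to end without
an external tool; it is documented as *not* a Refined IBD replacement (no
haplotypes, no LD model). For each sample pair and chromosome it takes
maximal runs of consecutive jointly-called markers containing at most
`max_ibs0` opposite-homozygote sites (default 0 — an opposite homozygote
is incompatible with IBD sharing absent genotyping error) and scores each
run as

$$\mathrm{LOD} = \sum_{\text{sites}} \log_{10}
  \frac{P(g_1, g_2 \mid \mathrm{IBD1})}{P(g_1, g_2 \mid \mathrm{IBD0})}$$

under Hardy–Weinberg with panel allele frequencies (frequencies are
clamped to $[10^{-4}, 1-10^{-4}]$; a small error-mixture weight
`err = 10^{-3}` keeps the IBD1 likelihood finite where tolerated
opposite-homozygotes occur).

One numerical subtlety matters. Because runs are *defined* as
opposite-homozygote-free, the within-run LOD is selection-biased upward:
the sites that carry the strongest evidence against sharing are exactly
the ones excluded at the boundaries. Uncorrected, this lets unrelated
pairs accumulate nominally significant runs wherever opposite homozygotes
happen to be sparse. The detector therefore adds the two flanking
opposite-homozygote sites (where they exist) to each run's score — about
$\log_{10}(\mathrm{err}) \approx -3$ each — which restores conservative
behaviour for unrelated pairs while leaving long true segments, whose
interior LOD dominates, essentially untouched. The other lever with real
consequences is the frequency model: scoring with frequencies from the
wrong population inflates the LOD badly (alleles common in the samples'
own population look like improbable coincidences), so `population` should
name the panel column the samples derive from.

Genetic lengths for detected segments come from the simulator's uniform
cM/Mb map.

## Cross-population statistics

Three descriptive statistics summarise how a gene's variation is
distributed across populations:

* **MAF spectra**: minor allele frequency is $\min(p, 1-p)$, binned into
  the six conventional bands 0–0.05, >0.05–0.1, >0.1–0.2, >0.2–0.3,
  >0.3–0.4, >0.4–0.5. The first bin is closed on both ends (a MAF of
  exactly 0.05 is "rare"), matching the band notation's plain reading.
* **Pathogenic fraction**: reported-pathogenic SNPs over total SNPs
  assigned to the gene. Flags come from annotation input (ClinVar/ANNOVAR
  style) or, in synthetic studies, from planted truth — they are never
  recomputed. An empty denominator yields `NA`, not 0: "no data" and "no
  pathogenic variants" are different statements.
* **Gene-level SNP frequency**: per-SNP MAFs aggregated over the gene
  span plus a flank (default 2 kb each side, the conventional
  up/downstream window). The default aggregation is the **sum**, which is
  unbounded above — burdened genes score > 1, which a mean of MAFs ≤ 0.5
  could never do, and which matches the magnitude class of published
  gene-level values; `mean` is available, and the aggregation used is
  recorded in the output metadata.

Family genotypes can enter as additional pseudo-population columns, so
families and reference panels are compared on one footing. Which variants
a column covers is part of the comparison: variants absent (`NA`) from a
population's column are excluded from that population's denominators.

## The synthetic-data generator

The generator's defaults *are* the study conditions: a two-family pedigree
(Family A: father, mother, MZ twin pair, brother — father, twins and
brother affected; Family B: father simulated but not genotyped, mother,
affected MZ twin pair, sister; six affected in total), a 20-population
frequency panel whose first population is the designated rare population
(30% of variants rare at MAF ≤ 0.05 there), founder haplotypes drawn from
the second (European-like) column, a ~390 Mb four-chromosome genome at a
uniform 1 cM/Mb map with 4000 variant sites and 12 genes per chromosome,
and a pathogenic plan planting one homozygous-in-all-affected candidate
per gene in 29 Family A genes and 18 Family B genes, 3 common to both —
the discovery scale of the motivating study.

Mechanics and modelling choices:

* **Meiosis**: crossovers are a Poisson process (no interference) on the
  uniform map; each gamete records a founder-origin track, and true IBD
  segments are maximal intervals where a pair shares a founder haplotype
  id on any haplotype combination. MZ twins receive copies of the *same*
  meiosis products, so their true IBD covers every chromosome end to end.
* **Planting**: the carrier pattern is imposed as a Mendelian-consistent
  genotype configuration (affected homozygous alternate, unaffected
  heterozygous by default), overwriting gene-dropped haplotypes at the
  planted sites. Planting through the realised transmissions alone is not
  generally possible — when an unaffected mother's children happen to
  inherit both of her haplotypes, any assignment through transmission
  would force her homozygous — and an impossible pattern (homozygous
  child of reference-homozygous parents) is an error, never a silent
  adjustment. Unaffected members default to heterozygous rather than
  reference so that no planted site introduces an opposite-homozygote
  pair inside a true IBD segment.
* **Panel coherence**: planted sites are pinned and forced rare
  (frequency < 0.005 in every population) *before* founder haplotypes are
  drawn, so only the planted pattern — never a chance founder allele —
  carries a candidate variant. This is what makes exact truth recovery a
  meaningful end-to-end check.
* **Predictor noise**: per-tool sensitivity/specificity default to 1.
  The default fixture is error-free (as is genotyping; a symmetric flip
  rate exists for stress tests), and noise is a dial used by the recovery
  experiments: at sensitivity 0.9 the retained fraction of true variants
  must match the exact binomial tail $P(\mathrm{Bin}(21, 0.9) \ge 17)
  \approx 0.948$.
* **Determinism**: every stage seeds a named substream derived from the
  master seed, so identical configurations produce byte-identical fixture
  bundles and toggling one stage never shifts another's randomness.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no LD or population history (frequencies are
parametric draws, not coalescent samples), no crossover interference, no
sex-specific maps, uniform variant placement, exonic status equated with
gene overlap, and a carrier-pattern abstraction in place of any
penetrance model. Tests against this generator validate the *machinery*
(filters, vote, interval algebra, transmission, detector) — not the
biological discovery power of the design.

## Problem sizes and numerical conventions

The test suite and the acceptance script size their simulations to the
smallest scales at which the checks are statistically meaningful: 10⁴
random profiles for vote equivalence, 5000 planted variants for binomial
recovery (3-standard-error band), 200 gene-drop replicates over a
35-chromosome-Morgan map for sib-pair sharing (expectation 0.75), and a
three-chromosome, 10⁴-marker error-free study for detector recovery
(≥ 90% of true segments > 5 cM recovered at ≥ 50% overlap; falsely
detected span between unrelated individuals ≤ 1% of the genome at
LOD ≥ 3).

Coordinates are 1-based inclusive everywhere in memory; BED input/output
converts at the boundary. Variant identity is the `chrom:pos:ref:alt`
string after multi-allelic decomposition. Ties and degenerate inputs are
resolved explicitly: empty candidate reports are valid results, empty MAF
input yields an all-zero spectrum flagged undefined, a segment exactly at
the LOD threshold is retained, and a MAF of exactly 0.05 falls in the
first bin.

## Known limitations

The detector is genotype-based and should not be used on real (error-prone,
LD-structured) data in place of a haplotype HMM. The rarity filter's
"frequency 0 when absent" convention assumes the panel is honest about
coverage. The pathogenic fraction inherits whatever ascertainment bias the
input flags carry. And the generator's 29/18/3 default plan reproduces the
*scale* of a published two-family analysis, not its genes: symbols are
synthetic, and no claim about any real locus follows from recovering them.
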