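---
title: "Mapping a recessive trait from trio sequencing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive trait from trio sequencing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

## The inheritance model

trioscan implements candidate-gene discovery for a fully penetrant
autosomal recessive trait segregating in a nuclear family. The model has
three consequences that the package turns into filters and checks:

1. **Trio genotype pattern.** If both parents are phenotypically normal
   carriers and an offspring is affected, then at the causal site the
   parents are heterozygous (`0/1`) and the affected offspring is
   homozygous for the alternate allele (`1/1`). `recessive_snv_pass()`
   extracts exactly this pattern from a father–mother–proband trio.
2. **Copy-number analogue.** A recessive deletion shows copy number 1 in
   each carrier parent and 0 in the affected offspring.
   `recessive_cnv_pass()` requires a deletion record with trio copy
   numbers (1, 1, 0), read from the `CN` FORMAT field only — the `GT`
   field of symbolic records is never consulted.
3. **Segregation.** In any family, every genotyped member constrains the
   candidate: affected members must be `hom_alt`; unaffected members must
   not be; a parent of an affected member is an obligate carrier and must
   carry at least one alternate allele. `check_recessive_segregation()`
   evaluates these rules per individual and `evaluate_candidate()`
   combines families: one contradicting family excludes a candidate,
   while support requires every family to be consistent and at least one
   family with three or more informative genotypes. The asymmetry is
   deliberate — exclusion is decisive under complete penetrance, support
   is only provisional.

Compound heterozygosity is intentionally out of scope: the pipeline
assumes a single shared causal allele, so the two variant-level filters
are strict single-site tests. A `permissive_parents` flag relaxes the
parental requirement to "carries at least one alternate allele", which
admits recessive-compatible configurations such as a homozygous-alternate
unaffected-by-chance parent; it is off by default because obligate
carriers in an outbred colony are expected heterozygous, and the strict
pattern is the one the screening procedure defines.

## Impact triage

Surviving SNVs/indels are joined to VEP-style consequence annotations and
classified into the four-tier impact scale (high > moderate > low >
modifier) by `classify_impact()`, using a term table frozen inside the
package so that counts are reproducible offline. A variant's tier is the
maximum over its terms, which makes the classifier monotone: adding a
term can never demote a variant. Unknown terms demote to modifier with a
warning rather than erroring, so a newer annotation vocabulary degrades
conservatively.

Gene aggregation keeps two books on purpose: a variant annotated against
several genes joins each gene's candidate list, but counts once in the
impact-tier tally (variant counts and gene counts are different
denominators and must not be conflated). CNV survivors are assigned to
genes by interval intersection (`genes_overlapping()`, 1-based inclusive
CNV span against a 0-based half-open BED gene map, any one-base overlap
counts) and enter gene candidates as high impact — a homozygous deletion
ablates the transcript — but are tallied separately from the SNV tiers.

## What the simulator emulates

`simulate_family()` generates the study design the filters assume: two
carrier parents and `n_offspring` children (default 4), genotyped at
`n_background_snvs` unlinked biallelic background sites plus one causal
SNV, and at `n_cnv_background` background deletion loci plus one causal
deletion. Key modelling choices:

* **Founders** draw background genotypes binomially from
  `founder_alt_freq` (Hardy–Weinberg). The default of 0.3 reflects
  variation segregating at intermediate frequency within a small closed
  breeding colony; the convergence checks in the test suite use 0.5,
  where double-heterozygous parental sites are most frequent.
* **Transmission** is one allele per parent per site, independently
  across sites. Sites are unlinked — no recombination map or LD — because
  every filter under test is single-site, so linkage structure would add
  runtime without exercising any additional code path.
* **Ascertainment.** Families enter a mapping study through an affected
  proband. The generator therefore conditions the first offspring to
  inherit the alternate allele from each (forced-heterozygous) parent at
  the causal SNV, and the deleted haplotype from each parent at the
  causal deletion. Without this conditioning roughly `(3/4)^4` of
  simulated families would contain no affected child and would never have
  been sequenced. All other offspring, and every background site,
  segregate freely, so Mendelian expectations (e.g. the 1/4
  homozygous-alternate fraction among double-het sites) hold unchanged on
  the background.
* **Phenotype** is affected iff homozygous-alternate at the causal site
  and a penetrance draw succeeds (default penetrance 1; phenocopy rate 0).
* **Genotyping error** replaces an observed call with a uniformly chosen
  different value of {hom_ref, het, hom_alt, missing} at rate
  `genotyping_error_rate` (default 0). Errors apply to observed SNV calls
  only; the error-free truth is retained so error-sensitivity tests can
  quantify filter dropout — with error rate ε, all three trio calls must
  survive corruption, so causal recovery is bounded below by (1−ε)³ in
  expectation.
* **Annotations** are positional: variants inside a gene draw from a
  fixed weighted vocabulary dominated by modifier/low terms with a
  minority of moderate/high ones (so triage tallies are nontrivial);
  variants outside genes annotate to the nearest gene with
  intergenic/upstream/downstream terms. The causal SNV's term is
  configurable and defaults to `stop_gained`.

What the simulator does **not** emulate: read-level data (coverage,
mapping artifacts, caller-specific error modes), linkage disequilibrium,
repeat expansions, multiallelic sites, and population structure beyond a
single family. Passing tests therefore demonstrate that the filters and
verdicts are correct given well-formed calls — not that the pipeline is
robust to upstream calling artifacts in real data.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout (VCF convention); gene
  maps use BED 0-based half-open coordinates and are converted only
  inside the interval intersection.
* Multiallelic VCF lines are split into one biallelic record per
  alternate allele; genotypes are recoded against that allele and a
  genotype carrying any *other* alternate becomes missing. The trio
  pattern presupposes biallelic coding, and splitting preserves the
  sample set of every line.
* A genotype with any missing allele (`./1`) is treated as missing, and
  missing always fails a filter — exclusion errs toward false negatives,
  never false positives.
* Sex-chromosome and mitochondrial records are removed before the
  autosomal-recessive test; a chromosome allow-list can override.
* Quality filtering is off by default (`pass_only = FALSE`): the
  extraction rule is defined over genotypes, and FILTER conventions vary
  by caller. The switch exists for callers that emit meaningful
  soft-filters.
* Percent reductions round half away from zero to integer percent, and
  cell-loss percentages to one decimal, mirroring the reporting precision
  conventional for these figures. Group-mean differences are plain
  subtraction on the reported means — note that a difference computed
  from unrounded raw data can disagree in the last digit with the
  difference of the rounded means.
* Trio copy-number requirements are evaluated on a single CNV record;
  matching parental and proband deletion calls across records with merely
  overlapping coordinates is not attempted, since reciprocal-overlap
  conventions are caller-specific and under-determined.
* Pipeline runs are reproducible by construction: every source of
  randomness derives from one seed, outputs carry no timestamps except
  the report's own `timestamp` field, and the report's provenance block
  records the package version, seed and full configuration verbatim.

## Problem sizes used in the checks

The test-suite and acceptance checks run at desk scale, chosen as the
smallest sizes at which the statistical assertions are sharp: 10,000
background sites for the Mendelian-fraction and Hardy–Weinberg checks
(3-sigma binomial band and chi-square goodness of fit at α = 0.01), 100
seeded simulations of 500 background SNVs and 10 background CNVs for
causal recovery, 1,000-record random sets for filter/oracle equivalence,
the exhaustive 4⁶ = 4,096 call assignments on the six-member family for
the segregation oracle, and 200 randomized instances for interval
overlap.

## A worked example

```{r example}
cfg <- run_config(
  simulation = simulation_config(seed = 1, n_background_snvs = 500,
                                 n_cnv_background = 10),
  outdir = file.path(tempdir(), "trioscan-demo"))
report <- run_pipeline(cfg)
report$counts[c("n_snv_examined", "n_snv_pass", "n_cnv_pass")]
head(report$genes)
report$truth$causal_gene
```

The planted causal gene appears at the top of the gene table at high
impact, together with whatever background variants happened to match the
trio pattern — exactly the situation a real screen faces before
segregation testing and literature triage narrow the list.

## Known limitations

Verdicts assume complete penetrance and no phenocopies; a single
misphenotyped individual can wrongly exclude a true candidate, and no
tolerance knob is provided. The segregation informativeness floor
(three genotypes) is a pragmatic minimum, not a statistical power
statement — no LOD score or linkage statistic is computed. The simulator
is a correctness instrument for this pipeline, not a population-genetic
simulator; for realistic genealogies and recombination use a dedicated
coalescent or forward simulator.
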