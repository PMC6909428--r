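---
title: "Bulked-segregant mapping of EMS mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant mapping of EMS mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The mapping model

`mutmapr` targets one experimental design: a recessive (optionally
dominant) point mutation induced by EMS in an inbred line, crossed back to
the wild-type parent, selfed once, and mapped by sequencing two
phenotype-defined DNA pools of F2 plants.

Let `A` be the reference (wild) allele and `a` the mutant allele at a SNP.
In the F2, genotype frequencies at any locus heterozygous in the F1 are
`AA:Aa:aa = 1:2:1`. For a recessive causal locus:

* the MT pool (mutant phenotype) contains only `aa` plants, so the expected
  allele frequency of `a` — and hence the expected SNP-index — is exactly 1;
* the WT pool has `AA:Aa:aa = 1:2:0`, an allele ratio `A:a = 2:1`, so the
  expected SNP-index is exactly 1/3.

`expected_indices()` derives both values by enumerating the genotype
classes conditional on pool membership rather than hard-coding them, which
makes the dominant case (2/3 and 0) and pool-specific expectations at
*linked* markers fall out of the same machinery. For a marker at
recombination fraction $r$ from the causal locus,
`expected_marker_index()` enumerates the 16 ordered pairs of two-locus F1
gametes (mutant alleles in coupling; gamete haplotype probabilities
$(1-r)/2$ parental, $r/2$ recombinant) and conditions on the phenotype; in
the recessive MT pool the expected marker index is $1-r$, decaying to 0.5
at unlinked loci. This enumeration is the package's analytic backbone and
is cross-checked in the tests against an independent Monte-Carlo gamete
simulation.

### The screen

`screen_candidates()` retains a site when

1. depth ≥ `min_depth` in **both** pools (default 10; pooled-sequencing
   studies rarely state a depth floor, so this is an explicit assumption
   of the implementation);
2. the MT pool is fixed for the mutant allele. With the default
   `mt_epsilon = 0` this is implemented at the count level — zero reference
   reads at nonzero depth — which is the exact meaning of "SNP-index =
   1.0". A relaxed rule `index ≥ 1 - mt_epsilon` is available because a
   single miscalled read destroys exact unity under realistic error rates;
3. the WT-pool index lies in `wt_center ± wt_halfwidth`, default 0.3 ± 0.1
   with **inclusive** endpoints. The band is centred on 0.3 (the
   conventional rounded target) rather than on the analytic 1/3, which lies
   comfortably inside it. Endpoint comparisons carry a 1e-9 guard so that
   a count-exact index of 0.4 is not rejected by floating-point noise.

### Segregation testing

`chisq_segregation()` is an uncorrected Pearson goodness-of-fit test
(`stats::chisq.test`, no Yates correction). With two phenotype classes the
continuity-corrected statistic noticeably inflates the p-value at
moderate counts (for 221:59 against 3:1 the corrected test gives ≈ 0.15
versus 0.129 uncorrected), and the uncorrected test is the standard choice
for segregation ratios, so no correction is applied.

### Fine-mapping by recombinant exclusion

The screen cannot separate SNPs in tight linkage — they are all fixed in a
small MT pool. `exclude_candidates()` therefore applies the individual-
level rule: under recessive inheritance, one plant that is phenotypically
mutant but not `aa` at a candidate, or wild type yet `aa`, excludes that
candidate outright (full penetrance and error-free genotypes are assumed;
one contradicting plant is decisive). A candidate with no contradiction
among ≥ 1 informative call is *completely linked*; zero informative calls
give *undetermined* with a warning. F3-derived confirmation data are
handled by simply appending those individuals to the genotype table — the
rule does not change, so no separate procedure is needed.

`find_recombinants()` flags plants whose two-locus genotype pair cannot be
formed from two non-recombinant gametes. With both mutant alleles in
coupling this reduces to the two codes differing; an `Aa`/`Aa` pair could
conceal two complementary recombinant gametes but is unphaseable from
genotype data, so it is deliberately not flagged.

### Effect annotation

`annotate_effect()` locates a SNP in a strand-aware CDS model (exons in
transcription order, 1-based closed coordinates, reading frame anchored at
the CDS start), substitutes the alternative allele — complemented for
minus-strand genes — and translates reference and alternative codons under
the standard genetic code (`Biostrings::GENETIC_CODE`). Consequences are
`synonymous`, `missense`, `stop_gained`, `stop_lost`, or `non_coding`
(intronic/intergenic). Exon indices in reports are transcription-order so
that "the 8th exon" of a minus-strand gene means what a biologist expects.
One cautionary note for interpreting nonsense candidates: no single
C→T (or strand-equivalent G→A) change can turn a Glu codon
(GAA/GAG) into a stop — EMS nonsense changes at `CAA/CAG` (Gln), `CGA`
(Arg) or `TGG` (Trp, on the other strand) are the canonical routes — so a
reported Glu→stop from an EMS screen usually indicates a Gln codon
upstream of a bookkeeping slip. The test suite checks all 576
codon × substitution cases on both strands against a brute-force
translate-and-compare oracle.

## The simulator

The generator reproduces the statistical structure the analysis assumes,
stage by stage, under one master seed that is split deterministically into
per-stage seeds (mutations / causal choice / meiosis / reads per pool), so
every artifact of a run is bit-reproducible.

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| scaffolds | 5 × 2 Mb | bp | enough linked + unlinked structure at desk scale |
| `recomb_rate` | 3 | cM/Mb | typical genome-wide rate for a legume-sized plant genome |
| `density` | 50 | SNPs/Mb | gives ~500 SNPs over 10 Mb, a realistic EMS load per genome unit |
| `spectrum` | 1.0 | fraction | pure G:C→A:T transitions, the canonical EMS signature |
| `n_progeny` | 280 | plants | a practical F2 family size for this design |
| `depth` | 50 | reads/site/pool | pooled resequencing depth; an assumption — pooled depths are rarely published |
| `error_rate` | 0 | per base | errors off by default so expectations are exact; set > 0 to study robustness |

Mutation counts per scaffold are Poisson(`length × density / 1e6`) with
uniform positions; non-EMS substitutions (when `spectrum < 1`) are drawn
uniformly from the ten substitutions outside G:C→A:T so the realised
spectrum fraction is interpretable. Meiosis uses the Haldane model:
crossovers are a Poisson process along the scaffold with no interference,
implemented as a Markov chain over loci whose switch probabilities are the
Haldane recombination fractions of the inter-locus distances — exactly
equivalent to placing Poisson crossovers, and O(individuals × loci).
Each F2 is two independent gametes; phenotype is a deterministic function
of the causal genotype (full penetrance, no phenocopies). Pool members
contribute DNA equally, so a read draws its allele Bernoulli(pool allele
frequency), is flipped with probability `error_rate`, and lands on either
strand with probability 1/2; site depth is Poisson.

What the simulator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: read-level artifacts (mapping bias,
base-quality structure, indel noise), variance in DNA contribution between
pooled plants, incomplete penetrance or phenotyping error, segregation
distortion, and polygenic or epistatic phenotypes. Simulation starts at
allele-count level by design; it validates the statistical logic of the
pipeline, not a caller.

## Numerical and scale choices

* Coordinates are 1-based fully closed everywhere, matching VCF.
* The WT-band comparison uses inclusive endpoints with a 1e-9 tolerance;
  SNP-index is `NA` (undefined), never 0/0, at zero depth.
* The config hash stamped into every output file is the md5 of the YAML
  serialisation of the scientific parameters (the output directory is
  excluded, so the same analysis hashes identically wherever it is
  written).
* Validation problem sizes were chosen so the whole suite runs at desk
  scale: Mendelian-ratio checks use 10,000 progeny; the marker-decay
  oracle uses a 200,000-plant population so that, at a read depth of
  10,000, pool-frequency noise (sd ≈ 0.001) is negligible against
  read-sampling noise and a 3-binomial-SE band is the operative
  tolerance; Monte-Carlo cross-checks of the analytic indices use 10^5 to
  10^6 draws. All stochastic checks use 3-standard-error bands under
  fixed seeds.

## Known limitations

* With ~280 plants, markers within a few tens of kb of the causal SNP
  often show no recombinant at all, so fine-mapping typically ends with a
  small *set* of completely linked SNPs rather than a single one; the
  pipeline reports the whole set and flags whether the causal SNP is
  uniquely linked. Narrowing further needs more plants or F3 progeny
  tests.
* The strict MT criterion (zero reference reads) is exact only with
  error-free reads; with realistic error rates use `mt_epsilon` of a few
  times the error rate, at the cost of admitting more linked neighbours.
* Only single-transcript CDS models are annotated: no splice-site, UTR or
  multi-transcript logic.
* The chi-square segregation test is asymptotic; for very small families
  an exact binomial test is preferable.
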