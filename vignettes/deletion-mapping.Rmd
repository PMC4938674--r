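---
title: "Mapping overlapping SHOX-region deletions from depth, pools and droplets"
author: "shoxdel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping overlapping SHOX-region deletions from depth, pools and droplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoxdel)
```

## The problem

Skeletal atavism in Shetland ponies is a recessive disorder in which the
ulna and fibula regrow to their full ancestral length, deforming the
limbs. The causal locus is the pseudoautosomal region (PAR) around the
*SHOX* gene, where two large overlapping deletions segregate: a larger
allele (*Del-1*, on the order of 160–180 kb, removing all of *SHOX*) and
a smaller allele (*Del-2*, 60–80 kb) that corresponds to the distal part
of *Del-1*. Both remove part of *CRLF2*. Animals are affected when both
haplotypes carry a deletion — homozygous for either allele or compound
heterozygous — because all three combinations lose the shared distal
segment.

This package implements the computational pipeline for mapping and
genotyping such nested deletions from three kinds of evidence:

1. a **fixed allele-frequency-difference screen** comparing individually
   sequenced cases against one pooled control sample;
2. **windowed read-depth copy-number analysis** of cases relative to the
   pool, with segment calling, soft-clip breakpoint refinement and
   tandem-repeat annotation;
3. **droplet digital PCR (ddPCR)** copy-number genotyping, and
   population summaries of the resulting genotype calls.

Because the PAR recombines in both sexes and escapes X-inactivation, the
region is diploid in males and females alike; ploidy is fixed at 2
throughout and sex never enters the model.

## The sequencing design and its synthetic emulation

The study design the simulator reproduces is: six affected individuals
sequenced separately at ~7X, and a single control pool of 21 unaffected
males combined in equimolar amounts and sequenced at ~56X. The generator
(`build_region_model()`, `simulate_depth()`,
`simulate_pool_snp_counts()`, `simulate_ddpcr()`,
`simulate_population()`) is a first-class, tested part of the package:
every downstream stage can be exercised end to end without any external
data.

Defaults encode the study conditions:

* **Geometry** — a 300 kb diploid region; *Del-1* of 170 kb (the middle
  of the published 160–180 kb bracket) placed centrally; *Del-2* of
  70 kb (middle of 60–80 kb) sharing *Del-1*'s distal end. This yields
  breakpoints BP1 (proximal end of *Del-1*), BP2 (proximal end of
  *Del-2*) and BP3 (the shared distal end).
* **Coverage** — 7X per case, 56X for the 21-member pool. The pool is
  simulated from its members' explicit genotypes, so equimolarity is
  exact by construction.
* **Depth model** — per-base depth is Poisson with mean
  `coverage × copy_number / 2`, the standard shotgun-coverage model at
  the scale where read-length correlation is negligible relative to
  1-kb windows. An optional uniform `mapping_noise` floor (default 0)
  lets deleted segments receive stray reads; the default is zero
  because the real cases showed essentially no reads over the
  deletions.
* **Breakpoint repeats** — perfect TGGA tandem runs of 1.2 kb are
  placed at BP1 and BP3 (the real runs exceed 1 kb). SNP sites are
  drawn uniformly outside repeat runs, with a Beta(0.8, 0.8) site
  frequency spectrum by default (mildly U-shaped, as population
  polymorphism tends to be).
* **Soft clips** — background clip rate 0.01 per read; a 10-fold
  enrichment within ±500 bp of a breakpoint is applied when the sample
  carries at least one junction chromosome *and* at least one
  chromosome intact across that breakpoint. The second condition is a
  deliberate modelling choice: junction-spanning reads cannot be
  anchored across the >1 kb TGGA runs flanking the real breakpoints, so
  visible clip signal needs locally mapped coverage from an intact
  haplotype. A homozygous deleted sample therefore shows no clip peak,
  while a carrier (or a pool containing carriers) does — matching where
  the enrichment was actually observed.
* **ddPCR** — droplet occupancy is the classical Poisson model: a
  droplet is positive with probability `1 − exp(−λ)`. The default load
  is 1.0 reference copies per droplet, a deliberate choice in the
  mid-range where the occupancy curve is steep and the λ estimator is
  near its precision optimum (the wet-lab load behind the published
  assays is not recoverable from the reported protocol). 15,000
  droplets per assay reflects a routine run.

What the generator does **not** emulate: read-level artefacts
(alignment, base quality, duplicates), GC or mappability bias along the
genome, linkage disequilibrium between SNP sites, and partial or
imprecise deletion boundaries. Passing tests therefore demonstrate that
the analysis logic is correct under the idealized counting model, not
that it is robust to alignment pathology in real BAMs — those effects
enter this pipeline only through the depth and count tables it consumes.

## The screen

At every biallelic SNP the screen demands the published signature: the
pool fixed for the reference allele (with at least one read — a pool
with no reads cannot assert fixation), and every *covered* case fixed
for the alternate allele. Cases with no reads at the site do not
disqualify it; that asymmetry is essential, because at the causal locus
the homozygous-deleted cases have no reads at all while hemizygous
cases read as homozygous-alternate. `min_covered_cases` (default 1) and
`min_case_depth` (default 1) are exposed because the study's hits were
covered in only three of six cases and the threshold actually used is
not stated; the defaults are the most permissive rules consistent with
the published description. Fixation is exact by default; an optional
`max_discordant_reads` (≤ 1 recommended) tolerates sequencing error in
noisy data but is off by default. The count-level rules replace the
genotype-caller-based filtering of the original analysis; they are
transparent, testable against a brute-force filter, and reproduce the
published signature on synthetic data.

## Windowed copy number

Depth is averaged in non-overlapping 1-kb windows (the window statistic
is the mean, matching the linear Poisson expectation; a median adds
nothing at this scale), normalized by each sample's genome-wide mean
depth, and expressed as a copy number
`2 × case_normalized / pool_normalized`. The genome background mean
includes deleted windows: at genome scale they are a negligible
fraction, and no exclusion rule is published. Windows where the pool's
normalized depth falls below `min_pool_normalized = 0.2` yield an
*undefined* copy number rather than an inflated ratio — below that the
pool itself lacks signal (unassembled or repetitive sequence). The pool
Z-score `(normalized − mean)/SD`, computed with all-window sample
moments (the whole-genome moments in the full-scale setting), verifies
pool uniformity; a constant normalized track has zero SD and is
rejected as degenerate rather than silently scored 0.

## Segment calling and breakpoints

Windows are classified with the same numeric ranges used for ddPCR
genotyping (two copies 1.7–2.3, one copy 0.7–1.3, null < 0.3) — one
classification vocabulary for both modalities. Consecutive same-state
deletion windows (state 0 or 1) are merged; runs of up to
`max_gap_windows = 2` ambiguous or undefined windows are bridged, and
segments need `min_windows = 3` supporting windows. These are the
smallest values that survive single-window noise at 7X; a window of the
*other* deletion state always terminates a segment, which is what
separates the one-copy and null-copy segments of a compound
heterozygote. Boundaries are reported at window resolution — the
breakpoints sit in kilobase-scale tandem repeats and are not base-
resolvable from short reads, so pretending otherwise would be false
precision.

Soft-clip enrichment is scanned in 500-bp sliding windows with a
binomial upper-tail test against the background clip rate and
Bonferroni control across windows (conservative, but the goal is peak
calling, not inference; a missed borderline window costs nothing while
a false peak sends a wet lab somewhere useless). Contiguous significant
windows collapse to one peak. `find_motif_runs()` reports maximal
perfect tandem runs (whole copies, given strand, leftmost-greedy) of at
least 1 kb by default, and `annotate_breakpoints()` pairs clip peaks
with their flanking runs.

## Genotyping

The two informative intervals are the segment unique to *Del-1*
(BP1–BP2) and the shared segment (BP2–BP3). The copy-state pair over
these maps bijectively onto the six genotypes; any pair violating the
nesting structure, or involving an ambiguous state, is `unresolved` —
a value, not an error, surfacing measurements the published analysis
resolved by manual cluster adjustment. The same classifier serves
sequencing-derived region means (`genotype_cohort()`) and
ddPCR-derived copy numbers (`ddpcr_genotype()`); with several replicate
assays per region a strict-majority consensus absorbs one discordant
assay out of three. `Del2/Del2` calls resting on fewer than three
windows carry a `low:few_windows` confidence flag, since that genotype
is distinguished from `Del1/*` only by the unique segment staying at
two copies.

ddPCR quantification is deliberately dimensionless: λ ratios need no
volume or concentration conversion, which is all the genotyping
requires. A saturated well (all droplets positive) is an error — the
sample needs re-dilution; extrapolating λ to infinity would be
meaningless. The null-state bound `zero_max = 0.3` mirrors the gap
below the one-copy range; the published genotyping found no outliers
requiring a null range at all.

## Population summaries

Allele frequencies use gene counting: each heterozygote contributes one
copy, each homozygote two, over `2n` chromosomes. No EM step is needed
because the assays observe deletion genotypes completely. Affected
individuals, absent from the published random set but possible in other
cohorts, are counted like any other genotype. Carrier fraction is the
heterozygote share of individuals, and Hardy–Weinberg expectations
follow the trinomial expansion with expected affected fraction
`(q1 + q2)^2` — the quantity that makes compound heterozygosity matter
for breeding decisions.

## Worked example

```{r example}
model <- build_region_model(seed = 1)
model

tracks <- list(
  case1 = simulate_depth(model, sample_spec("case1", c("Del1", "Del1")), seed = 11),
  case2 = simulate_depth(model, sample_spec("case2", c("Del1", "Del2")), seed = 12),
  pool  = simulate_depth(model, sample_spec("pool", mean_coverage = 56,
            pool_members = rep(list(c("WT", "WT")), 21)), seed = 13))
wt <- build_window_table(tracks, pool_id = "pool")
genotype_cohort(wt, model)
call_deletions(wt)
```

```{r ddpcr}
random_set <- c(rep(list(c("Del1", "WT")), 9), rep(list(c("Del2", "WT")), 2),
                rep(list(c("WT", "WT")), 83))
names(random_set) <- sprintf("rs%02d", seq_along(random_set))
assays <- simulate_ddpcr_cohort(random_set, seed = 14)
calls <- ddpcr_genotype(assays)
population_summary(genotype_counts(calls$genotype))
```

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open everywhere; positions become 1-based
only in the samtools-style depth TSV. All classification boundaries are
inclusive. Undefined quantities (zero-depth allele frequency, copy
number over a silent pool window, λ of an unmeasured assay) propagate
as `NA`/`NaN` and downstream classifiers treat them as ambiguous.
Errors are reserved for inputs that cannot mean anything: empty tracks,
unsorted windows, saturated wells, zero-SD Z-scores, inconsistent
deletion spans.

Every stochastic function takes an explicit integer seed and is
byte-reproducible under it. The test suite verifies the stages at the
study's own scale — 300 kb regions, 7X/56X coverage, 20–50 seeded
replicates, 15,000-droplet assays, a 94-individual population — sizes
at which the whole suite runs in about a minute.

## Limitations

* Breakpoints are window-resolution by design; no split-read assembly
  is attempted (the original chromosome-walking attempts across the
  TGGA runs failed, and count-level inputs contain no read sequence).
* The screen handles biallelic SNPs only; indels and multi-allelic
  sites are out of scope.
* Pool-based screening assumes one pool; designs with several pools
  would need a straightforward but unimplemented extension.
* Genotypes `Del2/Del2` and `WT/WT` differ only in the shared segment;
  at very low coverage that single contrast drives the call, which is
  why the few-window confidence flag exists.
* No pedigree-based inference: genotypes come from measurements, not
  relatives.
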