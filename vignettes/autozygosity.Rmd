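---
title: "Quantifying inbreeding from a single genome: windowed heterozygosity, ROH, gene dropping and pedigree ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inbreeding from a single genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozygy)
```

## The problem

A single diploid genome carries a readable record of its owner's recent
ancestry. When the parents are close relatives, long stretches of the
genome are *autozygous* — both haplotypes descend from the same ancestral
haplotype — and appear as megabase-scale **runs of homozygosity (ROH)**:
windows almost empty of heterozygous sites. Three questions follow, and
this package answers each:

1. **How inbred is the individual?** Estimated as
   $F_{ROH} = L_{ROH} / L_{genome}$, the fraction of the effective
   (unmasked, autosomal) genome covered by ROH above a length cutoff.
2. **Which mating produced it?** Different pedigrees with the same expected
   $F = 0.125$ (half-siblings, full avuncular pairs, grandparent–grandchild)
   differ in the *number and length distribution* of the autozygous
   segments they produce, because they differ in how many meioses — and of
   which sex — separate the focal individual from the shared ancestor.
   A gene-dropping simulator generates these distributions and a
   multinomial likelihood scores the observed callset against each model.
3. **Which variant explains a recessive phenotype?** For a recessive
   disorder in an inbred individual the causal variant should be
   homozygous, protein-changing, inside a known candidate gene, absent
   from unaffected comparison genomes, and — as a consistency check — sit
   inside a long ROH.

Everything runs on synthetic data generated by the package itself, so the
full pipeline is testable end to end without any external download.

## Windowed heterozygosity and ROH calling

The genome is tiled into non-overlapping 1-Mbp windows. Windows whose
overlap with a segmental-duplication mask exceeds 40% (strictly) are
dropped — duplications attract mismapped reads and fake heterozygosity.
For retained windows the density is corrected for masking:

$$\mathrm{het/kbp} = 1000 \cdot \frac{\#\{\text{het sites outside the mask}\}}{\text{window length} - \text{masked bp}}.$$

Both numerator and denominator refer to unmasked sequence, so a
half-masked window with the same underlying diversity reports the same
density as a clean one.

A ROH is a maximal run of at least two consecutive windows whose density
falls strictly below a threshold. Decisions the method needed that the
procedure's verbal description leaves open, and how this implementation
resolves them:

* **The threshold.** "Reduced heterozygosity" is relative to the
  individual's own diversity, so the default cut is $0.25\times$ the
  genome-wide median density of eligible windows — scale-free, robust to
  overall diversity level, and overridable by an absolute value
  (`het_threshold`). With a background of ~1 het/kbp, a clean 1-Mbp window
  has a Poisson(1000) count; the probability of falling below a 0.25
  threshold by chance is astronomically small, so false windows are not a
  practical concern at these settings.
* **Masked windows inside a run.** One masked (or trailing-short) window
  does not interrupt a run — it simply contributes no qualifying window —
  but two or more consecutive ones do. This mirrors the spirit of the
  500-kbp gap merge at the window scale.
* **Trailing windows.** The last window of a chromosome participates only
  if it is at least half the nominal window size; shorter windows have
  noisy densities.
* **Resolution.** Segment coordinates snap to window boundaries. The
  method is window-based; no site-level boundary refinement is attempted.

Called segments are then post-processed the same way simulated ones are:
segments separated by gaps strictly smaller than 500 kbp are merged
(merging first), then segments shorter than 2 Mbp are removed. Merge-first
lets a cluster of short sub-threshold segments survive as one long
segment — this is what allows adjacent two-window runs to accumulate into
the tens-of-megabases segments an inbred genome shows. The stricter
filter-first order is available via `postprocess_segments(order =
"filter_first")` for sensitivity analysis. $F_{ROH}$ divides the summed
segment lengths by the effective genome: the unmasked length retained by
the window track.

## The gene-dropping simulator

`pedigree_models()` enumerates ten inbred mating structures: five
relationship classes — half-siblings, uncle–niece, aunt–nephew,
grandfather–granddaughter, grandmother–grandson — each in two sex
configurations (which parent is shared, or through which sex the
generational link runs). Avuncular links use *full* siblings: with
half-siblings they would give $F = 0.0625$, outside this family of
models. Every model therefore has pedigree expectation $F = 0.125$, but
the models differ in the male/female composition of the meioses in the
inbreeding loop, which matters because recombination is sex-specific.

Founders receive two single-label haplotypes each (all labels globally
unique: founders are non-inbred and mutually unrelated). Each descendant
receives one gamete per parent. A gamete is formed per chromosome by:

* crossover count $\sim$ Poisson(rate $\times$ physical length), with
  rate $8.9\times10^{-9}$ crossovers/nucleotide for male meioses and
  $1.4\times10^{-8}$ for female meioses;
* crossover positions uniform, no interference, no obligate chiasma;
* a fair-coin starting haplotype, alternating strand at every crossover.

Autozygous segments of the focal individual are the maximal intervals on
which its two haplotypes carry the same founder label — identity by
descent with full penetrance (no mutation, no genotyping error). The
replicate loop is compiled (Rcpp); the step-by-step R functions
(`make_founder()`, `meiosis()`, `simulate_pedigree()`,
`extract_autozygous()`) call the same chromosome kernel, and a test pins
the equivalence of the two paths under a shared seed. Simulated segments
pass through exactly the same post-processing as the empirical callset so
the two length distributions are comparable.

Randomness is driven by R's global RNG: one `set.seed()` reproduces an
entire run bit for bit. Per-replicate sub-streams were considered and
rejected — R's base RNG has no cheap independent-stream facility, and
whole-run reproducibility is what the tests and the pipeline need.

## Ranking pedigree models

Post-processed segment lengths are binned into 5-Mbp classes starting at
the 2-Mbp cutoff (edges 2–7, 7–12, … Mbp, left-closed right-open, top bin
open-ended; no shorter segment can exist after filtering, so lower edges
below 2 Mbp would be dead bins). For each model, bin probabilities are
estimated from the segments pooled over all replicates with a 0.5
pseudocount per bin — without it a single observed segment in a bin the
simulation never produced would score $-\infty$. The observed counts
$c$ are then scored by the multinomial log-likelihood

$$\log P(c \mid p) = \log n! - \sum_i \log c_i! + \sum_i c_i \log p_i,
  \qquad n = \sum_i c_i.$$

Segment *number* enters only through $n$; no separate term on the segment
count is added by default, to keep the statistic exactly the binned
multinomial. Models are reported sorted by log-likelihood with explicit
ranks; ties share a rank and are never silently broken — with ten models
of identical pedigree $F$, near-ties are the expected outcome, and the
correct claim is usually "a 0.125-class pedigree", not a unique winner.
An empty observed callset is a hard error with guidance: no ROH means no
inbreeding signal to rank.

## The synthetic-data generator

The generator's defaults define the study conditions used throughout the
tests:

| parameter | default | meaning |
|---|---|---|
| genome | 22 autosomes, 2.875 Gbp | lengths proportional to GRCh37 autosomes |
| background rate | 1.0 het/kbp | great-ape-scale autosomal diversity |
| ROH rate | 0.05 het/kbp | residual (error-like) heterozygosity inside autozygous tracts |
| dup_fraction | 0.05 | fraction of genome covered by the duplication mask |
| planted ROH | one gene-dropped uncle–niece replicate | truth tracts with realistic number/length structure, $F \approx 0.125$ |
| panel | 2 individuals | comparison genomes for the privacy filter |

Heterozygous sites are a homogeneous Poisson process at the applicable
rate; no linkage structure is simulated because no downstream stage
consumes LD — only marginal site density. Planting the truth tracts by
actually gene-dropping a pedigree (rather than placing rectangles by
hand) gives the truth set the segment-size spectrum a genuinely inbred
genome would have. The candidate-variant fixture is constructed so that
exactly one variant — the planted causal one — survives the full funnel:
other in-gene homozygous non-synonymous variants are all shared with at
least one panel member, and background in-gene homozygous non-synonymous
records are demoted to heterozygous so they cannot create spurious
private candidates.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: alignment and calling artifacts (beyond the
duplication mask), callability/depth variation, LD and mutation-rate
heterogeneity, genotyping error inside ROH beyond a constant residual
rate, and sex chromosomes (hemizygosity breaks the heterozygosity model;
builds are autosome-only). Real-data F_ROH estimates also depend on
upstream SNV-calling quality, which is out of scope here.

## Numerical and edge-case conventions

* Coordinates: 0-based half-open everywhere in memory and in BED output;
  VCF positions 1-based per its standard. A variant at an interval's
  start coordinate is inside; at its end coordinate, outside.
* All comparisons stated as strict are strict: window dropped when
  overlap $> 0.40$; window low when density $<$ threshold; gap merged
  when $<$ 500 kbp; segment removed when $<$ 2 Mbp.
* A panel record with a missing genotype counts as allele absence for the
  privacy filter but flags the variant (`panel_missing`) so the
  ambiguity is surfaced, not hidden.
* Generators seed the RNG internally for reproducibility and restore the
  caller's RNG state on exit, so a generator call never perturbs a
  surrounding simulation's stream.

## Problem sizes

The full-scale reference analyses (2.875-Gbp genome, ten models at
10,000 replicates each) run in tens of seconds thanks to the compiled
simulator core; the package's tests exercise the full scale where the
quantity under test demands it (pedigree expectations, crossover
calibration, the default fixture) and smaller genomes (0.3–1.8 Gbp, a few
hundred to a few thousand replicates) for structural and oracle checks,
where the property being verified is size-independent.

## Worked example

```{r example, eval = FALSE}
study <- synthetic_study(seed = 1)
w <- het_windows(study$build, study$het_sites, study$dup_mask)
seg <- postprocess_segments(call_roh(w))
callset <- compute_f_roh(seg, sum(w$effective_bases[!w$masked_out]))
callset
#> <roh_callset> 17 segments, 287.0 Mbp / 2734.8 Mbp, F_ROH = 0.105

runs <- lapply(pedigree_models(), run_model, n_reps = 1000, seed = 2)
head(rank_models(callset$segments, runs), 3)

prioritize_variants(study$candidate$focal, study$genes,
                    study$candidate$panel, callset)$funnel
#>                stage    n
#> 1              input 2020
#> 2 hom_non_synonymous  321
#> 3  in_candidate_gene   20
#> 4            private    1
```

## Known limitations

* The ROH caller is a deterministic window-threshold scan, not an HMM; it
  cannot resolve segment boundaries below window size nor call segments
  shorter than two windows.
* The pedigree registry covers only the ten $F = 0.125$ structures;
  parent–offspring and full-sibling matings ($F = 0.25$) and half-avuncular
  ones ($F = 0.0625$) are deliberately out of scope, though
  `pedigree_model()` accepts arbitrary structures if a user supplies them.
* The likelihood compares binned counts only; two models whose binned
  spectra coincide are indistinguishable by construction, and the ranking
  reports such ties rather than resolving them.
* Crossover positions are interference-free Poisson; real meioses show
  positive interference and an obligate chiasma, which slightly narrows
  segment-length spread relative to this model.
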