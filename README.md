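# autozygy

Quantify inbreeding from a single diploid genome and infer the pedigree
behind it.

When an individual's parents are close relatives, long tracts of its genome
are *autozygous* — both haplotypes descend from one recent ancestral
haplotype — and show up as megabase-scale **runs of homozygosity (ROH)**.
`autozygy` implements the full analysis chain around that signal, for
population and conservation geneticists working with a single genome of
interest (e.g. a wild-born individual of an endangered species) plus a small
panel of comparison genomes:

* **Windowed heterozygosity** — het sites/kbp in 1-Mbp windows, with
  segmental-duplication masking (windows > 40% masked are dropped) and
  effective-base correction.
* **ROH calling and F_ROH** — maximal runs of ≥ 2 consecutive windows with
  density below a scale-free threshold; gap-merge (< 500 kbp) then
  length-filter (≥ 2 Mbp); the inbreeding coefficient
  `F_ROH = total ROH / effective genome`.
* **Gene-dropping pedigree simulation** — founders with labeled haplotypes
  dropped through ten enumerated inbred pedigrees (half-sib, avuncular,
  grandparent–grandchild; all with expected F = 0.125), with sex-specific
  Poisson recombination (8.9×10⁻⁹ crossovers/nt male, 1.4×10⁻⁸ female) in a
  compiled core (10,000 genome-scale replicates in seconds).
* **Multinomial pedigree ranking** — simulated and observed segment lengths
  binned in 5-Mbp classes; each pedigree model scored by the multinomial
  log-likelihood of the observed counts, ties reported rather than broken.
* **Recessive candidate-variant prioritization** — homozygous →
  non-synonymous → candidate-gene → private-against-panel funnel, with
  ROH-context annotation.
* **Synthetic-data generation** — genomes, planted autozygous tracts (by
  actually gene-dropping a pedigree), duplication masks, annotated variant
  tables and comparison panels, so every stage is testable offline.

## Worked example

```r
library(autozygy)

study <- synthetic_study(seed = 1)           # 22 autosomes, 2.875 Gbp
w   <- het_windows(study$build, study$het_sites, study$dup_mask)
seg <- postprocess_segments(call_roh(w))
callset <- compute_f_roh(seg, sum(w$effective_bases[!w$masked_out]))
callset
#> <roh_callset> 17 segments, 287.0 Mbp / 2734.8 Mbp, F_ROH = 0.105
```

The synthetic individual was planted with uncle–niece-level inbreeding
(truth fraction 0.104 at this seed); the caller recovers 17 post-processed
segments totalling 287 Mbp, i.e. `F_ROH = 0.105`, with the largest segment
43 Mbp. Which pedigree explains that segment spectrum?

```r
runs <- lapply(pedigree_models(), run_model,
               build = study$build, n_reps = 1000, seed = 2)
rank_models(callset$segments, runs)[, c("model_id", "log_likelihood", "rank")]
```

returns the ten models sorted by log-likelihood. The ten structures share
pedigree F = 0.125 and differ only in their meiosis sex-mix, so near-ties
are expected — the honest conclusion is usually a *class* of pedigrees, not
a unique one. Finally, the recessive-variant funnel:

```r
prioritize_variants(study$candidate$focal, study$genes,
                    study$candidate$panel, callset)$funnel
#>                stage    n
#> 1              input 2020
#> 2 hom_non_synonymous  321
#> 3  in_candidate_gene   20
#> 4            private    1
```

Of 2,020 focal variants, 321 are homozygous non-synonymous, 20 of those sit
in candidate genes, and exactly one is absent from both panel genomes — the
planted causal variant, which the ROH annotation places inside the 43-Mbp
run of homozygosity (`in_roh = TRUE`), as expected for a recessive allele
exposed by identity-by-descent.

## Layout

```
R/                  implementation (one file per stage)
src/gene_drop.cpp   compiled meiosis / gene-dropping kernel
tests/testthat/     unit, property and acceptance tests (with oracles)
vignettes/          methods vignette: models, assumptions, design choices
scripts/acceptance.R
```
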