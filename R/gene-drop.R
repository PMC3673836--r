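#' Sex-specific recombination rates
#'
#' Per-nucleotide crossover rates used by the gene-dropping simulator.
#' Defaults are the empirical sex-averaged human estimates:
#' 8.9e-9 crossovers/nucleotide for male meioses and 1.4e-8 for female
#' meioses (female map ~1.57x longer).
#'
#' @param male,female Crossovers per nucleotide (> 0).
#' @return A list of class `recombination_rates`.
#' @export
recombination_rates <- function(male = 8.9e-9, female = 1.4e-8) {
  if (male <= 0 || female <= 0) stop("recombination rates must be > 0")
  structure(list(male = male, female = female),
            class = "recombination_rates")
}

rate_for_sex <- function(rates, sex) {
  if (sex == "M") rates$male else rates$female
}

#' Create a founder genome with labeled haplotypes
#'
#' Each founder carries two haplotypes, each a single segment with one
#' globally unique founder-haplotype label; founders are therefore
#' non-inbred and mutually unrelated by construction. Autozygosity in a
#' descendant is defined as both haplotypes carrying the same label.
#'
#' @param build A [genome_build()].
#' @param sex `"M"` or `"F"`.
#' @param labels Integer pair of distinct haplotype labels.
#' @return A list of class `labeled_genome`: `chroms` (per chromosome,
#'   `h1`/`h2` each a list `brk`, `lab`), `sex`, `build`.
#' @export
make_founder <- function(build, sex, labels) {
  stopifnot(inherits(build, "genome_build"), sex %in% c("M", "F"),
            length(labels) == 2, labels[1] != labels[2])
  chroms <- lapply(seq_len(nrow(build)), function(i) {
    list(h1 = list(brk = 0, lab = as.integer(labels[1])),
         h2 = list(brk = 0, lab = as.integer(labels[2])))
  })
  names(chroms) <- build$chrom
  structure(list(chroms = chroms, sex = sex, build = build),
            class = "labeled_genome")
}

#' Simulate one meiosis
#'
#' Per chromosome, the crossover count is Poisson with mean
#' `rate * chromosome length` (rate chosen by the parent's sex), crossover
#' positions are uniform with no interference, the starting haplotype is a
#' fair coin, and the copied strand alternates at every crossover. Uses R's
#' RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param parent A [make_founder()]-style `labeled_genome`.
#' @param rates A [recombination_rates()].
#' @param sex Parent sex; defaults to `parent$sex`.
#' @return A list of class `gamete`: `haplotypes` (per chromosome list
#'   `brk`, `lab`) and `n_crossovers` (integer vector per chromosome).
#' @export
meiosis <- function(parent, rates = recombination_rates(),
                    sex = parent$sex) {
  stopifnot(inherits(parent, "labeled_genome"))
  res <- cpp_meiosis(unname(parent$chroms), parent$build$length,
                     rate_for_sex(rates, sex))
  haps <- lapply(res, function(x) list(brk = x$brk, lab = x$lab))
  names(haps) <- parent$build$chrom
  structure(list(haplotypes = haps,
                 n_crossovers = vapply(res, `[[`, 0L, "n_crossovers"),
                 build = parent$build),
            class = "gamete")
}

# Combine a paternal and a maternal gamete into a diploid genome.
fertilize <- function(paternal, maternal, sex) {
  build <- paternal$build
  chroms <- lapply(seq_len(nrow(build)), function(i) {
    list(h1 = paternal$haplotypes[[i]], h2 = maternal$haplotypes[[i]])
  })
  names(chroms) <- build$chrom
  structure(list(chroms = chroms, sex = sex, build = build),
            class = "labeled_genome")
}

#' Gene-drop through a pedigree and return the focal genome
#'
#' Founders are instantiated with unique haplotype labels; each descendant
#' receives one gamete from its father (male recombination rate) and one
#' from its mother (female rate), in the pedigree's topological order.
#'
#' @param model A [pedigree_model()].
#' @param build A [genome_build()].
#' @param rates A [recombination_rates()].
#' @return The focal individual's `labeled_genome`.
#' @export
simulate_pedigree <- function(model, build = default_build(),
                              rates = recombination_rates()) {
  stopifnot(inherits(model, "pedigree_model"))
  members <- model$members
  genomes <- vector("list", nrow(members))
  names(genomes) <- members$id
  label <- 0L
  for (i in seq_len(nrow(members))) {
    if (is.na(members$father[i])) {
      genomes[[i]] <- make_founder(build, members$sex[i],
                                   c(label + 1L, label + 2L))
      label <- label + 2L
    } else {
      pat <- meiosis(genomes[[members$father[i]]], rates, sex = "M")
      mat <- meiosis(genomes[[members$mother[i]]], rates, sex = "F")
      genomes[[i]] <- fertilize(pat, mat, members$sex[i])
    }
  }
  genomes[[model$focal]]
}

#' Extract autozygous segments from a diploid labeled genome
#'
#' Returns the maximal intervals on which the two haplotypes carry the same
#' founder-haplotype label (identity by descent through the pedigree, fully
#' penetrant: no mutation or genotyping error).
#'
#' @param genome A `labeled_genome`.
#' @return A data.frame `chrom`, `start`, `end`, `length` (0-based
#'   half-open), sorted; empty when the haplotype label sets are disjoint.
#' @export
extract_autozygous <- function(genome) {
  stopifnot(inherits(genome, "labeled_genome"))
  res <- cpp_extract_autozygous(unname(genome$chroms),
                                genome$build$length)
  out <- data.frame(chrom = genome$build$chrom[res$chrom],
                    start = res$start, end = res$end,
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out
}

#' Fraction of the genome covered by a segment set
#'
#' @param segments A data.frame with `start`, `end`.
#' @param build A [genome_build()].
#' @return Covered fraction in `[0, 1]`.
#' @export
autozygous_fraction <- function(segments, build) {
  sum(segments$end - segments$start) / total_length(build)
}

#' Run many gene-dropping replicates of one pedigree model
#'
#' Simulates `n_reps` independent focal individuals (compiled inner loop),
#' extracts their raw autozygous segments, and applies the same
#' post-processing as the empirical ROH callset (merge gaps < `max_gap`,
#' then drop segments < `min_length`) so simulated and observed
#' segment-length distributions are directly comparable.
#'
#' @param model A [pedigree_model()] (or an id from [pedigree_models()]).
#' @param build A [genome_build()].
#' @param rates A [recombination_rates()].
#' @param n_reps Number of replicates (default 10,000).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param min_length,max_gap Post-processing parameters, as in
#'   [postprocess_segments()].
#' @return A list of class `model_run`: `model_id`, `class`, `n_reps`,
#'   `segments` (post-processed, with a `rep` column), `raw_segments`,
#'   `prefilter_fraction` and `postfilter_fraction` (per-replicate genome
#'   fractions), `n_segments` (per-replicate post-filter counts), `params`.
#' @export
run_model <- function(model, build = default_build(),
                      rates = recombination_rates(), n_reps = 10000,
                      seed = NULL, min_length = 2e6, max_gap = 5e5) {
  if (is.character(model)) model <- pedigree_models()[[model]]
  stopifnot(inherits(model, "pedigree_model"), n_reps >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  members <- model$members
  fid <- match(members$father, members$id)
  mid <- match(members$mother, members$id)
  fid[is.na(fid)] <- 0L
  mid[is.na(mid)] <- 0L
  res <- cpp_run_model(as.integer(fid), as.integer(mid),
                       match(model$focal, members$id), build$length,
                       rates$male, rates$female, as.integer(n_reps))
  raw <- data.frame(rep = res$rep, chrom = build$chrom[res$chrom],
                    start = res$start, end = res$end,
                    stringsAsFactors = FALSE)
  raw$length <- raw$end - raw$start
  pre <- per_rep_fraction(raw, n_reps, build)
  post_seg <- postprocess_segments(raw, min_length = min_length,
                                   max_gap = max_gap)
  post <- per_rep_fraction(post_seg, n_reps, build)
  n_seg <- tabulate(post_seg$rep, nbins = n_reps)
  structure(list(model_id = model$model_id, class = model$class,
                 n_reps = n_reps, segments = post_seg, raw_segments = raw,
                 prefilter_fraction = pre, postfilter_fraction = post,
                 n_segments = n_seg,
                 params = list(rates = rates, min_length = min_length,
                               max_gap = max_gap)),
            class = "model_run")
}

per_rep_fraction <- function(seg, n_reps, build) {
  out <- numeric(n_reps)
  if (nrow(seg) > 0) {
    agg <- rowsum(seg$end - seg$start, seg$rep)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out / total_length(build)
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf(
    "<model_run> %s: %d reps, mean autozygous fraction %.4f (pre) / %.4f (post), %.1f segments/rep\n",
    x$model_id, x$n_reps, mean(x$prefilter_fraction),
    mean(x$postfilter_fraction), mean(x$n_segments)))
  invisible(x)
}
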