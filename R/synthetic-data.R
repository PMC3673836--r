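#' Describe the ground truth of a synthetic genome
#'
#' Bundles the parameters from which `gen_het_sites()` draws a heterozygous
#' site table: a background density, a (lower) density inside planted
#' autozygous tracts, the fraction of the genome to mask as duplicated, and a
#' seed. Defaults emulate an inbred great-ape autosomal genome: ~1
#' heterozygous site per kbp outside runs of homozygosity and a 20-fold
#' depletion inside them.
#'
#' @param planted_roh `NULL` or a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open): tracts generated with the low `roh_het_rate`.
#' @param background_het_rate Heterozygous sites per kbp outside planted ROH.
#' @param roh_het_rate Heterozygous sites per kbp inside planted ROH; must be
#'   strictly below `background_het_rate`.
#' @param dup_fraction Proportion of the genome covered by the duplication
#'   mask, in `[0, 1)`.
#' @param seed Integer seed driving all generators that consume this truth.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_roh = NULL, background_het_rate = 1.0,
                            roh_het_rate = 0.05, dup_fraction = 0.05,
                            seed = 1L) {
  if (background_het_rate < 0 || roh_het_rate < 0) {
    stop("heterozygosity rates must be >= 0")
  }
  if (roh_het_rate >= background_het_rate) {
    stop("'roh_het_rate' must be strictly below 'background_het_rate'")
  }
  if (dup_fraction < 0 || dup_fraction >= 1) {
    stop("'dup_fraction' must be in [0, 1)")
  }
  if (!is.null(planted_roh)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(planted_roh)))
    if (any(planted_roh$end <= planted_roh$start)) {
      stop("planted ROH must have end > start")
    }
    o <- order(planted_roh$chrom, planted_roh$start)
    planted_roh <- planted_roh[o, , drop = FALSE]
    same <- planted_roh$chrom[-1] == planted_roh$chrom[-nrow(planted_roh)]
    if (nrow(planted_roh) > 1 &&
        any(same & planted_roh$start[-1] <
              planted_roh$end[-nrow(planted_roh)])) {
      stop("planted ROH segments must not overlap")
    }
  }
  structure(list(planted_roh = planted_roh,
                 background_het_rate = background_het_rate,
                 roh_het_rate = roh_het_rate,
                 dup_fraction = dup_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

check_truth_against_build <- function(truth, build) {
  pr <- truth$planted_roh
  if (is.null(pr) || nrow(pr) == 0) return(invisible(TRUE))
  idx <- match_chrom(pr$chrom, build, what = "planted ROH")
  if (any(pr$start < 0) || any(pr$end > build$length[idx])) {
    stop("planted ROH extend beyond chromosome bounds")
  }
  invisible(TRUE)
}

#' Draw heterozygous sites as a Poisson process
#'
#' Site positions are a homogeneous Poisson process at
#' `background_het_rate` per kbp outside the planted ROH and `roh_het_rate`
#' inside them. No linkage structure is simulated: downstream stages consume
#' only marginal site density.
#'
#' @param build A [genome_build()].
#' @param truth A [synthetic_truth()]; its `seed` makes the draw
#'   reproducible.
#' @return A variant table: data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `gt` (all `"het"`), `consequence`, `gene`, sorted by
#'   (chrom, pos).
#' @export
gen_het_sites <- function(build, truth) {
  stopifnot(inherits(build, "genome_build"),
            inherits(truth, "synthetic_truth"))
  check_truth_against_build(truth, build)
  oseed <- push_seed(truth$seed)
  on.exit(restore_rng(oseed))
  acc <- list()
  for (i in seq_len(nrow(build))) {
    L <- build$length[i]
    pr <- truth$planted_roh
    if (!is.null(pr)) pr <- pr[pr$chrom == build$chrom[i], , drop = FALSE]
    # elementary intervals: outside-ROH pieces at background rate, planted
    # pieces at the ROH rate
    if (is.null(pr) || nrow(pr) == 0) {
      starts <- 0; ends <- L; rates <- truth$background_het_rate
    } else {
      starts <- c(0, pr$end)
      ends <- c(pr$start, L)
      keep <- ends > starts
      starts <- c(starts[keep], pr$start)
      ends <- c(ends[keep], pr$end)
      rates <- c(rep(truth$background_het_rate, sum(keep)),
                 rep(truth$roh_het_rate, nrow(pr)))
    }
    for (k in seq_along(starts)) {
      lambda <- rates[k] / 1000 * (ends[k] - starts[k])
      if (lambda <= 0) next
      n <- stats::rpois(1, lambda)
      if (n == 0) next
      p <- floor(stats::runif(n, starts[k], ends[k])) + 1 # 1-based
      acc[[length(acc) + 1]] <- data.frame(chrom = build$chrom[i], pos = p,
                                           stringsAsFactors = FALSE)
    }
  }
  out <- if (length(acc)) do.call(rbind, acc) else
    data.frame(chrom = character(0), pos = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
  out <- out[order(match(out$chrom, build$chrom), out$pos), , drop = FALSE]
  n <- nrow(out)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- alleles[(match(ref, alleles) + sample(1:3, n, replace = TRUE) - 1)
                 %% 4 + 1]
  variant_table(out$chrom, out$pos, ref, alt, gt = "het",
                consequence = "other", gene = NA_character_)
}

#' Generate a duplication mask
#'
#' Places intervals of roughly 50 kbp uniformly on each chromosome until the
#' requested coverage is reached, then merges overlaps, emulating a
#' segmental-duplication annotation used to exclude unreliable windows.
#'
#' @param build A [genome_build()].
#' @param dup_fraction Target proportion of the genome masked, in `[0, 1)`.
#' @param seed Integer seed.
#' @param mean_interval Nominal interval length in bp.
#' @return A data.frame `chrom`, `start`, `end` (0-based half-open), sorted
#'   and non-overlapping; total coverage approximates
#'   `dup_fraction * total_length(build)`.
#' @export
gen_dup_mask <- function(build, dup_fraction, seed, mean_interval = 5e4) {
  stopifnot(inherits(build, "genome_build"))
  if (dup_fraction < 0 || dup_fraction >= 1) {
    stop("'dup_fraction' must be in [0, 1)")
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (dup_fraction == 0) return(empty)
  oseed <- push_seed(seed)
  on.exit(restore_rng(oseed))
  pieces <- lapply(seq_len(nrow(build)), function(i) {
    L <- build$length[i]
    target <- dup_fraction * L
    len <- min(mean_interval, max(1, floor(L / 4)))
    k <- max(1L, as.integer(round(target / len)))
    s <- floor(stats::runif(k, 0, max(1, L - len)))
    data.frame(chrom = build$chrom[i], start = s,
               end = pmin(s + len, L), stringsAsFactors = FALSE)
  })
  merge_intervals(do.call(rbind, pieces), build)
}

# Sort and merge overlapping/bookended intervals (0-based half-open).
merge_intervals <- function(df, build = NULL) {
  if (nrow(df) == 0) return(df)
  if (!is.null(build)) {
    o <- order(match(df$chrom, build$chrom), df$start)
  } else {
    o <- order(df$chrom, df$start)
  }
  df <- df[o, , drop = FALSE]
  gr <- GenomicRanges::reduce(intervals_to_granges(df))
  granges_to_intervals(gr)
}

#' Generate candidate-gene intervals
#'
#' Places gene models (default: the four classical oculocutaneous-albinism
#' genes' names) on the genome. One gene can be pinned inside a given
#' interval so that, in the default fixture, the causal-gene analogue sits
#' inside a large planted run of homozygosity.
#'
#' @param build A [genome_build()].
#' @param seed Integer seed.
#' @param names Gene names.
#' @param pin_gene Name of the gene to place inside `pin_interval`, or
#'   `NULL`.
#' @param pin_interval A one-row data.frame (`chrom`, `start`, `end`) the
#'   pinned gene must fall into.
#' @param gene_length Gene length in bp.
#' @return A data.frame `gene`, `chrom`, `start`, `end` (0-based half-open).
#' @export
gen_candidate_genes <- function(build, seed,
                                names = c("TYR", "TYRP1", "OCA2", "SLC45A2"),
                                pin_gene = NULL, pin_interval = NULL,
                                gene_length = 2e5) {
  stopifnot(inherits(build, "genome_build"))
  oseed <- push_seed(seed)
  on.exit(restore_rng(oseed))
  n <- length(names)
  chrom_idx <- sample(seq_len(nrow(build)), n,
                      replace = nrow(build) < n,
                      prob = build$length)
  len <- pmin(gene_length, floor(build$length[chrom_idx] / 2))
  start <- floor(stats::runif(n, 0, build$length[chrom_idx] - len))
  out <- data.frame(gene = names, chrom = build$chrom[chrom_idx],
                    start = start, end = start + len,
                    stringsAsFactors = FALSE)
  if (!is.null(pin_gene)) {
    stopifnot(!is.null(pin_interval), pin_gene %in% names)
    i <- match(pin_gene, out$gene)
    span <- pin_interval$end - pin_interval$start
    glen <- min(gene_length, floor(span / 2))
    mid <- pin_interval$start + floor((span - glen) / 2)
    out$chrom[i] <- pin_interval$chrom
    out$start[i] <- mid
    out$end[i] <- mid + glen
  }
  out
}

#' Generate a candidate-variant fixture with one planted causal variant
#'
#' Builds the focal individual's annotated variant table plus a panel of
#' comparison individuals such that exactly one variant — the planted causal
#' one — is simultaneously homozygous-alt, non-synonymous, inside a candidate
#' gene, and absent from every panel individual. All other in-gene
#' homozygous non-synonymous variants are shared with at least one panel
#' member; background variants of every genotype/consequence class are added
#' inside and outside genes.
#'
#' @param build A [genome_build()].
#' @param genes Candidate-gene intervals from [gen_candidate_genes()].
#' @param planted_causal A list with `chrom`, `pos` (1-based), `ref`, `alt`;
#'   must fall inside a gene interval.
#' @param panel_size Number of comparison individuals (>= 0).
#' @param seed Integer seed.
#' @param n_shared_in_gene Number of non-private in-gene hom-alt
#'   non-synonymous variants (the focal funnel sees
#'   `n_shared_in_gene + 1` in-gene hom non-syn variants in total).
#' @param n_background Number of background variants in the focal table.
#' @param leak_causal_to_panel If `TRUE`, the causal allele is also inserted
#'   (heterozygous) into the first panel individual, violating privacy by
#'   construction.
#' @return A list with elements `focal` (variant table), `panel` (list of
#'   variant tables), `causal` (the planted spec), `genes`.
#' @export
gen_candidate_variants <- function(build, genes, planted_causal,
                                   panel_size = 2, seed = 1L,
                                   n_shared_in_gene = 19,
                                   n_background = 2000,
                                   leak_causal_to_panel = FALSE) {
  stopifnot(inherits(build, "genome_build"))
  pc <- planted_causal
  in_gene <- which(genes$chrom == pc$chrom & genes$start < pc$pos &
                     pc$pos <= genes$end)
  if (length(in_gene) == 0) {
    stop("'planted_causal' must lie inside a candidate-gene interval")
  }
  oseed <- push_seed(seed)
  on.exit(restore_rng(oseed))

  causal <- variant_table(pc$chrom, pc$pos, pc$ref, pc$alt, gt = "hom_alt",
                          consequence = "non_synonymous",
                          gene = genes$gene[in_gene[1]])

  # shared in-gene hom-alt non-synonymous variants
  gi <- sample(seq_len(nrow(genes)), n_shared_in_gene, replace = TRUE)
  spos <- floor(stats::runif(n_shared_in_gene, genes$start[gi],
                             genes$end[gi])) + 1
  shared <- variant_table(genes$chrom[gi], spos,
                          sample(c("A", "C", "G", "T"), n_shared_in_gene,
                                 replace = TRUE),
                          "T", gt = "hom_alt",
                          consequence = "non_synonymous",
                          gene = genes$gene[gi])
  shared$alt <- ifelse(shared$ref == "T", "A", "T")

  # background variants, mixed classes, mostly outside genes
  ci <- sample(seq_len(nrow(build)), n_background, replace = TRUE,
               prob = build$length)
  bpos <- floor(stats::runif(n_background, 0, build$length[ci])) + 1
  bg <- variant_table(build$chrom[ci], bpos,
                      sample(c("A", "C", "G", "T"), n_background,
                             replace = TRUE), "G",
                      gt = sample(c("het", "hom_alt"), n_background,
                                  replace = TRUE),
                      consequence = sample(
                        c("synonymous", "non_synonymous", "other"),
                        n_background, replace = TRUE),
                      gene = NA_character_)
  bg$alt <- ifelse(bg$ref == "G", "C", "G")
  bg <- annotate_gene_membership(bg, genes)
  # background must not create extra private in-gene hom non-syn variants:
  # demote in-gene hom-alt background records to heterozygous
  clash <- !is.na(bg$gene) & bg$gt == "hom_alt" &
    bg$consequence == "non_synonymous"
  bg$gt[clash] <- "het"

  focal <- rbind(causal, shared, bg)
  key <- paste(focal$chrom, focal$pos)
  focal <- focal[!duplicated(key), , drop = FALSE]
  focal <- focal[order(match(focal$chrom, build$chrom), focal$pos), ,
                 drop = FALSE]
  rownames(focal) <- NULL

  panel <- list()
  if (panel_size > 0) {
    carrier <- matrix(stats::runif(n_shared_in_gene * panel_size) < 0.7,
                      nrow = n_shared_in_gene)
    none <- rowSums(carrier) == 0
    carrier[cbind(which(none),
                  sample.int(panel_size, sum(none), replace = TRUE))] <- TRUE
    for (j in seq_len(panel_size)) {
      tab <- shared[carrier[, j], , drop = FALSE]
      if (nrow(tab) > 0) {
        tab$gt <- sample(c("het", "hom_alt"), nrow(tab), replace = TRUE)
      }
      own <- bg[sample.int(nrow(bg), min(200, nrow(bg))), , drop = FALSE]
      tab <- rbind(tab, own)
      if (leak_causal_to_panel && j == 1L) {
        leaked <- causal
        leaked$gt <- "het"
        tab <- rbind(tab, leaked)
      }
      tab <- tab[order(match(tab$chrom, build$chrom), tab$pos), ,
                 drop = FALSE]
      rownames(tab) <- NULL
      panel[[j]] <- tab
    }
  }
  list(focal = focal, panel = panel, causal = pc, genes = genes)
}

#' Generate the full default synthetic study
#'
#' One call that produces every input the pipeline consumes, under the
#' package's default study conditions: a 22-autosome 2.875-Gbp genome,
#' planted autozygous tracts obtained by gene-dropping one focal individual
#' through the paternal uncle–niece pedigree (so the truth has the segment
#' number/length structure of a genuinely inbred genome, F ~ 0.125),
#' background heterozygosity 1 site/kbp vs 0.05 inside tracts, a 5%
#' duplication mask, four candidate genes with the causal-gene analogue
#' pinned inside the largest planted tract, and a two-individual comparison
#' panel.
#'
#' @param seed Integer seed; every component is reproducible from it.
#' @param build Optional [genome_build()] (default [default_build()]).
#' @param model_id Pedigree model used to plant the truth tracts.
#' @param panel_size Comparison-panel size.
#' @return A list: `build`, `truth`, `het_sites`, `dup_mask`, `genes`,
#'   `candidate` (from [gen_candidate_variants()]), `seed`.
#' @export
synthetic_study <- function(seed = 1L, build = default_build(),
                            model_id = "uncle_niece_pat", panel_size = 2) {
  seed <- as.integer(seed)
  planted <- plant_roh_from_pedigree(build, model_id = model_id,
                                     seed = seed)
  truth <- synthetic_truth(planted_roh = planted, seed = seed)
  het_sites <- gen_het_sites(build, truth)
  dup_mask <- gen_dup_mask(build, truth$dup_fraction, seed = seed + 1L)
  host <- planted[which.max(planted$end - planted$start), , drop = FALSE]
  genes <- gen_candidate_genes(build, seed = seed + 2L,
                               pin_gene = "SLC45A2", pin_interval = host)
  gi <- match("SLC45A2", genes$gene)
  causal <- list(chrom = genes$chrom[gi],
                 pos = genes$start[gi] +
                   floor((genes$end[gi] - genes$start[gi]) / 2),
                 ref = "C", alt = "G")
  candidate <- gen_candidate_variants(build, genes, causal,
                                      panel_size = panel_size,
                                      seed = seed + 3L)
  list(build = build, truth = truth, het_sites = het_sites,
       dup_mask = dup_mask, genes = genes, candidate = candidate,
       seed = seed)
}

#' Plant autozygous tracts by gene-dropping one pedigree replicate
#'
#' Simulates a single focal individual under the given pedigree model and
#' returns its post-processed autozygous segments, for use as
#' `planted_roh` in a [synthetic_truth()].
#'
#' @inheritParams run_model
#' @param model_id Identifier from [pedigree_models()].
#' @param seed Integer seed.
#' @return A data.frame `chrom`, `start`, `end`.
#' @export
plant_roh_from_pedigree <- function(build, model_id = "uncle_niece_pat",
                                    seed = 1L, rates = recombination_rates(),
                                    min_length = 2e6, max_gap = 5e5) {
  run <- run_model(pedigree_models()[[model_id]], build, rates = rates,
                   n_reps = 1, seed = as.integer(seed),
                   min_length = min_length, max_gap = max_gap)
  seg <- run$segments
  seg[, c("chrom", "start", "end")]
}
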