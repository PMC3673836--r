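#' Pipeline configuration
#'
#' One object holding every tunable parameter of the end-to-end analysis,
#' with defaults matching the package's reference settings: 1-Mbp windows,
#' windows dropped above 40% duplication overlap, ROH from >= 2 consecutive
#' low-heterozygosity windows with a 2-Mbp minimum length and 500-kbp gap
#' merge, sex-specific recombination rates 8.9e-9 (male) and 1.4e-8
#' (female) crossovers/nucleotide, 10,000 gene-dropping replicates per
#' pedigree model, and 5-Mbp likelihood bins.
#'
#' @param window_size Window size in bp.
#' @param max_dup_overlap Window drop threshold (strict) on mask overlap.
#' @param min_windows Minimum qualifying windows per ROH run.
#' @param min_length Minimum post-processed segment length in bp.
#' @param max_gap Gap-merge threshold in bp (strict).
#' @param het_threshold Absolute density cut, or `NULL` for the scale-free
#'   default (see [call_roh()]).
#' @param threshold_factor Multiplier on the median density when
#'   `het_threshold` is `NULL`.
#' @param male_rate,female_rate Crossovers per nucleotide.
#' @param n_reps Gene-dropping replicates per model.
#' @param bin_width Likelihood bin width in bp.
#' @param pseudocount Per-bin smoothing pseudocount.
#' @param panel_size Comparison-panel size for the synthetic study.
#' @param seed Integer seed for the whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_size = 1e6, max_dup_overlap = 0.40,
                            min_windows = 2L, min_length = 2e6,
                            max_gap = 5e5, het_threshold = NULL,
                            threshold_factor = 0.25,
                            male_rate = 8.9e-9, female_rate = 1.4e-8,
                            n_reps = 10000L, bin_width = 5e6,
                            pseudocount = 0.5, panel_size = 2L,
                            seed = 1L) {
  cfg <- list(window_size = window_size, max_dup_overlap = max_dup_overlap,
              min_windows = as.integer(min_windows),
              min_length = min_length, max_gap = max_gap,
              het_threshold = het_threshold,
              threshold_factor = threshold_factor,
              male_rate = male_rate, female_rate = female_rate,
              n_reps = as.integer(n_reps), bin_width = bin_width,
              pseudocount = pseudocount,
              panel_size = as.integer(panel_size), seed = as.integer(seed))
  stopifnot(cfg$window_size > 0, cfg$min_windows >= 1, cfg$min_length >= 0,
            cfg$max_gap >= 0, cfg$n_reps >= 1, cfg$bin_width > 0,
            cfg$max_dup_overlap >= 0, cfg$max_dup_overlap < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The serialized form round-trips exactly through
#' `read_pipeline_config(write_pipeline_config(cfg, path))`.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline on a synthetic study
#'
#' Executes every stage in order — synthetic-data generation (unless inputs
#' are supplied), windowed heterozygosity, ROH calling and F_ROH,
#' gene-dropping simulation of all ten pedigree models, multinomial model
#' ranking, and candidate-variant prioritization — and returns one report.
#' The run is deterministic for a fixed `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param inputs `NULL` to generate a [synthetic_study()] from the config
#'   seed, or a study-shaped list (`build`, `het_sites`, `dup_mask`,
#'   `genes`, `candidate`).
#' @param outdir Optional directory: when given, the report (JSON), window
#'   track (TSV), ROH segments (BED), model ranking (TSV) and prioritized
#'   variants (TSV) are written there, each carrying the config hash.
#' @param models Pedigree models to simulate (default: all ten).
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_report`: `config`, `config_hash`,
#'   `windows`, `callset`, `roh_summary`, `ranking`, `prioritization`,
#'   `study`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         outdir = NULL, models = pedigree_models(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "synthetic_data"
  report <- tryCatch({
    study <- if (is.null(inputs)) {
      say("[synthetic_data] generating study (seed %d)", config$seed)
      synthetic_study(seed = config$seed, panel_size = config$panel_size)
    } else inputs

    stage <- "het_windows"
    say("[het_windows] tiling and counting")
    w <- het_windows(study$build, study$het_sites, study$dup_mask,
                     window_size = config$window_size,
                     max_overlap = config$max_dup_overlap)

    stage <- "roh_caller"
    seg <- call_roh(w, het_threshold = config$het_threshold,
                    threshold_factor = config$threshold_factor,
                    min_windows = config$min_windows)
    seg <- postprocess_segments(seg, config$min_length, config$max_gap)
    eff <- sum(w$effective_bases[!w$masked_out])
    callset <- compute_f_roh(seg, eff)
    roh_summary <- summarize_callset(callset, large_threshold =
                                       config$min_length)
    say("[roh_caller] F_ROH = %.3f over %d segments", callset$f_roh,
        nrow(seg))

    stage <- "pedigree_sim"
    rates <- recombination_rates(config$male_rate, config$female_rate)
    runs <- lapply(seq_along(models), function(i) {
      say("[pedigree_sim] %s (%d reps)", models[[i]]$model_id,
          config$n_reps)
      run_model(models[[i]], study$build, rates, n_reps = config$n_reps,
                seed = config$seed + i, min_length = config$min_length,
                max_gap = config$max_gap)
    })

    stage <- "model_likelihood"
    ranking <- rank_models(callset$segments, runs,
                           pseudocount = config$pseudocount)
    say("[model_likelihood] top model: %s", ranking$model_id[1])

    stage <- "variant_prioritization"
    prio <- prioritize_variants(study$candidate$focal, study$genes,
                                study$candidate$panel, callset)
    say("[variant_prioritization] %d variant(s) prioritized",
        nrow(prio$result))

    structure(list(config = config, config_hash = config_hash(config),
                   windows = w, callset = callset,
                   roh_summary = roh_summary, ranking = ranking,
                   prioritization = prio, study = study),
              class = "pipeline_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- paste("config_hash:", report$config_hash)
  write_windows_tsv(report$windows, file.path(outdir, "windows.tsv"),
                    header_lines = hash)
  write_bed(report$callset$segments, file.path(outdir, "roh.bed"))
  write_windows_tsv(report$ranking, file.path(outdir, "ranking.tsv"),
                    header_lines = hash)
  write_windows_tsv(report$prioritization$result,
                    file.path(outdir, "prioritized.tsv"),
                    header_lines = hash)
  s <- report$roh_summary
  jsonlite::write_json(
    list(config = unclass(report$config), config_hash = report$config_hash,
         f_roh = report$callset$f_roh,
         total_roh_bp = report$callset$total_roh,
         effective_genome_bp = report$callset$effective_genome,
         n_segments = s$n_segments, n_large = s$n_large,
         largest_bp = s$largest,
         top_model = report$ranking$model_id[1],
         funnel = report$prioritization$funnel),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$roh_summary
  cat(sprintf(
    "<pipeline_report> F_ROH = %.3f (%d segments, %d large, largest %.0f Mbp)\n",
    x$callset$f_roh, s$n_segments, s$n_large, s$largest / 1e6))
  cat(sprintf("  top model: %s (rank-1 ties: %d); prioritized variants: %d\n",
              x$ranking$model_id[1], sum(x$ranking$rank == 1),
              nrow(x$prioritization$result)))
  invisible(x)
}
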