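#' Construct a genome build
#'
#' A genome build is the coordinate frame shared by every stage of the
#' pipeline: an ordered set of autosome names and lengths. All interval
#' objects in the package (windows, masks, ROH segments) are 0-based
#' half-open in this frame; VCF positions are 1-based per the VCF standard.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Integer-valued vector of chromosome lengths in bp (> 0).
#' @return A `data.frame` of class `genome_build` with columns `chrom`,
#'   `length`.
#' @examples
#' genome_build(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length) || length(chrom) < 1L) {
    stop("'chrom' and 'length' must be non-empty vectors of equal length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(length != round(length))) {
    stop("chromosome lengths must be positive integers (bp)")
  }
  out <- data.frame(chrom = chrom, length = length,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_build", "data.frame")
  out
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %d chromosomes, %.1f Mbp total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat(sprintf("... and %d more\n", nrow(x) - 8L))
  invisible(x)
}

#' Total genome length in bp
#' @param build A [genome_build()].
#' @return Total length in bp.
#' @export
total_length <- function(build) {
  stopifnot(inherits(build, "genome_build"))
  sum(build$length)
}

# GRCh37 autosome lengths (chr1..chr22), used as the shape template for
# synthetic builds so chromosome-length proportions are realistic.
grch37_autosomes <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
  59128983, 63025520, 48129895, 51304566
)

#' Generate a synthetic genome build
#'
#' Chromosome lengths are proportional to the GRCh37 autosomes (recycled if
#' `n_chrom` exceeds 22), optionally jittered, and rounded by largest
#' remainder so they sum exactly to `total_length`.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param total_length Total genome length in bp (>= `n_chrom`).
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @param jitter Relative uniform jitter applied to the length proportions
#'   (0 disables it).
#' @return A [genome_build()] whose lengths sum exactly to `total_length`.
#' @examples
#' gen_build(3, 300e6, seed = 5)
#' @export
gen_build <- function(n_chrom, total_length, seed, jitter = 0.1) {
  if (!is.numeric(n_chrom) || length(n_chrom) != 1L || n_chrom < 1 ||
      n_chrom != round(n_chrom)) {
    stop("'n_chrom' must be a positive integer")
  }
  if (!is.numeric(total_length) || length(total_length) != 1L ||
      total_length < n_chrom) {
    stop("'total_length' must be >= n_chrom")
  }
  if (jitter < 0 || jitter >= 1) stop("'jitter' must be in [0, 1)")
  oseed <- push_seed(seed)
  on.exit(restore_rng(oseed))
  props <- rep_len(grch37_autosomes, n_chrom)
  if (jitter > 0) {
    props <- props * stats::runif(n_chrom, 1 - jitter, 1 + jitter)
  }
  props <- props / sum(props)
  lens <- largest_remainder_round(props * total_length, total_length)
  lens <- pmax(lens, 1)
  # pmax can only add length for degenerate tiny genomes; rebalance on the
  # largest chromosome so the total is conserved.
  excess <- sum(lens) - total_length
  if (excess > 0) lens[which.max(lens)] <- lens[which.max(lens)] - excess
  genome_build(paste0("chr", seq_len(n_chrom)), lens)
}

# Round a positive vector to integers preserving its (integer) sum.
largest_remainder_round <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Default synthetic genome build
#'
#' 22 autosomes totalling 2.875 Gbp with lengths proportional to the GRCh37
#' autosomes — the scale of the mammalian autosomal coordinate frame the
#' pipeline is designed for.
#'
#' @return A [genome_build()].
#' @export
default_build <- function() {
  gen_build(22, 2.875e9, seed = 1L, jitter = 0)
}

#' Read / write chromosome sizes as a two-column TSV
#'
#' @param path File path. The file has no header: `chrom<TAB>length`.
#' @return `read_chrom_sizes` returns a [genome_build()];
#'   `write_chrom_sizes` returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  genome_build(df$chrom, df$length)
}

#' @rdname read_chrom_sizes
#' @param build A [genome_build()].
#' @export
write_chrom_sizes <- function(build, path) {
  stopifnot(inherits(build, "genome_build"))
  utils::write.table(as.data.frame(build)[, c("chrom", "length")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Generators seed the RNG for their own determinism but must not disturb
# the caller's stream: capture the global RNG state and restore it on exit.
push_seed <- function(seed) {
  oseed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  oseed
}

restore_rng <- function(oseed) {
  if (is.null(oseed)) {
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  } else {
    assign(".Random.seed", oseed, envir = globalenv())
  }
}

# Map chromosome names in x to build order; error on unknowns unless
# warn_skip, in which case unknown rows are dropped with a count.
match_chrom <- function(chrom, build, warn_skip = FALSE, what = "record") {
  idx <- match(chrom, build$chrom)
  if (anyNA(idx)) {
    n_bad <- sum(is.na(idx))
    if (warn_skip) {
      warning(sprintf("%d %s(s) on chromosomes absent from the build; skipped",
                      n_bad, what))
    } else {
      stop(sprintf("%d %s(s) on chromosomes absent from the build",
                   n_bad, what))
    }
  }
  idx
}
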