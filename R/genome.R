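#' Define a genome layout
#'
#' A genome layout is the coordinate system every other function works in: an
#' ordered set of chromosomes with lengths and centromere positions. The
#' centromere splits each chromosome into a p arm `[0, centromere)` and a q arm
#' `[centromere, length)`. All coordinates in the package are 0-based,
#' half-open.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of chromosome lengths in bp (> 0).
#' @param centromere Centromere positions in bp, strictly inside each
#'   chromosome.
#'
#' @return A tibble with columns `chrom`, `length`, `centromere`, of class
#'   `ai_genome`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e8, 1.5e8), c(9e7, 6e7))
#' @export
genome_layout <- function(chrom, length, centromere) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(length <= 0)) abort("chromosome lengths must be positive")
  if (any(centromere <= 0 | centromere >= length)) {
    abort("centromere must lie strictly inside the chromosome")
  }
  out <- tibble(chrom = as.character(chrom),
                length = as.numeric(length),
                centromere = as.numeric(centromere))
  class(out) <- c("ai_genome", class(out))
  out
}

#' Toy genome used by the synthetic cohort
#'
#' Five 100-Mb chromosomes with centromeres at 40 Mb: large enough to carry
#' arm-level events, focal deletions and several recurrence peaks, small
#' enough that a full cohort simulation runs on a desktop.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param centromere Centromere position in bp.
#' @return An `ai_genome` tibble.
#' @export
toy_genome <- function(n_chrom = 5, chrom_length = 100e6, centromere = 40e6) {
  genome_layout(paste0("chr", seq_len(n_chrom)),
                rep(chrom_length, n_chrom),
                rep(centromere, n_chrom))
}

#' Look up chromosome length or centromere position
#'
#' @param genome An `ai_genome`.
#' @param chrom Chromosome name(s).
#' @return Length / centromere position in bp (`NA` for unknown names).
#' @export
genome_length <- function(genome, chrom) {
  genome$length[match(chrom, genome$chrom)]
}

#' @rdname genome_length
#' @export
genome_centromere <- function(genome, chrom) {
  genome$centromere[match(chrom, genome$chrom)]
}

#' Analysis configuration
#'
#' Collects the tunable thresholds of the pipeline. Defaults are the working
#' values used throughout the package: a 10-interval max-smoothing window, a
#' reporting cutoff of 15 tumors of prominence, a +0.10 LRR gain cutoff, a
#' -1.0 LRR homozygous-deletion cutoff, a 0.07 mirrored-BAF AI call threshold,
#' and the 80% arm coverage / 0.2 LRR arm gap isochromosome rule.
#'
#' @param smooth_window Max-filter window width, in inter-breakpoint intervals.
#' @param smooth_align `"centered"` or `"trailing"` window alignment.
#' @param prominence_min Minimum topographic prominence (tumors) to report a
#'   peak.
#' @param lrr_gain Mean-LRR threshold above which an AI segment is a gain;
#'   AI at or below it is a loss (copy-neutral LOH included).
#' @param lrr_homdel Per-probe LRR threshold below which probes are candidate
#'   homozygous deletion.
#' @param mbaf_ai Mean mirrored-BAF threshold for calling a segment AI.
#' @param min_probes_segment Minimum probes for an AI segment call.
#' @param min_probes_homdel Minimum consecutive probes for a homozygous
#'   deletion call.
#' @param merge_gap_max Adjacent AI segments of equal class closer than this
#'   (bp) are merged.
#' @param iso_arm_frac Minimum fraction of an arm covered by AI for the
#'   isochromosome rule.
#' @param iso_lrr_gap Minimum between-arm mean-LRR difference for the
#'   isochromosome rule.
#' @param lrr_alpha Array attenuation factor mapping log2 copy ratio to LRR.
#' @param lrr_floor Cap for LRR at zero total copies.
#' @param alpha_pairs Significance level (Bonferroni) for peak-pair
#'   associations.
#' @param fdr_expression BH FDR level for expression-dosage calls.
#'
#' @return A list of class `ai_config`.
#' @export
ai_config <- function(smooth_window = 10L,
                      smooth_align = c("centered", "trailing"),
                      prominence_min = 15,
                      lrr_gain = 0.10,
                      lrr_homdel = -1.0,
                      mbaf_ai = 0.07,
                      min_probes_segment = 10L,
                      min_probes_homdel = 5L,
                      merge_gap_max = 1e6,
                      iso_arm_frac = 0.80,
                      iso_lrr_gap = 0.2,
                      lrr_alpha = 0.55,
                      lrr_floor = -5,
                      alpha_pairs = 0.05,
                      fdr_expression = 0.10) {
  smooth_align <- match.arg(smooth_align)
  cfg <- list(
    smooth_window = as.integer(smooth_window),
    smooth_align = smooth_align,
    prominence_min = prominence_min,
    lrr_gain = lrr_gain,
    lrr_homdel = lrr_homdel,
    mbaf_ai = mbaf_ai,
    min_probes_segment = as.integer(min_probes_segment),
    min_probes_homdel = as.integer(min_probes_homdel),
    merge_gap_max = merge_gap_max,
    iso_arm_frac = iso_arm_frac,
    iso_lrr_gap = iso_lrr_gap,
    lrr_alpha = lrr_alpha,
    lrr_floor = lrr_floor,
    alpha_pairs = alpha_pairs,
    fdr_expression = fdr_expression
  )
  stopifnot(cfg$smooth_window >= 1L,
            cfg$prominence_min > 0, cfg$lrr_gain > 0, cfg$mbaf_ai > 0,
            cfg$iso_arm_frac > 0, cfg$iso_lrr_gap > 0, cfg$lrr_alpha > 0)
  class(cfg) <- "ai_config"
  cfg
}

#' Read / write an analysis configuration as YAML
#'
#' @param path File path.
#' @param config An `ai_config` list.
#' @return `read_ai_config()` returns an `ai_config`; `write_ai_config()`
#'   returns `path` invisibly.
#' @export
read_ai_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ai_config, vals)
}

#' @rdname read_ai_config
#' @export
write_ai_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
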