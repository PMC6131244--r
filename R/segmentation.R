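#' Mirrored B-allele frequency
#'
#' Folds the two allelic directions together: `m = |baf - 0.5|`, in
#' `[0, 0.5]`. A balanced heterozygous site gives 0; complete loss of one
#' allele gives 0.5. Segmentation runs on this quantity so that which parental
#' allele was lost or gained is irrelevant.
#'
#' @param baf Numeric vector of B-allele frequencies in `[0, 1]`.
#' @return Mirrored BAF vector.
#' @examples
#' mirror_baf(c(0.5, 0.25, 0.9, 0.1))
#' @export
mirror_baf <- function(baf) {
  stopifnot(all(baf >= 0 & baf <= 1, na.rm = TRUE))
  abs(baf - 0.5)
}

# Penalized least-squares multiple-changepoint search (binary segmentation on
# segment means). Returns the start indices (> 1) of new segments. The split
# penalty is BIC-style: a split is accepted when it lowers the residual sum
# of squares by more than penalty * sigma^2, with sigma estimated robustly
# from first differences and penalty defaulting to 3 * log(n).
binseg_changepoints <- function(y, min_seg = 10L, penalty = NULL) {
  n <- length(y)
  if (n < 2L * min_seg) return(integer(0))
  sigma <- mad(diff(y)) / sqrt(2)
  if (sigma <= 0) sigma <- stats::sd(y)
  if (is.na(sigma) || sigma <= 0) return(integer(0))
  if (is.null(penalty)) penalty <- 3 * log(n)
  thresh <- penalty * sigma^2
  s1 <- cumsum(y)
  s2 <- cumsum(y^2)
  css <- function(a, b) { # RSS of y[a..b] about its mean
    sy <- s1[b] - if (a > 1L) s1[a - 1L] else 0
    syy <- s2[b] - if (a > 1L) s2[a - 1L] else 0
    syy - sy^2 / (b - a + 1L)
  }
  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue) > 0L) {
    seg <- queue[[1L]]
    queue <- queue[-1L]
    lo <- seg[1L]; hi <- seg[2L]
    if (hi - lo + 1L < 2L * min_seg) next
    ks <- (lo + min_seg - 1L):(hi - min_seg)   # last index of left part
    sy_l <- s1[ks] - if (lo > 1L) s1[lo - 1L] else 0
    syy_l <- s2[ks] - if (lo > 1L) s2[lo - 1L] else 0
    n_l <- ks - lo + 1L
    cost_l <- syy_l - sy_l^2 / n_l
    sy_r <- s1[hi] - s1[ks]
    syy_r <- s2[hi] - s2[ks]
    n_r <- hi - ks
    cost_r <- syy_r - sy_r^2 / n_r
    total <- cost_l + cost_r
    k <- ks[which.min(total)]
    gain <- css(lo, hi) - min(total)
    if (gain > thresh) {
      cps <- c(cps, k + 1L)
      queue <- c(queue, list(c(lo, k)), list(c(k + 1L, hi)))
    }
  }
  sort(cps)
}

# Segment boundaries in bp: interior cuts midway between flanking probes,
# outer bounds half a median spacing beyond the terminal probes, clipped to
# the chromosome.
segment_bounds <- function(pos, cp_starts, chrom_len = NA) {
  n <- length(pos)
  spacing <- if (n > 1L) median(diff(pos)) else 1
  starts_i <- c(1L, cp_starts)
  ends_i <- c(cp_starts - 1L, n)
  cuts <- floor((pos[cp_starts] + pos[cp_starts - 1L]) / 2)
  lo <- max(0, floor(pos[1L] - spacing / 2))
  hi <- ceiling(pos[n] + spacing / 2)
  if (!is.na(chrom_len)) hi <- min(hi, chrom_len)
  tibble(start = c(lo, cuts), end = c(cuts, hi),
         first = starts_i, last = ends_i)
}

#' Call allelic-imbalance segments for one sample
#'
#' Runs penalized least-squares changepoint detection on the mirrored BAF of
#' each chromosome, then calls a segment as allelic imbalance when its mean
#' mirrored BAF reaches `config$mbaf_ai` with at least
#' `config$min_probes_segment` probes. Called segments are classified into
#' gains and losses by mean LRR ([classify_segments()]) and adjacent segments
#' of equal class closer than `config$merge_gap_max` bp are merged.
#' Chromosomes with fewer than `min_chrom_probes` probes are skipped.
#'
#' @param probes Probe tibble for a single sample (`chrom`, `pos`, `baf`,
#'   `lrr`, optionally `sample_id`), positions sorted within chromosome.
#' @param config An [ai_config()].
#' @param genome Optional `ai_genome` supplying chromosome lengths for the
#'   outer segment bounds.
#' @param min_chrom_probes Minimum probes per chromosome to attempt
#'   segmentation.
#' @return A segment tibble (`chrom`, `start`, `end`, `sample_id`, `klass`,
#'   `mean_lrr`, `mean_mbaf`, `n_probes`).
#' @export
segment_sample <- function(probes, config = ai_config(), genome = NULL,
                           min_chrom_probes = 20L) {
  assert_columns(probes, c("chrom", "pos", "baf", "lrr"))
  sid <- if ("sample_id" %in% names(probes)) {
    u <- unique(probes$sample_id)
    if (length(u) > 1L) abort("segment_sample() expects a single sample; see call_ai_segments()")
    u
  } else NA_character_
  per_chrom <- map(split(probes, probes$chrom), function(p) {
    if (is.unsorted(p$pos)) abort(sprintf("probes not sorted on %s", p$chrom[1]))
    if (nrow(p) < min_chrom_probes) return(NULL)
    m <- mirror_baf(p$baf)
    cps <- binseg_changepoints(m, min_seg = config$min_probes_segment)
    len <- if (!is.null(genome)) genome_length(genome, p$chrom[1]) else NA
    b <- segment_bounds(p$pos, cps, len)
    seg <- tibble(
      chrom = p$chrom[1], start = b$start, end = b$end,
      mean_lrr = map_dbl(seq_len(nrow(b)), \(i) mean(p$lrr[b$first[i]:b$last[i]])),
      mean_mbaf = map_dbl(seq_len(nrow(b)), \(i) mean(m[b$first[i]:b$last[i]])),
      n_probes = as.integer(b$last - b$first + 1L))
    seg <- seg[seg$mean_mbaf >= config$mbaf_ai &
                 seg$n_probes >= config$min_probes_segment, , drop = FALSE]
    if (nrow(seg) == 0L) return(NULL)
    seg
  })
  seg <- list_rbind(per_chrom[!map_lgl(per_chrom, is.null)])
  if (is.null(seg) || nrow(seg) == 0L) {
    return(empty_segments(sid))
  }
  seg$sample_id <- sid
  seg <- classify_segments(seg, config)
  seg <- merge_adjacent_segments(seg, config$merge_gap_max)
  seg[, c("chrom", "start", "end", "sample_id", "klass",
          "mean_lrr", "mean_mbaf", "n_probes")]
}

empty_segments <- function(sid = character(0)) {
  tibble(chrom = character(), start = double(), end = double(),
         sample_id = if (length(sid)) character() else character(),
         klass = character(), mean_lrr = double(), mean_mbaf = double(),
         n_probes = integer())
}

#' Call AI segments for every sample in a probe table
#'
#' @param probes Probe tibble with a `sample_id` column.
#' @inheritParams segment_sample
#' @return Segment tibble over all samples.
#' @export
call_ai_segments <- function(probes, config = ai_config(), genome = NULL,
                             min_chrom_probes = 20L) {
  assert_columns(probes, c("sample_id", "chrom", "pos", "baf", "lrr"))
  out <- map(split(probes, probes$sample_id),
             segment_sample, config = config, genome = genome,
             min_chrom_probes = min_chrom_probes)
  res <- list_rbind(out)
  if (nrow(res) == 0L) empty_segments() else res
}

#' Classify AI segments into gains and losses by mean LRR
#'
#' A segment is a `gain` when its mean LRR exceeds `config$lrr_gain`,
#' otherwise a `loss`. The loss class deliberately includes copy-neutral LOH,
#' whose LRR sits near zero while the B-allele is imbalanced.
#'
#' @param segments Segment tibble with `mean_lrr`.
#' @param config An [ai_config()].
#' @return The tibble with a `klass` column.
#' @export
classify_segments <- function(segments, config = ai_config()) {
  assert_columns(segments, "mean_lrr")
  segments$klass <- ifelse(segments$mean_lrr > config$lrr_gain, "gain", "loss")
  segments
}

# Merge same-class neighbours separated by < gap_max bp (per sample and
# chromosome), pooling probe-weighted means.
merge_adjacent_segments <- function(segments, gap_max) {
  if (nrow(segments) < 2L) return(segments)
  parts <- split(segments,
                 interaction(segments$sample_id, segments$chrom,
                             segments$klass, drop = TRUE))
  merged <- map(parts, function(s) {
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1, (s$start[-1] - s$end[-nrow(s)]) >= gap_max))
    s |>
      mutate(.grp = grp) |>
      group_by(.data$.grp) |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), sample_id = first(.data$sample_id),
                klass = first(.data$klass),
                mean_lrr = sum(.data$mean_lrr * .data$n_probes) / sum(.data$n_probes),
                mean_mbaf = sum(.data$mean_mbaf * .data$n_probes) / sum(.data$n_probes),
                n_probes = sum(.data$n_probes), .groups = "drop") |>
      select(-".grp")
  })
  out <- list_rbind(merged)
  out[order(out$sample_id, out$chrom, out$start), ]
}

#' Call homozygous deletions from per-probe LRR
#'
#' Reports maximal runs of at least `config$min_probes_homdel` consecutive
#' probes whose LRR falls below `config$lrr_homdel`. At such depths both
#' chromosomal copies are absent in the tumor fraction, so the BAF carries no
#' signal and the call rests on LRR alone.
#'
#' @param probes Probe tibble (one or more samples).
#' @param config An [ai_config()].
#' @return Segment tibble with `klass = "homozygous_deletion"`.
#' @export
call_homozygous_deletions <- function(probes, config = ai_config()) {
  assert_columns(probes, c("chrom", "pos", "lrr"))
  if (!"sample_id" %in% names(probes)) probes$sample_id <- NA_character_
  per <- map(split(probes, list(probes$sample_id, probes$chrom), drop = TRUE),
             function(p) {
    low <- p$lrr < config$lrr_homdel
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= config$min_probes_homdel
    if (!any(keep)) return(NULL)
    b <- map(which(keep), function(i) {
      fi <- starts[i]; la <- ends[i]
      spacing <- if (nrow(p) > 1L) median(diff(p$pos)) else 1
      tibble(chrom = p$chrom[1],
             start = max(0, floor(p$pos[fi] - spacing / 2)),
             end = ceiling(p$pos[la] + spacing / 2),
             sample_id = p$sample_id[1],
             klass = "homozygous_deletion",
             mean_lrr = mean(p$lrr[fi:la]),
             mean_mbaf = mean(mirror_baf(p$baf[fi:la])),
             n_probes = la - fi + 1L)
    })
    list_rbind(b)
  })
  res <- list_rbind(per[!map_lgl(per, is.null)])
  if (is.null(res) || nrow(res) == 0L) empty_segments() else res
}

#' Estimate tumor purity from AI segments
#'
#' Heuristic inversion of the mixture model: among a sample's AI segments with
#' near-neutral LRR (`|mean_lrr| <= config$lrr_gain`, the copy-neutral LOH
#' candidates), the largest mean mirrored BAF `delta_max` is assumed to come
#' from a clonal cn-LOH event, for which `delta = purity / 2`; hence
#' `purity_hat = 2 * delta_max`. When sample metadata already carries a
#' purity it is returned unchanged.
#'
#' @param segments Segment tibble (one or more samples).
#' @param meta Optional metadata tibble with `sample_id` and `purity`; if a
#'   sample's purity is present there, it overrides the estimate.
#' @return A tibble `sample_id`, `purity_hat`, `method` (`"cnloh_delta"` or
#'   `"metadata"`); samples with no eligible segment get `NA` and method
#'   `"none"`.
#' @export
estimate_purity <- function(segments, meta = NULL) {
  assert_columns(segments, c("sample_id", "mean_lrr", "mean_mbaf", "klass"))
  cfg_gain <- ai_config()$lrr_gain
  eligible <- segments |>
    filter(.data$klass != "homozygous_deletion",
           abs(.data$mean_lrr) <= cfg_gain)
  est <- if (nrow(eligible) == 0L) {
    tibble(sample_id = character(), purity_hat = double(),
           method = character())
  } else {
    eligible |>
      group_by(.data$sample_id) |>
      summarise(purity_hat = pmin(2 * max(.data$mean_mbaf), 1),
                .groups = "drop") |>
      mutate(method = "cnloh_delta")
  }
  all_ids <- unique(segments$sample_id)
  est <- tibble(sample_id = all_ids) |>
    left_join(est, by = "sample_id") |>
    mutate(method = ifelse(is.na(.data$purity_hat), "none", .data$method))
  if (!is.null(meta) && "purity" %in% names(meta)) {
    est <- est |>
      left_join(meta[, c("sample_id", "purity")], by = "sample_id") |>
      mutate(purity_hat = ifelse(!is.na(.data$purity), .data$purity, .data$purity_hat),
             method = ifelse(!is.na(.data$purity), "metadata", .data$method)) |>
      select(-"purity")
  }
  if (any(est$method == "none")) {
    warn(sprintf("%d sample(s) without AI segments eligible for purity estimation",
                 sum(est$method == "none")))
  }
  est
}

#' Estimate event clonality from purity-corrected BAF
#'
#' For loss-class segments, inverts the mixture model to the fraction `f` of
#' tumor cells carrying the event, given purity `rho` and the segment's BAF
#' deviation `delta = mean_mbaf`:
#' * copy-neutral LOH model (`|mean_lrr| <= lrr_gain`): `f = 2 delta / rho`;
#' * one-copy deletion model (`mean_lrr < -lrr_gain`): with observed
#'   `B = 0.5 - delta`, `f = (1 - 2B) / (rho (1 - B))`.
#'
#' Estimates above `1 + tol` are flagged (`capped = TRUE`) and truncated to
#' `1 + tol`; values slightly above 1 arise from noise on clonal events.
#'
#' @param segments Loss-class segment tibble.
#' @param purity Either a single purity or a tibble (`sample_id`, `purity`).
#' @param config An [ai_config()].
#' @param tol Overshoot tolerance before flagging.
#' @return The segments with `delta`, `model`, `clonality`, `purity`,
#'   `capped` columns.
#' @export
estimate_clonality <- function(segments, purity, config = ai_config(),
                               tol = 0.1) {
  assert_columns(segments, c("mean_lrr", "mean_mbaf", "klass"))
  seg <- segments[segments$klass == "loss", , drop = FALSE]
  if (is.data.frame(purity)) {
    seg <- left_join(seg, purity[, c("sample_id", "purity")], by = "sample_id")
  } else {
    if (any(purity <= 0)) abort("purity must be positive")
    seg$purity <- purity
  }
  if (any(is.na(seg$purity) | seg$purity <= 0)) {
    abort("every segment needs a positive purity")
  }
  delta <- seg$mean_mbaf
  cnloh <- abs(seg$mean_lrr) <= config$lrr_gain
  bhat <- 0.5 - delta
  f_del <- (1 - 2 * bhat) / (seg$purity * (1 - bhat))
  f_cnloh <- 2 * delta / seg$purity
  seg$delta <- delta
  seg$model <- ifelse(cnloh, "cnloh", "deletion")
  f <- ifelse(cnloh, f_cnloh, f_del)
  seg$capped <- f > 1 + tol
  seg$clonality <- pmin(f, 1 + tol)
  seg
}

#' Per-sample allelic-imbalance burden
#'
#' Base pairs covered by the union of a sample's AI segments (double-counting
#' of overlapping segments is removed per chromosome before summing).
#'
#' @param segments Segment tibble.
#' @param exclude_chroms Chromosomes to leave out (used when a burden
#'   covariate must exclude the chromosome of a studied locus).
#' @return A tibble `sample_id`, `burden_bp`.
#' @export
ai_burden <- function(segments, exclude_chroms = character(0)) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end"))
  seg <- segments[!segments$chrom %in% exclude_chroms, , drop = FALSE]
  if (nrow(seg) == 0L) return(tibble(sample_id = character(), burden_bp = double()))
  seg |>
    group_by(.data$sample_id, .data$chrom) |>
    summarise(bp = interval_union_bp(.data$start, .data$end), .groups = "drop") |>
    group_by(.data$sample_id) |>
    summarise(burden_bp = sum(.data$bp), .groups = "drop")
}

#' Fold change between group means
#'
#' `mean(values[groups == numerator]) / mean(values[groups == denominator])` --
#' the statistic behind "MSS tumors carry x-fold more AI than MSI tumors".
#'
#' @param values Numeric vector (e.g. per-sample burdens).
#' @param groups Group labels aligned with `values`.
#' @param numerator,denominator Group labels to compare.
#' @return A single fold change.
#' @export
group_fold <- function(values, groups, numerator, denominator) {
  a <- values[groups == numerator]
  b <- values[groups == denominator]
  if (length(a) == 0L || length(b) == 0L) {
    abort("both groups must be non-empty for a fold change")
  }
  mean(a) / mean(b)
}
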