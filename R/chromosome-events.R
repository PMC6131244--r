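#' Call isochromosome-like events per sample and chromosome
#'
#' A sample is called as carrying an isochromosome on a chromosome when at
#' least `config$iso_arm_frac` (default 80%) of at least one arm is covered
#' by the union of the sample's AI segments (any class) and the mean probe
#' LRR of the two arms differs by at least `config$iso_lrr_gap` (default
#' 0.2). A p-arm deficit (`mean LRR(p) <= mean LRR(q) - gap`) yields an
#' `i(q)` call -- one q arm gained, the p arm lost in the same event; the
#' mirrored deficit yields the generalized `i(p)` call, flagged by
#' `direction`.
#'
#' @param segments AI segment tibble for the cohort (or one sample).
#' @param probes Probe tibble providing per-arm LRR for the same samples.
#' @param genome An `ai_genome` with centromeres.
#' @param config An [ai_config()].
#' @return A tibble with one row per (sample, chromosome):
#'   `sample_id`, `chrom`, `arm_frac_p`, `arm_frac_q`, `mean_lrr_p`,
#'   `mean_lrr_q`, `iso_call`, `direction` (`"i(q)"`, `"i(p)"` or `NA`).
#' @export
call_isochromosome <- function(segments, probes, genome,
                               config = ai_config()) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end"))
  assert_columns(probes, c("sample_id", "chrom", "pos", "lrr"))
  if (any(is.na(genome$centromere))) abort("genome must define centromeres")
  combos <- tidyr::expand_grid(sample_id = unique(probes$sample_id),
                               chrom = genome$chrom)
  key <- function(sid, chr) paste(sid, chr, sep = "\r")
  probes_by <- split(probes[, c("pos", "lrr")],
                     key(probes$sample_id, probes$chrom))
  seg_by <- split(segments[, c("start", "end")],
                  key(segments$sample_id, segments$chrom))
  out <- pmap(combos, function(sample_id, chrom) {
    cen <- genome_centromere(genome, chrom)
    len <- genome_length(genome, chrom)
    p <- probes_by[[key(sample_id, chrom)]] %||%
      tibble(pos = double(), lrr = double())
    s <- seg_by[[key(sample_id, chrom)]] %||%
      tibble(start = double(), end = double())
    arm_cov <- function(a_start, a_end) {
      if (nrow(s) == 0L) return(0)
      cs <- pmax(s$start, a_start)
      ce <- pmin(s$end, a_end)
      keep <- ce > cs
      if (!any(keep)) return(0)
      o <- order(cs[keep])
      cs <- cs[keep][o]; ce <- ce[keep][o]
      covered <- 0; cur_s <- cs[1]; cur_e <- ce[1]
      for (i in seq_along(cs)[-1]) {
        if (cs[i] > cur_e) { covered <- covered + cur_e - cur_s
                             cur_s <- cs[i]; cur_e <- ce[i] }
        else cur_e <- max(cur_e, ce[i])
      }
      (covered + cur_e - cur_s) / (a_end - a_start)
    }
    frac_p <- arm_cov(0, cen)
    frac_q <- arm_cov(cen, len)
    on_p <- p$pos < cen
    lrr_p <- if (any(on_p)) mean(p$lrr[on_p]) else NA_real_
    lrr_q <- if (any(!on_p)) mean(p$lrr[!on_p]) else NA_real_
    covered <- max(frac_p, frac_q) >= config$iso_arm_frac
    dir <- NA_character_
    if (covered && !is.na(lrr_p) && !is.na(lrr_q)) {
      if (lrr_p <= lrr_q - config$iso_lrr_gap) dir <- "i(q)"
      else if (lrr_q <= lrr_p - config$iso_lrr_gap) dir <- "i(p)"
    }
    tibble(sample_id = sample_id, chrom = chrom,
           arm_frac_p = frac_p, arm_frac_q = frac_q,
           mean_lrr_p = lrr_p, mean_lrr_q = lrr_q,
           iso_call = !is.na(dir), direction = dir)
  })
  list_rbind(out)
}

#' Within-chromosome gain/loss co-occurrence odds-ratio scan
#'
#' Lays a grid of loci along one chromosome and, for every ordered pair
#' (gain locus x, loss locus y), tabulates samples by (has a gain segment
#' covering x) x (has a loss segment covering y) and reports the log2 odds
#' ratio. Zero cells get the Haldane-Anscombe 0.5 correction for the OR
#' display; the two-sided Fisher exact p-value reported for the maximal pair
#' uses the uncorrected table.
#'
#' @param segments Classified cohort segment tibble.
#' @param chrom Chromosome to scan.
#' @param genome An `ai_genome`.
#' @param grid_step Grid spacing in bp (default 1 Mb).
#' @return A list: `grid` (long tibble `x`, `y`, `log2_or`, `n11`, `n10`,
#'   `n01`, `n00`), `best` (one-row tibble for the maximal |log2 OR| pair
#'   with uncorrected OR and Fisher p), `n_samples`.
#' @export
cooccurrence_or_scan <- function(segments, chrom, genome, grid_step = 1e6) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "klass"))
  stopifnot(grid_step > 0)
  samples <- unique(segments$sample_id)
  n <- length(samples)
  if (n < 2L) abort("co-occurrence scan needs at least 2 samples")
  len <- genome_length(genome, chrom)
  grid <- seq(grid_step / 2, len, by = grid_step)
  covers <- function(kl) {
    s <- segments[segments$chrom == chrom & segments$klass == kl, ]
    m <- matrix(FALSE, n, length(grid))
    if (nrow(s) > 0L) {
      si <- match(s$sample_id, samples)
      for (k in seq_len(nrow(s))) {
        hit <- grid >= s$start[k] & grid < s$end[k]
        m[si[k], hit] <- TRUE
      }
    }
    m
  }
  g <- covers("gain")
  l <- covers("loss")
  n11 <- crossprod(g, l)                 # gain at x AND loss at y
  gx <- colSums(g)
  ly <- colSums(l)
  n10 <- matrix(gx, length(grid), length(grid)) - n11
  n01 <- matrix(ly, length(grid), length(grid), byrow = TRUE) - n11
  n00 <- n - n11 - n10 - n01
  zero <- n11 == 0 | n10 == 0 | n01 == 0 | n00 == 0
  hc <- ifelse(zero, 0.5, 0)
  log2_or <- log2(((n11 + hc) * (n00 + hc)) / ((n10 + hc) * (n01 + hc)))
  degenerate <- (gx == 0 | gx == n)
  degenerate_y <- (ly == 0 | ly == n)
  log2_or[degenerate, ] <- NA_real_
  log2_or[, degenerate_y] <- NA_real_
  if (all(is.na(log2_or))) {
    warn("degenerate cohort: all odds ratios undefined")
  }
  long <- tibble(
    x = rep(grid, times = length(grid)),
    y = rep(grid, each = length(grid)),
    log2_or = as.vector(log2_or),
    n11 = as.vector(n11), n10 = as.vector(n10),
    n01 = as.vector(n01), n00 = as.vector(n00))
  best <- NULL
  if (!all(is.na(long$log2_or))) {
    i <- which.max(long$log2_or)
    tab <- matrix(c(long$n11[i], long$n10[i], long$n01[i], long$n00[i]), 2)
    ft <- fisher.test(tab)
    best <- long[i, ] |>
      mutate(or = (long$n11[i] * long$n00[i]) / (long$n10[i] * long$n01[i]),
             p_value = ft$p.value)
  }
  list(grid = long, best = best, n_samples = n)
}
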