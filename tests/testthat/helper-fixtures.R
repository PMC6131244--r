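# Shared fixture builders. Everything is generated in code; no data files.

library(dplyr)
library(tibble)

# A single-chromosome genome for hand-built cases.
tiny_genome <- function(len = 1000, cen = 500) {
  genome_layout("c1", len, cen)
}

# Build a count-track tibble from a plain value vector (unit-width intervals).
values_track <- function(values, chrom = "c1") {
  n <- length(values)
  tibble(chrom = chrom, start = seq_len(n) - 1, end = seq_len(n),
         value = as.numeric(values))
}

# One sample's probes on one chromosome with piecewise-constant true BAF/LRR.
# events: tibble(start, end, c_t, b_t, f) in bp on [0, len).
synth_probes <- function(len = 30e6, spacing = 1e4, purity = 0.7,
                         events = NULL, sigma_baf = 0.03, sigma_lrr = 0.15,
                         alpha = 0.55, sample_id = "S1", chrom = "chr1") {
  pos <- seq(spacing / 2, len - spacing / 2, by = spacing)
  c_t <- rep(2, length(pos)); b_t <- rep(1, length(pos)); f <- rep(1, length(pos))
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      sel <- pos >= events$start[i] & pos < events$end[i]
      c_t[sel] <- events$c_t[i]; b_t[sel] <- events$b_t[i]; f[sel] <- events$f[i]
    }
  }
  mu_baf <- expected_baf(purity, f, c_t, b_t)
  mu_baf[is.nan(mu_baf)] <- 0.5
  mu_lrr <- expected_lrr(purity, f, c_t, alpha = alpha)
  flip <- runif(length(pos)) < 0.5
  baf <- ifelse(flip, mu_baf, 1 - mu_baf) + rnorm(length(pos), 0, sigma_baf)
  tibble(sample_id = sample_id, chrom = chrom, pos = pos,
         baf = pmin(pmax(baf, 0), 1),
         lrr = mu_lrr + rnorm(length(pos), 0, sigma_lrr))
}

# Minimal segment row constructor.
seg_row <- function(chrom, start, end, sample_id, klass,
                    mean_lrr = 0, mean_mbaf = 0.2, n_probes = 50L) {
  tibble(chrom = chrom, start = start, end = end, sample_id = sample_id,
         klass = klass, mean_lrr = mean_lrr, mean_mbaf = mean_mbaf,
         n_probes = as.integer(n_probes))
}

# A fast, small simulation config for tests that only need structure.
quick_sim_config <- function(...) {
  sim_config(n_samples = 6, snp_per_mb = 10, ...)
}
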