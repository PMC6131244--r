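test_that("mirrored BAF folds the allelic directions", {
  expect_equal(mirror_baf(0.5), 0)
  expect_equal(mirror_baf(0.25), 0.25)
  expect_equal(mirror_baf(c(0.9, 0.1)), c(0.4, 0.4))
  expect_error(mirror_baf(1.2))
})

test_that("a flat null genome yields no AI segments", {
  set.seed(10)
  probes <- synth_probes(len = 20e6, events = NULL)
  seg <- segment_sample(probes, ai_config())
  expect_equal(nrow(seg), 0)
})

test_that("a planted cn-LOH region is recovered with tight boundaries", {
  set.seed(11)
  spacing <- 1e4
  ev <- tibble(start = 10e6, end = 20e6, c_t = 2, b_t = 0, f = 1)
  probes <- synth_probes(len = 30e6, spacing = spacing, purity = 0.7,
                         events = ev)
  seg <- segment_sample(probes, ai_config())
  expect_equal(nrow(seg), 1)
  expect_equal(seg$klass, "loss")
  # purity 0.7 clonal cn-LOH: delta = 0.35
  expect_equal(seg$mean_mbaf, 0.35, tolerance = 0.02)
  expect_lte(abs(seg$start - 10e6), 5 * spacing)
  expect_lte(abs(seg$end - 20e6), 5 * spacing)
})

test_that("sub-threshold imbalance is not called", {
  set.seed(12)
  cfg <- ai_config()
  base <- synth_probes(len = 10e6, events = NULL, sigma_baf = 0)
  # constant mirrored BAF just under / just over the call threshold
  below <- mutate(base, baf = 0.5 + (cfg$mbaf_ai - 0.005))
  above <- mutate(base, baf = 0.5 + (cfg$mbaf_ai + 0.02))
  expect_equal(nrow(segment_sample(below, cfg)), 0)
  seg <- segment_sample(above, cfg)
  expect_equal(nrow(seg), 1)
})

test_that("unsorted probes are rejected", {
  probes <- synth_probes(len = 2e6)[c(2, 1, 3:10), ]
  expect_error(segment_sample(probes, ai_config()), "sorted")
})

test_that("segments classify into gain and loss by mean LRR", {
  seg <- bind_rows(
    seg_row("chr1", 0, 1e6, "S1", "loss", mean_lrr = 0.3),
    seg_row("chr1", 2e6, 3e6, "S1", "loss", mean_lrr = 0.0),
    seg_row("chr1", 4e6, 5e6, "S1", "loss", mean_lrr = -0.4))
  got <- classify_segments(seg, ai_config())
  expect_equal(got$klass, c("gain", "loss", "loss"))
})

test_that("homozygous deletions are called from LRR runs", {
  set.seed(13)
  cfg <- ai_config()
  probes <- synth_probes(len = 5e6, spacing = 1e4, sigma_lrr = 0.05)
  # 10 consecutive probes at LRR -2
  deep <- probes
  deep$lrr[100:109] <- -2
  hd <- call_homozygous_deletions(deep, cfg)
  expect_equal(nrow(hd), 1)
  expect_equal(hd$klass, "homozygous_deletion")
  expect_equal(hd$n_probes, 10L)
  # an isolated probe at -2 is below the minimum run length
  lone <- probes
  lone$lrr[200] <- -2
  expect_equal(nrow(call_homozygous_deletions(lone, cfg)), 0)
  # nothing below threshold, nothing called
  shallow <- mutate(probes, lrr = pmax(lrr, -0.5))
  expect_equal(nrow(call_homozygous_deletions(shallow, cfg)), 0)
})

test_that("purity is estimated from the largest near-neutral imbalance", {
  seg <- bind_rows(
    seg_row("chr1", 0, 10e6, "S1", "loss", mean_lrr = 0.01, mean_mbaf = 0.4),
    seg_row("chr2", 0, 10e6, "S1", "loss", mean_lrr = -0.35, mean_mbaf = 0.2))
  est <- estimate_purity(seg)
  expect_equal(est$purity_hat, 0.8)
  expect_equal(est$method, "cnloh_delta")
  # metadata overrides
  meta <- tibble(sample_id = "S1", purity = 0.66)
  est2 <- estimate_purity(seg, meta)
  expect_equal(est2$purity_hat, 0.66)
  expect_equal(est2$method, "metadata")
  # only far-from-neutral segments: no eligible cn-LOH candidate
  gains <- seg_row("chr1", 0, 1e6, "S2", "gain", mean_lrr = 0.4, mean_mbaf = 0.1)
  expect_warning(est3 <- estimate_purity(gains), "without AI segments")
  expect_true(is.na(est3$purity_hat))
})

test_that("AI burden sums the union of segment basepairs", {
  seg <- bind_rows(
    seg_row("chr1", 0, 1e6, "S1", "loss"),
    seg_row("chr2", 0, 2e6, "S1", "gain"))
  expect_equal(ai_burden(seg)$burden_bp, 3e6)
  # overlapping segments are not double-counted: brute-force bp oracle
  ov <- bind_rows(
    seg_row("c1", 100, 300, "S1", "loss"),
    seg_row("c1", 200, 400, "S1", "gain"),
    seg_row("c1", 600, 700, "S1", "loss"))
  bp_oracle <- sum(vapply(0:999, function(b) {
    any(ov$start <= b & ov$end > b)
  }, logical(1)))
  expect_equal(ai_burden(ov)$burden_bp, bp_oracle)
  # chromosome exclusion for burden covariates
  expect_equal(ai_burden(seg, exclude_chroms = "chr2")$burden_bp, 1e6)
})

test_that("group fold reproduces the burden-ratio statistic", {
  vals <- c(39, 39, 10, 10)
  grp <- c("MSS", "MSS", "MSI", "MSI")
  expect_equal(group_fold(vals, grp, "MSS", "MSI"), 3.9)
  expect_error(group_fold(vals, grp, "MSS", "absent"), "non-empty")
})

test_that("adjacent same-class segments merge across small gaps", {
  set.seed(14)
  # one event interrupted by a short noisy stretch still yields one segment
  ev <- tibble(start = c(5e6, 10.4e6), end = c(10e6, 16e6),
               c_t = c(1, 1), b_t = c(0, 0), f = c(1, 1))
  probes <- synth_probes(len = 25e6, purity = 0.7, events = ev)
  seg <- segment_sample(probes, ai_config())
  expect_equal(nrow(seg), 1)
  expect_lte(seg$start, 5.2e6)
  expect_gte(seg$end, 15.8e6)
})
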