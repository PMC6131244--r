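test_that("identical seeds give identical cohorts", {
  cfg <- quick_sim_config()
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_equal(a$probes, b$probes)
  expect_equal(a$snvs, b$snvs)
  expect_equal(a$truth$events, b$truth$events)
  c <- simulate_cohort(cfg, seed = 43)
  expect_false(isTRUE(all.equal(a$probes$baf, c$probes$baf)))
})

test_that("an event-free genome emits balanced, neutral signals", {
  cfg <- sim_config(n_samples = 3, snp_per_mb = 10,
                    drivers = NULL, iso_chrom = NA, iso_prob = 0,
                    fragile_sites = NULL, homdel_sites = NULL,
                    lambda_mss = 1e-9, lambda_msi = 1e-9)
  cohort <- simulate_cohort(cfg, seed = 7)
  m <- mirror_baf(cohort$probes$baf)
  # mirrored noise-only deviations: mean of |N(0, 0.03)| ~ 0.024
  expect_lt(mean(m), 0.04)
  expect_lt(abs(mean(cohort$probes$lrr)), 0.01)
  expect_equal(nrow(cohort$truth$events), 0)
})

test_that("driver recurrence in the truth is binomial at catalog probability", {
  drivers <- tibble(name = "D", chrom = "chr1", pos = 50e6,
                    klass = "loss_del", prob = 0.5, clonal_fraction = 1)
  cfg <- sim_config(n_samples = 300, snp_per_mb = 2, drivers = drivers,
                    driver_msi_mult = 1, iso_chrom = NA,
                    fragile_sites = NULL, homdel_sites = NULL)
  cohort <- simulate_cohort(cfg, seed = 5)
  carriers <- cohort$truth$events |>
    filter(.data$kind == "driver", .data$name == "D") |>
    distinct(.data$sample_id) |>
    nrow()
  ci <- qbinom(c(0.005, 0.995), 300, 0.5)
  expect_gte(carriers, ci[1])
  expect_lte(carriers, ci[2])
  # every carrier's event interval contains the locus
  ev <- filter(cohort$truth$events, .data$kind == "driver")
  expect_true(all(ev$start <= 50e6 & ev$end > 50e6))
})

test_that("emitted probes and SNVs respect genome and mask bounds", {
  cfg <- quick_sim_config()
  cohort <- simulate_cohort(cfg, seed = 2)
  lens <- cfg$genome$length[match(cohort$probes$chrom, cfg$genome$chrom)]
  expect_true(all(cohort$probes$pos >= 0 & cohort$probes$pos < lens))
  expect_true(all(cohort$probes$baf >= 0 & cohort$probes$baf <= 1))
  in_mask <- vapply(seq_len(nrow(cohort$snvs)), function(i) {
    m <- cohort$callable[cohort$callable$chrom == cohort$snvs$chrom[i], ]
    any(cohort$snvs$pos[i] >= m$start & cohort$snvs$pos[i] < m$end)
  }, logical(1))
  expect_true(all(in_mask))
})

test_that("probe signals inside truth events match the emission model", {
  set.seed(1)
  cfg <- sim_config(n_samples = 8, snp_per_mb = 20)
  cohort <- simulate_cohort(cfg, seed = 9)
  ev <- cohort$truth$events |>
    filter(.data$kind %in% c("driver", "background"), .data$f == 1) |>
    head(12)
  geno <- list(loss_del = c(c_t = 1, b_t = 0), cnloh = c(c_t = 2, b_t = 0),
               gain = c(c_t = 3, b_t = 2))
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    g <- geno[[e$klass]]
    rho <- cohort$meta$purity[cohort$meta$sample_id == e$sample_id]
    mu <- abs(expected_baf(rho, 1, g[["c_t"]], g[["b_t"]]) - 0.5)
    p <- cohort$probes |>
      filter(.data$sample_id == e$sample_id, .data$chrom == e$chrom,
             .data$pos >= e$start, .data$pos < e$end)
    # 3 sigma / sqrt(n) band around the expected mirrored deviation, plus the
    # small positive bias folding |0.5 + noise - 0.5| introduces near mu = 0
    tol <- 3 * 0.05 / sqrt(nrow(p)) + 0.03
    expect_lt(abs(mean(mirror_baf(p$baf)) - mu), tol)
  }
})

test_that("SNV placement follows the per-copy Poisson model", {
  gt1 <- list(chr1 = tibble(start = 0, end = 50e6, c_t = 2, b_t = 1, f = 1))
  gt2 <- list(chr1 = tibble(start = 0, end = 50e6, c_t = 4, b_t = 2, f = 1))
  mask <- tibble(chrom = "chr1", start = 0, end = 50e6)
  expect_equal(nrow(place_snvs(gt1, 0.8, mask, mu = 0)), 0)
  set.seed(3)
  n1 <- replicate(40, nrow(place_snvs(gt1, 1, mask, mu = 0.05)))
  n2 <- replicate(40, nrow(place_snvs(gt2, 1, mask, mu = 0.05)))
  # Poisson means 5 and 10 per replicate
  expect_equal(mean(n2) / mean(n1), 2, tolerance = 0.25)
  # pure diploid tumor: expected VAF 0.5
  set.seed(4)
  sv <- place_snvs(gt1, 1, mask, mu = 2)
  expect_equal(mean(sv$alt_reads / (sv$alt_reads + sv$ref_reads)), 0.5,
               tolerance = 0.03)
})

test_that("MSS samples carry more AI basepairs than MSI samples", {
  cfg <- sim_config(n_samples = 80, snp_per_mb = 2)
  cohort <- simulate_cohort(cfg, seed = 13)
  truth_bp <- cohort$truth$events |>
    filter(.data$klass != "homdel") |>
    group_by(.data$sample_id) |>
    summarise(bp = sum(.data$end - .data$start), .groups = "drop") |>
    right_join(cohort$meta, by = "sample_id") |>
    mutate(bp = ifelse(is.na(.data$bp), 0, .data$bp))
  fold <- group_fold(truth_bp$bp, truth_bp$msi_status, "MSS", "MSI")
  expect_gt(fold, 1.5)
})

test_that("driver loci outside the genome are rejected", {
  bad <- tibble(name = "X", chrom = "chr1", pos = 2e9, klass = "gain",
                prob = 0.5, clonal_fraction = 1)
  expect_error(sim_config(drivers = bad), "outside genome")
  bad2 <- tibble(name = "X", chrom = "chr99", pos = 1e6, klass = "gain",
                 prob = 0.5, clonal_fraction = 1)
  expect_error(sim_config(drivers = bad2), "outside genome")
})

test_that("cohort artifacts write to disk and read back", {
  cohort <- simulate_cohort(quick_sim_config(), seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_equal(read_probe_signals(file.path(dir, "probes.tsv")), cohort$probes)
  expect_equal(read_snvs(file.path(dir, "snvs.tsv"))$pos,
               sort_snv_pos <- arrange(cohort$snvs, .data$chrom, .data$pos,
                                       .data$sample_id)$pos)
  expect_equal(read_bed(file.path(dir, "genes.bed")), cohort$genes)
})
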