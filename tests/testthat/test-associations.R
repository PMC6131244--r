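test_that("2x2 contingency reproduces stratified percentages and OR", {
  # mutation by AI-at-locus strata: 129/178 gained vs 279/893 without AI
  got <- contingency_2x2(129, 49, 279, 614)
  expect_equal(got$pct_row1, 72)
  expect_equal(got$pct_row2, 31)
  expect_equal(got$odds_ratio, (129 * 614) / (49 * 279))
  expect_lt(got$p_value, 1e-20)
  flat <- contingency_2x2(1, 1, 1, 1)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  expect_error(contingency_2x2(0, 0, 0, 0), "all-zero")
})

test_that("Fisher p agrees with full enumeration at fixed margins", {
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(50)
  for (i in 1:20) {
    cells <- as.vector(stats::rmultinom(1, sample(10:40, 1), rep(0.25, 4)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    got <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p_value,
                 enum_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
  }
})

test_that("hypergeometric tail is exact and log-stable", {
  expect_equal(hypergeometric_tail(10, 10, 3, 3), 1)
  expect_equal(hypergeometric_tail(5, 1, 1, 1), 0.2)
  # all twelve of twelve drawn genes marked among 61 of 795:
  # P = C(61,12)/C(795,12), far below double-precision linear scale
  lp <- log_hypergeometric_tail(795, 61, 12, 12)
  expect_equal(lp, lchoose(61, 12) - lchoose(795, 12), tolerance = 1e-10)
  expect_error(hypergeometric_tail(5, 6, 3, 3), "inconsistent")
  # agreement with the distribution function on random cases
  set.seed(51)
  for (i in 1:25) {
    N <- sample(10:60, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    x <- sample(0:n, 1)
    expect_equal(hypergeometric_tail(N, K, n, x),
                 phyper(x - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # tail probabilities over all x sum to the full mean count identity:
  # P(X >= 0) = 1 always
  expect_equal(hypergeometric_tail(30, 12, 7, 0), 1)
})

test_that("multiple-testing adjustments match their definitions", {
  expect_equal(multiple_testing(0.01, "bonferroni", m = 1), 0.01)
  expect_equal(multiple_testing(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_error(multiple_testing(c(0.5, 1.2)), "\\[0, 1\\]")
  # BH equals the brute-force step-up construction
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(52)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(multiple_testing(p, "BH"), bh_oracle(p))
  }
})

# build a cohort segment table with AI at two peak loci plus background burden
coupled_segments <- function(n, p_i, p_j, coupling_or = 1) {
  ids <- sprintf("S%03d", seq_len(n))
  # sample presence with the requested odds ratio via conditional probabilities
  xi <- runif(n) < p_i
  p_j_given <- function(x) {
    if (coupling_or == 1) return(p_j)
    if (x) plogis(qlogis(p_j) + log(coupling_or) / 2)
    else plogis(qlogis(p_j) - log(coupling_or) / 2)
  }
  yj <- runif(n) < vapply(xi, p_j_given, numeric(1))
  rows <- list()
  for (s in seq_len(n)) {
    if (xi[s]) rows <- c(rows, list(seg_row("chr1", 10e6, 30e6, ids[s], "loss")))
    if (yj[s]) rows <- c(rows, list(seg_row("chr2", 40e6, 60e6, ids[s], "loss")))
    if (runif(1) < 0.5) rows <- c(rows, list(
      seg_row("chr3", 0, runif(1, 1e6, 90e6), ids[s], "gain")))
  }
  list(segments = purrr::list_rbind(rows), samples = ids)
}

peak_at <- function(chrom, start, end, klass = "loss") {
  tibble(chrom = chrom, klass = klass, apex_start = start, apex_end = end)
}

test_that("peak-pair logistic detects planted coupling and respects nulls", {
  set.seed(53)
  cp <- coupled_segments(400, 0.35, 0.35, coupling_or = 6)
  res <- peak_pair_logistic(cp$segments, peak_at("chr1", 15e6, 20e6),
                            peak_at("chr2", 45e6, 50e6), cp$samples)
  expect_gt(res$estimate, 0)
  expect_lt(res$p.value, 0.001)

  nul <- coupled_segments(400, 0.35, 0.35, coupling_or = 1)
  res0 <- peak_pair_logistic(nul$segments, peak_at("chr1", 15e6, 20e6),
                             peak_at("chr2", 45e6, 50e6), nul$samples)
  expect_gt(res0$p.value, 0.001)
  expect_error(
    peak_pair_logistic(cp$segments, peak_at("chr1", 1e6, 2e6),
                       peak_at("chr1", 5e6, 6e6), cp$samples),
    "different chromosomes")
})

test_that("complete separation falls back to a penalized fit", {
  ids <- sprintf("S%02d", 1:40)
  seg <- purrr::list_rbind(purrr::map(ids, \(s)
    seg_row("chr2", 40e6, 60e6, s, "loss")))  # outcome constant
  res <- peak_pair_logistic(seg, peak_at("chr1", 1e6, 2e6),
                            peak_at("chr2", 45e6, 50e6), ids)
  expect_true(res$separated)
  # half the samples get the predictor, outcome perfectly follows it
  seg2 <- bind_rows(
    purrr::list_rbind(purrr::map(ids[1:20], \(s)
      seg_row("chr1", 10e6, 30e6, s, "loss"))),
    purrr::list_rbind(purrr::map(ids[1:20], \(s)
      seg_row("chr2", 40e6, 60e6, s, "loss"))))
  res2 <- peak_pair_logistic(seg2, peak_at("chr1", 15e6, 20e6),
                             peak_at("chr2", 45e6, 50e6), ids)
  expect_equal(res2$method, "firth")
  expect_gt(res2$estimate, 0)
  expect_true(is.finite(res2$p.value))
})

test_that("phenotype association recovers a planted MSI fragile-site effect", {
  set.seed(54)
  n <- 300
  ids <- sprintf("S%03d", seq_len(n))
  msi <- runif(n) < 0.3
  hit <- runif(n) < ifelse(msi, 0.5, 0.06)
  rows <- list()
  for (s in seq_len(n)) {
    if (hit[s]) rows <- c(rows, list(
      seg_row("chr4", 15e6, 15.5e6, ids[s], "loss")))
    if (runif(1) < ifelse(msi[s], 0.1, 0.6)) rows <- c(rows, list(
      seg_row("chr5", 0, 100e6, ids[s], "loss")))
  }
  seg <- purrr::list_rbind(rows)
  res <- phenotype_logistic(seg, peak_at("chr4", 15e6, 15.4e6),
                            setNames(msi, ids))
  expect_gt(res$estimate, 0)
  expect_lt(res$p.value, 0.001)
  expect_error(
    phenotype_logistic(seg, peak_at("chr4", 15e6, 15.4e6),
                       setNames(rep(TRUE, n), ids)),
    "single class")
})

test_that("expression-dosage test flags planted slopes and skips degenerate genes", {
  set.seed(55)
  n <- 200
  ids <- sprintf("S%03d", seq_len(n))
  meta <- tibble(sample_id = ids, purity = runif(n, 0.3, 0.9))
  lrr <- rnorm(n, 0, 0.25)
  expr <- bind_rows(
    tibble(sample_id = ids, gene = "DOSED", lrr = lrr,
           expression = 1 * lrr + 0.5 * meta$purity + rnorm(n, 0, 0.5)),
    tibble(sample_id = ids, gene = "NULL1", lrr = rnorm(n, 0, 0.25),
           expression = 0.5 * meta$purity + rnorm(n, 0, 0.5)),
    tibble(sample_id = ids, gene = "FLAT", lrr = 0,
           expression = rnorm(n)))
  res <- expression_dosage_test(expr, meta)
  expect_lt(res$q.value[res$gene == "DOSED"], 0.1)
  expect_equal(res$slope[res$gene == "DOSED"], 1, tolerance = 0.2)
  expect_true(res$skipped[res$gene == "FLAT"])
  expect_gt(res$p.value[res$gene == "NULL1"], 0.001)
})

test_that("events per tumor count class-matched peaks only", {
  peaks <- bind_rows(
    peak_at("chr1", 10e6, 11e6, "gain"),
    peak_at("chr2", 10e6, 11e6, "gain"),
    peak_at("chr3", 10e6, 11e6, "gain"),
    peak_at("chr4", 10e6, 11e6, "loss"))
  seg <- bind_rows(
    seg_row("chr1", 9e6, 12e6, "S1", "gain"),
    seg_row("chr2", 5e6, 20e6, "S1", "gain"),
    seg_row("chr4", 0, 50e6, "S1", "loss"),
    seg_row("chr3", 9e6, 12e6, "S2", "loss"))  # loss at a gain peak: no count
  got <- events_per_tumor(seg, peaks, samples = c("S1", "S2"))
  expect_equal(got$n_events[got$sample_id == "S1"], 3L)
  expect_equal(got$n_events[got$sample_id == "S2"], 0L)
  # empty peak list: all zeros
  none <- events_per_tumor(seg, peaks[0, ], samples = c("S1", "S2"))
  expect_equal(none$n_events, c(0L, 0L))
  # monotone: adding a segment never lowers a count
  more <- bind_rows(seg, seg_row("chr3", 10e6, 10.5e6, "S2", "gain"))
  got2 <- events_per_tumor(more, peaks, samples = c("S1", "S2"))
  expect_true(all(got2$n_events >= got$n_events))
})

test_that("stratified event counts compare by rank test", {
  set.seed(56)
  counts <- tibble(sample_id = sprintf("S%02d", 1:60),
                   n_events = c(rpois(30, 12.5), rpois(30, 6.5)))
  strata <- setNames(rep(c("mutated", "WT"), each = 30), counts$sample_id)
  got <- stratify_event_counts(counts, strata)
  expect_equal(got$n1, 30)
  mean_mut <- if (got$group1 == "mutated") got$mean1 else got$mean2
  mean_wt <- if (got$group1 == "WT") got$mean1 else got$mean2
  expect_gt(mean_mut, mean_wt)
  expect_lt(got$p_value, 0.001)
  expect_error(stratify_event_counts(counts, setNames(rep("A", 60),
                                                      counts$sample_id)),
               "two strata")
})
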