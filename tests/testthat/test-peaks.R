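test_that("count track counts distinct samples per breakpoint interval", {
  g <- tiny_genome(len = 1000)
  seg <- bind_rows(
    seg_row("c1", 100, 200, "A", "loss"),
    seg_row("c1", 150, 250, "B", "loss"))
  tr <- build_count_track(seg, "loss", g)
  expect_equal(tr$start, c(0, 100, 150, 200, 250))
  expect_equal(tr$value, c(0, 1, 2, 1, 0))
})

test_that("a segment-free chromosome is one zero interval", {
  g <- tiny_genome(len = 1000)
  tr <- build_count_track(empty_seg <- seg_row("c1", 1, 2, "A", "gain")[0, ],
                          "loss", g)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$value, 0L)
  expect_equal(tr$end, 1000)
})

test_that("overlapping segments of one sample count once (per-bp oracle)", {
  g <- tiny_genome(len = 1000)
  set.seed(20)
  seg <- purrr::list_rbind(purrr::map(1:6, function(s) {
    k <- sample(1:3, 1)
    starts <- sort(sample(0:900, k))
    purrr::list_rbind(purrr::map(starts, function(st) {
      seg_row("c1", st, min(1000, st + sample(50:300, 1)),
              paste0("S", s), "loss")
    }))
  }))
  tr <- build_count_track(seg, "loss", g)
  # brute force: distinct samples covering each bp
  per_bp <- vapply(0:999, function(b) {
    length(unique(seg$sample_id[seg$start <= b & seg$end > b]))
  }, integer(1))
  idx <- findInterval(0:999, tr$start)
  expect_equal(per_bp, as.integer(tr$value[idx]))
})

test_that("segments past the chromosome end are an error", {
  g <- tiny_genome(len = 1000)
  expect_error(build_count_track(seg_row("c1", 900, 1100, "A", "loss"),
                                 "loss", g), "beyond chromosome end")
})

test_that("max smoothing follows the window rule", {
  expect_equal(max_smooth(c(1, 5, 2, 4), 1), c(1, 5, 2, 4))
  expect_equal(max_smooth(c(1, 3, 2), 3), c(3, 3, 3))
  # centered window for w = 4 spans i-1 .. i+2 (clipped at the ends)
  expect_equal(max_smooth(c(0, 0, 9, 0, 0, 0), 4), c(9, 9, 9, 9, 0, 0))
  # trailing window looks backwards only
  expect_equal(max_smooth(c(0, 9, 0, 0, 0), 3, align = "trailing"),
               c(0, 9, 9, 9, 0))
  # a max filter never lowers a value
  set.seed(21)
  v <- rpois(50, 3)
  for (w in c(2, 5, 10)) expect_true(all(max_smooth(v, w) >= v))
})

test_that("local maxima are strict plateau runs", {
  m <- find_local_maxima(c(0, 2, 1, 3, 0))
  expect_equal(m$value, c(2, 3))
  expect_equal(m$first, c(2, 4))
  expect_equal(nrow(find_local_maxima(c(0, 0, 0))), 0)
  all_const <- find_local_maxima(c(1, 1, 1))
  expect_equal(nrow(all_const), 1)
  expect_equal(all_const$first, 1)
  expect_equal(all_const$last, 3)
  # runs at chromosome ends qualify against their single inner neighbour
  edge <- find_local_maxima(c(5, 5, 1, 2))
  expect_equal(edge$value, c(5, 2))
})

test_that("prominence walk matches the stated examples", {
  expect_equal(track_prominence(c(0, 2, 1, 3, 0), 2, 2), 1)
  expect_equal(track_prominence(c(0, 2, 1, 3, 0), 4, 4), 3)
  expect_equal(track_prominence(c(5), 1, 1), 5)
  # the chromosome's highest peak keeps its full height
  expect_equal(track_prominence(c(1, 37, 2, 20, 1), 2, 2), 37)
  expect_equal(track_prominence(c(1, 37, 2, 20, 1), 4, 4), 20 - 2)
  expect_error(track_prominence(c(1, 2), 3, 3), "apex not on track")
})

test_that("prominence walk agrees with the flood-fill oracle on random tracks", {
  set.seed(22)
  for (rep in 1:200) {
    v <- sample(0:20, sample(3:50, 1), replace = TRUE)
    apexes <- find_local_maxima(max_smooth(v, sample(1:10, 1)))
    for (i in seq_len(nrow(apexes))) {
      expect_equal(track_prominence(v, apexes$first[i], apexes$last[i]),
                   prominence_oracle(v, apexes$first[i], apexes$last[i]))
    }
  }
})

test_that("peak calling ranks planted recurrences correctly", {
  g <- tiny_genome(len = 1000)
  cfg <- ai_config(prominence_min = 5, smooth_window = 3)
  # locus A at ~300 hit in 20 samples, locus B at ~700 in 10
  seg <- purrr::list_rbind(c(
    purrr::map(1:20, \(s) seg_row("c1", 300 - 10 * (s %% 5) - 20, 300 + 10 * (s %% 4) + 20,
                                  paste0("A", s), "loss")),
    purrr::map(1:10, \(s) seg_row("c1", 700 - 8 * (s %% 3) - 15, 700 + 9 * (s %% 4) + 15,
                                  paste0("B", s), "loss"))))
  peaks <- call_peaks(seg, "loss", g, cfg)
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$rank, 1:2)
  expect_gt(peaks$height[1], peaks$height[2])
  expect_true(peaks$apex_start[1] <= 300 & peaks$apex_end[1] >= 300)
  expect_true(peaks$apex_start[2] <= 700 & peaks$apex_end[2] >= 700)
  # prominence never exceeds height; highest chromosome peak keeps height
  expect_true(all(peaks$prominence <= peaks$height))
  expect_equal(peaks$prominence[1], peaks$height[1])
  # threshold above everything: silence
  expect_equal(nrow(call_peaks(seg, "loss", g, ai_config(prominence_min = 99))), 0)
})

test_that("adding a covering sample cannot lower an apex", {
  g <- tiny_genome(len = 1000)
  cfg <- ai_config(prominence_min = 2, smooth_window = 3)
  seg <- purrr::list_rbind(purrr::map(1:8, \(s)
    seg_row("c1", 400 - 5 * (s %% 3), 600 + 7 * (s %% 4), paste0("S", s), "loss")))
  before <- call_peaks(seg, "loss", g, cfg)
  more <- bind_rows(seg, seg_row("c1", 350, 650, "NEW", "loss"))
  after <- call_peaks(more, "loss", g, cfg)
  expect_gte(max(after$height), max(before$height))
})

test_that("gene assignment uses apex overlap, then flanking genes", {
  genes <- tibble(chrom = "c1",
                  start = c(100, 450, 800), end = c(150, 470, 850),
                  name = c("LEFT", "MID", "RIGHT"))
  pk <- tibble(chrom = "c1", apex_start = 440, apex_end = 480)
  got <- assign_genes(pk, genes)
  expect_equal(got$genes[[1]], "MID")
  expect_equal(got$n_genes_in_apex, 1L)
  # empty apex: both flanking genes
  pk2 <- tibble(chrom = "c1", apex_start = 500, apex_end = 600)
  got2 <- assign_genes(pk2, genes)
  expect_setequal(got2$genes[[1]], c("MID", "RIGHT"))
  expect_equal(got2$n_genes_in_apex, 0L)
  # at the chromosome start there is no left flank
  pk3 <- tibble(chrom = "c1", apex_start = 0, apex_end = 50)
  expect_equal(assign_genes(pk3, genes)$genes[[1]], "LEFT")
})
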