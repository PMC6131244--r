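#' Default planted driver catalog for the toy genome
#'
#' Six recurrent driver loci spread over the toy genome, with per-sample event
#' probabilities spanning 10-60% recurrence. Carrier samples receive an event
#' whose interval always contains the driver position but whose extent varies
#' from carrier to carrier, so cohort-level AI counts form a unimodal bump
#' apexed at the locus.
#'
#' @return A tibble with columns `name`, `chrom`, `pos`, `klass`
#'   (`loss_del`, `cnloh` or `gain`), `prob`, `clonal_fraction`.
#' @export
default_driver_catalog <- function() {
  tribble(
    ~name,   ~chrom,  ~pos,  ~klass,     ~prob, ~clonal_fraction,
    "DRV1",  "chr1",  20e6,  "loss_del", 0.60,  1,
    "DRV2",  "chr1",  75e6,  "gain",     0.40,  1,
    "DRV3",  "chr2",  30e6,  "cnloh",    0.50,  1,
    "DRV4",  "chr2",  80e6,  "gain",     0.25,  1,
    "DRV5",  "chr4",  55e6,  "loss_del", 0.35,  1,
    "DRV6",  "chr5",  60e6,  "gain",     0.10,  1
  )
}

#' Default fragile-site and homozygous-deletion catalogs
#'
#' Fragile sites receive short focal deletions whose probability is multiplied
#' in microsatellite-unstable (MSI) samples, mirroring the enrichment of
#' fragile-site breakage in MSI tumors. Homozygous-deletion loci receive rare
#' focal two-copy losses.
#'
#' @return Tibbles describing the loci.
#' @export
default_fragile_sites <- function() {
  tribble(
    ~name,    ~chrom,  ~pos,  ~prob, ~msi_mult,
    "FRAG1",  "chr4",  15e6,  0.05,  6,
    "FRAG2",  "chr2",  60e6,  0.04,  6
  )
}

#' @rdname default_fragile_sites
#' @export
default_homdel_sites <- function() {
  tribble(
    ~name,  ~chrom,  ~pos,  ~prob,
    "HD1",  "chr5",  20e6,  0.04
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic tumor cohort. The defaults describe the study
#' conditions every downstream module is validated against: a 5 x 100 Mb toy
#' genome at 100 heterozygous SNPs per Mb, purity drawn from Beta(5, 3), 15%
#' MSI samples, Poisson background aneuploidy counts of 6 (MSS) versus 1.5
#' (MSI) events per sample, a 6-driver catalog, an isochromosome arm on a
#' designated chromosome in 20% of samples, MSI-enriched fragile-site focal
#' deletions, somatic SNVs accruing at 0.05 per callable Mb per chromosomal
#' copy, and array-like noise (LRR attenuation 0.55, sigma_LRR 0.15,
#' sigma_BAF 0.03).
#'
#' @param genome An `ai_genome`; defaults to [toy_genome()].
#' @param n_samples Cohort size.
#' @param snp_per_mb Heterozygous-SNP density per Mb.
#' @param purity_shape Beta shape parameters for purity.
#' @param msi_fraction Fraction of MSI samples.
#' @param lambda_mss,lambda_msi Mean background chromosomal-instability events
#'   per MSS / MSI sample (whole-chromosome aneuploidies; see vignette).
#' @param background_class_probs Probabilities of `loss_del`, `cnloh`, `gain`
#'   for a background event.
#' @param background_subclonal_prob Probability that a background event is
#'   subclonal.
#' @param subclonal_range Range of the clonal fraction for subclonal events.
#' @param drivers Driver catalog tibble (see [default_driver_catalog()]).
#' @param driver_msi_mult Multiplier on driver probabilities for MSI samples
#'   (MSI tumors are largely chromosomally stable away from fragile sites).
#' @param driver_halfwidth_mb Range (Mb) of the random half-width of driver
#'   event intervals.
#' @param iso_chrom Chromosome carrying isochromosome events (`NA` disables).
#' @param iso_prob Per-sample isochromosome probability.
#' @param fragile_sites,homdel_sites Focal-event catalogs.
#' @param fragile_len_mb,homdel_len_mb Focal event length ranges (Mb).
#' @param lrr_alpha LRR attenuation factor.
#' @param lrr_floor LRR floor at zero copies.
#' @param sigma_lrr,sigma_baf Per-probe Gaussian noise sd (BAF truncated to
#'   `[0, 1]`).
#' @param mu_snv Somatic SNV rate per callable Mb per chromosomal copy.
#' @param depth_mean,depth_size Negative-binomial sequencing depth parameters.
#' @param expr_slope,expr_purity_coef,expr_sigma Expression model for planted
#'   genes: `expr = slope * LRR + purity_coef * purity + noise`.
#' @param expr_n_null Number of additional dosage-independent (null) genes in
#'   the expression table.
#'
#' @return A list of class `ai_sim_config`.
#' @export
sim_config <- function(genome = toy_genome(),
                       n_samples = 100L,
                       snp_per_mb = 100,
                       purity_shape = c(5, 3),
                       msi_fraction = 0.15,
                       lambda_mss = 6,
                       lambda_msi = 1.5,
                       background_class_probs = c(loss_del = 0.35, cnloh = 0.30, gain = 0.35),
                       background_subclonal_prob = 0.3,
                       subclonal_range = c(0.3, 0.9),
                       drivers = default_driver_catalog(),
                       driver_msi_mult = 0.25,
                       driver_halfwidth_mb = c(5, 30),
                       iso_chrom = "chr3",
                       iso_prob = 0.2,
                       fragile_sites = default_fragile_sites(),
                       homdel_sites = default_homdel_sites(),
                       fragile_len_mb = c(0.1, 1),
                       homdel_len_mb = c(0.05, 0.5),
                       lrr_alpha = 0.55,
                       lrr_floor = -5,
                       sigma_lrr = 0.15,
                       sigma_baf = 0.03,
                       mu_snv = 0.05,
                       depth_mean = 40,
                       depth_size = 10,
                       expr_slope = 1,
                       expr_purity_coef = 0.5,
                       expr_sigma = 0.5,
                       expr_n_null = 20L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples >= 1, cfg$snp_per_mb > 0,
            cfg$msi_fraction >= 0, cfg$msi_fraction <= 1,
            cfg$lambda_mss > 0, cfg$lambda_msi > 0, cfg$mu_snv >= 0,
            cfg$iso_prob >= 0, cfg$iso_prob <= 1,
            all(cfg$background_class_probs >= 0))
  if (!is.null(cfg$drivers) && nrow(cfg$drivers) > 0) {
    bad <- cfg$drivers$pos >= genome_length(genome, cfg$drivers$chrom) |
      is.na(genome_length(genome, cfg$drivers$chrom))
    if (any(bad)) {
      abort(sprintf("driver locus outside genome: %s",
                    paste(cfg$drivers$name[bad], collapse = ", ")))
    }
  }
  class(cfg) <- "ai_sim_config"
  cfg
}

# Paint one event (c_t, b_t, f) over a disjoint genotype map of a chromosome.
# Rows already present are clipped around [s, e); later events override
# earlier ones on the overlap.
paint_interval <- function(rows, s, e, c_t, b_t, f, kind) {
  keep <- rows[rows$end <= s | rows$start >= e, , drop = FALSE]
  left <- rows[rows$start < s & rows$end > s, , drop = FALSE]
  if (nrow(left) > 0) left$end <- s
  right <- rows[rows$start < e & rows$end > e, , drop = FALSE]
  if (nrow(right) > 0) right$start <- e
  new <- tibble(start = s, end = e, c_t = c_t, b_t = b_t, f = f, kind = kind)
  out <- bind_rows(keep, left, right, new)
  out[order(out$start), , drop = FALSE]
}

neutral_map <- function(genome) {
  map(setNames(seq_len(nrow(genome)), genome$chrom), function(i) {
    tibble(start = 0, end = genome$length[i],
           c_t = 2, b_t = 1, f = 1, kind = "neutral")
  })
}

event_genotype <- function(klass) {
  switch(klass,
         loss_del = c(c_t = 1, b_t = 0),
         cnloh    = c(c_t = 2, b_t = 0),
         gain     = c(c_t = 3, b_t = 2),
         homdel   = c(c_t = 0, b_t = 0),
         abort(sprintf("unknown event class '%s'", klass)))
}

# Segmentation-level class expected for a simulated event genotype.
expected_segment_class <- function(klass) {
  c(loss_del = "loss", cnloh = "loss", gain = "gain",
    homdel = "homozygous_deletion")[klass]
}

# Events within a sample are mutually exclusive in genomic space: a
# chromosome region carries one clonal aberration. Focal and recurrent
# events (drivers, isochromosome arms, fragile-site and homozygous
# deletions) are drawn first at their catalog probabilities; background
# aneuploidies are then rejected when they would overlap an accepted event.
# This keeps planted recurrences exactly binomial and makes cohort count
# tracks flat away from planted loci.
simulate_sample_events <- function(cfg, msi) {
  genome <- cfg$genome
  events <- list()
  overlaps_accepted <- function(chrom, s, e) {
    any(map_lgl(events, function(ev) {
      ev$chrom == chrom && ev$start < e && ev$end > s
    }))
  }
  add <- function(chrom, s, e, klass, f, kind, name) {
    events[[length(events) + 1L]] <<- tibble(
      chrom = chrom, start = s, end = e, klass = klass, f = f,
      kind = kind, name = name)
  }
  if (!is.null(cfg$drivers) && nrow(cfg$drivers) > 0) {
    p <- cfg$drivers$prob * if (msi) cfg$driver_msi_mult else 1
    hit <- runif(nrow(cfg$drivers)) < p
    for (i in which(hit)) {
      d <- cfg$drivers[i, ]
      hw <- runif(2, cfg$driver_halfwidth_mb[1], cfg$driver_halfwidth_mb[2]) * 1e6
      len <- genome_length(genome, d$chrom)
      s <- max(0, d$pos - hw[1]); e <- min(len, d$pos + hw[2])
      if (!overlaps_accepted(d$chrom, s, e)) {
        add(d$chrom, s, e, d$klass, d$clonal_fraction, "driver", d$name)
      }
    }
  }
  if (!is.na(cfg$iso_chrom) && runif(1) < cfg$iso_prob) {
    cen <- genome_centromere(genome, cfg$iso_chrom)
    len <- genome_length(genome, cfg$iso_chrom)
    stub <- runif(1, 1e6, 5e6)
    if (!overlaps_accepted(cfg$iso_chrom, stub, len)) {
      add(cfg$iso_chrom, stub, cen, "loss_del", 1, "isochromosome", "ISO_p")
      add(cfg$iso_chrom, cen, len, "gain", 1, "isochromosome", "ISO_q")
    }
  }
  if (!is.null(cfg$fragile_sites) && nrow(cfg$fragile_sites) > 0) {
    p <- cfg$fragile_sites$prob * ifelse(msi, cfg$fragile_sites$msi_mult, 1)
    hit <- runif(nrow(cfg$fragile_sites)) < pmin(p, 1)
    for (i in which(hit)) {
      fs <- cfg$fragile_sites[i, ]
      half <- runif(1, cfg$fragile_len_mb[1], cfg$fragile_len_mb[2]) * 1e6 / 2
      s <- max(0, fs$pos - half)
      e <- min(genome_length(genome, fs$chrom), fs$pos + half)
      if (!overlaps_accepted(fs$chrom, s, e)) {
        add(fs$chrom, s, e, "loss_del", 1, "fragile", fs$name)
      }
    }
  }
  if (!is.null(cfg$homdel_sites) && nrow(cfg$homdel_sites) > 0) {
    hit <- runif(nrow(cfg$homdel_sites)) < cfg$homdel_sites$prob
    for (i in which(hit)) {
      hs <- cfg$homdel_sites[i, ]
      half <- runif(1, cfg$homdel_len_mb[1], cfg$homdel_len_mb[2]) * 1e6 / 2
      s <- max(0, hs$pos - half)
      e <- min(genome_length(genome, hs$chrom), hs$pos + half)
      if (!overlaps_accepted(hs$chrom, s, e)) {
        add(hs$chrom, s, e, "homdel", 1, "homdel", hs$name)
      }
    }
  }
  lambda <- if (msi) cfg$lambda_msi else cfg$lambda_mss
  n_bg <- rpois(1, lambda)
  if (n_bg > 0) {
    for (i in seq_len(n_bg)) {
      chrom <- sample(genome$chrom, 1)
      if (overlaps_accepted(chrom, 0, genome_length(genome, chrom))) next
      klass <- sample(names(cfg$background_class_probs), 1,
                      prob = cfg$background_class_probs)
      f <- if (runif(1) < cfg$background_subclonal_prob) {
        runif(1, cfg$subclonal_range[1], cfg$subclonal_range[2])
      } else 1
      add(chrom, 0, genome_length(genome, chrom), klass, f,
          "background", NA_character_)
    }
  }
  if (length(events) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  klass = character(), f = double(), kind = character(),
                  name = character()))
  }
  list_rbind(events)
}

# Apply an event list to the neutral genome, later events painting over
# earlier ones. Background events are painted first so that focal/driver
# events dominate locally.
build_genotype <- function(events, genome) {
  gt <- neutral_map(genome)
  prio <- match(events$kind,
                c("background", "driver", "isochromosome", "fragile", "homdel"))
  events <- events[order(prio), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    g <- event_genotype(ev$klass)
    gt[[ev$chrom]] <- paint_interval(gt[[ev$chrom]], ev$start, ev$end,
                                     g["c_t"], g["b_t"], ev$f, ev$klass)
  }
  gt
}

probe_grid <- function(genome, snp_per_mb) {
  spacing <- 1e6 / snp_per_mb
  list_rbind(map(seq_len(nrow(genome)), function(i) {
    pos <- seq(spacing / 2, genome$length[i] - spacing / 2, by = spacing)
    tibble(chrom = genome$chrom[i], pos = floor(pos))
  }))
}

emit_probes <- function(grid, genotype, purity, cfg) {
  n <- nrow(grid)
  f <- c_t <- b_t <- numeric(n)
  for (chrom in names(genotype)) {
    sel <- which(grid$chrom == chrom)
    rows <- genotype[[chrom]]
    idx <- findInterval(grid$pos[sel], rows$start)
    f[sel] <- rows$f[idx]
    c_t[sel] <- rows$c_t[idx]
    b_t[sel] <- rows$b_t[idx]
  }
  mu_baf <- expected_baf(purity, f, c_t, b_t)
  mu_baf[is.nan(mu_baf)] <- 0.5
  mu_lrr <- expected_lrr(purity, f, c_t,
                         alpha = cfg$lrr_alpha, floor = cfg$lrr_floor)
  flip <- runif(n) < 0.5   # which parental allele is "B" per SNP
  baf <- ifelse(flip, mu_baf, 1 - mu_baf) + rnorm(n, 0, cfg$sigma_baf)
  new_tibble(list(chrom = grid$chrom, pos = grid$pos,
                  baf = pmin(pmax(baf, 0), 1),
                  lrr = mu_lrr + rnorm(n, 0, cfg$sigma_lrr)), nrow = n)
}

simulate_callable_mask <- function(genome, n_gaps = 4, gap_len_mb = c(0.5, 2)) {
  masks <- map(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    cen <- genome$centromere[i]
    gaps_s <- c(cen - 1.5e6, runif(n_gaps, 0, len - gap_len_mb[2] * 1e6))
    gaps_e <- c(cen + 1.5e6,
                gaps_s[-1] + runif(n_gaps, gap_len_mb[1], gap_len_mb[2]) * 1e6)
    gap_ir <- IRanges::reduce(to_iranges(pmax(gaps_s, 0), pmin(gaps_e, len)))
    call_ir <- IRanges::setdiff(to_iranges(0, len), gap_ir)
    bind_cols(tibble(chrom = genome$chrom[i]), from_iranges(call_ir))
  })
  list_rbind(masks)
}

#' Place somatic SNVs on a sample's genotype
#'
#' Implements the neutral accrual model: within each genotype interval the SNV
#' count is Poisson with mean `mu * c_t * callable Mb`, where `c_t` is the
#' interval's tumor copy number and callable Mb the intersection with the
#' callable mask. Each SNV sits on one chromosomal copy (multiplicity 1); alt
#' reads are Binomial(depth, `purity * f * 1 / total`) with
#' `total = 2(1 - purity) + purity * (2(1 - f) + f * c_t)` the mixture copies
#' at the locus. Depth is negative binomial with mean proportional to the
#' local DNA content (`depth_mean * total / 2`): extra chromosomal copies
#' yield proportionally more reads, so the expected mutated-read count per
#' SNV, `depth_mean * purity * f / 2`, is independent of copy number even as
#' SNV density rises with it. SNVs with zero alt reads are not emitted (they
#' would not be called).
#'
#' @param genotype A per-chromosome list of disjoint genotype tibbles
#'   (`start`, `end`, `c_t`, `b_t`, `f`).
#' @param purity Sample purity.
#' @param callable Callable mask tibble (`chrom`, `start`, `end`).
#' @param mu SNV rate per callable Mb per copy.
#' @param depth_mean,depth_size Negative binomial depth parameters.
#' @return An SNV tibble (`chrom`, `pos`, `ref_reads`, `alt_reads`, plus the
#'   truth columns `c_t` and `f`).
#' @export
place_snvs <- function(genotype, purity, callable, mu,
                       depth_mean = 40, depth_size = 10) {
  stopifnot(mu >= 0, purity > 0, purity <= 1)
  if (mu == 0) {
    return(tibble(chrom = character(), pos = double(),
                  ref_reads = integer(), alt_reads = integer(),
                  c_t = double(), f = double()))
  }
  out <- imap(genotype, function(rows, chrom) {
    mask <- callable[callable$chrom == chrom, , drop = FALSE]
    if (nrow(mask) == 0L) return(NULL)
    per_row <- map(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$c_t == 0) return(NULL)
      # clip callable mask to the genotype interval, plain vector arithmetic
      s <- pmax(mask$start, r$start)
      e <- pmin(mask$end, r$end)
      keep <- e > s
      if (!any(keep)) return(NULL)
      s <- s[keep]; e <- e[keep]
      w <- e - s
      mb <- sum(w) / 1e6
      n <- rpois(1, mu * r$c_t * mb)
      if (n == 0) return(NULL)
      pick <- sample.int(length(s), n, replace = TRUE, prob = w)
      pos <- floor(s[pick] + runif(n) * w[pick])
      cbar <- 2 * (1 - r$f) + r$f * r$c_t
      total <- 2 * (1 - purity) + purity * cbar   # mixture copies at locus
      p_alt <- purity * r$f * 1 / total
      # read depth tracks local DNA content: extra copies yield extra reads,
      # which is what keeps mutated-read counts flat across copy states
      depth <- pmax(1L, rnbinom(n, mu = depth_mean * total / 2,
                                size = depth_size))
      alt <- rbinom(n, depth, p_alt)
      new_tibble(list(chrom = rep(chrom, n), pos = pos,
                      ref_reads = as.integer(depth - alt),
                      alt_reads = as.integer(alt),
                      c_t = rep(r$c_t, n), f = rep(r$f, n)), nrow = n)
    })
    list_rbind(per_row[!map_lgl(per_row, is.null)])
  })
  res <- list_rbind(out[!map_lgl(out, is.null)])
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(chrom = character(), pos = double(),
                  ref_reads = integer(), alt_reads = integer(),
                  c_t = double(), f = double()))
  }
  res <- res[res$alt_reads > 0, ]
  res[order(res$chrom, res$pos), ]
}

simulate_gene_bed <- function(cfg) {
  genome <- cfg$genome
  bg <- list_rbind(map(seq_len(nrow(genome)), function(i) {
    starts <- seq(0.5e6, genome$length[i] - 1e6, by = 1e6)
    tibble(chrom = genome$chrom[i], start = starts, end = starts + 1e5,
           name = sprintf("%s_g%03d", genome$chrom[i], seq_along(starts)))
  }))
  planted <- bind_rows(
    if (!is.null(cfg$drivers) && nrow(cfg$drivers) > 0)
      tibble(chrom = cfg$drivers$chrom, start = cfg$drivers$pos - 5e4,
             end = cfg$drivers$pos + 5e4, name = cfg$drivers$name),
    if (!is.null(cfg$fragile_sites) && nrow(cfg$fragile_sites) > 0)
      tibble(chrom = cfg$fragile_sites$chrom, start = cfg$fragile_sites$pos - 5e4,
             end = cfg$fragile_sites$pos + 5e4, name = cfg$fragile_sites$name),
    if (!is.null(cfg$homdel_sites) && nrow(cfg$homdel_sites) > 0)
      tibble(chrom = cfg$homdel_sites$chrom, start = cfg$homdel_sites$pos - 5e4,
             end = cfg$homdel_sites$pos + 5e4, name = cfg$homdel_sites$name))
  # planted genes replace any background gene they overlap
  if (nrow(planted) > 0) {
    ov <- IRanges::findOverlaps(
      to_iranges(bg$start, bg$end), to_iranges(planted$start, planted$end))
    same_chrom <- bg$chrom[S4Vectors::queryHits(ov)] ==
      planted$chrom[S4Vectors::subjectHits(ov)]
    drop <- unique(S4Vectors::queryHits(ov)[same_chrom])
    if (length(drop) > 0) bg <- bg[-drop, ]
  }
  out <- bind_rows(bg, planted)
  out[order(out$chrom, out$start), ]
}

#' Simulate a tumor cohort with known ground truth
#'
#' Draws per-sample purity, MSI status and somatic events (background
#' aneuploidies, planted driver events, isochromosome arms, fragile-site and
#' homozygous deletions), then emits per-SNP BAF/LRR probe signals under the
#' two-population mixture model ([expected_baf()], [expected_lrr()]), somatic
#' SNVs under the per-copy accrual model ([place_snvs()]), a gene annotation
#' BED, a callable-region mask, and a dosage-responsive expression table.
#' Identical seeds give identical cohorts.
#'
#' @param config An `ai_sim_config` from [sim_config()].
#' @param seed Integer seed for all randomness.
#' @return A list of class `ai_cohort` with elements `probes`, `snvs`, `meta`,
#'   `genes`, `callable`, `expression`, `truth` (list: `events`, `genotype`,
#'   `drivers`) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 4, snp_per_mb = 5), seed = 1)
#' dplyr::count(cohort$probes, sample_id)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "ai_sim_config"))
  set.seed(seed)
  genome <- config$genome
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  purity <- rbeta(n, config$purity_shape[1], config$purity_shape[2])
  purity <- pmin(pmax(purity, 0.05), 1)
  msi <- runif(n) < config$msi_fraction

  callable <- simulate_callable_mask(genome)
  genes <- simulate_gene_bed(config)
  grid <- probe_grid(genome, config$snp_per_mb)

  probes <- vector("list", n)
  snvs <- vector("list", n)
  truth_events <- vector("list", n)
  truth_genotype <- vector("list", n)
  tp53_status <- character(n)

  for (s in seq_len(n)) {
    events <- simulate_sample_events(config, msi[s])
    genotype <- build_genotype(events, genome)
    p <- emit_probes(grid, genotype, purity[s], config)
    p$sample_id <- sample_ids[s]
    probes[[s]] <- p[, c("sample_id", "chrom", "pos", "baf", "lrr")]
    sv <- place_snvs(genotype, purity[s], callable, config$mu_snv,
                     config$depth_mean, config$depth_size)
    if (nrow(sv) > 0) sv$sample_id <- sample_ids[s]
    snvs[[s]] <- sv
    if (nrow(events) > 0) events$sample_id <- sample_ids[s]
    truth_events[[s]] <- events
    truth_genotype[[s]] <- genotype
    # the first driver in the catalog doubles as the cohort's TP53 analog:
    # its carriers are "mutated" for stratified event-count analyses
    tp53_status[s] <- if (nrow(events) > 0 &&
                          any(events$kind == "driver" &
                              events$name == config$drivers$name[1],
                              na.rm = TRUE)) "mutated" else "WT"
  }

  meta <- tibble(sample_id = sample_ids,
                 msi_status = ifelse(msi, "MSI", "MSS"),
                 purity = purity,
                 tp53_status = tp53_status)

  expression <- simulate_expression(config, meta, truth_genotype, genes)

  names(truth_genotype) <- sample_ids
  structure(list(
    probes = list_rbind(probes),
    snvs = list_rbind(snvs[!map_lgl(snvs, \(x) nrow(x) == 0L)]),
    meta = meta,
    genes = genes,
    callable = callable,
    expression = expression,
    truth = list(events = list_rbind(truth_events),
                 genotype = truth_genotype,
                 drivers = config$drivers),
    config = config,
    seed = seed
  ), class = "ai_cohort")
}

# Expression for planted driver genes (dosage slope expr_slope) plus
# expr_n_null dosage-independent genes at random background gene loci.
simulate_expression <- function(cfg, meta, truth_genotype, genes) {
  drv <- cfg$drivers
  if (is.null(drv) || nrow(drv) == 0) drv <- tibble(name = character())
  null_pool <- genes[!genes$name %in% drv$name, ]
  n_null <- min(cfg$expr_n_null, nrow(null_pool))
  null_genes <- null_pool[sample.int(nrow(null_pool), n_null), ]
  panel <- bind_rows(
    if (nrow(drv) > 0) tibble(gene = drv$name, chrom = drv$chrom,
                              pos = drv$pos, beta = cfg$expr_slope),
    if (n_null > 0) tibble(gene = null_genes$name, chrom = null_genes$chrom,
                           pos = (null_genes$start + null_genes$end) / 2,
                           beta = 0))
  if (nrow(panel) == 0) {
    return(tibble(sample_id = character(), gene = character(),
                  lrr = double(), expression = double()))
  }
  rows <- map(seq_len(nrow(meta)), function(s) {
    gt <- truth_genotype[[s]]
    lrr <- map_dbl(seq_len(nrow(panel)), function(g) {
      rows_g <- gt[[panel$chrom[g]]]
      idx <- findInterval(panel$pos[g], rows_g$start)
      expected_lrr(meta$purity[s], rows_g$f[idx], rows_g$c_t[idx],
                   alpha = cfg$lrr_alpha, floor = cfg$lrr_floor)
    })
    # segment-mean LRR noise: per-probe sigma shrunk by an effective 25 probes
    lrr <- lrr + rnorm(nrow(panel), 0, cfg$sigma_lrr / 5)
    tibble(sample_id = meta$sample_id[s], gene = panel$gene,
           lrr = lrr,
           expression = panel$beta * lrr +
             cfg$expr_purity_coef * meta$purity[s] +
             rnorm(nrow(panel), 0, cfg$expr_sigma))
  })
  list_rbind(rows)
}

#' Write every cohort artifact to a directory
#'
#' Emits the pipeline interchange files: `probes.tsv`, `snvs.tsv`,
#' `segments_truth.tsv` (planted events), `meta.tsv`, `genes.bed`,
#' `callable.bed`, `expression.tsv` and `truth.yaml` (per-sample planted
#' events in plain text).
#'
#' @param cohort An `ai_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_probe_signals(cohort$probes, file.path(dir, "probes.tsv"))
  write_snvs_tsv(cohort$snvs, file.path(dir, "snvs.tsv"))
  readr::write_tsv(cohort$meta, file.path(dir, "meta.tsv"))
  write_bed(cohort$genes, file.path(dir, "genes.bed"))
  write_bed(cohort$callable, file.path(dir, "callable.bed"))
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$truth$events, file.path(dir, "events_truth.tsv"))
  invisible(dir)
}
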