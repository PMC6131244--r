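#' SNV density per AI segment
#'
#' Counts, for every segment, the somatic SNVs falling inside the segment's
#' intersection with the callable mask, and reports the density per callable
#' Mb. SNVs are matched within sample. Segments whose callable overlap falls
#' below `min_callable_mb` are excluded (their densities would be dominated
#' by shot noise).
#'
#' @param segments Classified segment tibble.
#' @param snvs SNV tibble.
#' @param callable Callable mask tibble (`chrom`, `start`, `end`).
#' @param min_callable_mb Minimum callable overlap (Mb) to keep a segment.
#' @return The segment tibble with `callable_mb`, `n_snv`, `density`
#'   (SNVs per callable Mb); excluded segments are dropped with a warning
#'   count.
#' @export
snv_density_per_segment <- function(segments, snvs, callable,
                                    min_callable_mb = 0.5) {
  if (is.null(callable) || nrow(callable) == 0L) abort("callable mask is required")
  assert_columns(segments, c("sample_id", "chrom", "start", "end"))
  assert_columns(snvs, c("sample_id", "chrom", "pos"))
  mask_by_chrom <- split(callable, callable$chrom)
  seg <- segments
  seg$callable_mb <- map_dbl(seq_len(nrow(seg)), function(i) {
    m <- mask_by_chrom[[seg$chrom[i]]]
    if (is.null(m)) return(0)
    ir <- IRanges::intersect(to_iranges(seg$start[i], seg$end[i]),
                             to_iranges(m$start, m$end))
    sum(BiocGenerics::width(ir)) / 1e6
  })
  snv_callable <- snvs |>
    group_by(.data$chrom) |>
    filter({
      m <- mask_by_chrom[[.data$chrom[1]]]
      if (is.null(m)) rep(FALSE, dplyr::n())
      else IRanges::overlapsAny(to_iranges(.data$pos, .data$pos + 1),
                                to_iranges(m$start, m$end))
    }) |>
    ungroup()
  seg$n_snv <- map_int(seq_len(nrow(seg)), function(i) {
    sum(snv_callable$sample_id == seg$sample_id[i] &
          snv_callable$chrom == seg$chrom[i] &
          snv_callable$pos >= seg$start[i] &
          snv_callable$pos < seg$end[i])
  })
  drop <- seg$callable_mb < min_callable_mb
  if (any(drop)) {
    warn(sprintf("excluding %d segment(s) with callable overlap < %.2f Mb",
                 sum(drop), min_callable_mb))
  }
  seg <- seg[!drop, , drop = FALSE]
  seg$density <- seg$n_snv / seg$callable_mb
  seg
}

#' Per-SNV VAF statistics against segment LRR
#'
#' Assigns each SNV to the containing AI segment of its sample, carries the
#' segment's mean LRR onto the SNV, and summarises VAF and mutated-read
#' counts in LRR bins. SNVs falling in no segment are dropped and counted.
#'
#' @param snvs SNV tibble with `vaf` (see [read_snvs()]).
#' @param segments Segment tibble.
#' @param bin_width LRR bin width (default 0.1).
#' @return A list: `snvs` (per-SNV tibble with `segment_lrr`), `bins`
#'   (per-bin medians and means of VAF and alt reads; empty bins omitted),
#'   `n_dropped`.
#' @export
vaf_stats <- function(snvs, segments, bin_width = 0.1) {
  assert_columns(snvs, c("sample_id", "chrom", "pos", "alt_reads", "vaf"))
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "mean_lrr"))
  lrr <- rep(NA_real_, nrow(snvs))
  for (i in seq_len(nrow(segments))) {
    hit <- snvs$sample_id == segments$sample_id[i] &
      snvs$chrom == segments$chrom[i] &
      snvs$pos >= segments$start[i] & snvs$pos < segments$end[i]
    lrr[hit] <- segments$mean_lrr[i]
  }
  out <- snvs
  out$segment_lrr <- lrr
  n_dropped <- sum(is.na(lrr))
  out <- out[!is.na(lrr), , drop = FALSE]
  bins <- out |>
    mutate(bin = floor(.data$segment_lrr / bin_width) * bin_width) |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(),
              median_vaf = median(.data$vaf), mean_vaf = mean(.data$vaf),
              median_alt = median(.data$alt_reads),
              mean_alt = mean(.data$alt_reads), .groups = "drop")
  list(snvs = out, bins = bins, n_dropped = n_dropped)
}

#' Locally weighted regression curve
#'
#' Robust lowess fit (tricube-weighted local linear regression with
#' `iterations` rounds of bisquare robustness reweighting) used as the
#' visual guide on density- and VAF-versus-LRR panels.
#'
#' @param x,y Numeric vectors (>= 10 points).
#' @param frac Span: fraction of points entering each local fit.
#' @param iterations Robustness iterations.
#' @return A tibble `x`, `fitted`, sorted by `x`.
#' @export
lowess_curve <- function(x, y, frac = 0.3, iterations = 2) {
  if (length(x) < 10L) abort("lowess_curve() needs at least 10 points")
  stopifnot(length(x) == length(y))
  fit <- lowess(x, y, f = frac, iter = iterations)
  tibble(x = fit$x, fitted = fit$y)
}

#' Fit the per-copy somatic mutation rate
#'
#' Under the neutral accrual model each chromosomal copy collects mutations
#' at a constant rate mu per callable Mb, so a segment's SNV count is Poisson
#' with mean `mu * c_t * callable Mb`. The copy number is recovered from the
#' segment LRR by inverting the attenuated-log model ([lrr_to_copies()]), and
#' mu is the intercept of a Poisson regression with `log(c_hat * callable_mb)`
#' as offset (the maximum-likelihood estimate is total counts over total
#' copy-Mb). Profile-likelihood confidence limits come from the fitted GLM.
#'
#' @param density Per-segment tibble from [snv_density_per_segment()] with
#'   `mean_lrr`, `callable_mb`, `n_snv`, plus a `purity` column or a single
#'   purity via `purity`.
#' @param purity Sample purity (scalar) used when `density` has no `purity`
#'   column.
#' @param alpha LRR attenuation factor of the forward model.
#' @param conf_level Confidence level for the profile interval.
#' @return An object of class `ai_rate_fit`: a list with `mu_hat`, `ci`,
#'   `n_segments`, `fit` (the glm), and the data used.
#' @export
fit_per_copy_rate <- function(density, purity = NULL, alpha = 0.55,
                              conf_level = 0.95) {
  assert_columns(density, c("mean_lrr", "callable_mb", "n_snv"))
  d <- density
  if (!"purity" %in% names(d)) {
    if (is.null(purity)) abort("supply purity (column or scalar)")
    if (any(purity <= 0)) abort("purity must be positive")
    d$purity <- purity
  }
  d$c_hat <- lrr_to_copies(d$mean_lrr, d$purity, alpha)
  d <- d[d$c_hat > 0 & d$callable_mb > 0, , drop = FALSE]
  if (nrow(d) == 0L) abort("no segments with positive inferred copy number")
  if (sum(d$n_snv) == 0L) {
    return(structure(list(mu_hat = 0, ci = c(0, NA_real_),
                          n_segments = nrow(d), fit = NULL, data = d),
                     class = "ai_rate_fit"))
  }
  fit <- glm(n_snv ~ 1, offset = log(c_hat * callable_mb),
             family = poisson(), data = d)
  ci <- tryCatch(suppressMessages(exp(stats::confint(fit, level = conf_level))),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(mu_hat = unname(exp(coef(fit)[1])),
                 ci = unname(ci), n_segments = nrow(d),
                 fit = fit, data = d),
            class = "ai_rate_fit")
}

#' @export
print.ai_rate_fit <- function(x, ...) {
  cat(sprintf("Per-copy mutation rate fit: mu_hat = %.4g /Mb/copy (%d segments)\n",
              x$mu_hat, x$n_segments))
  if (!any(is.na(x$ci))) {
    cat(sprintf("  CI: [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ai_rate_fit <- function(x, ...) {
  tibble(term = "mu_per_mb_per_copy", estimate = x$mu_hat,
         conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @export
glance.ai_rate_fit <- function(x, ...) {
  tibble(n_segments = x$n_segments,
         total_snvs = sum(x$data$n_snv),
         total_copy_mb = sum(x$data$c_hat * x$data$callable_mb),
         deviance = if (is.null(x$fit)) NA_real_ else x$fit$deviance)
}
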