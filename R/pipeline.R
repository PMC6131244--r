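#' Run the full AI landscape analysis on a cohort
#'
#' Chains the pipeline stages: per-sample AI segmentation and
#' classification, homozygous-deletion calling, gain and loss recurrence
#' peak calling with gene assignment, isochromosome calling, per-sample AI
#' burden, and the MSS/MSI burden fold when metadata is available.
#'
#' @param probes Probe tibble (`sample_id`, `chrom`, `pos`, `baf`, `lrr`).
#' @param genome An `ai_genome`.
#' @param config An [ai_config()].
#' @param genes Optional gene BED tibble.
#' @param meta Optional sample metadata (`sample_id`, `msi_status`,
#'   `purity`).
#' @return A list of class `ai_analysis` with elements `segments`,
#'   `homdels`, `peaks` (gain and loss combined), `iso`, `burden` and, when
#'   metadata allows, `msi_fold`.
#' @export
run_ai_analysis <- function(probes, genome, config = ai_config(),
                            genes = NULL, meta = NULL) {
  segments <- call_ai_segments(probes, config, genome)
  homdels <- call_homozygous_deletions(probes, config)
  peaks <- bind_rows(
    call_peaks(segments, "loss", genome, config, genes),
    call_peaks(segments, "gain", genome, config, genes))
  iso <- call_isochromosome(segments, probes, genome, config)
  burden <- ai_burden(segments)
  msi_fold <- NULL
  if (!is.null(meta) && "msi_status" %in% names(meta)) {
    bm <- left_join(meta, burden, by = "sample_id") |>
      mutate(burden_bp = ifelse(is.na(.data$burden_bp), 0, .data$burden_bp))
    if (all(c("MSS", "MSI") %in% bm$msi_status)) {
      msi_fold <- group_fold(bm$burden_bp, bm$msi_status, "MSS", "MSI")
    }
  }
  structure(list(segments = segments, homdels = homdels, peaks = peaks,
                 iso = iso, burden = burden, msi_fold = msi_fold,
                 config = config),
            class = "ai_analysis")
}

#' @export
print.ai_analysis <- function(x, ...) {
  cat("AI landscape analysis\n")
  cat(sprintf("  %d AI segments in %d samples\n",
              nrow(x$segments), length(unique(x$segments$sample_id))))
  cat(sprintf("  %d homozygous deletions\n", nrow(x$homdels)))
  cat(sprintf("  %d peaks at prominence >= %g\n",
              nrow(x$peaks), x$config$prominence_min))
  cat(sprintf("  %d isochromosome calls\n", sum(x$iso$iso_call)))
  if (!is.null(x$msi_fold)) {
    cat(sprintf("  MSS/MSI AI burden fold: %.2f\n", x$msi_fold))
  }
  invisible(x)
}

#' @export
glance.ai_analysis <- function(x, ...) {
  tibble(n_samples = length(unique(x$segments$sample_id)),
         n_segments = nrow(x$segments),
         n_homdels = nrow(x$homdels),
         n_peaks = nrow(x$peaks),
         n_iso_calls = sum(x$iso$iso_call),
         msi_fold = x$msi_fold %||% NA_real_)
}
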