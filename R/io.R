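SEGMENT_CLASSES <- c("gain", "loss", "homozygous_deletion")

#' Read per-SNP tumor probe signals
#'
#' Reads a TSV of per-sample, per-SNP tumor measurements at germline
#' heterozygous loci. Columns: `sample_id`, `chrom`, `pos` (bp, 0-based),
#' `baf` (B-allele frequency in `[0, 1]`), `lrr` (log R ratio). Positions must
#' be sorted within each sample and chromosome; heterozygous-site selection is
#' assumed done upstream.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per probe, sorted as on disk.
#' @export
read_probe_signals <- function(path) {
  probes <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              sample_id = readr::col_character(),
                              chrom = readr::col_character(),
                              pos = readr::col_double(),
                              baf = readr::col_double(),
                              lrr = readr::col_double()))
  assert_columns(probes, c("sample_id", "chrom", "pos", "baf", "lrr"),
                 sprintf("probe file '%s'", path))
  if (nrow(probes) == 0L) {
    warn(sprintf("probe file '%s' contains no rows", path))
    return(probes)
  }
  validate_probes(probes)
  probes
}

validate_probes <- function(probes) {
  bad_baf <- which(is.na(probes$baf) | probes$baf < 0 | probes$baf > 1)
  if (length(bad_baf) > 0L) {
    abort(sprintf("BAF outside [0, 1] at data row %d (sample %s, %s:%s)",
                  bad_baf[1], probes$sample_id[bad_baf[1]],
                  probes$chrom[bad_baf[1]],
                  format(probes$pos[bad_baf[1]], scientific = FALSE)))
  }
  unsorted <- probes |>
    group_by(.data$sample_id, .data$chrom) |>
    summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
  if (any(!unsorted$ok)) {
    bad <- unsorted[!unsorted$ok, ][1, ]
    abort(sprintf("positions not sorted for sample %s on %s",
                  bad$sample_id, bad$chrom))
  }
  invisible(probes)
}

#' @rdname read_probe_signals
#' @param probes A probe tibble as returned by [read_probe_signals()].
#' @export
write_probe_signals <- function(probes, path) {
  assert_columns(probes, c("sample_id", "chrom", "pos", "baf", "lrr"))
  readr::write_tsv(probes, path)
  invisible(path)
}

#' Read and write AI segment calls
#'
#' Segments travel as a BED-like TSV with header: `chrom`, `start`, `end`
#' (bp, 0-based half-open), `sample_id`, `klass` (`gain`, `loss`, or
#' `homozygous_deletion`; matched case-insensitively), `mean_lrr`,
#' `mean_mbaf` (mean mirrored BAF, in `[0, 0.5]`), `n_probes`. The `loss`
#' class includes copy-neutral LOH. Writing then reading reproduces the
#' input exactly.
#'
#' @param path File path.
#' @return `read_segments_bed()` returns a segment tibble;
#'   `write_segments_bed()` returns `path` invisibly.
#' @export
read_segments_bed <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           sample_id = readr::col_character(),
                           klass = readr::col_character(),
                           mean_lrr = readr::col_double(),
                           mean_mbaf = readr::col_double(),
                           n_probes = readr::col_integer()))
  assert_columns(seg, c("chrom", "start", "end", "sample_id", "klass",
                        "mean_lrr", "mean_mbaf", "n_probes"),
                 sprintf("segment file '%s'", path))
  seg$klass <- tolower(seg$klass)
  validate_segments(seg)
  seg
}

validate_segments <- function(seg) {
  bad <- which(seg$start >= seg$end)
  if (length(bad) > 0L) {
    abort(sprintf("segment with start >= end at data row %d (%s:%s-%s)",
                  bad[1], seg$chrom[bad[1]],
                  format(seg$start[bad[1]], scientific = FALSE),
                  format(seg$end[bad[1]], scientific = FALSE)))
  }
  unknown <- setdiff(unique(seg$klass), SEGMENT_CLASSES)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown segment class token(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (any(seg$mean_mbaf < 0 | seg$mean_mbaf > 0.5, na.rm = TRUE)) {
    abort("mean_mbaf must lie in [0, 0.5]")
  }
  invisible(seg)
}

#' @rdname read_segments_bed
#' @param segments A segment tibble.
#' @export
write_segments_bed <- function(segments, path) {
  assert_columns(segments, c("chrom", "start", "end", "sample_id", "klass",
                             "mean_lrr", "mean_mbaf", "n_probes"))
  validate_segments(segments)
  readr::write_tsv(
    segments[, c("chrom", "start", "end", "sample_id", "klass",
                 "mean_lrr", "mean_mbaf", "n_probes")],
    path)
  invisible(path)
}

#' Read somatic SNV calls
#'
#' Accepts either a minimal VCF (one or more tumor sample columns carrying an
#' `AD` ref,alt allelic-depth field) or a TSV with columns `sample_id`,
#' `chrom`, `pos`, `ref_reads`, `alt_reads`. Records with zero total depth are
#' dropped with a warning; the variant allele fraction
#' `vaf = alt / (ref + alt)` is computed and records are sorted by
#' chromosome and position.
#'
#' @param path Path to a `.vcf` or TSV file.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `ref_reads`,
#'   `alt_reads`, `vaf`.
#' @export
read_snvs <- function(path) {
  snv <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_snvs_vcf(path)
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      sample_id = readr::col_character(),
                      chrom = readr::col_character(),
                      pos = readr::col_double(),
                      ref_reads = readr::col_integer(),
                      alt_reads = readr::col_integer()))
  }
  assert_columns(snv, c("sample_id", "chrom", "pos", "ref_reads", "alt_reads"),
                 sprintf("SNV file '%s'", path))
  if (any(snv$ref_reads < 0 | snv$alt_reads < 0, na.rm = TRUE)) {
    abort("negative read counts in SNV input")
  }
  depth0 <- snv$ref_reads + snv$alt_reads == 0
  if (any(depth0)) {
    warn(sprintf("dropping %d SNV record(s) with zero total depth", sum(depth0)))
    snv <- snv[!depth0, ]
  }
  snv |>
    mutate(vaf = .data$alt_reads / (.data$ref_reads + .data$alt_reads)) |>
    arrange(.data$chrom, .data$pos, .data$sample_id)
}

# VCF input via vcfR; the per-sample AD field carries ref,alt depths.
# VCF POS is 1-based; internal coordinates are 0-based, hence the - 1.
read_snvs_vcf <- function(path) {
  empty <- tibble(sample_id = character(), chrom = character(), pos = double(),
                  ref_reads = integer(), alt_reads = integer())
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(empty)
  if (ncol(v@gt) < 2L) abort(sprintf("'%s': VCF has no sample columns", path))
  if (!any(grepl("AD", v@gt[, "FORMAT"]))) {
    abort(sprintf("'%s': VCF records lack AD in FORMAT", path))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  fix <- vcfR::getFIX(v)
  out <- list_rbind(map(colnames(ad), function(s) {
    parts <- strsplit(unname(ad[, s]), ",", fixed = TRUE)
    tibble(sample_id = s,
           chrom = unname(fix[, "CHROM"]),
           pos = as.numeric(fix[, "POS"]) - 1,
           ref_reads = suppressWarnings(
             vapply(parts, \(p) as.integer(p[1]), integer(1))),
           alt_reads = suppressWarnings(
             vapply(parts, \(p) as.integer(p[2]), integer(1))))
  }))
  # a no-call sample column ("./.") yields NA depths: not a record
  out[!is.na(out$ref_reads) & !is.na(out$alt_reads), ]
}

#' @rdname read_snvs
#' @param snvs An SNV tibble.
#' @export
write_snvs_tsv <- function(snvs, path) {
  assert_columns(snvs, c("sample_id", "chrom", "pos", "ref_reads", "alt_reads"))
  readr::write_tsv(snvs[, c("sample_id", "chrom", "pos",
                            "ref_reads", "alt_reads")], path)
  invisible(path)
}

#' Read a BED interval file
#'
#' Plain BED3(+name): tab-separated `chrom`, `start`, `end` and, if present, a
#' fourth `name` column; no header line. Used for gene annotation and callable
#' region masks.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end` and (when present)
#'   `name`.
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0L) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  n_fields <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  nm <- c("chrom", "start", "end", "name")[seq_len(min(n_fields, 4L))]
  bed <- readr::read_tsv(path, col_names = nm, show_col_types = FALSE,
                         col_types = paste0(c("c", "d", "d", "c")[seq_along(nm)],
                                            collapse = ""))
  if (any(bed$start >= bed$end)) abort(sprintf("'%s': BED interval with start >= end", path))
  bed
}

#' @rdname read_bed
#' @param bed A tibble with `chrom`, `start`, `end` and optionally `name`.
#' @export
write_bed <- function(bed, path) {
  assert_columns(bed, c("chrom", "start", "end"))
  cols <- intersect(c("chrom", "start", "end", "name"), names(bed))
  readr::write_tsv(bed[, cols], path, col_names = FALSE)
  invisible(path)
}
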