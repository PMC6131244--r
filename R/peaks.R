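#' Build a cohort AI count track
#'
#' For one segment class, counts for every genomic interval how many distinct
#' samples carry a segment of that class covering it. Breakpoints are the
#' sorted unique segment endpoints plus the chromosome ends; a sample with
#' several overlapping segments contributes once (its segments are unioned
#' first).
#'
#' @param segments Classified segment tibble.
#' @param klass `"gain"` or `"loss"`.
#' @param genome An `ai_genome`; every chromosome yields a track even without
#'   segments.
#' @return A tibble `chrom`, `start`, `end`, `value` of piecewise-constant
#'   tumor counts, with attribute `klass`.
#' @export
build_count_track <- function(segments, klass, genome) {
  assert_columns(segments, c("sample_id", "chrom", "start", "end", "klass"))
  seg <- segments[segments$klass == klass, , drop = FALSE]
  beyond <- seg$end > genome_length(genome, seg$chrom)
  if (any(beyond, na.rm = TRUE) || any(is.na(beyond))) {
    abort("segment beyond chromosome end (or on unknown chromosome)")
  }
  tracks <- map(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    len <- genome$length[i]
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0L) {
      return(tibble(chrom = chrom, start = 0, end = len, value = 0L))
    }
    merged <- s |>
      group_by(.data$sample_id) |>
      reframe(from_iranges(IRanges::reduce(to_iranges(.data$start, .data$end))))
    bps <- sort(unique(c(0, len, merged$start, merged$end)))
    delta <- integer(length(bps))
    i1 <- match(merged$start, bps)
    i2 <- match(merged$end, bps)
    for (k in seq_len(nrow(merged))) {
      delta[i1[k]] <- delta[i1[k]] + 1L
      delta[i2[k]] <- delta[i2[k]] - 1L
    }
    tibble(chrom = chrom, start = bps[-length(bps)], end = bps[-1],
           value = cumsum(delta)[-length(bps)])
  })
  out <- list_rbind(tracks)
  attr(out, "klass") <- klass
  out
}

#' Max-filter smoothing over breakpoint intervals
#'
#' `max_smooth()` is the vector primitive: element `i` of the result is the
#' maximum of `values` over a window of `w` consecutive intervals -- centered,
#' `i - ceiling(w/2) + 1 ... i + floor(w/2)`, or trailing, `i - w + 1 ... i` --
#' clipped at the ends. `smooth_track()` applies it per chromosome and adds a
#' `smoothed` column.
#'
#' @param values Numeric vector of interval values.
#' @param w Window width in intervals (>= 1).
#' @param align `"centered"` or `"trailing"`.
#' @return `max_smooth()`: a vector; `smooth_track()`: the track tibble with
#'   `smoothed`.
#' @examples
#' max_smooth(c(1, 3, 2), 3)
#' @export
max_smooth <- function(values, w, align = c("centered", "trailing")) {
  align <- match.arg(align)
  stopifnot(w >= 1)
  n <- length(values)
  if (w == 1L || n == 0L) return(values)
  lo_off <- if (align == "centered") ceiling(w / 2) - 1L else w - 1L
  hi_off <- if (align == "centered") floor(w / 2) else 0L
  vapply(seq_len(n), function(i) {
    max(values[max(1L, i - lo_off):min(n, i + hi_off)])
  }, numeric(1))
}

#' @rdname max_smooth
#' @param track A count track from [build_count_track()].
#' @param config An [ai_config()] supplying `smooth_window` and
#'   `smooth_align`.
#' @export
smooth_track <- function(track, config = ai_config()) {
  assert_columns(track, c("chrom", "value"))
  track |>
    group_by(.data$chrom) |>
    mutate(smoothed = max_smooth(.data$value, config$smooth_window,
                                 config$smooth_align)) |>
    ungroup()
}

#' Local maxima of a piecewise-constant track
#'
#' Returns the maximal runs of equal value that are strictly greater than
#' both flanking interval values. A run touching a chromosome end qualifies
#' if strictly greater than its single inner neighbour; a constant nonzero
#' chromosome yields one run spanning it. Zero-height runs are excluded.
#'
#' @param values Numeric vector of interval values (one chromosome).
#' @return A tibble `first`, `last` (interval indices), `value`.
#' @examples
#' find_local_maxima(c(0, 2, 1, 3, 0))
#' @export
find_local_maxima <- function(values) {
  n <- length(values)
  if (n == 0L) return(tibble(first = integer(), last = integer(), value = double()))
  r <- rle(values)
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  k <- length(r$values)
  left_ok <- c(TRUE, r$values[-1] > r$values[-k])
  right_ok <- c(r$values[-k] > r$values[-1], TRUE)
  keep <- left_ok & right_ok & r$values > 0
  tibble(first = firsts[keep], last = ends[keep], value = r$values[keep])
}

#' Topographic prominence of an apex on a raw count track
#'
#' `track_prominence()` implements the contour definition by outward walks:
#' with apex height `h` (the maximum raw value within the apex run), each side
#' is walked outward from the raw summit to the nearest interval with raw
#' value greater than `h`,
#' recording the minimum value along the walk (the side col). A side that
#' never reaches higher terrain contributes sea level. Prominence is `h`
#' minus the highest col among sides that reach higher terrain, or `h` when
#' neither does -- so the highest peak of a chromosome has prominence equal
#' to its height.
#'
#' `prominence_oracle()` is an independent reference implementation of the
#' same definition by descending flood fill: the smallest level `L` at which
#' the connected run of intervals with value >= `L` containing the apex also
#' contains a value > `h` gives prominence `h - L`; if no level does, the
#' prominence is `h`.
#'
#' @param raw Numeric vector of raw (unsmoothed) interval values for one
#'   chromosome.
#' @param first,last Index range of the apex run on `raw`.
#' @return A single prominence value.
#' @examples
#' track_prominence(c(0, 2, 1, 3, 0), 2, 2)   # 1
#' prominence_oracle(c(0, 2, 1, 3, 0), 2, 2)  # 1
#' @export
track_prominence <- function(raw, first, last) {
  n <- length(raw)
  if (first < 1L || last > n || first > last) abort("apex not on track")
  h <- max(raw[first:last])
  # walks start at the raw summit inside the apex: a smoothed apex run can
  # contain raw dips, which belong to the walk, not to the summit
  s <- first - 1L + which.max(raw[first:last])
  side_col <- function(idx) {
    m <- Inf
    for (j in idx) {
      if (raw[j] > h) return(m)
      m <- min(m, raw[j])
    }
    NA_real_  # never reached higher terrain
  }
  cols <- c(
    if (s > 1L) side_col(seq(s - 1L, 1L)) else NA_real_,
    if (s < n) side_col(seq(s + 1L, n)) else NA_real_)
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0L) h else h - max(cols)
}

#' @rdname track_prominence
#' @export
prominence_oracle <- function(raw, first, last) {
  n <- length(raw)
  if (first < 1L || last > n || first > last) abort("apex not on track")
  h <- max(raw[first:last])
  s <- first - 1L + which.max(raw[first:last])  # raw summit anchors the fill
  levels <- sort(unique(c(raw[raw <= h], 0)), decreasing = TRUE)
  for (L in levels) {
    keep <- raw >= L
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    comp <- which(r$values & starts <= s & ends >= s)
    if (length(comp) == 1L) {
      run <- starts[comp]:ends[comp]
      if (any(raw[run] > h)) return(h - L)
    }
  }
  h
}

#' Call and rank recurrence peaks for one class
#'
#' Composes the track pipeline: build the class count track, smooth it with
#' the max filter, take local maxima of the smoothed track as apex plateaus,
#' measure each apex's height and topographic prominence on the unsmoothed
#' track, keep peaks with prominence at least `config$prominence_min`, and
#' rank by descending prominence (ties broken by height, then genomic order).
#'
#' @param segments Classified cohort segment tibble.
#' @param klass `"gain"` or `"loss"`.
#' @param genome An `ai_genome`.
#' @param config An [ai_config()].
#' @param genes Optional gene BED tibble for candidate-target assignment.
#' @return A peak tibble: `rank`, `chrom`, `klass`, `apex_start`, `apex_end`,
#'   `height`, `prominence`, `spans_chromosome` (flags a constant-track
#'   apex), and `genes` (list-column) when `genes` was supplied.
#' @export
call_peaks <- function(segments, klass, genome, config = ai_config(),
                       genes = NULL) {
  raw <- build_count_track(segments, klass, genome)
  sm <- smooth_track(raw, config)
  per_chrom <- map(split(sm, sm$chrom), function(tr) {
    tr <- tr[order(tr$start), ]
    apex <- find_local_maxima(tr$smoothed)
    if (nrow(apex) == 0L) return(NULL)
    tibble(
      chrom = tr$chrom[1],
      apex_start = tr$start[apex$first],
      apex_end = tr$end[apex$last],
      height = map_dbl(seq_len(nrow(apex)),
                       \(i) max(tr$value[apex$first[i]:apex$last[i]])),
      prominence = map_dbl(seq_len(nrow(apex)),
                           \(i) track_prominence(tr$value, apex$first[i], apex$last[i])),
      spans_chromosome = apex$first == 1L & apex$last == nrow(tr))
  })
  peaks <- list_rbind(per_chrom[!map_lgl(per_chrom, is.null)])
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- tibble(chrom = character(), apex_start = double(),
                    apex_end = double(), height = double(),
                    prominence = double(), spans_chromosome = logical())
  }
  peaks <- peaks[peaks$prominence >= config$prominence_min, , drop = FALSE]
  peaks$klass <- klass
  chrom_order <- match(peaks$chrom, genome$chrom)
  o <- order(-peaks$prominence, -peaks$height, chrom_order, peaks$apex_start)
  peaks <- peaks[o, , drop = FALSE]
  peaks$rank <- seq_len(nrow(peaks))
  peaks <- peaks[, c("rank", "chrom", "klass", "apex_start", "apex_end",
                     "height", "prominence", "spans_chromosome")]
  if (!is.null(genes)) peaks <- assign_genes(peaks, genes)
  peaks
}

#' Assign candidate target genes to peaks
#'
#' Genes overlapping the apex plateau `[apex_start, apex_end)` are the
#' candidates; when the plateau contains no gene, the nearest gene on each
#' side is taken instead (up to two flanking genes; fewer at chromosome
#' ends).
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param genes Gene BED tibble (`chrom`, `start`, `end`, `name`), sorted.
#' @return `peaks` with a `genes` list-column of gene names and an
#'   `n_genes_in_apex` count.
#' @export
assign_genes <- function(peaks, genes) {
  assert_columns(genes, c("chrom", "start", "end", "name"))
  lists <- map(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    inside <- g$start < peaks$apex_end[i] & g$end > peaks$apex_start[i]
    if (any(inside)) return(list(g$name[inside], sum(inside)))
    left <- g[g$end <= peaks$apex_start[i], , drop = FALSE]
    right <- g[g$start >= peaks$apex_end[i], , drop = FALSE]
    flank <- c(
      if (nrow(left) > 0) left$name[which.max(left$end)],
      if (nrow(right) > 0) right$name[which.min(right$start)])
    list(flank, 0L)
  })
  peaks$genes <- map(lists, 1)
  peaks$n_genes_in_apex <- map_int(lists, \(x) as.integer(x[[2]]))
  peaks
}
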