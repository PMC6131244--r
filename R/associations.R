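#' 2x2 contingency analysis
#'
#' Summarises a 2x2 table laid out as rows = exposure strata, columns =
#' outcome (yes, no): `a`, `b` are the outcome-yes / outcome-no counts of the
#' first stratum, `c`, `d` of the second. Reports the per-stratum outcome
#' percentages (rounded to integers for reporting), the cross-product odds
#' ratio `ad / bc` (with the Haldane-Anscombe 0.5 correction when any cell is
#' zero), and the two-sided Fisher exact p-value of the uncorrected table.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A one-row tibble: `pct_row1`, `pct_row2` (rounded percentages),
#'   `odds_ratio`, `p_value`, `haldane_corrected`.
#' @examples
#' contingency_2x2(129, 49, 279, 614)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) abort("all-zero contingency table")
  if (a + b == 0 || c + d == 0) abort("a contingency row is empty")
  zero <- any(cells == 0)
  hc <- if (zero) 0.5 else 0
  or <- ((a + hc) * (d + hc)) / ((b + hc) * (c + hc))
  p <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  tibble(pct_row1 = round(100 * a / (a + b)),
         pct_row2 = round(100 * c / (c + d)),
         odds_ratio = or, p_value = p, haldane_corrected = zero)
}

#' Upper-tail hypergeometric probability
#'
#' Exact `P(X >= x)` for X hypergeometric with population `N`, `K` marked
#' items and a draw of `n`, evaluated by summing log-binomial terms
#' (log-sum-exp), so tails far below machine epsilon on the linear scale are
#' still computed accurately.
#'
#' @param N Population size.
#' @param K Marked items in the population.
#' @param n Draw size.
#' @param x Threshold count of marked items in the draw.
#' @return `P(X >= x)` as a probability; use [log_hypergeometric_tail()] for
#'   the natural-log value.
#' @examples
#' hypergeometric_tail(10, 10, 3, 3)  # 1
#' hypergeometric_tail(5, 1, 1, 1)    # 0.2
#' @export
hypergeometric_tail <- function(N, K, n, x) {
  exp(log_hypergeometric_tail(N, K, n, x))
}

#' @rdname hypergeometric_tail
#' @export
log_hypergeometric_tail <- function(N, K, n, x) {
  if (!(x >= 0 && x <= n && n <= N && K <= N && K >= 0)) {
    abort("inconsistent hypergeometric counts: need 0 <= x <= n <= N, 0 <= K <= N")
  }
  ks <- seq(max(x, n - (N - K)), min(n, K))
  if (length(ks) == 0L || min(n, K) < x) return(-Inf)
  terms <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  logsumexp(terms)
}

#' Does a sample show class-matched AI at a peak?
#'
#' @param segments Classified segment tibble.
#' @param peak One-row peak tibble (`chrom`, `klass`, `apex_start`,
#'   `apex_end`).
#' @param samples Sample universe (defaults to samples present in
#'   `segments`).
#' @return Named logical vector over `samples`.
#' @export
peak_ai_indicator <- function(segments, peak, samples = NULL) {
  samples <- samples %||% unique(segments$sample_id)
  s <- segments[segments$chrom == peak$chrom &
                  segments$klass == peak$klass &
                  segments$start < peak$apex_end &
                  segments$end > peak$apex_start, ]
  setNames(samples %in% s$sample_id, samples)
}

# Firth-penalized logistic regression (Jeffreys prior), used when the
# unpenalized fit separates. Returns coefficients and Wald SEs.
firth_logit <- function(X, y, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    XW <- X * W
    info <- crossprod(X, XW)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) break
    h <- rowSums((X %*% info_inv) * XW)
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(info_inv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  list(coef = beta, se = se)
}

# Shared logistic machinery: outcome y ~ predictor + burden covariate.
burden_logistic <- function(y, predictor, burden_mb) {
  df <- tibble(y = as.numeric(y), x = as.numeric(predictor),
               burden = burden_mb)
  if (length(unique(df$y)) < 2L) {
    return(tibble(estimate = NA_real_, std.error = NA_real_,
                  p.value = NA_real_, method = "degenerate",
                  separated = TRUE))
  }
  fit <- withCallingHandlers(
    glm(y ~ x + burden, family = binomial(), data = df),
    warning = function(w) invokeRestart("muffleWarning"))
  co <- summary(fit)$coefficients
  separated <- !fit$converged || any(abs(coef(fit)[-1]) > 10, na.rm = TRUE) ||
    any(co[, "Std. Error"] > 100)
  if (!separated) {
    return(tibble(estimate = co["x", "Estimate"],
                  std.error = co["x", "Std. Error"],
                  p.value = co["x", "Pr(>|z|)"],
                  method = "ml", separated = FALSE))
  }
  if (stats::sd(df$x) == 0) {
    return(tibble(estimate = NA_real_, std.error = NA_real_,
                  p.value = NA_real_, method = "degenerate",
                  separated = TRUE))
  }
  # drop constant covariates (a zero-variance burden makes the information
  # matrix singular) before the penalized fit
  X <- cbind(1, df$x)
  if (stats::sd(df$burden) > 0) X <- cbind(X, df$burden)
  ff <- firth_logit(X, df$y)
  z <- ff$coef[2] / ff$se[2]
  tibble(estimate = ff$coef[2], std.error = ff$se[2],
         p.value = 2 * pnorm(-abs(z)), method = "firth", separated = TRUE)
}

#' Burden-controlled peak-pair association
#'
#' Logistic regression of class-matched AI at `peak_j` on class-matched AI at
#' `peak_i`, controlling for the sample's AI burden on chromosomes other than
#' those of the two peaks (in Mb). A positive coefficient means the two peaks
#' tend to be hit in the same samples beyond what overall instability
#' explains. Complete separation is flagged and refitted with Firth
#' penalization.
#'
#' @param segments Classified cohort segment tibble.
#' @param peak_i,peak_j One-row peak tibbles on different chromosomes.
#' @param samples Sample universe.
#' @return A one-row tibble: `estimate` (log-odds), `std.error`, `p.value`,
#'   `method`, `separated`.
#' @export
peak_pair_logistic <- function(segments, peak_i, peak_j, samples = NULL) {
  if (peak_i$chrom == peak_j$chrom) {
    abort("peak-pair association requires peaks on different chromosomes")
  }
  samples <- samples %||% unique(segments$sample_id)
  xi <- peak_ai_indicator(segments, peak_i, samples)
  yj <- peak_ai_indicator(segments, peak_j, samples)
  b <- ai_burden(segments, exclude_chroms = c(peak_i$chrom, peak_j$chrom))
  burden <- setNames(rep(0, length(samples)), samples)
  burden[b$sample_id] <- b$burden_bp / 1e6
  burden_logistic(yj, xi, burden[samples])
}

#' Burden-controlled peak-phenotype association
#'
#' Logistic regression of class-matched AI at a peak on a binary phenotype
#' (e.g. MSI status), controlling for AI burden on the other chromosomes.
#'
#' @param segments Classified cohort segment tibble.
#' @param peak One-row peak tibble.
#' @param phenotype Named logical/0-1 vector over samples.
#' @param samples Sample universe (defaults to `names(phenotype)`).
#' @return A one-row tibble as in [peak_pair_logistic()].
#' @export
phenotype_logistic <- function(segments, peak, phenotype, samples = NULL) {
  samples <- samples %||% names(phenotype)
  if (is.null(samples)) abort("phenotype must be named by sample")
  ph <- as.numeric(phenotype[samples])
  if (length(unique(ph[!is.na(ph)])) < 2L) {
    abort("phenotype has a single class; association undefined")
  }
  y <- peak_ai_indicator(segments, peak, samples)
  b <- ai_burden(segments, exclude_chroms = peak$chrom)
  burden <- setNames(rep(0, length(samples)), samples)
  burden[b$sample_id] <- b$burden_bp / 1e6
  burden_logistic(y, ph, burden[samples])
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjusted values.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param method `"bonferroni"` or `"BH"`.
#' @param m Number of tests (defaults to `length(pvalues)`).
#' @return Adjusted p-values.
#' @export
multiple_testing <- function(pvalues, method = c("bonferroni", "BH"),
                             m = length(pvalues)) {
  method <- match.arg(method)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  if (method == "bonferroni") pmin(1, m * pvalues)
  else p.adjust(pvalues, method = "BH", n = m)
}

#' Expression-dosage association per gene
#'
#' For each gene fits `expression ~ lrr + purity` across samples and reports
#' the Wald test on the LRR slope, with Benjamini-Hochberg adjustment across
#' genes. Genes with (near) zero LRR variance are skipped with a flag.
#'
#' @param expression Tibble `sample_id`, `gene`, `lrr`, `expression`.
#' @param meta Metadata tibble with `sample_id`, `purity`.
#' @param min_samples Minimum complete observations per gene.
#' @return A tibble per gene: `gene`, `n`, `slope`, `std.error`, `p.value`,
#'   `q.value`, `skipped`.
#' @export
expression_dosage_test <- function(expression, meta, min_samples = 30L) {
  assert_columns(expression, c("sample_id", "gene", "lrr", "expression"))
  assert_columns(meta, c("sample_id", "purity"))
  df <- left_join(expression, meta[, c("sample_id", "purity")], by = "sample_id")
  res <- df |>
    group_by(.data$gene) |>
    group_modify(function(g, key) {
      g <- g[complete.cases(g[, c("lrr", "expression", "purity")]), ]
      if (nrow(g) < min_samples) {
        return(tibble(n = nrow(g), slope = NA_real_, std.error = NA_real_,
                      p.value = NA_real_, skipped = TRUE))
      }
      if (stats::sd(g$lrr) < 1e-8) {
        return(tibble(n = nrow(g), slope = 0, std.error = NA_real_,
                      p.value = NA_real_, skipped = TRUE))
      }
      fit <- lm(expression ~ lrr + purity, data = g)
      co <- summary(fit)$coefficients
      tibble(n = nrow(g), slope = co["lrr", "Estimate"],
             std.error = co["lrr", "Std. Error"],
             p.value = co["lrr", "Pr(>|t|)"], skipped = FALSE)
    }) |>
    ungroup()
  res$q.value <- NA_real_
  ok <- !res$skipped
  res$q.value[ok] <- multiple_testing(res$p.value[ok], "BH")
  res
}

#' AI events in curated peaks per tumor
#'
#' Counts, for each sample, the curated peaks showing the peak's expected
#' class of AI over its apex: gain segments count only toward gain-type
#' peaks, loss segments only toward loss-type peaks. Adding a segment can
#' never decrease a count.
#'
#' @param segments Classified cohort segment tibble.
#' @param peaks Curated peak tibble (`chrom`, `klass`, `apex_start`,
#'   `apex_end`).
#' @param samples Sample universe.
#' @return Tibble `sample_id`, `n_events`.
#' @export
events_per_tumor <- function(segments, peaks, samples = NULL) {
  samples <- samples %||% unique(segments$sample_id)
  counts <- setNames(integer(length(samples)), samples)
  for (i in seq_len(nrow(peaks))) {
    hit <- peak_ai_indicator(segments, peaks[i, ], samples)
    counts <- counts + as.integer(hit)
  }
  tibble(sample_id = samples, n_events = unname(counts))
}

#' Compare event counts between two strata
#'
#' Two-sided Mann-Whitney rank test (normal approximation with tie
#' correction) comparing per-tumor event counts between two groups, with
#' group means and medians.
#'
#' @param counts Tibble from [events_per_tumor()].
#' @param strata Named vector of group labels over samples.
#' @return A one-row tibble with group summaries and the rank-test p-value.
#' @export
stratify_event_counts <- function(counts, strata) {
  df <- counts |>
    mutate(group = strata[.data$sample_id]) |>
    filter(!is.na(.data$group))
  gs <- sort(unique(df$group))
  if (length(gs) != 2L) abort("exactly two strata required")
  a <- df$n_events[df$group == gs[1]]
  b <- df$n_events[df$group == gs[2]]
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  tibble(group1 = gs[1], group2 = gs[2],
         n1 = length(a), n2 = length(b),
         mean1 = mean(a), mean2 = mean(b),
         median1 = median(a), median2 = median(b),
         p_value = wt$p.value)
}
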