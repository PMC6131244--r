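#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @import tibble
#' @importFrom rlang .data abort warn %||%
#' @importFrom purrr map pmap map_dbl map_int map_lgl imap list_rbind
#' @importFrom stats rnorm rbinom rpois rbeta rnbinom runif median mad
#'   glm binomial poisson fisher.test wilcox.test p.adjust lm coef
#'   pnorm complete.cases setNames lowess
NULL

# Intervals are 0-based half-open throughout; IRanges (1-based closed) is used
# for interval arithmetic behind these two converters.
to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

from_iranges <- function(ir) {
  tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

# Total bp covered by the union of [start, end) intervals.
interval_union_bp <- function(start, end) {
  if (length(start) == 0L) return(0)
  sum(BiocGenerics::width(IRanges::reduce(to_iranges(start, end))))
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
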