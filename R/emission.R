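#' Expected B-allele frequency under a two-population mixture
#'
#' Models a bulk tumor sample as a mixture of normal diploid cells (fraction
#' `1 - purity`, genotype AB) and tumor cells (fraction `purity`), of which a
#' fraction `clonal_fraction` carries the event and the rest remain AB. At a
#' germline-heterozygous SNP where the event leaves `b_copies` copies of the B
#' allele out of `total_copies` in the aberrant cells, the expected BAF is the
#' B-allele share of all chromosomal copies in the mixture:
#'
#' \deqn{E[BAF] = \frac{(1-\rho) + \rho[(1-f) + f b_t]}
#'                     {2(1-\rho) + \rho[2(1-f) + f c_t]}}
#'
#' with purity \eqn{\rho}, clonal fraction \eqn{f}, tumor copies \eqn{c_t} and
#' tumor B copies \eqn{b_t}. This is the mixture that purity-corrected BAF
#' (cBAF) clonality estimation inverts.
#'
#' @param purity Tumor cell fraction \eqn{\rho} in (0, 1].
#' @param clonal_fraction Fraction \eqn{f} in (0, 1] of tumor cells carrying
#'   the event.
#' @param total_copies Total chromosomal copies \eqn{c_t} in event-carrying
#'   cells (>= 0).
#' @param b_copies B-allele copies \eqn{b_t} (0 <= b_copies <= total_copies).
#'
#' @return Expected BAF in `[0, 1]`; `NaN` when the mixture contains no DNA at
#'   the locus (purity = 1, clonal fraction = 1, zero copies: the
#'   homozygous-deletion regime, where BAF is undefined).
#' @examples
#' expected_baf(1, 1, 2, 1)           # balanced het: 0.5
#' expected_baf(0.5, 1, 2, 0)         # cn-LOH at 50% purity: 0.25
#' @export
expected_baf <- function(purity, clonal_fraction, total_copies, b_copies) {
  stopifnot(all(purity > 0 & purity <= 1),
            all(clonal_fraction > 0 & clonal_fraction <= 1),
            all(total_copies >= 0), all(b_copies >= 0),
            all(b_copies <= total_copies))
  num <- (1 - purity) + purity * ((1 - clonal_fraction) + clonal_fraction * b_copies)
  den <- 2 * (1 - purity) + purity * (2 * (1 - clonal_fraction) + clonal_fraction * total_copies)
  ifelse(den == 0, NaN, num / den)
}

#' Expected log R ratio under the same mixture
#'
#' The LRR is modeled as an attenuated log2 ratio of total copies in the
#' mixture to the diploid expectation:
#' \deqn{E[LRR] = \alpha \log_2\frac{2(1-\rho) + \rho[2(1-f) + f c_t]}{2}}
#' Array intensities compress the true log ratio, hence the attenuation
#' factor \eqn{\alpha < 1}.
#'
#' @inheritParams expected_baf
#' @param alpha Attenuation factor (default 0.55).
#' @param floor Lower cap applied when total mixture copies reach 0.
#' @return Expected LRR (unitless).
#' @examples
#' expected_lrr(0.5, 1, 3)   # one-copy gain at 50% purity
#' expected_lrr(1, 1, 4, alpha = 1)  # 1.0: a doubled genome at alpha = 1
#' @export
expected_lrr <- function(purity, clonal_fraction, total_copies,
                         alpha = 0.55, floor = -5) {
  stopifnot(all(purity > 0 & purity <= 1),
            all(clonal_fraction > 0 & clonal_fraction <= 1),
            all(total_copies >= 0), alpha > 0)
  tot <- 2 * (1 - purity) + purity * (2 * (1 - clonal_fraction) + clonal_fraction * total_copies)
  out <- alpha * log2(tot / 2)
  pmax(out, floor)
}

#' Invert mean LRR to an estimated tumor copy number
#'
#' Solves the expected-LRR model for the event copy number assuming a clonal
#' event (`f = 1`): \eqn{\hat c_t = (2 \cdot 2^{lrr/\alpha} - 2(1-\rho))/\rho},
#' clipped at 0.
#'
#' @param lrr Observed mean LRR.
#' @param purity Tumor purity \eqn{\rho} in (0, 1].
#' @param alpha Attenuation factor used in the forward model.
#' @return Estimated copy number (>= 0).
#' @examples
#' lrr_to_copies(0, purity = 0.8)  # 2: neutral LRR inverts to diploid
#' @export
lrr_to_copies <- function(lrr, purity, alpha = 0.55) {
  if (any(purity <= 0)) abort("purity must be positive to invert LRR")
  pmax((2 * 2^(lrr / alpha) - 2 * (1 - purity)) / purity, 0)
}
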