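.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Hypoxia/adenosine-modulated Treg polarization probability
#'
#' The probability that a newly activated T cell polarizes to a regulatory
#' (suppressive) phenotype: the base rate plus a hypoxia term and an
#' adenosine term,
#' `P_Treg + r_Hr / (U + c) + r_Ar * Ad`, clamped into \[0, 1\].
#' `U` is the oxygen at the site of the activating DC.
#'
#' @param U_local Local oxygen concentration (>= 0); vectorized.
#' @param Ad Global adenosine level (>= 0); vectorized.
#' @param params Model parameters.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' treg_rate(0.8, 0, default_parameters())  # 0.305802...
treg_rate <- function(U_local, Ad, params) {
  .check_rate_inputs(U_local, Ad)
  .clamp01(params$P_Treg + params$r_Hr / (U_local + params$c) +
             params$r_Ar * Ad)
}

#' Hypoxia/adenosine-modulated tumor division probability
#'
#' Per-step division probability of a rim tumor cell:
#' `P_tumor + r_Ht / (U + c) + r_At * Ad`, clamped into \[0, 1\], with `U`
#' the oxygen at the dividing cell's site. Both hypoxia and adenosine promote
#' proliferation.
#'
#' @inheritParams treg_rate
#' @return Probability in \[0, 1\].
#' @export
tumor_rate <- function(U_local, Ad, params) {
  .check_rate_inputs(U_local, Ad)
  .clamp01(params$P_tumor + params$r_Ht / (U_local + params$c) +
             params$r_At * Ad)
}

#' Hypoxia/adenosine-modulated effector cytotoxicity
#'
#' Per-step probability that an effector cell kills a selected adjacent tumor
#' cell: `mu - r_He / (U + c) - r_Ae * Ad`, clamped into \[0, 1\], with `U`
#' the oxygen at the effector's site. Hypoxia and adenosine both suppress
#' killing; under severe hypoxia the raw expression goes negative and the
#' probability floors at zero.
#'
#' @inheritParams treg_rate
#' @return Probability in \[0, 1\].
#' @export
cytotoxicity_rate <- function(U_local, Ad, params) {
  .check_rate_inputs(U_local, Ad)
  .clamp01(params$mu - params$r_He / (U_local + params$c) -
             params$r_Ae * Ad)
}

.check_rate_inputs <- function(U_local, Ad) {
  if (any(U_local < 0)) stop("'U_local' must be non-negative")
  if (any(Ad < 0)) stop("'Ad' must be non-negative")
  invisible(NULL)
}
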