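#' Monod-type specific growth rate
#'
#' The specific growth rate of the cell population is the sum of three
#' saturating (Monod) terms in the intracellular concentrations of ATP,
#' glucose and glutamine:
#' \deqn{\lambda = \alpha_{atp}\frac{ATP}{k_{ap}+ATP}
#'   + \alpha_{glc}\frac{Glc_{in}}{k_{gc}+Glc_{in}}
#'   + \alpha_{gln}\frac{Gln_{in}}{k_{gn}+Gln_{in}}}
#' so that \eqn{0 \le \lambda \le \alpha_{atp}+\alpha_{glc}+\alpha_{gln}},
#' monotone in each nutrient.
#'
#' @param atp,glc_in,gln_in intracellular concentrations (mM), non-negative.
#' @param p growth parameters: named vector/list with `alpha_atp`,
#'   `alpha_glc`, `alpha_gln` (1/min) and `k_ap`, `k_gc`, `k_gn` (mM).
#' @return specific growth rate (1/min).
#' @export
specific_growth_rate <- function(atp, glc_in, gln_in, p) {
  if (any(c(atp, glc_in, gln_in) < 0))
    stop("negative concentration passed to specific_growth_rate")
  p <- as.list(p)
  p$alpha_atp * atp / (p$k_ap + atp) +
    p$alpha_glc * glc_in / (p$k_gc + glc_in) +
    p$alpha_gln * gln_in / (p$k_gn + gln_in)
}

#' Cell-number derivative (logistic growth with death)
#'
#' \deqn{\frac{dC_N}{dt} = \lambda\left(1 - \frac{C_N}{K_{CC}}\right)C_N
#'   - \alpha_d C_N}
#' Relative cell number is normalised to the inoculum (C_N(0) = 1);
#' `K_CC` is the carrying capacity in the same relative units.
#'
#' @param c_n relative cell number (>= 0).
#' @param lambda specific growth rate (1/min), e.g. from
#'   [specific_growth_rate()].
#' @param p growth parameters with `alpha_d` (1/min) and `K_CC`.
#' @return dC_N/dt (1/min).
#' @export
cell_number_derivative <- function(c_n, lambda, p) {
  if (any(c_n < 0)) stop("cell number must be non-negative")
  p <- as.list(p)
  lambda * (1 - c_n / p$K_CC) * c_n - p$alpha_d * c_n
}

#' Validate a growth-parameter set
#'
#' @param p named vector/list with the seven growth parameters
#'   (`alpha_atp`, `alpha_glc`, `alpha_gln`, `alpha_d`, `k_ap`, `k_gc`,
#'   `k_gn`) plus the carrying capacity `K_CC`.
#' @return the parameters as a named numeric vector (invisibly errors on
#'   invalid input).
#' @export
growth_parameters <- function(p) {
  need <- c("alpha_atp", "alpha_glc", "alpha_gln", "alpha_d",
            "k_ap", "k_gc", "k_gn", "K_CC")
  p <- unlist(p)[need]
  if (any(is.na(p))) stop("missing growth parameter(s): ",
                          paste(need[is.na(p)], collapse = ", "))
  if (any(p[1:7] < 0)) stop("growth parameters must be non-negative")
  if (p[["K_CC"]] <= 0) stop("carrying capacity K_CC must be positive")
  p
}

#' Names of the seven fitted growth parameters
#'
#' The carrying capacity is a configuration constant held fixed during
#' growth fitting; the seven free parameters are the three growth-rate
#' coefficients, the death rate, and the three half-saturation constants.
#' @return character vector of length 7.
#' @export
growth_free_names <- function() {
  c("alpha_atp", "alpha_glc", "alpha_gln", "alpha_d", "k_ap", "k_gc", "k_gn")
}
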