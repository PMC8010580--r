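# Hypoxia reduction factor (HRF/OER) model: photon parameterization in
# oxygen tension, radiation-quality extension in (Zeff/beta)^2, application
# to linear-quadratic parameters and hypoxic effective dose.

#' Hypoxia model parameters
#'
#' Defaults reproduce the phenomenological fit to in vitro survival data:
#' m = 2.94 (anoxic photon limit), K = 0.129% O2 (half-effect oxygen
#' tension), a = 2.988e6 and gamma = 2.169 controlling the fall-off of the
#' HRF with radiation quality. `reference_dose` and `survival` are only used
#' by the LQ-based HRF utility.
#'
#' @param m,K photon HRF parameters (unitless, % O2).
#' @param a,gamma radiation-quality parameters.
#' @param reference_dose Gy (default 2).
#' @param survival survival level for [hrf_from_lq()] (default 0.1).
#' @return a `hypoxia_params` list.
#' @export
hypoxia_params <- function(m = 2.94, K = 0.129, a = 2.988e6, gamma = 2.169,
                           reference_dose = 2, survival = 0.1) {
  stopifnot(m > 1, K > 0, a > 0, gamma > 0,
            reference_dose > 0, survival > 0, survival < 1)
  structure(list(m = m, K = K, a = a, gamma = gamma,
                 reference_dose = reference_dose, survival = survival),
            class = "hypoxia_params")
}

#' Photon hypoxia reduction factor
#'
#' HRF_ph(pO2) = (m K + pO2) / (K + pO2): m in the anoxic limit, 1 at full
#' oxygenation, decreasing in pO2.
#'
#' @param pO2 oxygen tension, % O2 (vectorized, >= 0).
#' @param params [hypoxia_params()].
#' @return HRF in (1, m].
#' @export
hrf_photon <- function(pO2, params = hypoxia_params()) {
  if (any(pO2 < 0)) stop("pO2 must be non-negative")
  (params$m * params$K + pO2) / (params$K + pO2)
}

#' Ion hypoxia reduction factor
#'
#' HRF_ion(RQE, pO2) = (a HRF_ph(pO2) + RQE^gamma) / (a + RQE^gamma): equals
#' the photon HRF as the radiation quality RQE = (Zeff/beta)^2 tends to 0
#' and tends to 1 (no hypoxia protection) at high RQE.
#'
#' @param RQE radiation quality (Zeff/beta)^2, > 0 (vectorized).
#' @param pO2 oxygen tension, % O2.
#' @param params [hypoxia_params()].
#' @return HRF in `[1, hrf_photon(pO2)]`.
#' @export
hrf_ion <- function(RQE, pO2, params = hypoxia_params()) {
  if (any(RQE <= 0)) stop("RQE must be positive")
  rg <- RQE^params$gamma
  (params$a * hrf_photon(pO2, params) + rg) / (params$a + rg)
}

#' HRF from hypoxic and normoxic LQ parameters
#'
#' The iso-effect dose ratio at survival level S within the LQ framework:
#' HRF = (sqrt(a_h^2 - 4 b_h ln S) - a_h) / (sqrt(a_n^2 - 4 b_n ln S) - a_n)
#' * (b_n / b_h). For dose-modifying inputs (a_n/H, b_n/H^2) it returns H at
#' every survival level.
#'
#' @param alpha_h,beta_h hypoxic LQ parameters (> 0).
#' @param alpha_n,beta_n normoxic LQ parameters (> 0).
#' @param S survival level in (0, 1).
#' @return the hypoxia reduction factor.
#' @export
hrf_from_lq <- function(alpha_h, beta_h, alpha_n, beta_n, S) {
  stopifnot(alpha_h > 0, beta_h > 0, alpha_n > 0, beta_n > 0)
  if (S <= 0 || S >= 1) stop("survival level must lie in (0, 1)")
  ln_s <- log(S)
  num <- sqrt(alpha_h^2 - 4 * beta_h * ln_s) - alpha_h
  den <- sqrt(alpha_n^2 - 4 * beta_n * ln_s) - alpha_n
  (num / den) * (beta_n / beta_h)
}

#' Apply the hypoxia reduction factor to ion LQ parameters
#'
#' alpha_h = alpha_ion / HRF and beta_h = beta_ion / HRF^2 with
#' HRF = [hrf_ion()] at the component's own radiation quality.
#'
#' @param alpha_ion,beta_ion normoxic ion LQ parameters.
#' @param RQE component radiation quality (Zeff/beta)^2.
#' @param pO2 oxygen tension, % O2.
#' @param params [hypoxia_params()].
#' @return list with `alpha_h`, `beta_h` and the `hrf` applied.
#' @export
apply_hrf <- function(alpha_ion, beta_ion, RQE, pO2, params = hypoxia_params()) {
  h <- hrf_ion(RQE, pO2, params)
  list(alpha_h = alpha_ion / h, beta_h = beta_ion / h^2, hrf = h)
}

#' Hypoxic effective dose of a mixed-field voxel
#'
#' Each field component is normalized by its own HRF (from its radiation
#' quality and the voxel oxygen tension), the hypoxic components are mixed
#' dose-weighted, and the resulting log-survival is converted back to the
#' photon-equivalent dose.
#'
#' @param dose,alpha,beta,RQE per-component physical doses (Gy), normoxic LQ
#'   parameters and radiation qualities.
#' @param pO2 voxel oxygen tension, % O2 (required).
#' @param photon [photon_lq()].
#' @param params [hypoxia_params()].
#' @return hypoxic effective dose D_OER,RBE per fraction, GyRBE.
#' @export
d_oer_rbe <- function(dose, alpha, beta, RQE, pO2, photon = photon_lq(),
                      params = hypoxia_params()) {
  if (missing(pO2) || is.null(pO2) || is.na(pO2)) stop("pO2 is required")
  if (sum(dose) == 0) return(0)
  h <- apply_hrf(alpha, beta, RQE, pO2, params)
  effective_dose(dose, h$alpha_h, h$beta_h, photon)
}

#' Hypoxia-induced effective dose ratio
#'
#' Delta_OER,RBE = D_RBE / D_OER,RBE, the fold-reduction of effective dose
#' caused by hypoxia; 1 under normoxia, bounded above by the photon HRF of
#' the voxel's oxygen tension.
#'
#' @param D_RBE normoxic effective dose, GyRBE.
#' @param D_OER_RBE hypoxic effective dose, GyRBE (> 0).
#' @return the ratio (NA where the denominator vanishes).
#' @export
delta_oer <- function(D_RBE, D_OER_RBE) {
  out <- D_RBE / D_OER_RBE
  out[D_OER_RBE <= 0] <- NA_real_
  out
}
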