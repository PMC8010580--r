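# Plan evaluation: dose / effective-dose / LET_D grids, cumulative volume
# histograms and Dx statistics, hypoxia forward calculation, tumor control
# probability.

#' TCP model parameters
#'
#' Poisson tumor control probability over target voxels:
#' TCP = prod_i exp(-S_i^n * v_i * p) with per-fraction survival S_i,
#' n identical fractions, voxel volume v_i (mm^3) and clonogen density p
#' (cells/mm^3).
#'
#' @param n_fractions number of fractions (default 10 of the 3 GyRBE plan).
#' @param cell_density clonogen density, cells per mm^3 (default 1e4).
#' @return a `tcp_params` list.
#' @export
tcp_params <- function(n_fractions = 10, cell_density = 1e4) {
  stopifnot(n_fractions >= 1, cell_density > 0)
  structure(list(n_fractions = n_fractions, cell_density = cell_density),
            class = "tcp_params")
}

#' Tumor control probability
#'
#' Computed in log space: log TCP = -p * sum(S_i^n * v_i). An empty voxel
#' set gives TCP = 1 (empty product).
#'
#' @param survival per-fraction survival per voxel, in `[0, 1]`.
#' @param params [tcp_params()].
#' @param voxel_volume voxel volume(s), mm^3 (scalar or per voxel).
#' @return probability in `[0, 1]`.
#' @export
tcp <- function(survival, params = tcp_params(), voxel_volume = 1) {
  if (length(survival) == 0) return(1)
  stopifnot(all(survival >= 0 & survival <= 1))
  exp(-params$cell_density *
        sum(survival^params$n_fractions * voxel_volume))
}

#' Cumulative volume histogram
#'
#' V(x) = fraction of the masked volume with value >= x; monotone
#' non-increasing from 1 to 0.
#'
#' @param values numeric vector/matrix (dose in GyRBE or LET in keV/um).
#' @param mask logical, same shape (default all).
#' @param bin_width histogram resolution.
#' @return a `vh_curve` list with `edges` and `volume`.
#' @export
cumulative_histogram <- function(values, mask = NULL, bin_width = 0.01) {
  v <- if (is.null(mask)) as.vector(values) else values[mask]
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty mask")
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  sv <- sort(v)
  # fraction of voxels with value >= edge, via binary search on sorted values
  vol <- 1 - findInterval(edges - bin_width * 1e-6, sv) / length(sv)
  structure(list(edges = edges, volume = vol), class = "vh_curve")
}

#' Dose (or LET) to the hottest x% of a structure
#'
#' Inverse of the cumulative volume histogram: the value received by at
#' least x% of the volume.
#'
#' @param curve a [cumulative_histogram()] curve.
#' @param x percent volume, in (0, 100).
#' @return value at the x% volume level.
#' @export
metric_dx <- function(curve, x) {
  stopifnot(x > 0, x < 100)
  frac <- x / 100
  idx <- which(curve$volume >= frac)
  if (!length(idx)) return(curve$edges[1])
  i <- max(idx)
  if (i == length(curve$edges)) return(curve$edges[i])
  v1 <- curve$volume[i]; v2 <- curve$volume[i + 1]
  if (v1 == v2) return(curve$edges[i])
  curve$edges[i] + (v1 - frac) / (v1 - v2) *
    (curve$edges[i + 1] - curve$edges[i])
}

# mixed-field grids of a plan: physical dose, mixed alpha, effective dose,
# dose-averaged LET (all as in-plane x slice matrices)
plan_grids <- function(plan, rows = NULL) {
  inf <- plan$influence; w <- plan$weights; ph <- plan$config$photon
  D <- inf$forward(w, "dose", rows)
  Da <- inf$forward(w, "dose_alpha", rows)
  Dl <- inf$forward(w, "dose_letd", rows)
  alpha_bar <- ifelse(D > 0, Da / D, ph$alpha_x)
  eff <- photon_equivalent_dose(alpha_bar * D + ph$beta_x * D^2, ph)
  letd <- ifelse(D > 0, Dl / D, NA_real_)
  list(dose = D, alpha_bar = alpha_bar, effective = eff, letd = letd)
}

#' Per-voxel dose-averaged LET grid of a plan
#'
#' LET_D = sum of (dose x track LET) over every spot and field component
#' divided by total dose; zero-dose voxels are `NA` (undefined).
#'
#' @param plan a `sharc_plan`.
#' @param rows optional in-plane row subset.
#' @return matrix (in-plane points x slices), keV/um.
#' @export
letd_grid <- function(plan, rows = NULL) {
  plan_grids(plan, rows)$letd
}

# hypoxia forward calculation: hypoxic mixed LQ grids and D_OER,RBE.
# Accumulates per-pO2-level mixes (each field component normalized by its
# own HRF) and assembles per-voxel values from the scenario pO2 map.
hypoxic_grids <- function(plan, rows = NULL) {
  scen <- plan$scenario
  if (is.null(scen$po2)) stop("scenario has no pO2 map; run build_po2_map()")
  inf <- plan$influence; w <- plan$weights; ph <- plan$config$photon
  if (is.null(rows)) rows <- seq_len(nrow(scen$xy))
  po2 <- scen$po2[rows, , drop = FALSE]
  levels_all <- sort(unique(as.vector(po2)))

  g <- plan_grids(plan, rows)
  D <- g$dose
  Dah <- Dsh <- matrix(0, nrow(D), ncol(D))
  for (l in seq_along(levels_all)) {
    sel <- po2 == levels_all[l]
    if (!any(sel)) next
    al <- inf$forward(w, "dose_alpha_h", rows, level = levels_all[l])
    sb <- inf$forward(w, "dose_sqbeta_h", rows, level = levels_all[l])
    Dah[sel] <- al[sel]
    Dsh[sel] <- sb[sel]
  }
  alpha_h <- ifelse(D > 0, Dah / D, ph$alpha_x)
  sqbeta_h <- ifelse(D > 0, Dsh / D, sqrt(ph$beta_x))
  nls_h <- alpha_h * D + sqbeta_h^2 * D^2
  d_oer <- photon_equivalent_dose(nls_h, ph)
  list(dose = D, effective = g$effective, alpha_bar = g$alpha_bar,
       alpha_h = alpha_h, beta_h = sqbeta_h^2,
       d_oer_rbe = d_oer, delta = delta_oer(g$effective, d_oer))
}

#' Total particles per beam angle
#'
#' @param plan a `sharc_plan`.
#' @return data.frame with `angle_deg`, `particles` and `relative`
#'   (normalized to the maximum).
#' @export
angular_fluence_map <- function(plan) {
  agg <- stats::aggregate(list(particles = plan$weights),
                          by = list(angle_deg = plan$spots$angle_deg), FUN = sum)
  agg$relative <- agg$particles / max(agg$particles)
  agg
}

#' Hypoxia effective-dose-ratio volume histogram
#'
#' Cumulative histogram of Delta_OER,RBE = D_RBE / D_OER,RBE over a mask;
#' zero-dose voxels are excluded (their count is reported).
#'
#' @param d_rbe,d_oer matching effective-dose grids, GyRBE.
#' @param mask logical mask.
#' @param bin_width histogram resolution (default 0.001).
#' @return a `vh_curve` with attribute `n_excluded`.
#' @export
delta_oer_vh <- function(d_rbe, d_oer, mask, bin_width = 0.001) {
  ratio <- delta_oer(d_rbe, d_oer)
  excl <- mask & (is.na(ratio) | d_oer <= 0)
  curve <- cumulative_histogram(ratio, mask & !excl, bin_width)
  attr(curve, "n_excluded") <- sum(excl)
  curve
}

# TCP of a plan at a dose-scale factor s (per-fraction doses scaled,
# fraction number fixed); survival from the supplied mixed LQ grids
tcp_at_scale <- function(s, D, alpha, beta, mask, params, voxel_volume) {
  surv <- exp(-(alpha[mask] * s * D[mask] + beta[mask] * (s * D[mask])^2))
  tcp(surv, params, voxel_volume)
}

#' Total effective dose at 50% tumor control
#'
#' Scales the per-fraction dose by a factor s at fixed fraction number,
#' computes TCP per the Poisson voxel model and finds the scale with
#' TCP = 0.5 by root bracketing; the result is reported as the total
#' (n-fraction) mean target effective dose on the normoxic RBE-weighted
#' scale, so hypoxic and normoxic values are comparable.
#'
#' @param eval_grids output of the internal grid evaluation: needs `dose`,
#'   `alpha_bar` and (for hypoxic TCP) `alpha_h`, `beta_h`.
#' @param scenario the plan scenario (target mask, voxel size).
#' @param params [tcp_params()].
#' @param hypoxic use hypoxia-adjusted survival (default FALSE).
#' @param photon [photon_lq()].
#' @return TCP50 in GyRBE (total effective dose).
#' @export
tcp50 <- function(eval_grids, scenario, params = tcp_params(),
                  hypoxic = FALSE, photon = photon_lq()) {
  mask <- scenario$target
  vol <- scenario$voxel_size^3
  D <- eval_grids$dose
  if (hypoxic) {
    alpha <- eval_grids$alpha_h; beta <- eval_grids$beta_h
  } else {
    alpha <- eval_grids$alpha_bar
    beta <- matrix(photon$beta_x, nrow(D), ncol(D))
  }
  f <- function(s) tcp_at_scale(s, D, alpha, beta, mask, params, vol) - 0.5
  lo <- 0.2; hi <- 5
  it <- 0
  while (f(lo) > 0 && it < 20) { lo <- lo / 1.5; it <- it + 1 }
  it <- 0
  while (f(hi) < 0 && it < 20) { hi <- hi * 1.5; it <- it + 1 }
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf("TCP does not cross 0.5 in the scale bracket [%.3g, %.3g]", lo, hi))
  s50 <- stats::uniroot(f, c(lo, hi), tol = 1e-5)$root
  # total effective dose on the normoxic RBE-weighted axis at that scale
  ab <- eval_grids$alpha_bar[mask]
  drbe <- photon_equivalent_dose(ab * s50 * D[mask] +
                                   photon$beta_x * (s50 * D[mask])^2, photon)
  params$n_fractions * mean(drbe)
}

#' Evaluate a plan
#'
#' Computes the full metrics report: effective dose and LET_D grids, target
#' and OAR DVH statistics, core LET_D percentiles, LET_D localization, the
#' angular fluence map, and (with `hypoxia = TRUE` on a pO2-mapped scenario)
#' the hypoxic effective dose, Delta_OER statistics and TCP/TCP50 values.
#'
#' LET_D localization metrics consider voxels receiving at least 10% of the
#' prescription effective dose, so that near-zero-dose voxels do not define
#' maxima.
#'
#' @param plan a `sharc_plan`.
#' @param hypoxia also run the hypoxia forward calculation.
#' @param tcp_pars [tcp_params()] for TCP/TCP50 (hypoxia mode).
#' @return a `metrics_report` list with `grids` and `metrics`.
#' @export
evaluate_plan <- function(plan, hypoxia = FALSE, tcp_pars = tcp_params()) {
  scen <- plan$scenario
  cfg <- plan$config
  g <- if (hypoxia) hypoxic_grids(plan) else plan_grids(plan)
  eff <- g$effective
  letd <- if (!is.null(g$letd)) g$letd else letd_grid(plan)
  g$letd <- letd

  rx <- cfg$prescription
  sig <- !is.na(letd) & eff > 0.1 * rx
  letd_sig <- ifelse(sig, letd, -Inf)
  imax <- arrayInd(which.max(letd_sig), dim(letd_sig))
  loc <- c(scen$xy[imax[1], ], z = scen$zc[imax[2]])

  m <- list(
    target_mean_eff = mean(eff[scen$target]),
    target_d2 = metric_dx(cumulative_histogram(eff, scen$target), 2),
    target_d95 = metric_dx(cumulative_histogram(eff, scen$target), 95),
    core_letd = stats::quantile(letd[scen$core & sig], c(0.5, 1),
                                na.rm = TRUE, names = FALSE),
    letd_max = max(letd_sig),
    letd_max_location = loc,
    letd_max_in_core = scen$core[imax[1], imax[2]],
    nt_letd_max = if (any(scen$normal & sig))
      max(letd_sig[scen$normal]) else NA_real_,
    n_active_spots = sum(plan$weights > 0)
  )
  if (any(scen$oar)) {
    m$oar_max_eff <- max(eff[scen$oar])
    m$oar_d2 <- metric_dx(cumulative_histogram(eff, scen$oar), 2)
  }
  if (hypoxia) {
    m$core_delta_median <- stats::median(g$delta[scen$core & g$dose > 0],
                                         na.rm = TRUE)
    m$tcp50_normoxic <- tcp50(g, scen, tcp_pars, hypoxic = FALSE, cfg$photon)
    m$tcp50_hypoxic <- tcp50(g, scen, tcp_pars, hypoxic = TRUE, cfg$photon)
    m$tcp50_shift <- m$tcp50_hypoxic - m$tcp50_normoxic
  }
  structure(list(grids = g, metrics = m,
                 angular_fluence = angular_fluence_map(plan)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  cat("<metrics_report>\n")
  cat(sprintf("  target mean D_RBE %.3f GyRBE (D2 %.3f, D95 %.3f)\n",
              m$target_mean_eff, m$target_d2, m$target_d95))
  cat(sprintf("  core LET_D,50 %.1f keV/um, LET_D,max %.1f (in core: %s)\n",
              m$core_letd[1], m$letd_max, m$letd_max_in_core))
  if (!is.null(m$oar_max_eff))
    cat(sprintf("  OAR max %.3f GyRBE, D2%% %.3f\n", m$oar_max_eff, m$oar_d2))
  if (!is.null(m$tcp50_shift))
    cat(sprintf("  TCP50 shift %.2f GyRBE (hypoxic - normoxic)\n", m$tcp50_shift))
  invisible(x)
}
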