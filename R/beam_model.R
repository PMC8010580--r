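# Depth-resolved beam physics tables: integrated depth dose with range
# straggling, nuclear attenuation and fragment build-up, component-resolved
# LET / radiation quality, and lateral spread.

# straggling: sigma_R = k R^0.935 / sqrt(A), k set to give 1.2 mm at
# R = 100 mm for protons; carbon adds a 1.5 mm ripple-filter spread.
.STRAGGLE_K <- 1.2 / 100^0.935
.RIPPLE_SIGMA_C <- 1.5

# nuclear interaction lengths in water (mm) and fragment model per ion:
# one effective light-fragment group for helium, a helium-like plus
# hydrogen-like pair for carbon, and a short-ranged secondary-proton group
# (truncated at the peak) recovering part of the attenuated energy for
# protons. `recover` is the fraction of removed primary energy re-deposited
# locally by charged secondaries; `tau` the distal tail decay length (mm).
beam_generation_defaults <- function(ion) {
  switch(as_ion(ion)$label,
    proton = list(lambda = 850, recover = 0.60,
      groups = data.frame(label = "h_sec", Z = 1, A = 1, E = 60,
                          share = 1, tau = 1.5)),
    helium = list(lambda = 450, recover = 0.65,
      groups = data.frame(label = "light_frag", Z = 2, A = 4, E = 150,
                          share = 1, tau = 25)),
    carbon = list(lambda = 255, recover = 0.75,
      groups = data.frame(label = c("he_frag", "h_frag"), Z = c(2, 1),
                          A = c(4, 1), E = c(200, 150),
                          share = c(0.6, 0.4), tau = c(30, 60))))
}

#' Lateral pencil-beam sigma at depth
#'
#' Quadrature sum of the initial spot sigma at isocenter and a multiple-
#' Coulomb-scattering term growing as c_ion * z * (z/R)^0.8, with scattering
#' coefficients 0.025 / 0.013 / 0.008 for p / He / C. Non-decreasing with
#' depth; protons spread more than carbon at equal fractional depth.
#'
#' @param ion [ion_species()] or label.
#' @param E beam energy, MeV/u.
#' @param depth depth in water, mm (vectorized, >= 0).
#' @return sigma in mm.
#' @export
lateral_sigma <- function(ion, E, depth) {
  ion <- as_ion(ion)
  stopifnot(all(depth >= 0))
  r0 <- csda_range(ion, E)
  cc <- switch(ion$label, proton = 0.025, helium = 0.013, carbon = 0.008)
  mcs <- cc * depth * (depth / r0)^0.8
  sqrt(ion$initial_spot_sigma^2 + mcs^2)
}

#' Build a depth-resolved physics table for one beam
#'
#' Central-axis integrated depth dose per primary particle composed of
#' (i) the Bethe stopping-power term broadened by Gaussian range straggling
#' (plus ripple-filter spread for carbon), (ii) exponential nuclear
#' attenuation of the primary fluence, and (iii) fragment groups building
#' up linearly to the peak and decaying exponentially beyond it. Each depth
#' carries the component decomposition (dose fraction, track LET, beta,
#' radiation quality (Zeff/beta)^2).
#'
#' @param ion [ion_species()] or label.
#' @param E beam energy, MeV/u, inside the calibrated window.
#' @param dz depth-grid step, mm (default 0.5).
#' @param opts generation parameters; `beam_generation_defaults(ion)` unless
#'   overridden.
#' @return a `depth_profile` object: depth grid (mm), `dose_per_primary`
#'   (Gy mm^2), per-component matrices, `sigma` (mm), `R80` (mm).
#' @export
build_depth_profile <- function(ion, E, dz = 0.5, opts = NULL) {
  ion <- as_ion(ion)
  if (is.null(opts)) opts <- beam_generation_defaults(ion)
  r0 <- csda_range(ion, E)
  sig_str <- .STRAGGLE_K * r0^0.935 / sqrt(ion$A)
  if (!is.null(opts$straggle_sigma)) sig_str <- opts$straggle_sigma
  if (sig_str <= 0) stop("straggling sigma must be positive")
  sig_sm <- if (ion$label == "carbon")
    sqrt(sig_str^2 + .RIPPLE_SIGMA_C^2) else sig_str

  tail_ext <- switch(ion$label, proton = 20, helium = 80, carbon = 110)
  z <- seq(0, r0 + tail_ext, by = dz)
  # pristine (unsmeared) grid, refined over the last 3 mm where the
  # stopping power varies by orders of magnitude within a voxel
  zp_coarse <- seq(0, max(r0 - 3, 0), by = dz)
  zp_fine <- r0 - rev(exp(seq(log(5e-3), log(3), length.out = 80)))
  zp <- sort(unique(c(zp_coarse, zp_fine[zp_fine > max(zp_coarse)])))
  dzp <- diff(c(zp, r0))                            # segment widths to r0
  e_res <- energy_from_range(ion, pmax(r0 - zp, 0))
  s_pr <- stopping_power(ion, e_res)                # MeV/mm
  let_pr <- s_pr                                    # keV/um numerically
  beta_pr <- beta_from_energy(ion, e_res)
  phi <- exp(-zp / opts$lambda)

  # Gaussian straggle smear, columns normalized to conserve deposited energy
  G <- stats::dnorm(outer(z, zp, "-"), sd = sig_sm)
  G <- sweep(G, 2, pmax(colSums(G) * dz, 1e-300), "/")
  w_pr <- s_pr * phi * dzp                          # MeV per column
  d_prim <- as.vector(G %*% w_pr)                   # MeV/mm at each z
  let_num <- as.vector(G %*% (w_pr * let_pr))
  beta_num <- as.vector(G %*% (w_pr * beta_pr))
  pos <- d_prim > max(d_prim) * 1e-12
  let_prim <- ifelse(pos, let_num / pmax(d_prim, 1e-300), let_pr[length(let_pr)])
  beta_prim <- ifelse(pos, beta_num / pmax(d_prim, 1e-300), beta_pr[length(beta_pr)])

  # energy removed from the primary by nuclear interactions (MeV)
  e_removed <- max(E * ion$A - sum(w_pr), 0)
  groups <- opts$groups
  frag <- matrix(0, length(z), nrow(groups))
  for (g in seq_len(nrow(groups))) {
    shape <- ifelse(z <= r0, z / r0, exp(-(z - r0) / groups$tau[g]))
    shape <- shape / sum(shape * dz)
    frag[, g] <- opts$recover * groups$share[g] * e_removed * shape
  }

  total <- d_prim + rowSums(frag)
  # distal 80% fall-off of the (smeared) peak
  pk <- which.max(total)
  distal <- total[pk:length(z)]
  i80 <- which(distal < 0.8 * total[pk])[1]
  if (is.na(i80) || i80 < 2) stop("no distal 80% fall-off found")
  z1 <- z[pk + i80 - 2]; z2 <- z[pk + i80 - 1]
  f1 <- distal[i80 - 1]; f2 <- distal[i80]
  r80 <- z1 + (f1 - 0.8 * total[pk]) / (f1 - f2) * (z2 - z1)

  # component bookkeeping
  n_comp <- 1L + nrow(groups)
  f <- cbind(d_prim, frag) / ifelse(total > 0, total, 1)
  f[total <= 0, ] <- 0
  beta_g <- beta_from_energy("proton", groups$E)
  let_g <- stopping_power_za(groups$Z, groups$E)
  let_m <- cbind(let_prim, matrix(rep(let_g, each = length(z)), length(z)))
  beta_m <- cbind(beta_prim, matrix(rep(beta_g, each = length(z)), length(z)))
  zc <- c(ion$Z, groups$Z)
  rqe_m <- sapply(seq_len(n_comp), function(j) {
    (zeff_barkas(zc[j], pmax(beta_m[, j], 1e-6)) / pmax(beta_m[, j], 1e-6))^2
  })

  structure(list(
    ion = ion, energy = E, depth = z,
    dose_per_primary = total * .MEV_TO_GY_MM2,
    sigma = lateral_sigma(ion, E, z),
    R80 = r80, R0 = r0, straggle_sigma = sig_sm,
    component_labels = c(ion$label, groups$label),
    component_Z = zc, component_A = c(ion$A, groups$A),
    fraction = f, let = let_m, beta = beta_m, rqe = rqe_m,
    generation = opts), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s at %.2f MeV/u: R80 = %.2f mm, peak %.3g Gy mm^2\n",
              x$ion$label, x$energy, x$R80, max(x$dose_per_primary)))
  invisible(x)
}

# cached profile lookup (plans reuse tables heavily)
depth_profile_cached <- function(ion, E, dz = 0.5) {
  ion <- as_ion(ion)
  key <- sprintf("prof_%s_%.4f_%g", ion$label, E, dz)
  if (is.null(.hadronarc_cache[[key]]))
    .hadronarc_cache[[key]] <- build_depth_profile(ion, E, dz = dz)
  .hadronarc_cache[[key]]
}

#' Dose-averaged LET at a depth of a beam table
#'
#' LET_D = sum(d_j LET_j) / sum(d_j) over the field components at that
#' depth (linear interpolation between grid points).
#'
#' @param table a [build_depth_profile()] object.
#' @param depth depth in mm, inside the table grid.
#' @return dose-averaged LET in keV/um; `NA` where the total dose vanishes.
#' @export
depth_letd <- function(table, depth) {
  if (any(depth < min(table$depth)) || any(depth > max(table$depth)))
    stop("depth outside table grid")
  letd_g <- rowSums(table$fraction * table$let)
  tot <- table$dose_per_primary
  letd_g[tot <= 0] <- NA_real_
  stats::approx(table$depth, letd_g, xout = depth)$y
}

#' Beam energy with a given distal 80% fall-off depth
#'
#' Inverts the forward R80 computation of [build_depth_profile()] by root
#' finding; the returned energy reproduces the requested R80 to better than
#' 0.2 mm.
#'
#' @param ion [ion_species()] or label.
#' @param depth requested R80, mm.
#' @param dz depth-grid step passed to the profile builder.
#' @return energy in MeV/u.
#' @examples
#' \donttest{energy_for_r80("carbon", 100)}
#' @export
energy_for_r80 <- function(ion, depth, dz = 0.5) {
  ion <- as_ion(ion)
  m <- range_model(ion)
  if (depth < 2 || depth > 0.95 * m$max_range)
    stop(sprintf("requested R80 outside admissible window (2-%.0f mm)",
                 0.95 * m$max_range))
  e0 <- energy_from_range(ion, depth)      # CSDA-based starting bracket
  f <- function(E) build_depth_profile(ion, E, dz = dz)$R80 - depth
  lo <- e0 * 0.96; hi <- e0 * 1.04
  while (f(lo) > 0) lo <- lo * 0.96
  while (f(hi) < 0) hi <- hi * 1.04
  stats::uniroot(f, c(lo, hi), tol = 1e-4 * e0)$root
}

#' Build a beam library
#'
#' A map ion -> energy -> depth profile, with the guarantee that every
#' stored table reproduces its stored R80 through the profile builder.
#'
#' @param ions character vector of ion labels.
#' @param energies list of numeric energy vectors (MeV/u), one per ion.
#' @param dz grid step, mm.
#' @return a `beam_library` object.
#' @export
build_beam_library <- function(ions, energies, dz = 0.5) {
  stopifnot(length(ions) == length(energies))
  lib <- lapply(seq_along(ions), function(i) {
    tabs <- lapply(energies[[i]], function(e) build_depth_profile(ions[i], e, dz = dz))
    names(tabs) <- sprintf("%.4f", energies[[i]])
    tabs
  })
  names(lib) <- ions
  structure(list(tables = lib, dz = dz,
                 provenance = list(created = as.character(Sys.time()),
                                   straggle_k = .STRAGGLE_K)),
            class = "beam_library")
}

#' Write a beam library as plain-text CSV tables
#'
#' One CSV per (ion, energy) with depth, dose per primary, lateral sigma and
#' per-component columns, plus a JSON sidecar of generation parameters.
#'
#' @param lib [build_beam_library()] object.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_beam_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ion in names(lib$tables)) {
    for (en in names(lib$tables[[ion]])) {
      tb <- lib$tables[[ion]][[en]]
      df <- data.frame(depth_mm = tb$depth,
                       dose_per_primary = tb$dose_per_primary,
                       sigma_mm = tb$sigma)
      for (j in seq_along(tb$component_labels)) {
        lab <- tb$component_labels[j]
        df[[paste0("f_", lab)]] <- tb$fraction[, j]
        df[[paste0("let_", lab)]] <- tb$let[, j]
        df[[paste0("rqe_", lab)]] <- tb$rqe[, j]
      }
      p <- file.path(dir, sprintf("%s_%s.csv", ion, en))
      utils::write.csv(df, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  side <- file.path(dir, "generation.json")
  jsonlite::write_json(lib$provenance, side, auto_unbox = TRUE)
  invisible(c(paths, side))
}
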