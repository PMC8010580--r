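# Configuration, end-to-end orchestration, text-format output and
# deterministic fixture generation.

#' Run configuration
#'
#' A fully serializable description of one pipeline run; identical configs
#' reproduce identical outputs for a fixed seed.
#'
#' @param case_id scenario case, `"A"` or `"B"`.
#' @param ion ion label.
#' @param technique planning technique (see [plan_config()]).
#' @param voxel_size mm.
#' @param slab_half_height optional reduced axial evaluation domain, mm.
#' @param hypoxia_forward run the hypoxia forward calculation (requires a
#'   pO2 map, which is then attached automatically).
#' @param seed RNG seed.
#' @param outdir output directory (`NULL`: no artifacts written).
#' @param ... further arguments passed to [plan_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(case_id = "A", ion = "carbon", technique = "sharc",
                       voxel_size = 2, slab_half_height = NULL,
                       hypoxia_forward = FALSE, seed = 1, outdir = NULL, ...) {
  structure(list(case_id = case_id, ion = ion, technique = technique,
                 voxel_size = voxel_size, slab_half_height = slab_half_height,
                 hypoxia_forward = hypoxia_forward, seed = seed,
                 outdir = outdir, plan_args = list(...)), class = "run_config")
}

#' Serialize / parse a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   the parsed `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x$plan_args) == 0) x$plan_args <- list()
  if (is.null(x$slab_half_height)) x$slab_half_height <- NULL
  if (is.null(x$outdir)) x$outdir <- NULL
  structure(x, class = "run_config")
}

# minimal ASCII-encoded NRRD volume writer (text deliverable; axis order
# x, y, z with mm spacings, origin at the first voxel center). `grid` is an
# (in-plane points x slices) matrix which is re-embedded in the bounding box.
write_nrrd <- function(grid, scenario, path, fill = 0) {
  vs <- scenario$voxel_size
  xs <- sort(unique(scenario$xy[, 1])); ys <- sort(unique(scenario$xy[, 2]))
  arr <- array(fill, c(length(xs), length(ys), length(scenario$zc)))
  ix <- match(scenario$xy[, 1], xs); iy <- match(scenario$xy[, 2], ys)
  for (k in seq_along(scenario$zc))
    arr[cbind(ix, iy, k)] <- grid[, k]
  con <- file(path, "w")
  writeLines(c("NRRD0004",
               "type: double", "dimension: 3",
               sprintf("sizes: %d %d %d", length(xs), length(ys),
                       length(scenario$zc)),
               "encoding: ascii",
               sprintf("spacings: %g %g %g", vs, vs, vs),
               sprintf("axis mins: %g %g %g", xs[1], ys[1], scenario$zc[1]),
               ""), con)
  writeLines(paste(format(as.vector(arr), digits = 8, trim = TRUE),
                   collapse = " "), con)
  close(con)
  invisible(path)
}

#' Run the full pipeline for one configuration
#'
#' Beam library -> scenario -> spot placement -> optimization -> pruning ->
#' evaluation (optionally with the hypoxia forward calculation). When
#' `config$outdir` is set, writes effective dose / LET_D volumes (ASCII
#' NRRD), DVH and LET_DVH curves (CSV), the spot list (CSV), a JSON metrics
#' report and a manifest with file checksums.
#'
#' @param config a [run_config()].
#' @return a list with `plan`, `report` and `artifacts` (paths, possibly
#'   empty).
#' @export
run_pipeline <- function(config) {
  scen <- build_scenario(config$case_id, config$voxel_size,
                         slab_half_height = config$slab_half_height)
  if (config$hypoxia_forward) scen <- build_po2_map(scen)
  pc <- do.call(plan_config, c(list(ion = config$ion,
                                    technique = config$technique,
                                    seed = config$seed), config$plan_args))
  plan <- make_plan(scen, pc)
  report <- evaluate_plan(plan, hypoxia = config$hypoxia_forward)

  artifacts <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outdir, f)
    write_nrrd(report$grids$effective, scen, p("d_rbe.nrrd"))
    letd0 <- report$grids$letd; letd0[is.na(letd0)] <- 0
    write_nrrd(letd0, scen, p("let_d.nrrd"))
    dvh <- cumulative_histogram(report$grids$effective, scen$target)
    utils::write.csv(data.frame(dose_gyrbe = dvh$edges, volume = dvh$volume),
                     p("dvh_target.csv"), row.names = FALSE)
    lvh <- cumulative_histogram(report$grids$letd, scen$target &
                                  !is.na(report$grids$letd), bin_width = 0.5)
    utils::write.csv(data.frame(let_kev_um = lvh$edges, volume = lvh$volume),
                     p("letdvh_target.csv"), row.names = FALSE)
    utils::write.csv(plan$spots[plan$weights > 0,
                                c("angle_deg", "u_mm", "v_mm",
                                  "energy_MeV_u", "weight")],
                     p("spots.csv"), row.names = FALSE)
    if (config$hypoxia_forward) {
      write_nrrd(report$grids$d_oer_rbe, scen, p("d_oer_rbe.nrrd"))
      delta0 <- report$grids$delta; delta0[is.na(delta0)] <- 1
      write_nrrd(delta0, scen, p("delta_oer.nrrd"))
    }
    jsonlite::write_json(report$metrics, p("metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    artifacts <- list.files(config$outdir, full.names = TRUE)
    manifest <- data.frame(file = basename(artifacts),
                           md5 = vapply(artifacts, function(f)
                             unname(tools::md5sum(f)), character(1)))
    jsonlite::write_json(manifest, p("manifest.json"))
    artifacts <- c(artifacts, p("manifest.json"))
  }
  list(plan = plan, report = report, artifacts = artifacts)
}

#' Generate miniature deterministic test fixtures
#'
#' Small, seeded assets for tests: coarse beam tables, a 4 mm-voxel slab
#' scenario, a 5-spot toy plan specification and random mixed-field voxel
#' sets together with brute-force oracle answers (dose-averaged LET and
#' mixed LQ parameters computed by explicit component summation).
#'
#' @param seed RNG seed.
#' @return a list of fixtures.
#' @export
make_fixtures <- function(seed = 1) {
  set.seed(seed)
  scen <- build_scenario("A", voxel_size = 4, slab_half_height = 8)
  tabs <- list(proton = build_depth_profile("proton", 100, dz = 1),
               carbon = build_depth_profile("carbon", 200, dz = 1))
  toy_spots <- data.frame(angle_deg = c(0, 90, 180, 270, 0),
                          u_mm = c(0, 0, 4.8, -4.8, 9.6),
                          v_mm = c(0, 0, 0, 0, 0),
                          weight = c(1e6, 2e6, 5e5, 5e5, 1e6))
  n_sets <- 8
  mixed <- lapply(seq_len(n_sets), function(i) {
    k <- sample(2:10, 1)
    d <- stats::runif(k, 0.01, 2)
    let <- stats::runif(k, 0.5, 120)
    a <- stats::runif(k, 0.05, 0.9)
    b <- rep(0.025, k)
    list(dose = d, let = let, alpha = a, beta = b,
         oracle_letd = sum(d * let) / sum(d),
         oracle_alpha_bar = sum(d * a) / sum(d),
         oracle_beta_bar = (sum(d * sqrt(b)) / sum(d))^2)
  })
  list(seed = seed, scenario = scen, tables = tabs, toy_spots = toy_spots,
       mixed_fields = mixed)
}
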