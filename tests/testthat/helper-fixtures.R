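# Shared small fixtures. Plans for the acceptance suite are built lazily and
# cached for the session so several criteria can share one optimization.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# study-resolution scenarios on the central slab (2 mm voxels)
accept_scenario <- function(case_id) {
  fixture(paste0("scen_", case_id), function() {
    s <- build_scenario(case_id, voxel_size = 2, slab_half_height = 10)
    build_po2_map(s)
  })
}

accept_plan <- function(case_id, ion, technique) {
  fixture(sprintf("plan_%s_%s_%s", case_id, ion, technique), function() {
    cfg <- plan_config(ion, technique, n_outer = 3, n_inner = 20)
    make_plan(accept_scenario(case_id), cfg)
  })
}

accept_report <- function(case_id, ion, technique, hypoxia = FALSE) {
  fixture(sprintf("rep_%s_%s_%s_%d", case_id, ion, technique, hypoxia),
          function() {
            evaluate_plan(accept_plan(case_id, ion, technique),
                          hypoxia = hypoxia)
          })
}

# a tiny, fast scenario for unit tests of the planning machinery
tiny_scenario <- function() {
  fixture("tiny_scen", function() build_scenario("A", voxel_size = 4,
                                                 slab_half_height = 8))
}
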