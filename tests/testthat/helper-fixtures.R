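# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(build), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# coarse sulcated mesh + atlas (fast enough for solver tests)
coarse_sulcal <- function() {
  fixture("coarse_sulcal",
          build_sulcal_mesh(n_folds = 12, element_size = 0.004))
}

coarse_smooth <- function() {
  fixture("coarse_smooth",
          build_smooth_mesh(n_folds = 12, element_size = 0.004))
}

# unit reference quad, counter-clockwise
unit_quad <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
}

# deterministic zero-dispersion profile spec
delta_spec <- function(lin_vel = 3.9, lin_acc = 428, rot_vel = 25,
                       rot_acc = 3000, n = 1L) {
  profile_spec(1, n, c(lin_vel, 0), c(lin_acc, 0), c(rot_vel, 0),
               c(rot_acc, 0))
}

simulate_cohort_fixture <- function(n_per_profile, seed) {
  specs <- default_profile_specs(n_impacts = n_per_profile)
  events <- generate_cohort(specs, seed)
  built <- coarse_sulcal()
  mats <- default_materials()
  fields <- lapply(events, function(ev)
    simulate_impact(built$mesh, mats, ev$trace, duration = 0.045))
  summaries <- dplyr::bind_rows(purrr::map2(events, fields, function(ev, fld) {
    vox <- rasterize_impact(fld, built$mesh, built$atlas, voxel_size = 2)
    impact_summary(vox, built$atlas$region_table, event_id = ev$event_id)
  }))
  list(events = events, built = built, fields = fields,
       cohort = summarize_cohort(events, summaries))
}

# a small simulated cohort shared by roi / stats / acceptance tests:
# 15 impacts (5/7/3) on the coarse sulcated mesh, full pipeline summaries
smoke_cohort <- function() {
  fixture("smoke_cohort", simulate_cohort_fixture(c(5L, 7L, 3L), 424242))
}

# the larger desk-scale cohort for the profile-contrast and correlation
# acceptance checks: 49 impacts (16/23/10), same conditions
acceptance_cohort <- function() {
  fixture("acceptance_cohort", simulate_cohort_fixture(c(16L, 23L, 10L), 424242))
}
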