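# End-to-end orchestration: generate kinematics -> simulate -> rasterize ->
# summarize -> analyze, as a reproducible, configured, logged run. Per-event
# seeds are counter-derived from the master seed inside generate_cohort(),
# so cohort composition does not depend on processing order.

#' Build a run configuration
#'
#' A single declarative object holding every knob of a pipeline run; it is
#' YAML-serializable and every run writes its resolved copy next to its
#' outputs.
#'
#' @param n_per_profile Length-3 cohort sizes (default 49, 69, 30).
#' @param mesh List of [build_sulcal_mesh()] arguments plus `type`
#'   (`"sulcal"` or `"smooth"`).
#' @param materials List with `brain` and `csf` sublists of
#'   [material_model()] arguments (`density`, `shear_modulus`,
#'   `bulk_modulus`).
#' @param solver List: `duration` (s), `dt_safety`, `damping`, `hourglass`.
#' @param kinematics List: `amplitude_scale`, a multiplier applied to every
#'   generated acceleration pulse (0 gives quiescent loading; the statistics
#'   stage then flags the degenerate all-zero strain columns).
#' @param voxel_size Rasterization voxel edge, mm.
#' @param seed Master RNG seed.
#' @param outdir Output directory.
#' @param write_nifti Write per-event NIfTI volumes (disable for speed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_per_profile = c(49L, 69L, 30L),
                       mesh = list(), materials = list(), solver = list(),
                       kinematics = list(), voxel_size = 1, seed = 1L,
                       outdir = "sulcalstrain_run", write_nifti = TRUE) {
  mesh_def <- list(type = "sulcal", n_folds = 12L, sulcal_depth = 0.012,
                   csf_thickness = 0.002, outer_radius = 0.08,
                   element_size = 0.001, inner_radius = 0.012,
                   cortex_thickness = 0.006)
  mat_def <- list(brain = list(density = 1040, shear_modulus = 2500,
                               bulk_modulus = 5e7),
                  csf = list(density = 1000, shear_modulus = 50,
                             bulk_modulus = 5e7))
  sol_def <- list(duration = 0.045, dt_safety = 0.9, damping = 0,
                  hourglass = 0.05)
  kin_def <- list(amplitude_scale = 1)
  cfg <- list(n_per_profile = as.integer(n_per_profile),
              mesh = utils::modifyList(mesh_def, mesh),
              materials = utils::modifyList(mat_def, materials),
              solver = utils::modifyList(sol_def, solver),
              kinematics = utils::modifyList(kin_def, kinematics),
              voxel_size = voxel_size, seed = as.integer(seed),
              outdir = outdir, write_nifti = isTRUE(write_nifti))
  stopifnot(length(cfg$n_per_profile) == 3, all(cfg$n_per_profile >= 0),
            cfg$mesh$type %in% c("sulcal", "smooth"), cfg$voxel_size > 0,
            cfg$kinematics$amplitude_scale >= 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.cfg_mesh <- function(cfg) {
  m <- cfg$mesh
  if (m$type == "smooth")
    build_smooth_mesh(n_folds = m$n_folds, csf_thickness = m$csf_thickness,
                      outer_radius = m$outer_radius,
                      element_size = m$element_size,
                      inner_radius = m$inner_radius,
                      cortex_thickness = m$cortex_thickness)
  else
    build_sulcal_mesh(n_folds = m$n_folds, sulcal_depth = m$sulcal_depth,
                      csf_thickness = m$csf_thickness,
                      outer_radius = m$outer_radius,
                      element_size = m$element_size,
                      inner_radius = m$inner_radius,
                      cortex_thickness = m$cortex_thickness)
}

.cfg_materials <- function(cfg) {
  lapply(cfg$materials, function(m)
    material_model(m$density, m$shear_modulus, m$bulk_modulus,
                   prony = m$prony))
}

.stage <- function(name, event_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s'%s failed: %s", name,
                 if (is.null(event_id)) "" else paste0(" (event ", event_id, ")"),
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Generates the cohort, simulates every impact on the configured mesh,
#' rasterizes strain and strain-rate fields (optionally writing
#' `<event_id>_strain.nii.gz`, `<event_id>_strainrate.nii.gz` and
#' `atlas.nii.gz`), assembles `cohort.csv` and the per-profile summary, and
#' writes the statistics report. Stage failures propagate with the stage
#' name and event id.
#'
#' @param cfg A [run_config()].
#' @param verbose Print per-stage progress.
#' @return (Invisibly) a list with `cohort` (the `cohort_table`), `stats`
#'   (from [cohort_stats()]), `mesh`, `atlas` and `dir`.
#' @export
run_pipeline <- function(cfg, verbose = interactive()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(cfg$outdir, "config.yaml"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("generate: cohort of %s impacts", sum(cfg$n_per_profile))
  events <- .stage("generate", NULL, {
    specs <- default_profile_specs(n_impacts = cfg$n_per_profile)
    evs <- generate_cohort(specs, cfg$seed)
    sc <- cfg$kinematics$amplitude_scale
    if (sc != 1) {
      evs <- lapply(evs, function(ev) {
        tr <- kinematics_trace(
          ev$trace$t,
          sc * as.matrix(ev$trace[, c("ax", "ay", "az")]),
          sc * as.matrix(ev$trace[, c("alx", "aly", "alz")]))
        ev$trace <- tr
        ev$summary <- peak_resultant(tr)
        ev
      })
    }
    evs
  })
  manifest <- cohort_manifest(events)
  utils::write.csv(manifest, file.path(cfg$outdir, "manifest.csv"),
                   row.names = FALSE)

  say("mesh: %s", cfg$mesh$type)
  built <- .stage("mesh", NULL, .cfg_mesh(cfg))
  mesh <- built$mesh; atlas <- built$atlas
  mats <- .stage("materials", NULL, .cfg_materials(cfg))

  summaries <- vector("list", length(events))
  atlas_written <- FALSE
  for (k in seq_along(events)) {
    ev <- events[[k]]
    say("simulate: %s (%d/%d)", ev$event_id, k, length(events))
    field <- .stage("simulate", ev$event_id,
                    simulate_impact(mesh, mats, ev$trace,
                                    duration = cfg$solver$duration,
                                    dt_safety = cfg$solver$dt_safety,
                                    damping = cfg$solver$damping,
                                    hourglass = cfg$solver$hourglass))
    vox <- .stage("rasterize", ev$event_id,
                  rasterize_impact(field, mesh, atlas, cfg$voxel_size))
    if (cfg$write_nifti) {
      write_nifti(vox$strain,
                  file.path(cfg$outdir, paste0(ev$event_id, "_strain.nii.gz")))
      write_nifti(vox$strain_rate,
                  file.path(cfg$outdir, paste0(ev$event_id, "_strainrate.nii.gz")))
      if (!atlas_written) {
        write_nifti(vox$atlas, file.path(cfg$outdir, "atlas.nii.gz"))
        atlas_written <- TRUE
      }
    }
    summaries[[k]] <- .stage("summarize", ev$event_id,
                             impact_summary(vox, atlas$region_table,
                                            event_id = ev$event_id))
  }
  summaries <- dplyr::bind_rows(summaries)
  cohort <- .stage("summarize", NULL, summarize_cohort(manifest, summaries))
  utils::write.csv(dplyr::select(cohort, -dplyr::any_of("roi")),
                   file.path(cfg$outdir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(profile_table(cohort, tidy = TRUE),
                   file.path(cfg$outdir, "profile_summary.csv"),
                   row.names = FALSE)

  say("analyze")
  stats <- .stage("analyze", NULL, cohort_stats(cohort))
  writeLines(report_markdown(stats, cohort),
             file.path(cfg$outdir, "report.md"))
  if (!isTRUE(stats$degenerate)) {
    utils::write.csv(stats$correlations,
                     file.path(cfg$outdir, "correlations.csv"),
                     row.names = FALSE)
  }
  invisible(list(cohort = cohort, stats = stats, mesh = mesh, atlas = atlas,
                 dir = cfg$outdir))
}

#' Run the statistical battery on a cohort table
#'
#' Applies the full set of cohort comparisons; degenerate inputs (zero
#' variance in the strain columns, e.g. from zero-amplitude pulses) are
#' flagged in the result instead of raising.
#'
#' @param cohort A `cohort_table`.
#' @param alpha Normality-gate level passed through to the tests.
#' @return Object of class `cohort_stats`: paired comparisons, one-way
#'   ANOVAs, repeated-measures ANOVAs, correlations and regressions, plus
#'   `notes` recording any component skipped as degenerate.
#' @export
cohort_stats <- function(cohort, alpha = 0.05) {
  notes <- character()
  strain_cols <- c("p90_strain", "p90_strain_rate", "sulcal_mean_strain",
                   "gyral_mean_strain", "sulcal_mean_strain_rate",
                   "gyral_mean_strain_rate")
  degenerate_cols <- strain_cols[vapply(strain_cols, function(cl)
    nrow(cohort) == 0 || stats::sd(cohort[[cl]]) == 0, logical(1))]
  if (length(degenerate_cols) == length(strain_cols)) {
    return(structure(list(
      degenerate = TRUE,
      notes = paste("all strain columns degenerate (zero variance):",
                    "no statistics computed")), class = "cohort_stats"))
  }
  if (length(degenerate_cols))
    notes <- c(notes, paste("degenerate (zero-variance) columns:",
                            paste(degenerate_cols, collapse = ", ")))
  safely <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, sprintf("%s skipped: %s", label, conditionMessage(e)))
      NULL
    })
  }
  long <- function(value_s, value_g) {
    tibble::tibble(
      subject = rep(cohort$event_id, 2),
      profile = rep(cohort$profile, 2),
      region = rep(c("sulcal", "gyral"), each = nrow(cohort)),
      value = c(cohort[[value_s]], cohort[[value_g]]))
  }
  anovas <- lapply(stats::setNames(nm = c("p90_strain", "p90_strain_rate",
                                          "peak_lin_acc", "peak_lin_vel",
                                          "peak_rot_acc", "peak_rot_vel")),
                   function(cl) safely(paste("one-way ANOVA", cl),
                                       one_way_anova(cohort[[cl]],
                                                     cohort$profile)))
  out <- list(
    degenerate = FALSE,
    paired_strain = safely("paired strain",
                           paired_compare(cohort$sulcal_mean_strain,
                                          cohort$gyral_mean_strain, alpha)),
    paired_strain_rate = safely("paired strain rate",
                                paired_compare(cohort$sulcal_mean_strain_rate,
                                               cohort$gyral_mean_strain_rate,
                                               alpha)),
    anova = anovas,
    rm_strain = safely("repeated-measures ANOVA strain",
                       rm_anova(long("sulcal_mean_strain",
                                     "gyral_mean_strain"))),
    rm_strain_rate = safely("repeated-measures ANOVA strain rate",
                            rm_anova(long("sulcal_mean_strain_rate",
                                          "gyral_mean_strain_rate"))),
    correlations = safely("correlations", kinematics_correlations(cohort)),
    regression_strain = safely("regression strain",
                               kinematics_regression(cohort,
                                                     "sulcal_mean_strain")),
    regression_strain_rate = safely("regression strain rate",
                                    kinematics_regression(
                                      cohort, "sulcal_mean_strain_rate")),
    notes = notes)
  structure(out, class = "cohort_stats")
}

#' Render a cohort statistics report as Markdown lines
#'
#' @param stats A [cohort_stats()] result.
#' @param cohort The `cohort_table` it was computed from.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(stats, cohort) {
  ln <- c("# Cohort strain statistics", "")
  if (isTRUE(stats$degenerate)) {
    return(c(ln, "**Degenerate cohort**: ", stats$notes))
  }
  fmt_a <- function(a) sprintf("F(%d, %d) = %.3f, p = %.3g",
                               a$df_between, a$df_residual, a$F, a$p_value)
  ln <- c(ln, sprintf("Impacts: %d (profiles: %s)", nrow(cohort),
                      paste(sprintf("%d x profile %s",
                                    as.integer(table(cohort$profile)),
                                    names(table(cohort$profile))),
                            collapse = ", ")), "")
  ln <- c(ln, "## Sulci vs gyri (paired)", "")
  for (nm in c("paired_strain", "paired_strain_rate")) {
    p <- stats[[nm]]
    if (is.null(p)) next
    ln <- c(ln, sprintf(
      "- %s: %s, statistic = %.3g, p = %.3g, d = %.2f (sulcal %.3g ± %.3g vs gyral %.3g ± %.3g)",
      sub("paired_", "", nm), p$test, p$statistic, p$p_value, p$cohens_d,
      p$mean_sulcal, p$sd_sulcal, p$mean_gyral, p$sd_gyral))
  }
  ln <- c(ln, "", "## Profile effects (one-way ANOVA + Tukey HSD)", "")
  for (nm in names(stats$anova)) {
    a <- stats$anova[[nm]]
    if (is.null(a)) next
    ln <- c(ln, sprintf("- %s: %s", nm, fmt_a(a)))
    sig <- a$posthoc[a$posthoc$p_adj < 0.05, ]
    if (nrow(sig))
      ln <- c(ln, sprintf("    - Tukey: %s (p = %.3g)", sig$comparison,
                          sig$p_adj))
  }
  ln <- c(ln, "", "## Profile x region (repeated measures)", "")
  for (nm in c("rm_strain", "rm_strain_rate")) {
    r <- stats[[nm]]
    if (is.null(r)) next
    ln <- c(ln, sprintf("- %s (transform: %s):", sub("rm_", "", nm),
                        r$transform))
    ln <- c(ln, sprintf("    - %s: F(%d, %d) = %.3f, p = %.3g",
                        r$effects$term, r$effects$df1, r$effects$df2,
                        r$effects$F, r$effects$p_value))
  }
  if (!is.null(stats$correlations)) {
    ln <- c(ln, "", "## Kinematics correlations (r^2, 95% CI)", "")
    co <- stats$correlations
    ln <- c(ln, sprintf("- %s ~ %s: r^2 = %.2f (%.2f-%.2f), p = %.3g",
                        co$response, co$predictor, co$r2, co$r2_lo, co$r2_hi,
                        co$p_value))
  }
  ln <- c(ln, "", "## Multiple regression on peak kinematics", "")
  for (nm in c("regression_strain", "regression_strain_rate")) {
    rg <- stats[[nm]]
    if (is.null(rg)) next
    ln <- c(ln, sprintf("- %s (R^2 = %.2f%s):", rg$response, rg$r_squared,
                        if (rg$collinearity_warning)
                          "; collinear design flagged" else ""))
    ln <- c(ln, sprintf("    - %s: beta = %.4g (95%% CI %.4g to %.4g), p = %.3g",
                        rg$coefficients$term, rg$coefficients$beta,
                        rg$coefficients$conf_lo, rg$coefficients$conf_hi,
                        rg$coefficients$p_value))
  }
  if (length(stats$notes)) ln <- c(ln, "", "## Notes", "", paste("-", stats$notes))
  ln
}

#' @export
print.cohort_stats <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<cohort_stats> degenerate cohort; no statistics computed\n")
  } else {
    cat("<cohort_stats>\n")
    if (!is.null(x$paired_strain)) print(x$paired_strain)
    if (!is.null(x$anova$p90_strain)) {
      cat("p90 strain by profile: "); print(x$anova$p90_strain)
    }
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Run the analytic validation suite
#'
#' Fast self-checks of the solver and statistics machinery against closed
#' forms: strain of the identity and of affine maps, the simple-shear
#' eigenvalue, objectivity under rigid motion of the whole mesh, the
#' order-statistic percentile, and a reduced-replicate null-calibration of
#' the one-way ANOVA. Failures are report rows, not errors.
#'
#' @param seed RNG seed for the stochastic checks.
#' @param null_reps Replicates for the ANOVA type-I-rate check.
#' @return Tibble with `check`, `pass` and `detail`.
#' @export
validate_suite <- function(seed = 1L, null_reps = 200L) {
  checks <- list()
  add <- function(check, pass, detail)
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail)

  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  e0 <- max(abs(green_lagrange(deformation_gradient(sq, sq))))
  add("identity map has zero strain", e0 < 1e-12, sprintf("max |E| = %.2g", e0))

  lam <- 1.2
  e1 <- max_principal(green_lagrange(diag(c(lam, 1))))
  add("uniaxial stretch 1.2 gives 0.22", abs(e1 - 0.22) < 1e-12,
      sprintf("value %.6f", e1))

  # closed-form 2x2 eigenvalue: (tr + sqrt(tr^2 - 4 det)) / 2
  e2 <- max_principal(green_lagrange(matrix(c(1, 0, 0.5, 1), 2, 2)))
  closed <- (0.125 + sqrt(0.125^2 + 4 * 0.25^2)) / 2
  add("simple shear 0.5 gives 0.320194",
      abs(e2 - closed) < 1e-12 && abs(e2 - 0.320194) < 1e-6,
      sprintf("value %.6f", e2))

  rig <- .with_seed(seed, {
    built <- build_sulcal_mesh(n_folds = 6, element_size = 0.006,
                               sulcal_depth = 0.012)
    spec <- profile_spec(1, 1, c(3, 0), c(300, 0), c(20, 0), c(2000, 0))
    ev <- generate_impact_pulse(spec, seed)
    fld <- simulate_impact(built$mesh, default_materials(), ev$trace,
                           prescribe_all = TRUE)
    max(fld$peak_strain)
  })
  add("rigid motion of all nodes gives zero strain", rig <= 1e-8,
      sprintf("max peak strain %.2g", rig))

  p90 <- percentile_90(array(1:10, c(10, 1, 1)), array(TRUE, c(10, 1, 1)))
  add("percentile of 1..10 is 9.1", abs(p90 - 9.1) < 1e-12,
      sprintf("value %.3f", p90))

  rej <- .with_seed(seed + 1L, {
    mean(replicate(null_reps, {
      y <- stats::rnorm(148)
      g <- rep(1:3, c(49, 69, 30))
      one_way_anova(y, g)$p_value < 0.05
    }))
  })
  se3 <- 3 * sqrt(0.05 * 0.95 / null_reps)
  add("one-way ANOVA null rejection rate near 0.05",
      abs(rej - 0.05) <= se3,
      sprintf("rate %.3f (tolerance ±%.3f)", rej, se3))

  dplyr::bind_rows(checks)
}
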