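# Strain measures against closed forms, constitutive checks, CFL estimate,
# and the explicit solver's objectivity / quiescence / monotonicity.

test_that("deformation gradient reproduces affine maps exactly", {
  sq <- unit_quad()
  expect_equal(deformation_gradient(sq, sq), diag(2))
  # uniform stretch x' = 1.2 x
  st <- sq %*% diag(c(1.2, 1))
  expect_equal(deformation_gradient(sq, st), diag(c(1.2, 1)))
  # random affine maps on a random (non-degenerate) quad: F = A to machine precision
  set.seed(2)
  for (k in 1:20) {
    A <- matrix(rnorm(4, sd = 0.5), 2) + diag(2)
    b <- rnorm(2)
    ref <- unit_quad() + matrix(rnorm(8, sd = 0.05), 4, 2)
    cur <- t(A %*% t(ref) + b)
    expect_equal(deformation_gradient(ref, cur), A, tolerance = 1e-12)
  }
  # degenerate reference element
  bad <- matrix(c(0, 0, 1, 0, 2, 0, 3, 0), 4, 2, byrow = TRUE)
  expect_error(deformation_gradient(bad, bad), "degenerate")
})

test_that("Green-Lagrange strain matches direct matrix arithmetic", {
  expect_equal(green_lagrange(diag(2)), matrix(0, 2, 2))
  expect_equal(green_lagrange(diag(c(1.2, 1))), diag(c(0.22, 0)))
  # simple shear gamma = 0.5: E = [[0, 0.25], [0.25, 0.125]]
  Fs <- matrix(c(1, 0, 0.5, 1), 2, 2)   # column-major: F12 = 0.5
  expect_equal(green_lagrange(Fs),
               matrix(c(0, 0.25, 0.25, 0.125), 2, 2))
  # symmetric by construction for random F
  set.seed(3)
  Fr <- matrix(rnorm(9), 3, 3) + diag(3)
  E <- green_lagrange(Fr)
  expect_equal(E, t(E))
})

test_that("max principal value agrees with the closed-form 2x2 eigenvalues", {
  expect_equal(max_principal(diag(c(0.22, 0))), 0.22)
  expect_equal(max_principal(matrix(0, 2, 2)), 0)
  # simple shear gamma = 0.5: (tr + sqrt(tr^2 - 4 det)) / 2
  E <- matrix(c(0, 0.25, 0.25, 0.125), 2, 2)
  tr <- sum(diag(E)); dt <- det(E)
  expect_equal(max_principal(E), (tr + sqrt(tr^2 - 4 * dt)) / 2)
  expect_equal(max_principal(E), 0.320194, tolerance = 1e-6)
  expect_error(max_principal(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("strain rate is the principal value of the tensor difference quotient", {
  D <- matrix(c(1, 2, 2, -1), 2, 2)
  expect_equal(strain_rate(D, D, 1e-5), 0)
  # linear growth E(t) = t D: rate is max principal of D at every step
  expect_equal(strain_rate(0.3 * D, 0.2 * D, 0.1), max_principal(D))
  # random symmetric pair vs brute-force eigen decomposition
  set.seed(4)
  for (k in 1:10) {
    A <- crossprod(matrix(rnorm(4), 2)); B <- crossprod(matrix(rnorm(4), 2))
    expect_equal(strain_rate(A, B, 1e-5),
                 max(eigen((A - B) / 1e-5)$values))
  }
  expect_error(strain_rate(D, D, 0), "positive")
})

test_that("material model validates its card", {
  expect_error(material_model(-1, 2500, 5e7), "positive")
  expect_error(material_model(1000, 2500, 5e7,
                              prony = data.frame(g = 1.2, tau = 0.01)),
               "Prony")
  expect_error(material_model(1000, 2500, 5e7,
                              prony = data.frame(g = c(0.6, 0.6),
                                                 tau = c(0.01, 0.1))),
               "Prony")
  m <- material_model(1000, 2500, 5e7, prony = data.frame(g = 0.3, tau = 0.01))
  expect_s3_class(m, "material_model")
})

one_element_mesh <- function() {
  structure(list(nodes = unit_quad(), elems = matrix(1:4, 1),
                 material = "brain", skull_nodes = integer(0),
                 params = list(element_size = 1)), class = "brain_mesh")
}

test_that("internal forces vanish at rest and match linear elasticity for small shear", {
  mesh <- one_element_mesh()
  mats <- default_materials()
  f0 <- internal_forces(mesh, mats, matrix(0, 4, 2))
  expect_equal(max(abs(f0)), 0)

  # homogeneous small simple shear u_x = gamma * y: internal force should be
  # V0 * sigma . B0 with sigma_xy = mu * gamma (volumetric part vanishes, J = 1)
  gam <- 1e-4
  mu <- mats$brain$shear_modulus
  disp <- cbind(gam * mesh$nodes[, 2], 0)
  f <- internal_forces(mesh, mats, disp, hourglass = 0)
  xi <- c(-1, 1, 1, -1); eta <- c(-1, -1, 1, 1)
  B0 <- cbind(xi / 2, eta / 2)          # unit-square gradients at centroid
  f_lin <- cbind(mu * gam * B0[, 2], mu * gam * B0[, 1])
  expect_lt(max(abs(f - f_lin)) / max(abs(f_lin)), 0.01)
  expect_error(internal_forces(mesh, mats, matrix(NaN, 4, 2)), "finite")
})

test_that("Prony shear relaxation follows the closed form", {
  mu <- 1000; g <- 0.3; tau <- 0.01; gam <- 0.1
  n <- 1000; dt <- 1e-4
  Fpath <- matrix(rep(c(1, gam, 0, 1), each = n), n, 4)  # held simple shear
  sig <- sulcalstrain:::cpp_stress_history(Fpath, dt, mu, kappa = 1e6,
                                           g = g, tau = tau)
  tgrid <- (seq_len(n) - 1) * dt
  # step shear held constant: sigma_xy(t) = mu*gam*((1 - g) + g*exp(-t/tau))
  expect_equal(sig[, 3], mu * gam * ((1 - g) + g * exp(-tgrid / tau)),
               tolerance = 1e-10)
  # long-time limit is the relaxed modulus
  expect_equal(sig[n, 3], (1 - g) * mu * gam, tolerance = 1e-3)
  # elastic-only path is time-independent
  sig0 <- sulcalstrain:::cpp_stress_history(Fpath, dt, mu, 1e6,
                                            numeric(0), numeric(0))
  expect_equal(sig0[, 3], rep(mu * gam, n))
})

test_that("stable timestep follows CFL scaling and the per-element minimum", {
  mats <- default_materials()
  # geometrically similar meshes (every length scaled together) so the
  # characteristic length of every element halves exactly
  sized <- function(e) build_sulcal_mesh(
    n_folds = 6, element_size = e, csf_thickness = 2 * e,
    outer_radius = 20 * e, inner_radius = 3 * e, sulcal_depth = 3 * e,
    cortex_thickness = 2 * e)$mesh
  m1 <- sized(0.008); m2 <- sized(0.004)
  dt1 <- stable_timestep(m1, mats)
  dt2 <- stable_timestep(m2, mats)
  expect_equal(dt2 / dt1, 0.5, tolerance = 1e-8)

  stiff <- default_materials()
  stiff$brain$bulk_modulus <- 4 * stiff$brain$bulk_modulus
  stiff$csf$bulk_modulus <- 4 * stiff$csf$bulk_modulus
  expect_equal(stable_timestep(m1, stiff) / dt1, 0.5, tolerance = 0.02)

  # brute-force scan over elements
  areas <- element_areas(m1)
  brute <- Inf
  for (e in seq_len(nrow(m1$elems))) {
    xy <- m1$nodes[m1$elems[e, ], ]
    ed <- sqrt(rowSums((xy[c(2, 3, 4, 1), ] - xy)^2))
    mat <- mats[[m1$material[e]]]
    cw <- sqrt((mat$bulk_modulus + 4 * mat$shear_modulus / 3) / mat$density)
    brute <- min(brute, areas[e] / max(ed) / cw)
  }
  expect_equal(dt1, 0.9 * brute)
  expect_true(is.finite(dt1) && dt1 > 0)
})

test_that("quiescent and rigid-body loading produce (numerically) zero strain", {
  built <- coarse_sulcal()
  mats <- default_materials()
  n <- 201
  tr0 <- kinematics_trace(seq(0, 0.01, length.out = n),
                          matrix(0, n, 3), matrix(0, n, 3))
  f0 <- simulate_impact(built$mesh, mats, tr0, duration = 0.01)
  expect_lte(max(f0$peak_strain), 1e-10)

  # full-mesh rigid motion (translation + rotation): objectivity of E
  ev <- generate_impact_pulse(delta_spec(lin_vel = 3, rot_vel = 20), 5)
  fr <- simulate_impact(built$mesh, mats, ev$trace, prescribe_all = TRUE)
  expect_lte(max(fr$peak_strain), 1e-8)
  expect_lte(max(fr$peak_strain_rate), 1e-4)
})

test_that("uniaxial stretch of a single-element patch gives (lambda^2 - 1) / 2", {
  lam <- 1.2
  sq <- unit_quad()
  F <- deformation_gradient(sq, sq %*% diag(c(lam, 1)))
  expect_equal(max_principal(green_lagrange(F)), (lam^2 - 1) / 2,
               tolerance = 1e-6)
})

test_that("doubling a small rotational pulse increases whole-brain strain", {
  built <- coarse_sulcal()
  mats <- default_materials()
  brain <- built$atlas$labels != 2
  p90 <- vapply(c(2, 4), function(om) {
    ev <- generate_impact_pulse(
      profile_spec(1, 1, c(0.01, 0), c(10, 0), c(om, 0), c(500, 0)), 1)
    fld <- simulate_impact(built$mesh, mats, ev$trace, duration = 0.03)
    unname(quantile(fld$peak_strain[brain], 0.9))
  }, numeric(1))
  expect_gt(p90[2], p90[1])
})

test_that("running strain peaks never decrease with longer simulation", {
  built <- coarse_sulcal()
  mats <- default_materials()
  ev <- generate_impact_pulse(delta_spec(lin_vel = 1, rot_vel = 5), 2)
  f_short <- simulate_impact(built$mesh, mats, ev$trace, duration = 0.015)
  f_long <- simulate_impact(built$mesh, mats, ev$trace, duration = 0.03)
  expect_true(all(f_long$peak_strain >= f_short$peak_strain - 1e-12))
})

test_that("solver rejects durations that cut the pulse short", {
  built <- coarse_sulcal()
  ev <- generate_impact_pulse(delta_spec(), 3)
  expect_error(simulate_impact(built$mesh, default_materials(), ev$trace,
                               duration = ev$pulse_duration / 2),
               "cover the loading pulse")
})
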