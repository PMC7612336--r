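# Strain measures and the explicit-dynamics driver. The element technology
# lives in src/solver.cpp; here are the user-facing kinematic operators, the
# material card, the CFL estimate and the simulation wrapper.

.dN_center <- local({
  xi <- c(-1, 1, 1, -1); eta <- c(-1, -1, 1, 1)
  cbind(xi, eta) / 4
})

#' Deformation gradient of a quad element at its centroid
#'
#' Evaluates F via isoparametric shape-function gradients: linear (affine)
#' maps are reproduced exactly, and F equals the identity when current and
#' reference coordinates coincide.
#'
#' @param ref 4 x 2 matrix of reference node coordinates (counter-clockwise).
#' @param cur 4 x 2 matrix of current node coordinates.
#' @return 2 x 2 deformation gradient (dimensionless).
#' @export
deformation_gradient <- function(ref, cur) {
  ref <- as.matrix(ref); cur <- as.matrix(cur)
  stopifnot(all(dim(ref) == c(4, 2)), all(dim(cur) == c(4, 2)))
  J <- t(ref) %*% .dN_center
  if (det(J) <= 0)
    stop("degenerate reference element (non-positive Jacobian)", call. = FALSE)
  B0 <- .dN_center %*% solve(J)
  t(cur) %*% B0
}

#' Green-Lagrange strain tensor
#'
#' E = (F'F - I) / 2: the finite-deformation strain measure, invariant to
#' rigid-body motion and symmetric by construction.
#'
#' @param F Square deformation-gradient matrix (2 x 2 or 3 x 3).
#' @return Symmetric strain tensor of the same dimension.
#' @export
green_lagrange <- function(F) {
  F <- as.matrix(F)
  stopifnot(nrow(F) == ncol(F), all(is.finite(F)))
  (t(F) %*% F - diag(nrow(F))) / 2
}

#' Maximum principal value of a symmetric tensor
#'
#' @param S Symmetric matrix.
#' @param tol Asymmetry tolerance relative to the largest entry.
#' @return Largest real eigenvalue.
#' @export
max_principal <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  scale <- max(abs(S), 1e-300)
  if (max(abs(S - t(S))) > tol * scale)
    stop("`S` is not symmetric within tolerance", call. = FALSE)
  eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values[1]
}

#' Max-principal strain rate from consecutive strain tensors
#'
#' The reported strain rate is the maximum principal value of the
#' finite-difference time derivative of the Green-Lagrange tensor (the tensor
#' is differentiated first, then its principal value taken).
#'
#' @param E_now,E_prev Symmetric strain tensors at consecutive steps.
#' @param dt Time step, seconds (> 0).
#' @return Scalar strain rate, 1/s.
#' @export
strain_rate <- function(E_now, E_prev, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("`dt` must be a positive scalar", call. = FALSE)
  max_principal((as.matrix(E_now) - as.matrix(E_prev)) / dt)
}

#' Constitutive material card
#'
#' Nearly incompressible neo-Hookean solid with optional Prony-series shear
#' relaxation (quasi-linear viscoelasticity on the deviatoric stress).
#'
#' @param density Mass density, kg/m^3.
#' @param shear_modulus Instantaneous shear modulus, Pa.
#' @param bulk_modulus Bulk modulus, Pa.
#' @param prony Optional data frame with columns `g` (modulus fractions in
#'   (0, 1], summing to <= 1) and `tau` (relaxation time constants, s).
#' @return An object of class `material_model`.
#' @export
material_model <- function(density, shear_modulus, bulk_modulus, prony = NULL) {
  if (density <= 0 || shear_modulus <= 0 || bulk_modulus <= 0)
    stop("density and moduli must be positive", call. = FALSE)
  if (!is.null(prony)) {
    prony <- as.data.frame(prony)
    stopifnot(all(c("g", "tau") %in% names(prony)))
    if (any(prony$g <= 0) || any(prony$g > 1) || sum(prony$g) > 1 ||
        any(prony$tau <= 0))
      stop("Prony fractions must lie in (0,1], sum to <= 1, with tau > 0",
           call. = FALSE)
  }
  structure(list(density = density, shear_modulus = shear_modulus,
                 bulk_modulus = bulk_modulus, prony = prony),
            class = "material_model")
}

#' Default brain and CSF material cards
#'
#' Shear moduli in the range standard for brain finite-element models:
#' brain 2.5 kPa, CSF 0.05 kPa (a very soft solid that transmits little
#' shear), both with 50 MPa bulk modulus (near incompressibility at a
#' tractable explicit time step) and densities near water.
#'
#' @param brain_prony Optional Prony data frame for the brain (see
#'   [material_model()]).
#' @return Named list with `brain` and `csf` material cards.
#' @export
default_materials <- function(brain_prony = NULL) {
  list(brain = material_model(1040, 2500, 5e7, prony = brain_prony),
       csf = material_model(1000, 50, 5e7))
}

#' Stable explicit time step (CFL estimate)
#'
#' Safety factor times the minimum over elements of characteristic length
#' (area / longest edge) divided by the dilatational wave speed
#' sqrt((K + 4 mu / 3) / rho).
#'
#' @param mesh A `brain_mesh`.
#' @param materials Named list of [material_model()]s keyed by the mesh's
#'   material labels.
#' @param safety Safety factor in (0, 1].
#' @return Time step in seconds.
#' @export
stable_timestep <- function(mesh, materials, safety = 0.9) {
  areas <- element_areas(mesh)
  x <- matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE)
  y <- matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  emax <- numeric(nrow(x))
  for (k in 1:4) {
    k2 <- k %% 4 + 1
    emax <- pmax(emax, sqrt((x[, k2] - x[, k])^2 + (y[, k2] - y[, k])^2))
  }
  L <- areas / emax
  cw <- vapply(mesh$material, function(m) {
    mm <- materials[[m]]
    sqrt((mm$bulk_modulus + 4 * mm$shear_modulus / 3) / mm$density)
  }, numeric(1), USE.NAMES = FALSE)
  safety * min(L / cw)
}

#' Internal nodal forces of a displaced state
#'
#' Elastic (instantaneous-modulus) internal force vector for a nodal
#' displacement field: zero for the undeformed, quiescent state. Viscoelastic
#' history is a property of a running simulation and is not part of this
#' single-state evaluation.
#'
#' @param mesh A `brain_mesh`.
#' @param materials Named list of [material_model()]s.
#' @param disp N x 2 nodal displacement matrix, metres.
#' @param hourglass Hourglass stiffness coefficient.
#' @return N x 2 matrix of internal nodal forces, N (per metre of thickness).
#' @export
internal_forces <- function(mesh, materials, disp, hourglass = 0.05) {
  disp <- as.matrix(disp)
  stopifnot(nrow(disp) == nrow(mesh$nodes), ncol(disp) == 2)
  if (any(!is.finite(disp)))
    stop("non-finite displacement state", call. = FALSE)
  mu <- vapply(mesh$material, function(m) materials[[m]]$shear_modulus,
               numeric(1), USE.NAMES = FALSE)
  kap <- vapply(mesh$material, function(m) materials[[m]]$bulk_modulus,
                numeric(1), USE.NAMES = FALSE)
  cpp_internal_forces(mesh$nodes, mesh$elems, disp, mu, kap, hourglass)
}

# Rigid-motion series (translation + planar rotation) derived from a trace,
# sampled at the solver step: linear acceleration acts through its in-plane
# projection, rotation uses the resultant rotational acceleration magnitude.
.prescribed_motion <- function(trace, dt, nsteps) {
  ts <- (0:nsteps) * dt
  interp <- function(y) stats::approx(trace$t, y, xout = ts, rule = 2,
                                      yleft = 0)$y
  ax <- interp(trace$ax); ay <- interp(trace$ay)
  amag <- interp(sqrt(trace$alx^2 + trace$aly^2 + trace$alz^2))
  vx <- .cumtrapz(ts, ax); vy <- .cumtrapz(ts, ay)
  om <- .cumtrapz(ts, amag)
  list(dx = .cumtrapz(ts, vx), dy = .cumtrapz(ts, vy),
       th = .cumtrapz(ts, om))
}

#' Simulate one head impact on a brain mesh
#'
#' Explicit central-difference integration with lumped mass: the skull node
#' set follows the rigid motion obtained by twice-integrating the kinematics
#' trace (in-plane translation plus planar rotation about the domain
#' centroid), interior nodes evolve under internal forces, and per-element
#' running peaks of max-principal Green-Lagrange strain and strain rate are
#' recorded at every time step.
#'
#' @param mesh A `brain_mesh`.
#' @param materials Named list of [material_model()]s keyed by material label
#'   (see [default_materials()]).
#' @param trace A [kinematics_trace()].
#' @param duration Simulated time, seconds; defaults to the trace length.
#'   Must cover the pulse.
#' @param dt_safety CFL safety factor passed to [stable_timestep()].
#' @param damping Mass-proportional damping coefficient, 1/s (default 0;
#'   nonzero damping suppresses ringing but biases strain-rate peaks).
#' @param hourglass Stiffness hourglass-control coefficient for the
#'   single-point quadrature elements.
#' @param prescribe_all If `TRUE`, prescribe the rigid motion to every node
#'   (objectivity checks: strain must vanish).
#' @return A tibble of class `strain_field` with columns `element`,
#'   `material`, `peak_strain` (dimensionless) and `peak_strain_rate` (1/s),
#'   with the time step and duration stored as attributes.
#' @export
simulate_impact <- function(mesh, materials, trace, duration = NULL,
                            dt_safety = 0.9, damping = 0, hourglass = 0.05,
                            prescribe_all = FALSE) {
  stopifnot(inherits(mesh, "brain_mesh"))
  duration <- duration %||% max(trace$t)
  if (duration < max(trace$t[rowSums(abs(
    trace[, c("ax", "ay", "az", "alx", "aly", "alz")])) > 0], 0))
    stop("`duration` must cover the loading pulse", call. = FALSE)
  dt <- stable_timestep(mesh, materials, safety = dt_safety)
  nsteps <- ceiling(duration / dt)

  kinds <- unique(mesh$material)
  if (!all(kinds %in% names(materials)))
    stop("`materials` must name every mesh material: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  matid <- match(mesh$material, kinds)
  mu <- vapply(kinds, function(k) materials[[k]]$shear_modulus, numeric(1))
  kap <- vapply(kinds, function(k) materials[[k]]$bulk_modulus, numeric(1))
  rho <- vapply(kinds, function(k) materials[[k]]$density, numeric(1))
  pg <- lapply(kinds, function(k) {
    p <- materials[[k]]$prony
    if (is.null(p)) numeric(0) else as.numeric(p$g)
  })
  pt <- lapply(kinds, function(k) {
    p <- materials[[k]]$prony
    if (is.null(p)) numeric(0) else as.numeric(p$tau)
  })

  pm <- .prescribed_motion(trace, dt, nsteps + 2L)
  skull <- if (prescribe_all) seq_len(nrow(mesh$nodes)) else mesh$skull_nodes
  res <- cpp_simulate(mesh$nodes, mesh$elems, matid, mu, kap, rho,
                      pg, pt, as.integer(skull),
                      pm$dx, pm$dy, pm$th, dt, duration,
                      0, 0, dt, dt_safety, damping, hourglass, 25L)
  if (res$status == 1)
    stop(sprintf("solver diverged (non-finite or runaway displacement) at t = %.4g s",
                 res$t_fail), call. = FALSE)
  if (res$status == 2)
    stop(sprintf("solver time step collapsed (excessive element distortion) at t = %.4g s",
                 res$t_fail), call. = FALSE)
  out <- tibble::tibble(element = seq_len(nrow(mesh$elems)),
                        material = mesh$material,
                        peak_strain = res$peak_strain,
                        peak_strain_rate = res$peak_strain_rate)
  class(out) <- c("strain_field", class(out))
  attr(out, "dt") <- dt
  attr(out, "duration") <- duration
  out
}
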