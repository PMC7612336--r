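# Idealized 2D plane-strain brain cross-section: an annular domain whose
# outer cortical surface is radially modulated by sinusoidal folds, a CSF
# layer filling the gap to a rigid skull boundary, and a matching sulcal /
# gyral ROI atlas. Structured polar quad meshing; the annulus (free inner
# boundary) avoids the degenerate pole of a disc mesh.

.surface_radius <- function(theta, r_crest, sulcal_depth, n_folds) {
  r_crest - sulcal_depth * (1 - cos(n_folds * theta)) / 2
}

#' Build an idealized sulcated brain mesh and ROI atlas
#'
#' Constructs a structured quad mesh of an annular brain cross-section whose
#' outer surface carries `n_folds` sinusoidal folds (crests = gyri, troughs =
#' sulci), with cerebrospinal fluid filling the gap up to a rigid circular
#' skull boundary. Motion of the outermost node ring (the skull) is
#' prescribed during simulation. Cortical elements (within
#' `cortex_thickness` of the local brain surface) are labelled per fold:
#' sulcal where the surface modulation is in the deeper half of its
#' trough-to-crest span (fundus and lower walls), gyral around the crests.
#' Deep brain and CSF are labelled `other`.
#'
#' @param n_folds Number of folds around the circumference (>= 2).
#' @param sulcal_depth Trough-to-crest fold amplitude, metres. `0` gives the
#'   smooth control labelling (no sulcal elements).
#' @param csf_thickness CSF gap between fold crests and skull, metres.
#' @param outer_radius Skull (outer boundary) radius, metres.
#' @param element_size Target element edge, metres; must resolve the folds
#'   (>= 4 elements across a fold arc).
#' @param inner_radius Inner (free) boundary radius, metres.
#' @param cortex_thickness Depth of the cortical ROI band below the local
#'   brain surface, metres.
#' @return List with components `mesh` (class `brain_mesh`: `nodes` N x 2
#'   matrix in metres, `elems` M x 4 counter-clockwise quad connectivity,
#'   `material` per element in `{"brain","csf"}`, `skull_nodes` index set)
#'   and `atlas` (class `roi_atlas`: integer `labels` per element plus a
#'   `region_table` tibble with `label`, `name`, `class`).
#' @export
build_sulcal_mesh <- function(n_folds = 12L, sulcal_depth = 0.012,
                              csf_thickness = 0.002, outer_radius = 0.08,
                              element_size = 0.001, inner_radius = 0.012,
                              cortex_thickness = 0.006) {
  if (n_folds < 2) stop("`n_folds` must be >= 2", call. = FALSE)
  if (sulcal_depth < 0 || sulcal_depth >= outer_radius / 2)
    stop("`sulcal_depth` must be in [0, outer_radius/2)", call. = FALSE)
  if (csf_thickness <= 0 || element_size <= 0)
    stop("`csf_thickness` and `element_size` must be positive", call. = FALSE)
  r_crest <- outer_radius - csf_thickness
  if (inner_radius <= 0 || inner_radius >= r_crest - sulcal_depth)
    stop("`inner_radius` must lie inside the brain annulus", call. = FALSE)
  fold_arc <- 2 * pi * r_crest / n_folds
  if (element_size > fold_arc / 4)
    stop("`element_size` does not resolve the folds: need >= 4 elements ",
         "across a fold arc of ", signif(fold_arc, 3), " m", call. = FALSE)

  r_mid <- (inner_radius + r_crest) / 2
  n_t <- n_folds * max(4L, round(2 * pi * r_mid / (element_size * n_folds)))
  theta <- 2 * pi * (seq_len(n_t) - 1) / n_t
  r_surf <- .surface_radius(theta, r_crest, sulcal_depth, n_folds)

  n_rb <- max(2L, round((mean(r_surf) - inner_radius) / element_size))
  n_rc <- max(1L, round(csf_thickness / element_size))
  n_r <- n_rb + n_rc + 1L                       # radial node count per column

  # nodes: column-major over (radial index within theta column)
  nodes <- matrix(0, n_t * n_r, 2)
  for (j in seq_len(n_t)) {
    rb <- inner_radius + (r_surf[j] - inner_radius) * (0:n_rb) / n_rb
    rc <- r_surf[j] + (outer_radius - r_surf[j]) * (1:n_rc) / n_rc
    r <- c(rb, rc)
    rows <- (j - 1L) * n_r + seq_len(n_r)
    nodes[rows, 1] <- r * cos(theta[j])
    nodes[rows, 2] <- r * sin(theta[j])
  }
  idx <- function(j, i) as.integer(((j - 1L) %% n_t) * n_r + i)  # i in 1..n_r

  n_el <- n_t * (n_r - 1L)
  elems <- matrix(0L, n_el, 4)
  e <- 0L
  for (j in seq_len(n_t)) for (i in seq_len(n_r - 1L)) {
    e <- e + 1L
    elems[e, ] <- c(idx(j, i), idx(j, i + 1L), idx(j + 1L, i + 1L), idx(j + 1L, i))
  }
  layer <- rep(seq_len(n_r - 1L), times = n_t)    # radial layer of each element
  material <- ifelse(layer <= n_rb, "brain", "csf")
  skull_nodes <- vapply(seq_len(n_t), function(j) idx(j, n_r), integer(1))

  mesh <- structure(
    list(nodes = nodes, elems = elems, material = material,
         skull_nodes = skull_nodes,
         params = list(n_folds = n_folds, sulcal_depth = sulcal_depth,
                       csf_thickness = csf_thickness,
                       outer_radius = outer_radius,
                       inner_radius = inner_radius,
                       element_size = element_size,
                       cortex_thickness = cortex_thickness,
                       n_theta = n_t, n_radial_brain = n_rb,
                       n_radial_csf = n_rc)),
    class = "brain_mesh")

  atlas <- .build_atlas(mesh, smooth = (sulcal_depth == 0))
  list(mesh = mesh, atlas = atlas)
}

#' Build the smooth-cortex control mesh
#'
#' Same annular domain and discretization as [build_sulcal_mesh()] but with
#' an unmodulated cortical surface; cortical elements are labelled as gyral
#' sectors (`smooth_cortex_k`), so the sulcal class is empty.
#'
#' @inheritParams build_sulcal_mesh
#' @return As [build_sulcal_mesh()].
#' @export
build_smooth_mesh <- function(n_folds = 12L, csf_thickness = 0.002,
                              outer_radius = 0.08, element_size = 0.001,
                              inner_radius = 0.012, cortex_thickness = 0.006) {
  build_sulcal_mesh(n_folds = n_folds, sulcal_depth = 0,
                    csf_thickness = csf_thickness,
                    outer_radius = outer_radius, element_size = element_size,
                    inner_radius = inner_radius,
                    cortex_thickness = cortex_thickness)
}

.build_atlas <- function(mesh, smooth = FALSE) {
  p <- mesh$params
  cen <- element_centroids(mesh)
  theta_c <- atan2(cen[, 2], cen[, 1]) %% (2 * pi)
  r_c <- sqrt(rowSums(cen^2))
  r_crest <- p$outer_radius - p$csf_thickness
  r_surf_c <- .surface_radius(theta_c, r_crest, p$sulcal_depth, p$n_folds)
  modu <- (1 - cos(p$n_folds * theta_c)) / 2      # 0 at crest, 1 at trough

  cortical <- mesh$material == "brain" & r_c >= r_surf_c - p$cortex_thickness
  labels <- integer(nrow(mesh$elems))
  labels[mesh$material == "csf"] <- 2L
  labels[mesh$material == "brain"] <- 1L

  crest_k <- (round(p$n_folds * theta_c / (2 * pi)) %% p$n_folds) + 1L
  trough_k <- (floor(p$n_folds * theta_c / (2 * pi)) %% p$n_folds) + 1L
  if (smooth) {
    labels[cortical] <- 200L + crest_k[cortical]
  } else {
    sulcal <- cortical & modu > 0.5
    gyral <- cortical & modu <= 0.5
    labels[sulcal] <- 100L + trough_k[sulcal]
    labels[gyral] <- 200L + crest_k[gyral]
  }

  present <- sort(unique(labels))
  region_table <- dplyr::bind_rows(lapply(present, function(l) {
    if (l == 2L) tibble::tibble(label = l, name = "csf", class = "other")
    else if (l == 1L) tibble::tibble(label = l, name = "deep_brain", class = "other")
    else if (l > 100L && l <= 200L)
      tibble::tibble(label = l, name = sprintf("sulcus_%02d", l - 100L),
                     class = "sulcal")
    else tibble::tibble(label = l,
                        name = sprintf(if (smooth) "smooth_cortex_%02d"
                                       else "gyrus_%02d", l - 200L),
                        class = "gyral")
  }))
  structure(list(labels = labels, region_table = region_table),
            class = "roi_atlas")
}

#' Element centroids
#' @param mesh A `brain_mesh`.
#' @return M x 2 matrix of element centroid coordinates, metres.
#' @export
element_centroids <- function(mesh) {
  x <- matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE)
  y <- matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  cbind(rowMeans(x), rowMeans(y))
}

#' Element areas (shoelace formula)
#' @param mesh A `brain_mesh`.
#' @return Numeric vector of element areas, m^2.
#' @export
element_areas <- function(mesh) {
  x <- matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE)
  y <- matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  0.5 * abs(
    x[, 1] * y[, 2] - x[, 2] * y[, 1] + x[, 2] * y[, 3] - x[, 3] * y[, 2] +
    x[, 3] * y[, 4] - x[, 4] * y[, 3] + x[, 4] * y[, 1] - x[, 1] * y[, 4])
}

#' Mesh quality measures
#'
#' Per-element minimum corner Jacobian determinant (positive for valid,
#' non-degenerate bilinear quads) and interior corner angles.
#'
#' @param mesh A `brain_mesh`.
#' @return Tibble with `element`, `min_jacobian` (m^2 per unit parent area)
#'   and `min_angle`, `max_angle` (degrees).
#' @export
mesh_quality <- function(mesh) {
  n_el <- nrow(mesh$elems)
  minj <- numeric(n_el); amin <- numeric(n_el); amax <- numeric(n_el)
  for (e in seq_len(n_el)) {
    xy <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
    dets <- numeric(4); ang <- numeric(4)
    for (a in 1:4) {
      prv <- xy[(a - 2) %% 4 + 1, ]; nxt <- xy[a %% 4 + 1, ]
      v1 <- nxt - xy[a, ]; v2 <- prv - xy[a, ]
      dets[a] <- v1[1] * v2[2] - v1[2] * v2[1]   # corner Jacobian (x2 area)
      ang[a] <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2)))))
    }
    minj[e] <- min(dets) / 4
    amin[e] <- min(ang) * 180 / pi
    amax[e] <- max(ang) * 180 / pi
  }
  tibble::tibble(element = seq_len(n_el), min_jacobian = minj,
                 min_angle = amin, max_angle = amax)
}

#' @export
print.brain_mesh <- function(x, ...) {
  cat(sprintf(
    "<brain_mesh> %d nodes, %d quads (%d brain, %d csf), %d skull nodes\n",
    nrow(x$nodes), nrow(x$elems), sum(x$material == "brain"),
    sum(x$material == "csf"), length(x$skull_nodes)))
  p <- x$params
  cat(sprintf("  outer R %.0f mm, %d folds, depth %.0f mm, element ~%.1f mm\n",
              1000 * p$outer_radius, p$n_folds, 1000 * p$sulcal_depth,
              1000 * p$element_size))
  invisible(x)
}

#' @export
print.roi_atlas <- function(x, ...) {
  cls <- table(x$region_table$class)
  cat(sprintf("<roi_atlas> %d regions (%s)\n", nrow(x$region_table),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Write / read a mesh with per-element fields as legacy VTK
#'
#' Plain-ASCII legacy VTK unstructured grids (cell type 9, quads) with
#' optional per-element `CELL_DATA` scalars, for inspection in standard
#' viewers. The reader understands the subset the writer emits.
#'
#' @param mesh A `brain_mesh`.
#' @param path Output `.vtk` path.
#' @param cell_data Named list of numeric per-element vectors.
#' @return `write_vtk()` returns `path` invisibly; `read_vtk()` returns a
#'   list with `nodes`, `elems` and `cell_data`.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  n_n <- nrow(mesh$nodes); n_e <- nrow(mesh$elems)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "sulcalstrain mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n_n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", n_e, 5L * n_e), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L,
                     mesh$elems[, 2] - 1L, mesh$elems[, 3] - 1L,
                     mesh$elems[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", n_e), con)
  writeLines(rep("9", n_e), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", n_e), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", as.numeric(cell_data[[nm]])), con)
    }
  }
  invisible(path)
}

#' @rdname write_vtk
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  if (is.na(ip)) stop("not a legacy VTK file: no POINTS section", call. = FALSE)
  n_n <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + n_n)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  ic <- grep("^CELLS", ln)[1]
  n_e <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cls <- do.call(rbind, lapply(ln[(ic + 1):(ic + n_e)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]])))
  if (any(cls[, 1] != 4L)) stop("only quad cells supported", call. = FALSE)
  cell_data <- list()
  id <- grep("^CELL_DATA", ln)
  if (length(id)) {
    pos <- id[1] + 1L
    while (pos <= length(ln) && grepl("^SCALARS", ln[pos])) {
      nm <- strsplit(ln[pos], "\\s+")[[1]][2]
      vals <- as.numeric(ln[(pos + 2):(pos + 1 + n_e)])
      cell_data[[nm]] <- vals
      pos <- pos + 2L + n_e
    }
  }
  list(nodes = pts[, 1:2, drop = FALSE], elems = cls[, 2:5] + 1L,
       cell_data = cell_data)
}
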