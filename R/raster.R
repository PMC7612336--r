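# Element fields -> regular voxel grids -> NIfTI-1 volumes. 2D plane-strain
# fields are stored as one-slice volumes with unit slice thickness so a
# single I/O path serves both 2D and (future) 3D meshes. Transfer is
# piecewise-constant (each voxel centre inherits the value of the element
# containing it); no smoothing, so sulcal strain concentrations survive.

#' Construct a voxel field
#'
#' @param data Numeric array; 2D matrices are promoted to one-slice volumes.
#' @param voxel_size In-plane voxel edge, millimetres.
#' @param origin World (mm) coordinates of the first voxel centre, length 3.
#' @param background Value carried by out-of-mesh voxels.
#' @return Object of class `voxel_field`: `data` (3D array), `affine`
#'   (4 x 4 voxel-to-world RAS+ transform, mm), `voxel_size`, `background`.
#' @export
voxel_field <- function(data, voxel_size, origin = c(0, 0, 0), background = 0) {
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3, voxel_size > 0)
  affine <- diag(c(voxel_size, voxel_size, 1, 1))
  affine[1:3, 4] <- origin
  structure(list(data = data, affine = affine, voxel_size = voxel_size,
                 background = background),
            class = "voxel_field")
}

#' Rasterize a per-element field onto a voxel grid
#'
#' Piecewise-constant transfer: each voxel whose centre falls inside a mesh
#' element carries that element's value; voxels outside the mesh carry
#' `background`. The grid covers the mesh bounding box. Rasterizing the ROI
#' atlas labels through the same call yields an atlas volume congruent with
#' the field volumes (same grid, same affine: registration is the identity).
#'
#' @param values Per-element numeric vector (e.g. a `strain_field` column or
#'   atlas labels).
#' @param mesh The `brain_mesh` the values live on.
#' @param voxel_size Voxel edge, millimetres; should not exceed the element
#'   size or elements may be skipped.
#' @param background Value for voxels outside the mesh.
#' @return A [voxel_field()].
#' @export
rasterize <- function(values, mesh, voxel_size = 1, background = 0) {
  stopifnot(inherits(mesh, "brain_mesh"))
  if (length(values) != nrow(mesh$elems))
    stop("`values` must have one entry per element", call. = FALSE)
  if (voxel_size <= 0) stop("`voxel_size` must be positive", call. = FALSE)
  if (voxel_size / 1000 > 2 * mesh$params$element_size)
    stop("voxel grid too coarse for the mesh: voxel_size ",
         voxel_size, " mm vs element size ",
         1000 * mesh$params$element_size, " mm", call. = FALSE)
  h <- voxel_size / 1000                    # metres
  xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
  nx <- ceiling(diff(xr) / h) + 1L
  ny <- ceiling(diff(yr) / h) + 1L
  xc <- xr[1] + (seq_len(nx) - 0.5) * h
  yc <- yr[1] + (seq_len(ny) - 0.5) * h
  pts <- cbind(rep(xc, times = ny), rep(yc, each = nx))
  idx <- cpp_locate_points(mesh$nodes, mesh$elems, pts)
  vals <- rep(background, length(idx))
  hit <- idx > 0L
  vals[hit] <- values[idx[hit]]
  arr <- array(vals, dim = c(nx, ny, 1L))
  voxel_field(arr, voxel_size, origin = c(1000 * (xr[1] + h / 2),
                                          1000 * (yr[1] + h / 2), 0),
              background = background)
}

#' Rasterize strain results and atlas onto one shared grid
#'
#' Convenience wrapper producing congruent strain, strain-rate and integer
#' atlas volumes plus the in-brain voxel mask.
#'
#' @param field A `strain_field` from [simulate_impact()].
#' @param mesh,atlas The mesh and ROI atlas the field was computed on.
#' @param voxel_size Voxel edge, mm.
#' @return List with `strain`, `strain_rate`, `atlas` ([voxel_field()]s) and
#'   `brain_mask` (logical array).
#' @export
rasterize_impact <- function(field, mesh, atlas, voxel_size = 1) {
  strain <- rasterize(field$peak_strain, mesh, voxel_size)
  rate <- rasterize(field$peak_strain_rate, mesh, voxel_size)
  atl <- rasterize(atlas$labels, mesh, voxel_size, background = 0)
  brain_labels <- atlas$region_table$label[atlas$region_table$name != "csf"]
  list(strain = strain, strain_rate = rate, atlas = atl,
       brain_mask = array(atl$data %in% brain_labels, dim = dim(atl$data)))
}

#' Write / read a voxel field as NIfTI-1
#'
#' Volumes are written as float32 with the RAS+ affine in both sform and
#' qform; reading recovers the array and affine.
#'
#' @param field A [voxel_field()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_nifti()` returns `path` invisibly; `read_nifti()` returns
#'   a [voxel_field()].
#' @export
write_nifti <- function(field, path) {
  stopifnot(inherits(field, "voxel_field"))
  img <- RNifti::asNifti(field$data, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  affine <- matrix(as.numeric(RNifti::xform(img, useQuaternionFirst = FALSE)),
                   4, 4)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  vs <- abs(affine[1, 1])
  structure(list(data = data, affine = affine, voxel_size = vs,
                 background = NA_real_),
            class = "voxel_field")
}

#' @export
print.voxel_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_field> %d x %d x %d @ %.3g mm; range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}
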