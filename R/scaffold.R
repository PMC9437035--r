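#' Build a voxel surface scaffold of the olfactory bulb glomerular layer
#'
#' Discretizes the bulb surface into a grid of cubic voxels, one slab of
#' voxels per serial section along each of the three sectioning axes, and
#' retains the voxels that intersect the glomerular layer (the outer shell).
#' The default shape is an axis-aligned ellipsoid spanning the grid; a point
#' cloud read from a triangulated surface mesh can be supplied instead. The
#' mediolateral midplane (optionally tilted in the AP-ML plane to emulate the
#' bulb's non-orthogonal symmetry line) splits the shell into medial and
#' lateral halves.
#'
#' @param sections_per_axis integer vector of length 3 (AP, DV, ML): number of
#'   sections collected along each axis; one slab of voxels per section.
#' @param voxel_size voxel edge length in micrometers (default 100, the
#'   section thickness).
#' @param semiaxes optional ellipsoid semi-axes in micrometers (AP, DV, ML);
#'   defaults to half the grid extent minus half a voxel so the surface lies
#'   inside the grid.
#' @param layer_thickness thickness of the retained glomerular layer in
#'   voxels (default 1, i.e. a 100 um shell at the default voxel size).
#' @param symmetry_tilt_deg tilt of the medial/lateral symmetry plane in the
#'   AP-ML plane, degrees (default 0 = vertical ML midplane).
#' @param mesh optional n x 3 numeric matrix of surface vertex coordinates in
#'   micrometers (e.g. from [read_surface_mesh()]); when given, shell voxels
#'   are those whose center lies within `layer_thickness * voxel_size` of a
#'   vertex, replacing the analytic ellipsoid rule.
#'
#' @return An object of class `glom_scaffold`: a list with `voxels` (data
#'   frame of grid indices `i_ap`, `i_dv`, `i_ml`, center coordinates in
#'   micrometers and `side`), `dims`, `voxel_size`, `center`, `semiaxes`,
#'   `layer_thickness` and `symmetry_tilt_deg`.
#' @examples
#' sc <- build_scaffold(c(7, 7, 7), voxel_size = 100)
#' table(sc$voxels$side)
#' @export
build_scaffold <- function(sections_per_axis, voxel_size = 100,
                           semiaxes = NULL, layer_thickness = 1,
                           symmetry_tilt_deg = 0, mesh = NULL) {
  dims <- as.integer(sections_per_axis)
  if (length(dims) != 3L || any(dims < 2L)) {
    stopf("`sections_per_axis` must give >= 2 sections for each of AP, DV, ML")
  }
  center <- dims * voxel_size / 2
  if (is.null(semiaxes)) semiaxes <- dims * voxel_size / 2 - voxel_size / 2
  if (any(semiaxes <= voxel_size)) {
    stopf("degenerate ellipsoid: every semi-axis must exceed the voxel size")
  }

  grid <- expand.grid(i_ap = seq_len(dims[1]), i_dv = seq_len(dims[2]),
                      i_ml = seq_len(dims[3]))
  xyz <- cbind((grid$i_ap - 0.5) * voxel_size,
               (grid$i_dv - 0.5) * voxel_size,
               (grid$i_ml - 0.5) * voxel_size)
  half <- layer_thickness * voxel_size / 2

  if (is.null(mesh)) {
    rel <- sweep(sweep(xyz, 2, center), 2, semiaxes, "/")
    f <- sqrt(rowSums(rel^2))           # scaled radial coordinate; surface at 1
    rho <- sqrt(rowSums(sweep(xyz, 2, center)^2))
    # signed distance to the surface along the center ray, in micrometers
    d <- ifelse(f > 0, rho * (f - 1) / f, -min(semiaxes))
    shell <- d > -half & d <= half
  } else {
    mesh <- as.matrix(mesh)
    if (ncol(mesh) != 3L) stopf("`mesh` must be an n x 3 coordinate matrix")
    tol <- layer_thickness * voxel_size
    shell <- vapply(seq_len(nrow(xyz)), function(i) {
      min(sqrt(colSums((t(mesh) - xyz[i, ])^2))) <= tol
    }, logical(1))
  }

  vox <- grid[shell, , drop = FALSE]
  pos <- xyz[shell, , drop = FALSE]
  tilt <- tan(symmetry_tilt_deg * pi / 180)
  plane_ml <- center[3] + tilt * (pos[, 1] - center[1])
  vox$x_um <- pos[, 1]; vox$y_um <- pos[, 2]; vox$z_um <- pos[, 3]
  vox$side <- ifelse(pos[, 3] <= plane_ml, "medial", "lateral")
  rownames(vox) <- NULL

  structure(list(voxels = vox, dims = dims, voxel_size = voxel_size,
                 center = center, semiaxes = semiaxes,
                 layer_thickness = layer_thickness,
                 symmetry_tilt_deg = symmetry_tilt_deg),
            class = "glom_scaffold")
}

#' @export
print.glom_scaffold <- function(x, ...) {
  cat(sprintf("Voxel surface scaffold: %d x %d x %d grid, %g um voxels\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size))
  cat(sprintf("  %d shell voxels (%d medial, %d lateral), layer %d voxel(s)\n",
              nrow(x$voxels), sum(x$voxels$side == "medial"),
              sum(x$voxels$side == "lateral"), x$layer_thickness))
  invisible(x)
}

# Shell voxel count per slab along one axis (zero-count slabs included).
shell_counts <- function(scaffold, axis) {
  check_axis(axis)
  idx <- switch(axis, AP = scaffold$voxels$i_ap, DV = scaffold$voxels$i_dv,
                ML = scaffold$voxels$i_ml)
  n <- scaffold$dims[match(axis, AXES)]
  tabulate(idx, nbins = n)
}

#' Serialize or restore a voxel scaffold as JSON
#'
#' @param scaffold a `glom_scaffold`.
#' @param path file path.
#' @return `read_scaffold()` returns a `glom_scaffold`.
#' @export
write_scaffold <- function(scaffold, path) {
  obj <- list(dims = scaffold$dims, voxel_size = scaffold$voxel_size,
              center = scaffold$center, semiaxes = scaffold$semiaxes,
              layer_thickness = scaffold$layer_thickness,
              symmetry_tilt_deg = scaffold$symmetry_tilt_deg,
              voxels = scaffold$voxels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scaffold
#' @export
read_scaffold <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(voxels = as.data.frame(obj$voxels), dims = as.integer(obj$dims),
                 voxel_size = obj$voxel_size, center = as.numeric(obj$center),
                 semiaxes = as.numeric(obj$semiaxes),
                 layer_thickness = obj$layer_thickness,
                 symmetry_tilt_deg = obj$symmetry_tilt_deg),
            class = "glom_scaffold")
}

#' Read vertex coordinates from an ASCII PLY or OBJ surface mesh
#'
#' Only vertex positions are used: the scaffold needs a point cloud dense on
#' the surface, not the face topology.
#'
#' @param path path to an ASCII `.ply` or `.obj` file.
#' @return numeric matrix with one row per vertex (x, y, z).
#' @export
read_surface_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v\\s", lines, value = TRUE)
    mat <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  } else if (ext == "ply") {
    if (!grepl("^ply", lines[1])) stopf("not a PLY file: %s", path)
    nv <- as.integer(sub("element vertex\\s+", "",
                         grep("^element vertex", lines, value = TRUE)[1]))
    start <- which(lines == "end_header")[1] + 1L
    mat <- do.call(rbind, lapply(strsplit(trimws(lines[start:(start + nv - 1L)]),
                                          "\\s+"), function(p) as.numeric(p[1:3])))
  } else {
    stopf("unsupported mesh format '%s' (use ASCII PLY or OBJ)", ext)
  }
  mat
}
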