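#' Build the labelled voxel grid around a structure
#'
#' Projects the structure onto a cubic lattice (default 1 Angstrom step). A
#' lattice point is a *protein* point when it lies within `protein_radius`
#' (default 2, non-strict) of any atom center; a protein point is INTERIOR
#' when all six axis neighbours are protein points and SURFACE otherwise;
#' everything else is EMPTY. The lattice is anchored at the componentwise
#' floor of the minimum atom coordinate minus `pad`, so it is pinned to
#' integer offsets of the bounding box and results are deterministic.
#'
#' @param structure A `protein_structure`, or an n x 3 coordinate matrix.
#' @param step Lattice spacing in Angstrom (default 1).
#' @param protein_radius Distance from an atom center within which a lattice
#'   point counts as protein (default 2).
#' @param pad Margin added around the bounding box; must be at least
#'   `protein_radius + step` so no protein point touches the extent boundary.
#' @param origin,dims Optional explicit lattice anchor and extent (used by the
#'   overlap test to label two structures on one shared lattice).
#' @return A `voxel_grid`: `origin`, `step`, `dims`, integer `labels`
#'   (0 EMPTY, 1 SURFACE, 2 INTERIOR, in x-fastest order), `n_interior`,
#'   `n_surface`.
#' @export
build_labeled_grid <- function(structure, step = 1.0, protein_radius = 2.0,
                               pad = 4.0, origin = NULL, dims = NULL) {
  xyz <- if (inherits(structure, "protein_structure")) coords(structure) else as.matrix(structure)
  if (is.null(dim(xyz)) || nrow(xyz) == 0)
    sm_error("sitematch_error_no_atoms", "cannot grid an empty structure")
  stopifnot(step > 0, pad >= protein_radius + step)
  if (is.null(origin)) {
    origin <- floor(apply(xyz, 2, min)) - pad
    hi <- ceiling(apply(xyz, 2, max)) + pad
    dims <- as.integer(floor((hi - origin) / step)) + 1L
  }
  labels <- .grid_label_cpp(xyz, as.numeric(origin), as.integer(dims),
                            step, protein_radius)
  structure(list(origin = as.numeric(origin), step = step,
                 dims = as.integer(dims), labels = labels,
                 n_interior = sum(labels == 2L),
                 n_surface = sum(labels == 1L),
                 protein_radius = protein_radius),
            class = "voxel_grid")
}

#' Number of INTERIOR lattice points of a grid
#' @param grid A `voxel_grid`.
#' @return Integer count.
#' @export
count_interior <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$n_interior
}

#' Flag the surface atoms of a structure
#'
#' An atom is a surface atom when it lies within `atom_surface_radius`
#' (default 1.5, non-strict) of some SURFACE lattice point of the grid built
#' for the same structure.
#'
#' @param structure A `protein_structure` (or coordinate matrix).
#' @param grid The `voxel_grid` built from the same structure.
#' @param atom_surface_radius Distance threshold in Angstrom (default 1.5).
#' @return A `surface_annotation`: logical vector `is_surface_atom` (one entry
#'   per atom) plus the grid parameters used.
#' @export
annotate_surface_atoms <- function(structure, grid, atom_surface_radius = 1.5) {
  stopifnot(inherits(grid, "voxel_grid"))
  xyz <- if (inherits(structure, "protein_structure")) coords(structure) else as.matrix(structure)
  hi <- grid$origin + grid$step * (grid$dims - 1L)
  inside <- xyz[, 1] >= grid$origin[1] & xyz[, 1] <= hi[1] &
            xyz[, 2] >= grid$origin[2] & xyz[, 2] <= hi[2] &
            xyz[, 3] >= grid$origin[3] & xyz[, 3] <= hi[3]
  if (!all(inside))
    sm_error("sitematch_error_grid_mismatch",
             "atom outside grid extent; grid was not built from this structure")
  flags <- .surface_atoms_cpp(xyz, grid$origin, grid$dims, grid$step,
                              grid$labels, atom_surface_radius)
  structure(list(is_surface_atom = as.logical(flags),
                 atom_surface_radius = atom_surface_radius),
            class = "surface_annotation")
}

# lattice coordinates (n x 3 matrix) of points with a given label
grid_points <- function(grid, label) {
  i <- which(grid$labels == label) - 1L
  nx <- grid$dims[1]; ny <- grid$dims[2]
  ix <- i %% nx
  iy <- (i %/% nx) %% ny
  iz <- i %/% (nx * ny)
  cbind(grid$origin[1] + grid$step * ix,
        grid$origin[2] + grid$step * iy,
        grid$origin[3] + grid$step * iz)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "), " @ ", x$step,
      " A: ", x$n_surface, " surface, ", x$n_interior, " interior points\n",
      sep = "")
  invisible(x)
}

#' Dump a labelled grid as an XYZ-label table
#'
#' Debug helper: writes one row per non-EMPTY lattice point with its
#' coordinates and label.
#'
#' @param grid A `voxel_grid`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
dump_grid <- function(grid, path) {
  pts <- rbind(cbind(as.data.frame(grid_points(grid, 1L)), label = "SURFACE"),
               cbind(as.data.frame(grid_points(grid, 2L)), label = "INTERIOR"))
  names(pts)[1:3] <- c("x", "y", "z")
  write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
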