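#' Steric-overlap veto for a rigid transform
#'
#' Applies the transform to the second structure, lays ONE shared lattice
#' over the union of the two structures (anchored to the union bounding box,
#' so "interior for both proteins" is well-defined), labels it independently
#' for each protein exactly as in the surface-detection stage, and counts
#' `X` (lattice points interior to both), `X1` and `X2` (interior points of
#' each protein alone). The pair does not overlap when
#' `X <= overlap_ratio * min(X1, X2)` (non-strict: equality counts as no
#' overlap).
#'
#' @param structA,structB `protein_structure`s (or coordinate matrices).
#' @param transform `rigid_transform` applied to `structB`.
#' @param overlap_ratio Veto threshold on `X / min(X1, X2)` (default 0.05).
#' @param step,protein_radius,pad Lattice parameters as in
#'   [build_labeled_grid()].
#' @return An `overlap_result`: `X`, `X1`, `X2`, `overlapping` (logical).
#' @export
check_overlap <- function(structA, structB, transform = rigid_transform(),
                          overlap_ratio = 0.05, step = 1.0,
                          protein_radius = 2.0, pad = 4.0) {
  xyzA <- if (inherits(structA, "protein_structure")) coords(structA) else as.matrix(structA)
  xyzB <- if (inherits(structB, "protein_structure")) coords(structB) else as.matrix(structB)
  if (nrow(xyzA) == 0 || nrow(xyzB) == 0)
    sm_error("sitematch_error_no_atoms", "cannot test overlap of an empty structure")
  xyzBt <- apply_transform(transform, xyzB)
  all_xyz <- rbind(xyzA, xyzBt)
  origin <- floor(apply(all_xyz, 2, min)) - pad
  hi <- ceiling(apply(all_xyz, 2, max)) + pad
  dims <- as.integer(floor((hi - origin) / step)) + 1L
  gA <- build_labeled_grid(xyzA, step = step, protein_radius = protein_radius,
                           pad = pad, origin = origin, dims = dims)
  gB <- build_labeled_grid(xyzBt, step = step, protein_radius = protein_radius,
                           pad = pad, origin = origin, dims = dims)
  X1 <- gA$n_interior
  X2 <- gB$n_interior
  X <- sum(gA$labels == 2L & gB$labels == 2L)
  structure(list(X = X, X1 = X1, X2 = X2,
                 overlapping = X > overlap_ratio * min(X1, X2),
                 overlap_ratio = overlap_ratio),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result> X = ", x$X, ", X1 = ", x$X1, ", X2 = ", x$X2,
      if (x$overlapping) " (OVERLAP)" else " (no overlap)", "\n", sep = "")
  invisible(x)
}
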