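#' Filter a conserved segment into surface-exposed candidate sites
#'
#' A window of a matched segment qualifies as a candidate binding site when it
#' contains at least `min_pairs` matched atom pairs and, on each protein
#' separately, at least `min_fraction` of the window's matched atoms are
#' surface atoms. Only maximal qualifying windows are returned (a window that
#' can be extended left or right while still qualifying is not reported, and
#' no reported window is nested in another): the subsegment search of the
#' rigid-matching stage refines them further, so emitting every qualifying
#' subsegment would only duplicate work. Gap columns of the source segment do
#' not count towards the pair count or the fraction denominators.
#'
#' @param mseg A `matched_segment` (see [matched_columns()]).
#' @param surfA,surfB `surface_annotation`s of the two structures, or `NULL`
#'   to skip the surface test (the ablation mode); one of them may be `NULL`
#'   to test a single side (site-search mode, where the query is a site and
#'   surface-exposed by construction).
#' @param seqA,seqB The `atom_sequence`s the segment positions index into.
#' @param min_pairs Minimum matched pairs per candidate (default 15).
#' @param min_fraction Minimum surface fraction per side (default 2/3).
#' @return List of `candidate_site` objects: `columns` (posA, posB, orig,
#'   atomA, atomB), `surface_fraction_A`, `surface_fraction_B`, `n_pairs`,
#'   `gap_count`.
#' @export
enumerate_candidates <- function(mseg, surfA, surfB, seqA, seqB,
                                 min_pairs = 15L, min_fraction = 2 / 3) {
  stopifnot(inherits(mseg, "matched_segment"))
  n <- nrow(mseg$columns)
  if (n < min_pairs) return(list())
  atomA <- seqA$atom_index[mseg$columns$posA]
  atomB <- seqB$atom_index[mseg$columns$posB]
  sA <- if (is.null(surfA)) rep(TRUE, n) else surfA$is_surface_atom[atomA]
  sB <- if (is.null(surfB)) rep(TRUE, n) else surfB$is_surface_atom[atomB]
  csA <- c(0, cumsum(sA))
  csB <- c(0, cumsum(sB))
  qualifies <- function(i, j) {
    len <- j - i + 1
    len >= min_pairs &
      (csA[j + 1] - csA[i]) >= min_fraction * len &
      (csB[j + 1] - csB[i]) >= min_fraction * len
  }
  # row i of the qualification table, vectorised over window ends
  q_row <- function(i) {
    j <- seq_len(n)
    ok <- j >= i + min_pairs - 1
    ok[ok] <- qualifies(i, j[ok])
    ok
  }
  out <- list()
  q_prev <- rep(FALSE, n) # q(i-1, j), none for i = 1
  for (i in seq_len(n)) {
    qi <- q_row(i)
    js <- which(qi)
    for (j in js) {
      extend_left <- i > 1 && q_prev[j]
      extend_right <- j < n && qi[j + 1]
      if (!extend_left && !extend_right) {
        out[[length(out) + 1L]] <- new_candidate(mseg, i, j, atomA, atomB,
                                                 csA, csB)
      }
    }
    q_prev <- qi
  }
  drop_nested_candidates(out)
}

new_candidate <- function(mseg, i, j, atomA, atomB, csA, csB) {
  len <- j - i + 1
  idx <- i:j
  structure(list(
    columns = data.frame(posA = mseg$columns$posA[idx],
                         posB = mseg$columns$posB[idx],
                         orig = mseg$columns$orig[idx],
                         atomA = atomA[idx], atomB = atomB[idx]),
    surface_fraction_A = (csA[j + 1] - csA[i]) / len,
    surface_fraction_B = (csB[j + 1] - csB[i]) / len,
    n_pairs = len,
    gap_count = window_gap_count(mseg, i, j)
  ), class = "candidate_site")
}

drop_nested_candidates <- function(cands) {
  if (length(cands) < 2) return(cands)
  iv <- t(vapply(cands, function(cs) range(cs$columns$orig), numeric(2)))
  keep <- vapply(seq_along(cands), function(k) {
    !any(iv[, 1] <= iv[k, 1] & iv[, 2] >= iv[k, 2] &
           (iv[, 1] < iv[k, 1] | iv[, 2] > iv[k, 2]))
  }, logical(1))
  cands[keep]
}

#' @export
print.candidate_site <- function(x, ...) {
  cat("<candidate_site> ", x$n_pairs, " pairs, surface fractions ",
      round(x$surface_fraction_A, 3), "/", round(x$surface_fraction_B, 3),
      ", ", x$gap_count, " gaps\n", sep = "")
  invisible(x)
}
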