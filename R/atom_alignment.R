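#' Scoring scheme for atom-level local alignment
#'
#' Matched atoms of the same name score +1; a mismatch between two different
#' atom names is forbidden (it can never appear in an alignment, implemented
#' as a disallowed transition rather than a large negative number); aligning
#' an atom against a space costs -2.
#'
#' @param match_score Score of a matched identical pair (default 1).
#' @param gap_score Score of an atom aligned to a space (default -2).
#' @return A `scoring_scheme`.
#' @export
scoring_scheme <- function(match_score = 1L, gap_score = -2L) {
  stopifnot(match_score > 0, gap_score < 0)
  structure(list(match_score = as.integer(match_score),
                 gap_score = as.integer(gap_score)),
            class = "scoring_scheme")
}

encode_tokens <- function(seqA, seqB) {
  lev <- unique(c(seqA$tokens, seqB$tokens))
  list(a = match(seqA$tokens, lev), b = match(seqB$tokens, lev))
}

as_segment <- function(raw, seqA, seqB) {
  posA <- raw$posA
  posB <- raw$posB
  matched <- !is.na(posA) & !is.na(posB)
  seg <- structure(list(
    columns = data.frame(posA = posA, posB = posB),
    score = raw$score,
    n_matched = sum(matched),
    n_gaps = sum(!matched)
  ), class = "segment_alignment")
  validate_segment(seg, seqA, seqB)
  seg
}

validate_segment <- function(seg, seqA = NULL, seqB = NULL) {
  pa <- seg$columns$posA[!is.na(seg$columns$posA)]
  pb <- seg$columns$posB[!is.na(seg$columns$posB)]
  stopifnot(!is.unsorted(pa, strictly = TRUE), !is.unsorted(pb, strictly = TRUE))
  if (!is.null(seqA)) {
    m <- !is.na(seg$columns$posA) & !is.na(seg$columns$posB)
    stopifnot(identical(seqA$tokens[seg$columns$posA[m]],
                        seqB$tokens[seg$columns$posB[m]]))
  }
  invisible(seg)
}

#' Optimal local alignment of two atom sequences
#'
#' Smith-Waterman local alignment under [scoring_scheme()]: identical atom
#' names match (+1), differing names can never be aligned, gaps cost -2.
#' Traceback ties prefer the match transition, then a gap in the second
#' sequence, then a gap in the first; among equal-score end cells the
#' lexicographically smallest is used, so the result is deterministic.
#'
#' @param seqA,seqB `atom_sequence` objects (see [extract_atom_sequence()]).
#' @param scoring A [scoring_scheme()].
#' @return A `segment_alignment`: `columns` (data frame of `posA`, `posB`
#'   positions into the two sequences, `NA` marking a gap), `score`,
#'   `n_matched`, `n_gaps`. Score 0 with no columns when no legal alignment
#'   exists.
#' @export
smith_waterman <- function(seqA, seqB, scoring = scoring_scheme()) {
  stopifnot(inherits(seqA, "atom_sequence"), inherits(seqB, "atom_sequence"))
  if (length(seqA$tokens) == 0 || length(seqB$tokens) == 0)
    sm_error("sitematch_error_empty_sequence", "empty atom sequence")
  enc <- encode_tokens(seqA, seqB)
  raw <- .sw_align_cpp(enc$a, enc$b, scoring$match_score, scoring$gap_score)
  as_segment(raw, seqA, seqB)
}

#' Suboptimal non-overlapping local alignments (conserved segments)
#'
#' Waterman-Eggert style enumeration: report the best local alignment, ban its
#' matched cells, realign, and stop when the next-best alignment has fewer
#' than `min_matches` matched columns (or the score drops to 0, or
#' `max_segments` is reached). Returned segments are mutually non-overlapping
#' in their matched cells and sorted by score, best first.
#'
#' @inheritParams smith_waterman
#' @param min_matches Minimum matched columns for a reportable segment
#'   (default 15, the smallest subsegment the downstream stages can use).
#' @param max_segments Cap on the number of reported segments (default 100).
#' @return List of `segment_alignment` objects.
#' @export
suboptimal_alignments <- function(seqA, seqB, scoring = scoring_scheme(),
                                  min_matches = 15L, max_segments = 100L) {
  stopifnot(min_matches >= 1)
  if (length(seqA$tokens) == 0 || length(seqB$tokens) == 0)
    sm_error("sitematch_error_empty_sequence", "empty atom sequence")
  enc <- encode_tokens(seqA, seqB)
  raws <- .sw_suboptimal_cpp(enc$a, enc$b, as.integer(min_matches),
                             as.integer(max_segments),
                             scoring$match_score, scoring$gap_score)
  lapply(raws, as_segment, seqA = seqA, seqB = seqB)
}

#' Restrict a segment to its matched columns
#'
#' Keeps only the columns with identical atom pairs; the positions of the
#' dropped gap columns are retained as a per-column `orig` index so that gap
#' counts of any window can still be recovered (`gap_count` annotations are
#' what the final reports count).
#'
#' @param segment A `segment_alignment`.
#' @return A `matched_segment`: data frame `columns` with `posA`, `posB`,
#'   `orig` (original column number), plus `gap_count` (total gap columns of
#'   the source segment) and the source `score`.
#' @export
matched_columns <- function(segment) {
  stopifnot(inherits(segment, "segment_alignment"))
  m <- which(!is.na(segment$columns$posA) & !is.na(segment$columns$posB))
  structure(list(
    columns = data.frame(posA = segment$columns$posA[m],
                         posB = segment$columns$posB[m],
                         orig = m),
    gap_count = nrow(segment$columns) - length(m),
    score = segment$score
  ), class = "matched_segment")
}

# gap columns of the source segment strictly inside window [i, j] of a
# matched_segment
window_gap_count <- function(mseg, i, j) {
  (mseg$columns$orig[j] - mseg$columns$orig[i]) - (j - i)
}

#' @export
print.segment_alignment <- function(x, ...) {
  cat("<segment_alignment> score ", x$score, ", ", x$n_matched, " matched, ",
      x$n_gaps, " gap columns\n", sep = "")
  invisible(x)
}
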