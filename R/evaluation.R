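#' Read a reference binding-site table
#'
#' TSV with columns `protein_id`, `chain`, `residues` (comma-separated
#' residue numbers), one reference site per row -- the interchange format for
#' site databases of the SitesBase kind (which is not redistributed here).
#'
#' @param path TSV path.
#' @return List of `reference_site`s: `protein_id`, `residues` (data frame
#'   `chain`, `resno`).
#' @export
read_reference_sites <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "chain", "residues") %in% names(tab)))
  lapply(seq_len(nrow(tab)), function(i) {
    rn <- as.integer(strsplit(tab$residues[i], ",")[[1]])
    reference_site(tab$protein_id[i], chain = tab$chain[i], residues = rn)
  })
}

#' Construct a reference site
#' @param protein_id Structure identifier (same convention as the reports).
#' @param residues Integer residue numbers.
#' @param chain Chain identifier.
#' @return A `reference_site`.
#' @export
reference_site <- function(protein_id, residues, chain = "A") {
  stopifnot(length(residues) > 0)
  structure(list(protein_id = protein_id,
                 residues = data.frame(chain = chain,
                                       resno = as.integer(residues),
                                       stringsAsFactors = FALSE)),
            class = "reference_site")
}

report_residues <- function(predicted, protein_id) {
  if (predicted$proteinA_id == protein_id) {
    unique(predicted$matched_atoms$resno_A)
  } else if (predicted$proteinB_id == protein_id) {
    unique(predicted$matched_atoms$resno_B)
  } else {
    sm_error("sitematch_error_id_mismatch",
             paste0("reference protein '", protein_id,
                    "' matches neither side of the prediction (",
                    predicted$proteinA_id, ", ", predicted$proteinB_id, ")"))
  }
}

#' Confirm a predicted site against a reference site
#'
#' A prediction is confirmed when at least `min_shared_residues` of its
#' residues (on the side whose structure the reference describes) coincide
#' with the reference residues. The default of 2 is the standard confirmation
#' rule; 1 reproduces the laxer single-residue rule used for methods that
#' report very short sites.
#'
#' @param predicted A `site_pair_report`.
#' @param reference A `reference_site`.
#' @param min_shared_residues Minimum shared residues (default 2).
#' @return Logical.
#' @export
confirm_site <- function(predicted, reference, min_shared_residues = 2L) {
  res <- report_residues(predicted, reference$protein_id)
  length(intersect(res, reference$residues$resno)) >= min_shared_residues
}

confirms_quietly <- function(predicted, reference, k) {
  if (predicted$proteinA_id != reference$protein_id &&
      predicted$proteinB_id != reference$protein_id) return(FALSE)
  confirm_site(predicted, reference, k)
}

#' Precision, recall and gap statistics of a prediction set
#'
#' Precision is the number of predictions confirmed by at least one reference
#' site divided by the number of predictions; recall is the number of
#' reference sites hit by at least one prediction divided by the number of
#' reference sites. Reference sites with two or fewer residues are excluded
#' from the denominator (only sites of more than two complete residues
#' count). A prediction confirming several references counts once towards
#' precision but can recall each of them.
#'
#' @param predictions List of `site_pair_report`s (a `site_report_list`, or a
#'   concatenation of several).
#' @param references List of `reference_site`s.
#' @param min_shared_residues Confirmation threshold (default 2).
#' @return An `eval_summary`: `n_output`, `n_confirmed`, `n_reference`,
#'   `precision`, `recall`, `gap_histogram`.
#' @export
precision_recall <- function(predictions, references, min_shared_residues = 2L) {
  references <- Filter(function(r) nrow(r$residues) > 2, references)
  n_out <- length(predictions)
  n_ref <- length(references)
  conf_mat <- matrix(FALSE, n_out, max(n_ref, 1))
  if (n_out > 0 && n_ref > 0) {
    for (i in seq_len(n_out))
      for (j in seq_len(n_ref))
        conf_mat[i, j] <- confirms_quietly(predictions[[i]], references[[j]],
                                           min_shared_residues)
  }
  n_confirmed <- if (n_out > 0 && n_ref > 0) sum(apply(conf_mat, 1, any)) else 0L
  n_recalled <- if (n_out > 0 && n_ref > 0) sum(apply(conf_mat, 2, any)) else 0L
  if (n_out == 0) warning("no predictions: precision reported as 0")
  structure(list(
    n_output = n_out,
    n_confirmed = n_confirmed,
    n_reference = n_ref,
    precision = if (n_out > 0) n_confirmed / n_out else 0,
    recall = if (n_ref > 0) n_recalled / n_ref else 0,
    gap_histogram = gap_histogram(predictions)
  ), class = "eval_summary")
}

#' Gap histogram of a prediction set
#'
#' Buckets the per-site gap counts (unmatched atoms inside the reported
#' segment) into 0, 1, 2, 3, 4, 5 and more-than-5 gaps.
#'
#' @param predictions List of `site_pair_report`s (anything carrying a
#'   `gap_count` field).
#' @return Named integer vector with names `"0" ... "5", ">5"`, summing to
#'   the number of predictions.
#' @export
gap_histogram <- function(predictions) {
  gaps <- vapply(predictions, `[[`, integer(1), "gap_count")
  buckets <- c(as.character(0:5), ">5")
  h <- setNames(integer(7), buckets)
  if (length(gaps)) {
    b <- ifelse(gaps > 5, ">5", as.character(gaps))
    tb <- table(b)
    h[names(tb)] <- as.integer(tb)
  }
  h
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("<eval_summary>\n",
      "  predictions: ", x$n_output, " (", x$n_confirmed, " confirmed)\n",
      "  reference sites (>2 residues): ", x$n_reference, "\n",
      sprintf("  precision: %.1f%%   recall: %.1f%%\n",
              100 * x$precision, 100 * x$recall),
      "  gaps: ", paste(sprintf("%s:%d", names(x$gap_histogram),
                                x$gap_histogram), collapse = " "), "\n",
      sep = "")
  invisible(x)
}
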