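#' Run configuration for the site-finding pipeline
#'
#' Collects every tunable of the three stages. Defaults follow the method's
#' operating point: superposition threshold `d = 1.5` Angstrom, approximation
#' slack `eps = 0.1`, sites of at least 15 matched atoms, surface fraction at
#' least 2/3 on both sides, steric veto at 5 percent shared interior volume,
#' 1 Angstrom lattice with a 2 Angstrom protein radius and a 1.5 Angstrom
#' surface-atom radius.
#'
#' @param d Superposition distance threshold, Angstrom.
#' @param eps Approximation slack for accepted bottlenecks.
#' @param min_pairs Minimum matched atom pairs per reported site.
#' @param min_surface_fraction Surface-atom fraction each side of a candidate
#'   must reach.
#' @param overlap_ratio Steric veto threshold on shared interior points.
#' @param grid_step,protein_radius,atom_surface_radius,pad Voxel-grid
#'   parameters (see [build_labeled_grid()], [annotate_surface_atoms()]).
#' @param skip_surface_step Ablation switch: bypass the surface filter
#'   entirely.
#' @param max_segments Cap on enumerated conserved segments.
#' @param chain_a,chain_b Chains to read when inputs are file paths.
#' @param group_angle_deg,group_translation Tolerances for pooling reports
#'   whose transforms agree (one physical transform often supports several
#'   windows).
#' @return A `run_config` list.
#' @export
run_config <- function(d = 1.5, eps = 0.1, min_pairs = 15L,
                       min_surface_fraction = 2 / 3, overlap_ratio = 0.05,
                       grid_step = 1.0, protein_radius = 2.0,
                       atom_surface_radius = 1.5, pad = 4.0,
                       skip_surface_step = FALSE, max_segments = 100L,
                       chain_a = NULL, chain_b = NULL,
                       group_angle_deg = 5, group_translation = 0.5) {
  stopifnot(d > 0, eps > 0, eps < 1, min_pairs >= 1,
            min_surface_fraction > 0, min_surface_fraction <= 1,
            overlap_ratio > 0, overlap_ratio <= 1,
            grid_step > 0, protein_radius > 0, atom_surface_radius > 0,
            pad >= protein_radius + grid_step)
  structure(list(d = d, eps = eps, min_pairs = as.integer(min_pairs),
                 min_surface_fraction = min_surface_fraction,
                 overlap_ratio = overlap_ratio, grid_step = grid_step,
                 protein_radius = protein_radius,
                 atom_surface_radius = atom_surface_radius, pad = pad,
                 skip_surface_step = skip_surface_step,
                 max_segments = as.integer(max_segments),
                 chain_a = chain_a, chain_b = chain_b,
                 group_angle_deg = group_angle_deg,
                 group_translation = group_translation),
            class = "run_config")
}

as_structure <- function(x, chain = NULL) {
  if (inherits(x, "protein_structure")) return(x)
  read_pdb(x, chain = chain)
}

#' Compare two structures and report shared binding sites
#'
#' Full pipeline: atom-level local alignment enumerates conserved segments;
#' their matched columns are filtered for surface exposure into candidate
#' sites (skipped under `skip_surface_step`); each candidate is searched for
#' contiguous windows that superpose rigidly within `(1 + eps) d`; windows
#' whose transform makes the two proteins interpenetrate are vetoed; the
#' survivors are grouped by agreeing transforms and reported sorted by pair
#' count (descending) then bottleneck (ascending). Deterministic for fixed
#' inputs and configuration.
#'
#' @param pdbA,pdbB Paths to PDB files, or `protein_structure` objects.
#' @param config A [run_config()].
#' @param surface_sides Which sides the surface-fraction rule applies to:
#'   `"both"` (default), `"B"` (site-search mode, where the query is a site
#'   and surface-exposed by construction), or `"none"`.
#' @return A `site_report_list`: list of `site_pair_report`s (see package
#'   vignette) with a `groups` attribute mapping each report to its
#'   transform group.
#' @export
compare_pair <- function(pdbA, pdbB, config = run_config(),
                         surface_sides = c("both", "B", "none")) {
  surface_sides <- match.arg(surface_sides)
  stopifnot(inherits(config, "run_config"))
  A <- as_structure(pdbA, config$chain_a)
  B <- as_structure(pdbB, config$chain_b)
  seqA <- extract_atom_sequence(A)
  seqB <- extract_atom_sequence(B)
  segs <- suboptimal_alignments(seqA, seqB, scoring_scheme(),
                                min_matches = config$min_pairs,
                                max_segments = config$max_segments)
  msegs <- lapply(segs, matched_columns)
  surfA <- surfB <- NULL
  if (!config$skip_surface_step && surface_sides != "none") {
    if (surface_sides == "both") {
      gA <- build_labeled_grid(A, step = config$grid_step,
                               protein_radius = config$protein_radius,
                               pad = config$pad)
      surfA <- annotate_surface_atoms(A, gA, config$atom_surface_radius)
    }
    gB <- build_labeled_grid(B, step = config$grid_step,
                             protein_radius = config$protein_radius,
                             pad = config$pad)
    surfB <- annotate_surface_atoms(B, gB, config$atom_surface_radius)
  }
  skip_surface <- config$skip_surface_step || surface_sides == "none"
  cands <- list()
  for (ms in msegs) {
    cs <- if (skip_surface) {
      enumerate_candidates(ms, NULL, NULL, seqA, seqB,
                           min_pairs = config$min_pairs, min_fraction = 0)
    } else {
      enumerate_candidates(ms, surfA, surfB, seqA, seqB,
                           min_pairs = config$min_pairs,
                           min_fraction = config$min_surface_fraction)
    }
    cands <- c(cands, cs)
  }
  params <- match_parameters(d = config$d, eps = config$eps,
                             min_pairs = config$min_pairs)
  # the steric veto compares the two protein BODIES; in site-search mode the
  # query is a bare site with no body, so any faithful match would overlap
  # its own image in the target and the veto would reject everything
  apply_veto <- surface_sides != "B"
  reports <- list()
  for (cand in cands) {
    matches <- find_matching_subsegments(cand, A, B, params)
    for (m in matches) {
      # the reported subsegment is itself a candidate site, so the
      # surface-fraction rule applies to it directly: without this a buried
      # stretch diluted inside a long, mostly-exposed conserved segment
      # would escape the surface filter
      if (!skip_surface) {
        if (!is.null(surfA) &&
            mean(surfA$is_surface_atom[m$columns$atomA]) <
              config$min_surface_fraction) next
        if (!is.null(surfB) &&
            mean(surfB$is_surface_atom[m$columns$atomB]) <
              config$min_surface_fraction) next
      }
      ov <- NULL
      if (apply_veto) {
        ov <- check_overlap(A, B, m$transform,
                            overlap_ratio = config$overlap_ratio,
                            step = config$grid_step,
                            protein_radius = config$protein_radius,
                            pad = config$pad)
        if (ov$overlapping) next
      }
      reports[[length(reports) + 1L]] <- build_report(A, B, cand, m, ov)
    }
  }
  finalize_reports(reports, config, coords(B))
}

build_report <- function(A, B, cand, m, ov) {
  atA <- A$atoms[m$columns$atomA, , drop = FALSE]
  atB <- B$atoms[m$columns$atomB, , drop = FALSE]
  structure(list(
    proteinA_id = A$id, proteinB_id = B$id,
    residue_ranges_A = residue_ranges(atA),
    residue_ranges_B = residue_ranges(atB),
    matched_atoms = data.frame(name = atA$name,
                               resno_A = atA$resno, resno_B = atB$resno,
                               stringsAsFactors = FALSE),
    atom_index_A = m$columns$atomA, atom_index_B = m$columns$atomB,
    transform = m$transform,
    pair_distances = m$pair_distances,
    bottleneck = m$bottleneck,
    n_pairs = m$n_pairs,
    gap_count = m$gap_count,
    overlap = ov
  ), class = "site_pair_report")
}

residue_ranges <- function(at) {
  key <- paste(at$chain, at$resno)
  u <- !duplicated(key)
  ch <- at$chain[u]; rn <- at$resno[u]
  brk <- c(TRUE, diff(rn) != 1 | ch[-1] != ch[-length(ch)])
  grp <- cumsum(brk)
  data.frame(chain = tapply(ch, grp, `[`, 1),
             start = as.integer(tapply(rn, grp, min)),
             end = as.integer(tapply(rn, grp, max)),
             row.names = NULL, stringsAsFactors = FALSE)
}

rotation_angle <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

finalize_reports <- function(reports, config, xyzB = NULL) {
  if (length(reports) == 0)
    return(structure(list(), class = "site_report_list",
                     groups = integer(0)))
  ord <- order(-vapply(reports, `[[`, integer(1), "n_pairs"),
               vapply(reports, `[[`, numeric(1), "bottleneck"))
  reports <- reports[ord]
  # pool reports whose transforms agree within tolerance; translations are
  # compared by the transforms' action at the matched atoms (a raw
  # translation-vector comparison is meaningless far from the origin)
  same_transform <- function(ri, rj) {
    if (rotation_angle(ri$transform$R, rj$transform$R) > config$group_angle_deg)
      return(FALSE)
    if (is.null(xyzB)) {
      return(sqrt(sum((ri$transform$t - rj$transform$t)^2)) <=
               config$group_translation)
    }
    cc <- colMeans(xyzB[c(ri$atom_index_B, rj$atom_index_B), , drop = FALSE])
    sqrt(sum((apply_transform(ri$transform, cc) -
                apply_transform(rj$transform, cc))^2)) <=
      config$group_translation
  }
  groups <- integer(length(reports))
  reps <- integer(0) # index of each group's representative report
  for (i in seq_along(reports)) {
    g <- 0L
    for (j in seq_along(reps)) {
      if (same_transform(reports[[i]], reports[[reps[j]]])) { g <- j; break }
    }
    if (g == 0L) { reps <- c(reps, i); g <- length(reps) }
    groups[i] <- g
  }
  for (i in seq_along(reports)) reports[[i]]$group <- groups[i]
  structure(reports, class = "site_report_list", groups = groups)
}

#' Search a binding site against target structures
#'
#' Uses a known site (a PDB file plus a residue list) as the query and runs
#' the pairwise pipeline against each target, with the surface-fraction rule
#' applied to the target side only -- the query is a binding site and hence
#' surface-exposed by construction.
#'
#' @param query Either a list with elements `pdb` (path), `chain`, `residues`
#'   (integer vector), a path to a JSON file with those fields, or a
#'   `protein_structure` already restricted to the site.
#' @param targets Character vector of PDB paths, or list of
#'   `protein_structure`s.
#' @param config A [run_config()].
#' @return Named list (by target id) of `site_report_list`s.
#' @export
search_site <- function(query, targets, config = run_config()) {
  if (length(targets) == 0)
    sm_error("sitematch_error_no_targets", "empty target list")
  qs <- load_query_site(query, config)
  if (nrow(qs$atoms) < config$min_pairs)
    sm_error("sitematch_error_short_query",
             paste0("query site has ", nrow(qs$atoms), " atoms; need >= ",
                    config$min_pairs))
  out <- list()
  for (tg in targets) {
    Tst <- as_structure(tg, config$chain_b)
    out[[Tst$id]] <- compare_pair(qs, Tst, config, surface_sides = "B")
  }
  out
}

load_query_site <- function(query, config) {
  if (inherits(query, "protein_structure")) return(query)
  if (is.character(query) && length(query) == 1) {
    query <- jsonlite::read_json(query, simplifyVector = TRUE)
  }
  if (!is.list(query) || is.null(query$pdb) || is.null(query$residues))
    sm_error("sitematch_error_bad_query",
             "query must provide 'pdb' and 'residues' (and optionally 'chain')")
  st <- read_pdb(query$pdb, chain = query$chain)
  keep <- st$atoms$resno %in% as.integer(query$residues)
  if (!any(keep))
    sm_error("sitematch_error_bad_query", "no atoms match the query residues")
  st$atoms <- st$atoms[keep, , drop = FALSE]
  rownames(st$atoms) <- NULL
  st$id <- paste0(st$id, "site")
  st
}

#' @export
print.site_report_list <- function(x, ...) {
  cat("<site_report_list> ", length(x), " site pair(s), ",
      length(unique(attr(x, "groups"))), " transform group(s)\n", sep = "")
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' Summarise a report list as a data frame (one row per site pair)
#' @param x A `site_report_list`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.site_report_list <- function(x, ...) {
  if (length(x) == 0)
    return(data.frame(proteinA = character(0), proteinB = character(0),
                      residues_A = character(0), residues_B = character(0),
                      n_pairs = integer(0), bottleneck = numeric(0),
                      gap_count = integer(0), group = integer(0)))
  fmt_rng <- function(rr) paste(sprintf("%s:%d-%d", rr$chain, rr$start, rr$end),
                                collapse = ",")
  data.frame(
    proteinA = vapply(x, `[[`, character(1), "proteinA_id"),
    proteinB = vapply(x, `[[`, character(1), "proteinB_id"),
    residues_A = vapply(x, function(r) fmt_rng(r$residue_ranges_A), character(1)),
    residues_B = vapply(x, function(r) fmt_rng(r$residue_ranges_B), character(1)),
    n_pairs = vapply(x, `[[`, integer(1), "n_pairs"),
    bottleneck = round(vapply(x, `[[`, numeric(1), "bottleneck"), 6),
    gap_count = vapply(x, `[[`, integer(1), "gap_count"),
    group = vapply(x, `[[`, integer(1), "group"),
    stringsAsFactors = FALSE
  )
}

#' Write reports as canonical JSON
#'
#' 6-decimal floats; transforms as 3 x 4 row-major matrices.
#'
#' @param reports A `site_report_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(reports, path) {
  lst <- lapply(reports, function(r) {
    list(proteinA = r$proteinA_id, proteinB = r$proteinB_id,
         residue_ranges_A = r$residue_ranges_A,
         residue_ranges_B = r$residue_ranges_B,
         matched_atoms = r$matched_atoms,
         transform = format_transform(r$transform),
         bottleneck = round(r$bottleneck, 6),
         n_pairs = r$n_pairs, gap_count = r$gap_count,
         overlap = if (is.null(r$overlap)) NULL else
           list(X = r$overlap$X, X1 = r$overlap$X1, X2 = r$overlap$X2),
         group = r$group)
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(path)
}
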