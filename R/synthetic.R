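#' Idealised residue templates for synthetic structures
#'
#' Atom-name templates (standard PDB order: N, CA, C, O, then side chain) for
#' the residue types the synthetic generator instantiates. Geometry is
#' produced by the generator's self-avoiding walk, not by these templates:
#' the downstream pipeline uses nothing beyond atom names and coordinates.
#'
#' @return Named list of character vectors of atom names.
#' @export
residue_templates <- function() {
  list(
    GLY = c("N", "CA", "C", "O"),
    ALA = c("N", "CA", "C", "O", "CB"),
    SER = c("N", "CA", "C", "O", "CB", "OG"),
    CYS = c("N", "CA", "C", "O", "CB", "SG"),
    VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
    THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
    LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
    ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  )
}

# disjoint-vocabulary palettes for negative-control fixtures: the two share
# no atom-name token, so no alignment column is ever legal between them
disjoint_palettes <- function() {
  list(
    A = list(XAA = c("C1", "C2", "C3", "C4"), XAB = c("C1", "C2", "C5", "C6", "C7")),
    B = list(XBA = c("N1", "N2", "N3", "N4"), XBB = c("N1", "N2", "N5", "N6", "N7"))
  )
}

# Self-avoiding random walk of n_atoms points: consecutive points `step_len`
# apart, every pair at least `min_dist` apart, optional confinement ball and
# external obstacles. Directions have persistence so chains wander without
# knotting. Errors (with the seed in the message) after bounded retries.
atom_walk <- function(n_atoms, start = c(0, 0, 0), step_len = 2.9,
                      min_dist = 2.5, persistence = 0.5,
                      within_radius = NULL, center = start,
                      slab_half = NULL, obstacles = NULL,
                      max_tries = 60L, seed_label = NA) {
  pts <- matrix(NA_real_, n_atoms, 3)
  pts[1, ] <- start
  dir <- rand_unit()
  clash <- function(p, upto) {
    if (upto >= 1 &&
        min(rowSums(sweep(pts[seq_len(upto), , drop = FALSE], 2, p)^2)) < min_dist^2)
      return(TRUE)
    if (!is.null(obstacles) &&
        min(rowSums(sweep(obstacles, 2, p)^2)) < min_dist^2)
      return(TRUE)
    if (!is.null(within_radius) && sum((p - center)^2) > within_radius^2)
      return(TRUE)
    if (!is.null(slab_half) && abs(p[3] - center[3]) > slab_half)
      return(TRUE)
    FALSE
  }
  i <- 2L
  restarts <- 0L
  while (i <= n_atoms) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      d <- dir * persistence + rand_unit()
      d <- d / sqrt(sum(d^2))
      p <- pts[i - 1L, ] + step_len * d
      # the predecessor sits at step_len >= min_dist by construction
      if (!clash(p, i - 1L)) {
        pts[i, ] <- p
        dir <- d
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # back up a few steps and retry; bounded total restarts
      restarts <- restarts + 1L
      if (restarts > 500L)
        sm_error("sitematch_error_placement",
                 paste0("self-avoiding walk failed (seed ", seed_label, ")"))
      i <- max(2L, i - 6L)
      dir <- rand_unit()
      next
    }
    i <- i + 1L
  }
  pts
}

# confinement radius giving ~30 cubic Angstrom of walk volume per atom
# (compact enough that the decoy body carries a realistic interior volume
# relative to a thin site patch, loose enough that the walk stays feasible)
blob_radius <- function(n_atoms) {
  max(8, (30 * n_atoms * 3 / (4 * pi))^(1 / 3) + 1)
}

rand_unit <- function() {
  repeat {
    v <- runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-4 && n2 <= 1) return(v / sqrt(n2))
  }
}

rand_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

build_atoms_df <- function(res_names, res_atoms, xyz, chain = "A",
                           resno_start = 1L) {
  n_per <- lengths(res_atoms)
  data.frame(
    serial = seq_len(nrow(xyz)),
    name = unlist(res_atoms, use.names = FALSE),
    element = derive_element(unlist(res_atoms, use.names = FALSE)),
    resid = rep(res_names, n_per),
    resno = rep(seq_along(res_names) + resno_start - 1L, n_per),
    insert = "",
    chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic protein-like structure
#'
#' Residues are drawn from `palette` and instantiated in the standard atom
#' order along a self-avoiding random walk (consecutive atoms 2.9 Angstrom
#' apart, no two atoms closer than 2.5 Angstrom). Deterministic for a fixed
#' seed; the seed is recorded in the provenance and written as a REMARK by
#' [write_pdb()].
#'
#' @param n_residues Number of residues.
#' @param seed Integer seed.
#' @param palette Named list of residue templates (default
#'   [residue_templates()]).
#' @param id Structure identifier.
#' @param chain Chain identifier (default "A").
#' @param start,obstacles,within_radius,center Walk placement controls (used
#'   by the site-planting functions).
#' @param persistence Walk direction persistence in `[0, 1)`; lower is more
#'   tortuous.
#' @return A `protein_structure`.
#' @export
generate_protein <- function(n_residues, seed = 1L, palette = residue_templates(),
                             id = sprintf("SYN%04d", seed %% 10000), chain = "A",
                             start = c(0, 0, 0), obstacles = NULL,
                             within_radius = NULL, center = start,
                             persistence = 0.5) {
  stopifnot(n_residues >= 1)
  set.seed(seed)
  res_names <- sample(names(palette), n_residues, replace = TRUE)
  res_atoms <- palette[res_names]
  n_atoms <- sum(lengths(res_atoms))
  xyz <- atom_walk(n_atoms, start = start, obstacles = obstacles,
                   within_radius = within_radius, center = center,
                   persistence = persistence, seed_label = seed)
  atoms <- build_atoms_df(res_names, res_atoms, xyz, chain = chain)
  new_protein_structure(id, atoms,
                        provenance = list(generator = "synthetic", seed = seed))
}

# body-centred cubic lattice points within a shell [r_in, r_out] of the
# reference points (burial cage: nearest-neighbour distance a*sqrt(3)/2,
# covering radius small enough that no solvent channel reaches the site)
bcc_shell <- function(ref, r_in = 2.0, r_out = 4.8, a = 2.31) {
  lo <- apply(ref, 2, min) - r_out - a
  hi <- apply(ref, 2, max) + r_out + a
  gx <- seq(lo[1], hi[1], by = a)
  gy <- seq(lo[2], hi[2], by = a)
  gz <- seq(lo[3], hi[3], by = a)
  base <- as.matrix(expand.grid(gx, gy, gz))
  pts <- rbind(base, sweep(base, 2, c(a / 2, a / 2, a / 2), "+"))
  dmin <- apply(pts, 1, function(p) min(sqrt(rowSums(sweep(ref, 2, p)^2))))
  pts[dmin >= r_in & dmin <= r_out, , drop = FALSE]
}

# Plug solvent channels in a burial cage: any lattice point that is empty yet
# close to a site atom lets a surface point reach the site, so filler atoms
# are inserted into such holes (respecting the 2.5 A spacing) until the site
# region is watertight or nothing more can be inserted.
plug_cage_holes <- function(site_xyz, cage_xyz, min_dist = 2.5,
                            reach = 3.0, passes = 6L) {
  for (p in seq_len(passes)) {
    all_xyz <- rbind(site_xyz, cage_xyz)
    g <- build_labeled_grid(all_xyz)
    open <- which(g$labels != 2L) # EMPTY or SURFACE lattice points
    i <- open - 1L
    nx <- g$dims[1]; ny <- g$dims[2]
    pts <- cbind(g$origin[1] + g$step * (i %% nx),
                 g$origin[2] + g$step * ((i %/% nx) %% ny),
                 g$origin[3] + g$step * (i %/% (nx * ny)))
    dsite <- apply(site_xyz, 1, function(a)
      sqrt(rowSums(sweep(pts, 2, a, "-")^2)))
    near <- which(apply(dsite, 1, min) <= reach)
    if (length(near) == 0) break
    added <- 0L
    for (k in near) {
      q <- pts[k, ]
      dall <- sqrt(rowSums(sweep(rbind(site_xyz, cage_xyz), 2, q, "-")^2))
      if (min(dall) >= min_dist) {
        cage_xyz <- rbind(cage_xyz, q)
        added <- added + 1L
      } else {
        # nudge the point radially away from its nearest atom to spacing
        nn <- which.min(dall)
        anchor <- rbind(site_xyz, cage_xyz)[nn, ]
        v <- q - anchor
        nv <- sqrt(sum(v^2))
        if (nv < 1e-6) next
        q2 <- anchor + v / nv * (min_dist + 0.05)
        dall2 <- sqrt(rowSums(sweep(rbind(site_xyz, cage_xyz), 2, q2, "-")^2))
        if (min(dall2) >= min_dist) {
          cage_xyz <- rbind(cage_xyz, q2)
          added <- added + 1L
        }
      }
    }
    if (added == 0L) break
  }
  cage_xyz
}

# group loose filler atoms into pseudo-residues with template atom names
filler_residues <- function(xyz, palette = residue_templates()) {
  sizes <- lengths(palette)
  res_names <- character(0)
  n_left <- nrow(xyz)
  while (n_left > 0) {
    ok <- names(palette)[sizes <= n_left]
    if (length(ok) == 0) {
      # pad by trimming the last template
      res_names <- c(res_names, "GLY")
      n_left <- n_left - 4L
      next
    }
    pick <- sample(ok, 1)
    res_names <- c(res_names, pick)
    n_left <- n_left - sizes[[pick]]
  }
  res_atoms <- palette[res_names]
  extra <- sum(lengths(res_atoms)) - nrow(xyz)
  if (extra > 0) { # trim the final residue to fit
    last <- res_atoms[[length(res_atoms)]]
    res_atoms[[length(res_atoms)]] <- last[seq_len(length(last) - extra)]
  }
  list(res_names = res_names, res_atoms = res_atoms)
}

#' Plant a shared site in a pair of synthetic structures
#'
#' Generates two structures that share one contiguous stretch of residues:
#' the stretch is generated once, carried verbatim by the first structure,
#' and copied into the second under a random rigid transform with isotropic
#' Gaussian jitter (`jitter_sigma`) and optional `gap_edits` atom deletions
#' (which become gap columns in the atom-level alignment). With
#' `placement = "surface"` the stretch sits on the periphery of both
#' structures; with `placement = "buried"` it is additionally enclosed in a
#' body-centred-cubic shell of filler residues in the FIRST structure, so
#' its surface fraction there falls below the 2/3 candidate rule while the
#' copy in the second structure stays exposed (a site buried on both sides
#' could never pass the steric-overlap veto, which would make the
#' surface-ablation comparison vacuous).
#'
#' @param n_residues_a,n_residues_b Decoy residues in each structure.
#' @param site_residues Residues in the shared stretch (default 4, about 20
#'   atoms with the default palette).
#' @param jitter_sigma Per-coordinate Gaussian jitter of the copied stretch,
#'   Angstrom (default 0.2).
#' @param placement `"surface"` or `"buried"`.
#' @param gap_edits Number of atoms deleted from the copy (default 0).
#' @param seed Integer seed (controls everything).
#' @param palette Residue templates.
#' @return List with `A`, `B` (`protein_structure`s), and `truth`: data frame
#'   `pairs` (atom row indices in A and B of the planted correspondence),
#'   `transform` (the `rigid_transform` mapping the copy in B back onto A,
#'   the same direction the pipeline reports), the planted residue numbers
#'   on both sides, and the seed.
#' @export
plant_shared_site <- function(n_residues_a = 80L, n_residues_b = 80L,
                              site_residues = 4L, jitter_sigma = 0.2,
                              placement = c("surface", "buried"),
                              gap_edits = 0L, seed = 1L,
                              palette = residue_templates()) {
  placement <- match.arg(placement)
  stopifnot(site_residues >= 1, jitter_sigma >= 0, gap_edits >= 0)
  set.seed(seed)

  # --- the shared stretch (compact walk at the origin) ---
  site_names <- sample(setdiff(names(palette), "GLY"), site_residues, replace = TRUE)
  site_atoms <- palette[site_names]
  n_site <- sum(lengths(site_atoms))
  # the stretch is a thin patch (slab-confined walk): binding sites are
  # surface patches, and a globular stretch would share its own interior
  # volume with its copy under the matching transform and trip the veto
  site_xyz <- atom_walk(n_site, start = c(0, 0, 0), persistence = 0.3,
                        within_radius = max(7, 1.5 * n_site / 4),
                        center = c(0, 0, 0), slab_half = 0.8,
                        seed_label = seed)

  # --- structure A: decoys + stretch (+ cage when buried) ---
  # decoy palettes share no side-chain token across the two structures, so
  # the decoy bodies carry no conserved segments of their own and the
  # planted stretch dominates the alignment stage (the backbone tokens
  # alone cannot accumulate a qualifying score against the gap penalty)
  half_a <- n_residues_a %/% 2L
  decoyA_names <- sample(c("SER", "ASP"), n_residues_a, replace = TRUE)
  decoyA_atoms <- palette[decoyA_names]
  nA_dec <- sum(lengths(decoyA_atoms))
  cage_xyz <- NULL
  if (placement == "buried") {
    cage_xyz <- bcc_shell(site_xyz)
    rot <- rand_rotation() # decorrelate the cage lattice axes between runs
    ctr <- colMeans(site_xyz)
    cage_xyz <- sweep(sweep(cage_xyz, 2, ctr) %*% t(rot), 2, ctr, "+")
    # re-check spacing after rotation about the site
    dmin <- apply(cage_xyz, 1, function(p)
      min(sqrt(rowSums(sweep(site_xyz, 2, p)^2))))
    cage_xyz <- cage_xyz[dmin >= 2.0, , drop = FALSE]
    # the cage packs at 2.0 A (tighter than the walk's 2.5 A): burial under
    # a 2 A protein radius is infeasible at walk spacing, and real cores
    # pack at bonded distances anyway
    cage_xyz <- plug_cage_holes(site_xyz, cage_xyz, min_dist = 2.0)
  }
  site_extent <- max(sqrt(rowSums(site_xyz^2)))
  # confine each decoy blob to a ball sized for its atom count so the two
  # blobs sit on opposite sides of the site and cannot collide under the
  # planting transform (a collision would trip the steric veto spuriously)
  rA <- blob_radius(nA_dec)
  offA <- site_extent + (if (placement == "buried") 12 else 8) + rA
  decoyA_xyz <- atom_walk(nA_dec, start = c(-offA, 0, 0),
                          obstacles = rbind(site_xyz, cage_xyz),
                          within_radius = rA, center = c(-offA, 0, 0),
                          persistence = 0.5, seed_label = seed)

  # --- structure B: independent decoys + transformed copy of the stretch ---
  decoyB_names <- sample(c("CYS", "THR"), n_residues_b, replace = TRUE)
  decoyB_atoms <- palette[decoyB_names]
  nB_dec <- sum(lengths(decoyB_atoms))
  plant <- rigid_transform(rand_rotation(), c(200, 50, -30), check = FALSE)
  siteB_xyz <- apply_transform(plant, site_xyz)
  if (jitter_sigma > 0)
    siteB_xyz <- siteB_xyz + matrix(rnorm(length(siteB_xyz), 0, jitter_sigma),
                                    ncol = 3)
  rB <- blob_radius(nB_dec)
  offB <- site_extent + (if (placement == "buried") 10 else 8) + rB
  # opposite side (+x in the site's local frame, mapped through the plant)
  ctrB <- as.numeric(apply_transform(plant, c(offB, 0, 0)))
  decoyB_xyz <- atom_walk(nB_dec, start = ctrB,
                          obstacles = siteB_xyz,
                          within_radius = rB, center = ctrB,
                          persistence = 0.5, seed_label = seed)

  # --- assemble A: first-half decoys, stretch, cage-or-rest decoys ---
  splitA <- cumsum(lengths(decoyA_atoms))
  cutA <- sum(lengths(decoyA_atoms[seq_len(half_a)]))
  resA_names <- c(decoyA_names[seq_len(half_a)], site_names,
                  decoyA_names[-seq_len(half_a)])
  resA_atoms <- c(decoyA_atoms[seq_len(half_a)], site_atoms,
                  decoyA_atoms[-seq_len(half_a)])
  xyzA <- rbind(decoyA_xyz[seq_len(cutA), , drop = FALSE],
                site_xyz,
                decoyA_xyz[-seq_len(cutA), , drop = FALSE])
  if (!is.null(cage_xyz) && nrow(cage_xyz) > 0) {
    fill <- filler_residues(cage_xyz, palette[c("GLY", "SER", "ASP")])
    resA_names <- c(resA_names, fill$res_names)
    resA_atoms <- c(resA_atoms, fill$res_atoms)
    xyzA <- rbind(xyzA, cage_xyz)
  }
  atomsA <- build_atoms_df(resA_names, resA_atoms, xyzA)
  A <- new_protein_structure(sprintf("SYNA%03d", seed %% 1000), atomsA,
                             provenance = list(generator = "synthetic",
                                               seed = seed, role = "site carrier A",
                                               placement = placement))
  site_atom_idx_A <- cutA + seq_len(n_site)
  site_resno_A <- unique(atomsA$resno[site_atom_idx_A])

  # --- assemble B: first-half decoys, stretch copy, rest ---
  half_b <- n_residues_b %/% 2L
  cutB <- sum(lengths(decoyB_atoms[seq_len(half_b)]))
  keepB <- seq_len(n_site)
  if (gap_edits > 0) {
    # delete interior atoms of the copy (never the first/last, so the
    # alignment stays a single segment with internal gaps)
    deletable <- 2:(n_site - 1)
    drop <- sort(sample(deletable, min(gap_edits, length(deletable))))
    keepB <- setdiff(keepB, drop)
  }
  siteB_names <- site_names
  siteB_atoms <- site_atoms
  if (gap_edits > 0) {
    # rebuild per-residue atom-name lists after deletion
    res_of_atom <- rep(seq_along(site_atoms), lengths(site_atoms))
    offs <- c(0, cumsum(lengths(site_atoms)))
    siteB_atoms <- lapply(seq_along(site_atoms), function(r) {
      keep_in_res <- keepB[res_of_atom[keepB] == r] - offs[r]
      site_atoms[[r]][keep_in_res]
    })
    names(siteB_atoms) <- site_names
    nonempty <- lengths(siteB_atoms) > 0
    siteB_atoms <- siteB_atoms[nonempty]
    siteB_names <- siteB_names[nonempty]
  }
  resB_names <- c(decoyB_names[seq_len(half_b)], siteB_names,
                  decoyB_names[-seq_len(half_b)])
  resB_atoms <- c(decoyB_atoms[seq_len(half_b)], siteB_atoms,
                  decoyB_atoms[-seq_len(half_b)])
  xyzB <- rbind(decoyB_xyz[seq_len(cutB), , drop = FALSE],
                siteB_xyz[keepB, , drop = FALSE],
                decoyB_xyz[-seq_len(cutB), , drop = FALSE])
  atomsB <- build_atoms_df(resB_names, resB_atoms, xyzB)
  B <- new_protein_structure(sprintf("SYNB%03d", seed %% 1000), atomsB,
                             provenance = list(generator = "synthetic",
                                               seed = seed, role = "site carrier B",
                                               placement = placement))
  site_atom_idx_B <- cutB + seq_along(keepB)
  site_resno_B <- unique(atomsB$resno[site_atom_idx_B])

  truth <- list(
    pairs = data.frame(atomA = site_atom_idx_A[keepB],
                       atomB = site_atom_idx_B),
    transform = invert_transform(plant), # maps the copy in B back onto A
    site_resno_A = site_resno_A,
    site_resno_B = site_resno_B,
    seed = seed
  )
  list(A = A, B = B, truth = truth)
}

#' Write a structure to a PDB file
#'
#' wwPDB-column-compliant ATOM records (via bio3d), with a REMARK line
#' recording the generator seed when the structure is synthetic. Round trips
#' through [read_pdb()] preserve names, numbering and coordinates to 3
#' decimals.
#'
#' @param structure A `protein_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atoms
  hdr <- character(0)
  if (!is.null(structure$provenance$seed))
    hdr <- sprintf("REMARK 999 SYNTHETIC STRUCTURE SEED %d",
                   as.integer(structure$provenance$seed))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  # fixed-column ATOM records (wwPDB v3.3): name in cols 13-16, left-padded
  # for 1-3 character names as usual
  fmt_name <- function(nm) ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                                  sprintf(" %-3s", nm))
  lines <- sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   at$serial %% 100000, fmt_name(at$name), "",
                   at$resid, at$chain, at$resno %% 10000, at$insert,
                   at$x, at$y, at$z, 1.00, 0.00, at$element)
  writeLines(lines, con)
  writeLines("TER", con)
  writeLines("END", con)
  invisible(path)
}

#' Plant several rigidly co-oriented sites in a pair of synthetic structures
#'
#' Emulates the situation where two proteins share several binding-site
#' segments that all superpose under ONE rigid transformation: thin surface
#' patches are generated at fixed residue ranges, carried verbatim by the
#' first structure, and copied into the second under a single random rigid
#' transform with small jitter. The decoy bodies of the two structures sit on
#' opposite faces of the patch plane so the matching transform cannot make
#' them interpenetrate. This is a SYNTHETIC stand-in used to exercise the
#' multi-segment / one-transform reporting path.
#'
#' @param seed Integer seed.
#' @param segment_resno List of integer vectors: the residue numbers of each
#'   shared segment (defaults to three segments at residues 84-86, 95-100
#'   and 125-128).
#' @param n_residues Total residues per structure (default 170).
#' @param jitter_sigma Per-coordinate jitter of the copies (default 0.1).
#' @param palette Residue templates.
#' @return List with `A`, `B`, and `truth` (per-segment atom index pairs,
#'   the planting transform, the seed).
#' @export
plant_multi_segment_pair <- function(seed = 1L,
                                     segment_resno = list(84:86, 95:100, 125:128),
                                     n_residues = 170L, jitter_sigma = 0.1,
                                     palette = residue_templates()) {
  set.seed(seed)
  seg_res <- sort(unique(unlist(segment_resno)))
  stopifnot(max(seg_res) <= n_residues)
  # decoy residue types are drawn from palettes whose side chains share no
  # atom-name token across the two structures, so spurious decoy-decoy
  # alignments score poorly and the shared segments rank at the top of the
  # suboptimal-alignment enumeration (as conserved sites do in real pairs)
  typesA <- sample(c("SER", "ASP"), n_residues, replace = TRUE)
  typesB <- sample(c("CYS", "THR"), n_residues, replace = TRUE)
  for (rr in segment_resno) {
    # lean segments: just enough atoms to be reportable, so the patch adds
    # little interior volume of its own
    tt <- sample(c("GLY", "ALA", "VAL"), length(rr), replace = TRUE)
    while (sum(lengths(palette[tt])) < 16) {
      k <- sample(length(tt), 1)
      tt[k] <- sample(c("VAL", "LEU"), 1)
    }
    typesA[rr] <- tt
    typesB[rr] <- tt
  }
  # thin patches on the z ~ 0 plane, spread in y
  k <- length(segment_resno)
  centers <- cbind(0, (seq_len(k) - (k + 1) / 2) * 30, 0)
  patches <- vector("list", k)
  for (i in seq_len(k)) {
    n_at <- sum(lengths(palette[typesA[segment_resno[[i]]]]))
    patches[[i]] <- atom_walk(n_at, start = centers[i, ], persistence = 0.3,
                              within_radius = max(7, sqrt(n_at / 0.25)),
                              center = centers[i, ], slab_half = 0.5,
                              obstacles = do.call(rbind, patches[seq_len(i - 1)]),
                              seed_label = seed)
  }
  patch_xyz <- do.call(rbind, patches)
  plant <- rigid_transform(rand_rotation(), c(300, -40, 80), check = FALSE)
  patchB_xyz <- apply_transform(plant, patch_xyz)
  if (jitter_sigma > 0)
    patchB_xyz <- patchB_xyz + matrix(rnorm(length(patchB_xyz), 0, jitter_sigma),
                                      ncol = 3)
  # decoy bodies on opposite faces of the patch plane
  decoy_res_A <- setdiff(seq_len(n_residues), seg_res)
  nA_dec <- sum(lengths(palette[typesA[decoy_res_A]]))
  nB_dec <- sum(lengths(palette[typesB[decoy_res_A]]))
  rA <- blob_radius(nA_dec)
  ctrA <- c(0, 0, -(rA + 7))
  decoyA_xyz <- atom_walk(nA_dec, start = ctrA, center = ctrA,
                          within_radius = rA, obstacles = patch_xyz,
                          persistence = 0.5, seed_label = seed)
  rB <- blob_radius(nB_dec)
  ctrB <- as.numeric(apply_transform(plant, c(0, 0, rB + 7)))
  decoyB_xyz <- atom_walk(nB_dec, start = ctrB, center = ctrB,
                          within_radius = rB, obstacles = patchB_xyz,
                          persistence = 0.5, seed_label = seed)
  assemble <- function(types, seg_xyz, decoy_xyz, id_fmt) {
    res_atoms <- palette[types]
    xyz <- matrix(NA_real_, sum(lengths(res_atoms)), 3)
    seg_ptr <- 1L; dec_ptr <- 1L; row <- 1L
    seg_members <- integer(0)
    for (r in seq_along(types)) {
      na <- lengths(res_atoms)[r]
      if (r %in% seg_res) {
        xyz[row:(row + na - 1L), ] <- seg_xyz[seg_ptr:(seg_ptr + na - 1L), ]
        seg_members <- c(seg_members, row:(row + na - 1L))
        seg_ptr <- seg_ptr + na
      } else {
        xyz[row:(row + na - 1L), ] <- decoy_xyz[dec_ptr:(dec_ptr + na - 1L), ]
        dec_ptr <- dec_ptr + na
      }
      row <- row + na
    }
    at <- build_atoms_df(types, res_atoms, xyz)
    list(st = new_protein_structure(sprintf(id_fmt, seed %% 1000), at,
                                    provenance = list(generator = "synthetic",
                                                      seed = seed,
                                                      role = "multi-segment pair")),
         seg_members = seg_members)
  }
  # patches are stored in residue order, matching the assembly traversal
  ordA <- order(unlist(lapply(seq_len(k), function(i)
    rep(segment_resno[[i]][1], nrow(patches[[i]])))))
  segA <- assemble(typesA, patch_xyz[ordA, , drop = FALSE], decoyA_xyz, "SYNM%03dA")
  segB <- assemble(typesB, patchB_xyz[ordA, , drop = FALSE], decoyB_xyz, "SYNM%03dB")
  truth <- list(
    pairs = data.frame(atomA = segA$seg_members, atomB = segB$seg_members),
    transform = invert_transform(plant), # maps the copies in B back onto A
    segments = segment_resno,
    seed = seed
  )
  list(A = segA$st, B = segB$st, truth = truth)
}
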