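# Independent oracles and small fixture builders shared across the tests.

mkseq <- function(tokens) {
  structure(list(tokens = tokens, atom_index = seq_along(tokens)),
            class = "atom_sequence")
}

# Brute-force local alignment score by memoised suffix recursion over
# explicit path choices (match / gap in either sequence / stop), maximised
# over every start cell -- an independent formulation of the same problem
# the C++ matrix DP solves.
sw_oracle <- function(a, b, match = 1, gap = -2) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n + 1, m + 1)
  suf <- function(i, j) {
    if (i > n || j > m) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- 0
    if (a[i] == b[j]) best <- max(best, match + suf(i + 1, j + 1))
    best <- max(best, gap + suf(i + 1, j), gap + suf(i, j + 1))
    memo[i, j] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) best <- max(best, suf(i, j))
  best
}

# Exhaustive point-by-point lattice classification (0 empty, 1 surface,
# 2 interior), x-fastest linearisation like the production grid.
grid_oracle_labels <- function(xyz, origin, dims, step = 1, radius = 2) {
  prot <- array(FALSE, dims)
  for (iz in seq_len(dims[3])) for (iy in seq_len(dims[2])) for (ix in seq_len(dims[1])) {
    p <- origin + step * c(ix - 1, iy - 1, iz - 1)
    d2 <- min(rowSums(sweep(xyz, 2, p)^2))
    prot[ix, iy, iz] <- d2 <= radius^2
  }
  lab <- array(0L, dims)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (iz in seq_len(dims[3])) for (iy in seq_len(dims[2])) for (ix in seq_len(dims[1])) {
    if (!prot[ix, iy, iz]) next
    interior <- TRUE
    for (k in 1:6) {
      q <- c(ix, iy, iz) + nb[k, ]
      if (any(q < 1) || any(q > dims) || !prot[q[1], q[2], q[3]]) {
        interior <- FALSE
        break
      }
    }
    lab[ix, iy, iz] <- if (interior) 2L else 1L
  }
  as.integer(lab)
}

# All maximal qualifying windows of a matched segment, by quadratic
# enumeration of every subsegment.
candidate_oracle <- function(sA, sB, min_pairs = 15, min_fraction = 2 / 3) {
  n <- length(sA)
  qual <- function(i, j) {
    len <- j - i + 1
    len >= min_pairs &&
      sum(sA[i:j]) >= min_fraction * len &&
      sum(sB[i:j]) >= min_fraction * len
  }
  wins <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j >= i && qual(i, j)) wins[[length(wins) + 1]] <- c(i, j)
  }
  if (length(wins) == 0) return(wins)
  keep <- vapply(seq_along(wins), function(k) {
    !any(vapply(wins, function(w)
      w[1] <= wins[[k]][1] && w[2] >= wins[[k]][2] &&
        (w[1] < wins[[k]][1] || w[2] > wins[[k]][2]), logical(1)))
  }, logical(1))
  unique(wins[keep])
}

mk_surface_annotation <- function(flags) {
  structure(list(is_surface_atom = flags, atom_surface_radius = 1.5),
            class = "surface_annotation")
}

# a matched_segment of n all-matched columns (orig defaults contiguous)
mk_matched_segment <- function(n, orig = seq_len(n)) {
  structure(list(columns = data.frame(posA = seq_len(n), posB = seq_len(n),
                                      orig = orig),
                 gap_count = max(orig) - n, score = n),
            class = "matched_segment")
}

mk_candidate <- function(A, B, orig = seq_len(nrow(A))) {
  n <- nrow(A)
  structure(list(columns = data.frame(posA = seq_len(n), posB = seq_len(n),
                                      orig = orig, atomA = seq_len(n),
                                      atomB = seq_len(n)),
                 surface_fraction_A = 1, surface_fraction_B = 1,
                 n_pairs = n, gap_count = 0L),
            class = "candidate_site")
}

rand_rotation_matrix <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M)
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# instance of k pairs where a planted transform achieves bottleneck <= frac*d
planted_pair_instance <- function(k, d = 1.5, frac = 0.95, spread = 12) {
  A <- matrix(runif(3 * k, 0, spread), k, 3)
  R <- rand_rotation_matrix()
  tt <- runif(3, -20, 20)
  delta <- matrix(rnorm(3 * k), k, 3)
  delta <- delta / sqrt(rowSums(delta^2)) * runif(k, 0, frac * d)
  # B such that R %*% B + t = A + delta
  B <- sweep(A + delta, 2, tt) %*% R # == t(t(R) %*% t(A + delta - t))
  planted <- rigid_transform(R, tt, check = FALSE)
  list(A = A, B = B, transform = planted,
       bottleneck = bottleneck_under_transform(planted, A, B))
}

# hand-written 3-residue (GLY-ALA-GLY) PDB with chains A and B and one
# altloc pair; column layout per wwPDB v3.3
fixture_pdb_text <- function() {
  c(
    "HEADER    TEST FIXTURE",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA AALA A   2       3.988   2.839   0.000  0.60  0.00           C",
    "ATOM      7  CA BALA A   2       4.100   2.900   0.100  0.40  0.00           C",
    "ATOM      8  C   ALA A   2       5.504   2.693   0.000  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       6.030   1.583   0.000  1.00  0.00           O",
    "ATOM     10  CB  ALA A   2       3.560   3.663   1.217  1.00  0.00           C",
    "ATOM     11  N   GLY A   3       6.189   3.829   0.000  1.00  0.00           N",
    "ATOM     12  CA  GLY A   3       7.645   3.836   0.000  1.00  0.00           C",
    "ATOM     13  C   GLY A   3       8.211   5.247   0.000  1.00  0.00           C",
    "ATOM     14  O   GLY A   3       7.471   6.234   0.000  1.00  0.00           O",
    "TER",
    "ATOM     15  N   GLY B   1      20.000   0.000   0.000  1.00  0.00           N",
    "ATOM     16  CA  GLY B   1      21.458   0.000   0.000  1.00  0.00           C",
    "ATOM     17  C   GLY B   1      22.009   1.420   0.000  1.00  0.00           C",
    "ATOM     18  O   GLY B   1      21.251   2.390   0.000  1.00  0.00           O",
    "HETATM   19  O   HOH B 101      25.000   5.000   5.000  1.00  0.00           O",
    "END"
  )
}

write_fixture_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_text(), path)
  path
}
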