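#' Rigid-transform constructor
#'
#' A proper rotation (orthonormal, determinant +1) plus a translation,
#' applied to coordinates as `x %*% t(R) + t`.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @param check Validate orthonormality/determinant (tolerance 1e-9).
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            check = TRUE) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (check) {
    stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3,
              max(abs(crossprod(rotation) - diag(3))) < 1e-9,
              abs(det(rotation) - 1) < 1e-9)
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform`.
#' @param x An n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates, same shape as `x`.
#' @export
apply_transform <- function(transform, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  sweep(x %*% t(transform$R), 2, transform$t, "+")
}

#' Inverse of a rigid transform
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$t), check = FALSE)
}

#' Compose two rigid transforms (first `g`, then `f`)
#' @param f,g `rigid_transform`s.
#' @return The composite `rigid_transform`.
#' @export
compose_transforms <- function(f, g) {
  rigid_transform(f$R %*% g$R, as.numeric(f$R %*% g$t) + f$t, check = FALSE)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Returns the proper-rotation rigid transform minimising the RMSD of
#' `pointsB` onto `pointsA`; a reflection is never returned (the smallest
#' singular direction is flipped when the raw solution is improper).
#'
#' @param pointsA,pointsB n x 3 matrices of paired points, n >= 3, not all
#'   collinear.
#' @param weights Optional non-negative per-pair weights.
#' @return A `rigid_transform` `T` with `apply_transform(T, pointsB)`
#'   approximating `pointsA`.
#' @export
kabsch_superpose <- function(pointsA, pointsB, weights = NULL) {
  A <- as.matrix(pointsA); B <- as.matrix(pointsB)
  stopifnot(ncol(A) == 3, ncol(B) == 3, nrow(A) == nrow(B))
  if (nrow(A) < 3)
    sm_error("sitematch_error_degenerate_points",
             "rigid superposition needs at least 3 point pairs")
  w <- if (is.null(weights)) rep(1, nrow(A)) else as.numeric(weights)
  w <- w / sum(w)
  ca <- colSums(A * w); cb <- colSums(B * w)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Bc * w, Ac)
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    sm_error("sitematch_error_degenerate_points",
             "collinear or coincident points: rotation underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ca - as.numeric(R %*% cb))
}

#' Bottleneck distance of paired points under a transform
#'
#' The maximum over pairs of the Euclidean distance between `pairsA[i, ]` and
#' the transformed `pairsB[i, ]` -- the quantity the matching stage bounds by
#' `(1 + eps) * d`.
#'
#' @param transform A `rigid_transform` applied to `pairsB`.
#' @param pairsA,pairsB n x 3 matrices of paired points, n >= 1.
#' @return The bottleneck distance (Angstrom).
#' @export
bottleneck_under_transform <- function(transform, pairsA, pairsB) {
  A <- as.matrix(pairsA); B <- as.matrix(pairsB)
  if (nrow(A) != nrow(B))
    sm_error("sitematch_error_length_mismatch", "paired point lists differ in length")
  max(pair_distances(transform, A, B))
}

pair_distances <- function(transform, A, B) {
  d <- A - apply_transform(transform, B)
  sqrt(rowSums(d * d))
}

# Center of the (approximate) minimal enclosing ball of a point set, by the
# Badoiu-Clarkson iteration: repeatedly step towards the farthest point with
# step 1/(k+1). Error after k iterations is O(radius/k).
meb_center <- function(P, iters = 600L) {
  c0 <- colMeans(P)
  for (k in seq_len(iters)) {
    d2 <- rowSums(sweep(P, 2, c0)^2)
    f <- which.max(d2)
    c0 <- c0 + (P[f, ] - c0) / (k + 1)
  }
  c0
}

# Best translation for a fixed rotation: the bottleneck objective
# max_i | A_i - (R B_i + t) | is minimised by the center of the minimal
# enclosing ball of the residuals A_i - R B_i.
best_translation <- function(R, A, B, iters = 600L) {
  res <- A - B %*% t(R)
  if (nrow(A) == 1) return(as.numeric(res))
  meb_center(res, iters)
}

#' Refine a rigid transform towards the minimum-bottleneck transform
#'
#' Seeded refinement used by the subsegment search when the least-squares
#' transform alone does not meet the `(1 + eps) d` bound. For any candidate
#' rotation the optimal translation is computed exactly (center of the
#' minimal enclosing ball of the residuals); rotations are explored by
#' iteratively reweighted least squares (weights concentrating on the worst
#' pairs) followed by an axis-angle pattern search around the incumbent with
#' angular step `eps * d / r_max` (`r_max` = largest distance of a point of
#' `pairsB` from its centroid), halving until convergence. The result is
#' never worse than the seed.
#'
#' @param seed A `rigid_transform`, typically from [kabsch_superpose()].
#' @param pairsA,pairsB n x 3 matrices of paired points.
#' @param params A [match_parameters()].
#' @param target Optional bottleneck value at which to stop early (the
#'   subsegment search passes `(1 + eps) d`; `NULL` refines to convergence).
#' @return A `rigid_transform` whose bottleneck is <= the seed's.
#' @export
refine_transform <- function(seed, pairsA, pairsB, params = match_parameters(),
                             target = NULL) {
  A <- as.matrix(pairsA); B <- as.matrix(pairsB)
  best <- seed
  best_bn <- bottleneck_under_transform(seed, A, B)
  if (best_bn == 0) return(seed)
  done <- function() !is.null(target) && best_bn <= target
  consider <- function(R) {
    t1 <- best_translation(R, A, B)
    cand <- rigid_transform(R, t1, check = FALSE)
    bn <- bottleneck_under_transform(cand, A, B)
    if (bn < best_bn) { best <<- cand; best_bn <<- bn; TRUE } else FALSE
  }
  consider(seed$R)
  # iteratively reweighted least squares: upweight the worst pairs
  if (nrow(A) >= 3 && !done()) {
    Rw <- seed$R
    for (it in 1:10) {
      di <- pair_distances(rigid_transform(Rw, best_translation(Rw, A, B),
                                           check = FALSE), A, B)
      tau <- max(median(di), 1e-6)
      w <- exp((di - max(di)) / tau)
      fit <- tryCatch(kabsch_superpose(A, B, weights = w / sum(w)),
                      error = function(e) NULL)
      if (is.null(fit)) break
      Rw <- fit$R
      consider(Rw)
      if (best_bn == 0 || done()) return(best)
    }
  }
  # axis-angle pattern search around the incumbent rotation; step eps*d/rmax
  rmax <- max(sqrt(rowSums(sweep(B, 2, colMeans(B))^2)), 1e-6)
  delta <- min(max(params$eps * params$d / rmax, 1e-4), 0.2)
  dirs <- rbind(diag(3), -diag(3), expand_grid_dirs())
  delta_min <- delta / 16
  evals <- 0L
  while (delta >= delta_min && evals < 600L && !done()) {
    improved <- FALSE
    for (k in seq_len(nrow(dirs))) {
      for (mult in c(1, 3)) {
        Rp <- axis_angle_rotation(dirs[k, ], delta * mult) %*% best$R
        evals <- evals + 1L
        if (consider(Rp)) improved <- TRUE
        if (best_bn == 0 || done()) break
      }
      if (best_bn == 0 || done()) break
    }
    if (!improved) delta <- delta / 2
    if (best_bn == 0) break
  }
  best
}

expand_grid_dirs <- function() {
  g <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  unname(g / sqrt(3))
}

axis_angle_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Matching parameters for the rigid-superposition stage
#'
#' @param d Distance threshold in Angstrom under which a matched atom pair
#'   counts as superposed (default 1.5, a user parameter).
#' @param eps Approximation slack: accepted windows may have bottleneck up to
#'   `(1 + eps) * d` (default 0.1).
#' @param min_pairs Minimum matched pairs per reported window (default 15).
#' @return A `match_parameters` list.
#' @export
match_parameters <- function(d = 1.5, eps = 0.1, min_pairs = 15L) {
  stopifnot(d > 0, eps > 0, eps < 1, min_pairs >= 1)
  structure(list(d = d, eps = eps, min_pairs = as.integer(min_pairs)),
            class = "match_parameters")
}

# Try to certify a window: accept when a transform with bottleneck
# <= (1+eps) d is found. If the least-squares RMSD already exceeds d the
# window is provably infeasible (the Kabsch RMSD is a lower bound on the
# RMSD of any rigid transform, and RMSD(T) <= bottleneck(T)), so the
# refinement is only ever attempted on windows that could qualify.
test_window <- function(A, B, params) {
  seed <- tryCatch(kabsch_superpose(A, B), error = function(e) NULL)
  if (is.null(seed)) return(NULL)
  di <- pair_distances(seed, A, B)
  bn <- max(di)
  lim <- (1 + params$eps) * params$d
  if (bn <= lim) return(list(transform = seed, bottleneck = bn))
  if (sqrt(mean(di^2)) > params$d) return(NULL)
  ref <- refine_transform(seed, A, B, params, target = lim)
  bn <- bottleneck_under_transform(ref, A, B)
  if (bn <= lim) list(transform = ref, bottleneck = bn) else NULL
}

#' Find rigidly matching subsegments of a candidate site
#'
#' Searches the contiguous column windows of a candidate for windows of at
#' least `min_pairs` pairs that admit a single rigid transform bringing every
#' matched pair within `(1 + eps) * d`. Every window start is seeded at width
#' `min_pairs`, accepted windows are greedily extended right then left while
#' the bound holds, nested windows are dropped, and overlapping accepted
#' windows are merged when their union still passes. Approximation contract:
#' any window of >= `min_pairs` pairs for which some transform achieves
#' bottleneck <= `d` contains an accepted seed, so a covering window is
#' always reported (possibly at bottleneck up to `(1 + eps) d`).
#'
#' @param candidate A `candidate_site` (see [enumerate_candidates()]).
#' @param structA,structB The two `protein_structure`s (or coordinate
#'   matrices indexed by the candidate's `atomA`/`atomB` columns).
#' @param params A [match_parameters()].
#' @return List of `match_result`s: `range` (first/last candidate column),
#'   `transform`, `pair_distances`, `bottleneck`, `n_pairs`, `gap_count`.
#' @export
find_matching_subsegments <- function(candidate, structA, structB,
                                      params = match_parameters()) {
  stopifnot(inherits(candidate, "candidate_site"))
  xyzA <- if (inherits(structA, "protein_structure")) coords(structA) else as.matrix(structA)
  xyzB <- if (inherits(structB, "protein_structure")) coords(structB) else as.matrix(structB)
  A <- xyzA[candidate$columns$atomA, , drop = FALSE]
  B <- xyzB[candidate$columns$atomB, , drop = FALSE]
  n <- nrow(A)
  k0 <- max(params$min_pairs, 3L)
  if (n < k0) return(list())
  accepted <- list()
  covered_upto <- 0L
  s <- 1L
  while (s <= n - k0 + 1L) {
    e <- s + k0 - 1L
    if (e <= covered_upto) { s <- s + 1L; next }
    hit <- test_window(A[s:e, , drop = FALSE], B[s:e, , drop = FALSE], params)
    if (is.null(hit)) { s <- s + 1L; next }
    l <- s
    # extend right, then left, re-certifying the whole window each step
    while (e < n) {
      h2 <- test_window(A[l:(e + 1L), , drop = FALSE], B[l:(e + 1L), , drop = FALSE], params)
      if (is.null(h2)) break
      e <- e + 1L; hit <- h2
    }
    while (l > 1L) {
      h2 <- test_window(A[(l - 1L):e, , drop = FALSE], B[(l - 1L):e, , drop = FALSE], params)
      if (is.null(h2)) break
      l <- l - 1L; hit <- h2
    }
    accepted[[length(accepted) + 1L]] <- list(l = l, e = e, hit = hit)
    covered_upto <- max(covered_upto, e)
    s <- s + 1L
  }
  accepted <- merge_windows(accepted, A, B, params)
  lapply(accepted, function(w) {
    idx <- w$l:w$e
    new_match_result(candidate, w$l, w$e, w$hit$transform,
                     pair_distances(w$hit$transform,
                                    A[idx, , drop = FALSE], B[idx, , drop = FALSE]))
  })
}

merge_windows <- function(wins, A, B, params) {
  if (length(wins) < 2) return(wins)
  # drop nested
  keep <- vapply(seq_along(wins), function(k) {
    !any(vapply(wins, function(w) {
      w$l <= wins[[k]]$l && w$e >= wins[[k]]$e &&
        (w$l < wins[[k]]$l || w$e > wins[[k]]$e)
    }, logical(1)))
  }, logical(1))
  wins <- wins[keep]
  # attempt union of overlapping windows; keep both when the union fails
  repeat {
    merged <- FALSE
    if (length(wins) >= 2) {
      ord <- order(vapply(wins, `[[`, integer(1), "l"))
      wins <- wins[ord]
      for (k in seq_len(length(wins) - 1L)) {
        a <- wins[[k]]; b <- wins[[k + 1L]]
        if (b$l <= a$e + 1L && !(a$l <= b$l && a$e >= b$e)) {
          l <- min(a$l, b$l); e <- max(a$e, b$e)
          hit <- test_window(A[l:e, , drop = FALSE], B[l:e, , drop = FALSE], params)
          if (!is.null(hit)) {
            wins[[k]] <- list(l = l, e = e, hit = hit)
            wins[[k + 1L]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
    }
    if (!merged) break
  }
  wins
}

new_match_result <- function(candidate, l, e, transform, dists) {
  idx <- l:e
  structure(list(
    range = c(l, e),
    columns = candidate$columns[idx, , drop = FALSE],
    transform = transform,
    pair_distances = dists,
    bottleneck = max(dists),
    n_pairs = length(idx),
    gap_count = {
      orig <- candidate$columns$orig[idx]
      (orig[length(orig)] - orig[1]) - (length(orig) - 1L)
    }
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", x$n_pairs, " pairs, bottleneck ",
      round(x$bottleneck, 3), " A, ", x$gap_count, " gaps\n", sep = "")
  invisible(x)
}

#' Serialise a rigid transform as a 3 x 4 row-major matrix string
#' @param transform A `rigid_transform`.
#' @param digits Decimal places (default 6).
#' @return Character vector of 3 rows, `"r11 r12 r13 | t1"` style values.
#' @export
format_transform <- function(transform, digits = 6) {
  m <- cbind(transform$R, transform$t)
  apply(round(m, digits), 1, paste, collapse = " ")
}
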