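test_that("generation is deterministic and respects spacing", {
  s1 <- generate_protein(30, seed = 1)
  s2 <- generate_protein(30, seed = 1)
  expect_identical(s1$atoms, s2$atoms)
  d <- dist(coords(s1))
  expect_gte(min(d), 2.5)
})

test_that("residue templates drive the atom count", {
  ala_only <- residue_templates()["ALA"]
  st <- generate_protein(30, seed = 2, palette = ala_only)
  expect_equal(nrow(st$atoms), 150) # 5 atoms per residue
  expect_equal(unique(st$atoms$resid), "ALA")
  expect_identical(st$atoms$name[1:5], c("N", "CA", "C", "O", "CB"))
})

test_that("planted stretches are congruent up to the requested jitter", {
  ps0 <- plant_shared_site(seed = 3, jitter_sigma = 0, gap_edits = 0)
  pr <- ps0$truth$pairs
  bn0 <- bottleneck_under_transform(ps0$truth$transform,
                                    coords(ps0$A)[pr$atomA, ],
                                    coords(ps0$B)[pr$atomB, ])
  expect_lt(bn0, 1e-9)

  ok <- 0
  for (s in 1:10) {
    ps <- plant_shared_site(seed = s, jitter_sigma = 0.2)
    pr <- ps$truth$pairs
    tr <- kabsch_superpose(coords(ps$A)[pr$atomA, ], coords(ps$B)[pr$atomB, ])
    if (bottleneck_under_transform(tr, coords(ps$A)[pr$atomA, ],
                                   coords(ps$B)[pr$atomB, ]) < 1.5) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("gap edits appear as alignment gap columns inside the stretch", {
  ps <- plant_shared_site(seed = 5, jitter_sigma = 0, gap_edits = 2)
  tokA <- ps$A$atoms$name[ps$A$atoms$resno %in% ps$truth$site_resno_A]
  tokB <- ps$B$atoms$name[ps$B$atoms$resno %in% ps$truth$site_resno_B]
  expect_equal(length(tokA) - length(tokB), 2)
  seg <- smith_waterman(mkseq(tokA), mkseq(tokB))
  expect_equal(seg$n_gaps, 2)
  expect_equal(seg$n_matched, length(tokB))
})

test_that("surface placement exposes the stretch on both carriers", {
  for (s in 1:3) {
    ps <- plant_shared_site(seed = s)
    gA <- build_labeled_grid(ps$A)
    gB <- build_labeled_grid(ps$B)
    fA <- mean(annotate_surface_atoms(ps$A, gA)$is_surface_atom[ps$truth$pairs$atomA])
    fB <- mean(annotate_surface_atoms(ps$B, gB)$is_surface_atom[ps$truth$pairs$atomB])
    expect_gte(fA, 2 / 3)
    expect_gte(fB, 2 / 3)
  }
})

test_that("buried placement hides the stretch in the first carrier only", {
  ps <- plant_shared_site(seed = 4, placement = "buried")
  gA <- build_labeled_grid(ps$A)
  gB <- build_labeled_grid(ps$B)
  fA <- mean(annotate_surface_atoms(ps$A, gA)$is_surface_atom[ps$truth$pairs$atomA])
  fB <- mean(annotate_surface_atoms(ps$B, gB)$is_surface_atom[ps$truth$pairs$atomB])
  expect_lt(fA, 2 / 3)
  expect_gte(fB, 2 / 3)
})

test_that("multi-segment pairs share one transform across all segments", {
  mp <- plant_multi_segment_pair(seed = 2)
  pr <- mp$truth$pairs
  tr <- kabsch_superpose(coords(mp$A)[pr$atomA, ], coords(mp$B)[pr$atomB, ])
  expect_lt(bottleneck_under_transform(tr, coords(mp$A)[pr$atomA, ],
                                       coords(mp$B)[pr$atomB, ]), 0.6)
  # the planted residues live at the advertised residue numbers on both sides
  for (rr in mp$truth$segments) {
    expect_true(all(rr %in% mp$A$atoms$resno[pr$atomA]))
    expect_true(all(rr %in% mp$B$atoms$resno[pr$atomB]))
  }
})

test_that("disjoint atom vocabularies admit no alignment at all", {
  pal <- sitematch:::disjoint_palettes()
  a <- generate_protein(12, seed = 6, palette = pal$A)
  b <- generate_protein(12, seed = 7, palette = pal$B)
  seg <- smith_waterman(extract_atom_sequence(a), extract_atom_sequence(b))
  expect_equal(seg$score, 0)
  expect_equal(nrow(seg$columns), 0)
})
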