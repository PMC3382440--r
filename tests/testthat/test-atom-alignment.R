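test_that("local alignment matches the hand-checked cases", {
  s <- smith_waterman(mkseq(c("N", "CA", "C", "O", "CB")),
                      mkseq(c("N", "CA", "C", "O", "CB")))
  expect_equal(s$score, 5)
  expect_equal(s$n_matched, 5)
  expect_equal(s$n_gaps, 0)

  s <- smith_waterman(mkseq("CA"), mkseq("CB"))
  expect_equal(s$score, 0) # mismatch forbidden: no legal column
  expect_equal(nrow(s$columns), 0)

  s <- smith_waterman(mkseq(c("N", "CA", "C", "O", "CB", "CG", "CD")),
                      mkseq(c("N", "CA", "C", "CB", "CG", "CD")))
  expect_equal(s$score, 4) # 6 matches - one 1-atom gap
  expect_equal(s$n_matched, 6)
  expect_equal(s$n_gaps, 1)
})

test_that("score equals brute-force enumeration on random token pairs", {
  set.seed(42)
  alphabet <- c("N", "CA", "C", "O", "CB")
  for (rep in 1:60) {
    a <- sample(alphabet, sample(1:12, 1), replace = TRUE)
    b <- sample(alphabet, sample(1:12, 1), replace = TRUE)
    s <- smith_waterman(mkseq(a), mkseq(b))
    expect_equal(s$score, sw_oracle(a, b))
    # every matched column pairs identical tokens; stored score recomputes
    m <- !is.na(s$columns$posA) & !is.na(s$columns$posB)
    if (any(m)) expect_identical(a[s$columns$posA[m]], b[s$columns$posB[m]])
    expect_equal(s$score, sum(m) - 2 * sum(!m))
  }
})

test_that("appending tokens to both sequences never decreases the score", {
  set.seed(7)
  alphabet <- c("N", "CA", "C", "O")
  for (rep in 1:20) {
    a <- sample(alphabet, 8, replace = TRUE)
    b <- sample(alphabet, 8, replace = TRUE)
    s0 <- smith_waterman(mkseq(a), mkseq(b))$score
    ext <- sample(alphabet, 3, replace = TRUE)
    s1 <- smith_waterman(mkseq(c(a, ext)), mkseq(c(b, ext)))$score
    expect_gte(s1, s0)
  }
})

test_that("suboptimal enumeration recovers disjoint planted repeats", {
  set.seed(11)
  r1 <- paste0("R", 1:20)
  r2 <- paste0("S", 1:20)
  fillA <- paste0("FA", 1:15)
  fillB <- paste0("FB", 1:15)
  a <- c(r1, fillA, r2)
  b <- c(fillB[1:7], r1, fillB[8:15], r2)
  segs <- suboptimal_alignments(mkseq(a), mkseq(b), min_matches = 15)
  expect_length(segs, 2)
  expect_true(all(vapply(segs, `[[`, integer(1), "n_matched") == 20))
  # matched cells of the two segments are disjoint
  cells <- lapply(segs, function(s) {
    m <- !is.na(s$columns$posA) & !is.na(s$columns$posB)
    paste(s$columns$posA[m], s$columns$posB[m])
  })
  expect_length(intersect(cells[[1]], cells[[2]]), 0)
  # sorted by score descending
  expect_false(is.unsorted(rev(vapply(segs, `[[`, numeric(1), "score"))))
})

test_that("suboptimal enumeration respects the minimum-match threshold", {
  a <- c("N", "CA", "C", "O", "CB")
  expect_length(suboptimal_alignments(mkseq(a), mkseq(a), min_matches = 6), 0)
  motif <- paste0("M", 1:15)
  a2 <- c(paste0("XA", 1:6), motif)
  b2 <- c(motif, paste0("XB", 1:6))
  segs <- suboptimal_alignments(mkseq(a2), mkseq(b2), min_matches = 15)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$n_matched, 15)
})

test_that("matched_columns keeps order and annotates gaps", {
  s <- smith_waterman(mkseq(c("N", "CA", "C", "O", "CB", "CG", "CD")),
                      mkseq(c("N", "CA", "C", "CB", "CG", "CD")))
  ms <- matched_columns(s)
  expect_equal(nrow(ms$columns), 6)
  expect_equal(ms$gap_count, 1)
  expect_false(is.unsorted(ms$columns$posA, strictly = TRUE))
  expect_false(is.unsorted(ms$columns$posB, strictly = TRUE))
  # the gap sits between matched columns 3 and 4 (original columns 3, 5)
  expect_equal(sitematch:::window_gap_count(ms, 1, 6), 1)
  expect_equal(sitematch:::window_gap_count(ms, 4, 6), 0)

  all_match <- smith_waterman(mkseq(c("N", "CA")), mkseq(c("N", "CA")))
  ms2 <- matched_columns(all_match)
  expect_equal(nrow(ms2$columns), 2)
  expect_equal(ms2$gap_count, 0)
})
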