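mk_report <- function(idA = "P1", idB = "P2", resA = 84:86, resB = resA,
                      gaps = 0L) {
  structure(list(proteinA_id = idA, proteinB_id = idB,
                 matched_atoms = data.frame(name = "CA",
                                            resno_A = resA, resno_B = resB),
                 gap_count = as.integer(gaps)),
            class = "site_pair_report")
}

test_that("confirmation needs the minimum number of shared residues", {
  ref <- reference_site("P1", residues = 84:87)
  expect_true(confirm_site(mk_report(resA = 84:86), ref)) # 3 shared >= 2
  expect_false(confirm_site(mk_report(resA = c(84, 200, 201)), ref)) # 1 shared
  expect_true(confirm_site(mk_report(resA = c(84, 200, 201)), ref,
                           min_shared_residues = 1))
  expect_false(confirm_site(mk_report(resA = 300:305), ref,
                            min_shared_residues = 1))
  expect_error(confirm_site(mk_report(), reference_site("OTHER", 1:5)),
               class = "sitematch_error_id_mismatch")
})

test_that("confirmation can read either side of a prediction", {
  ref_b <- reference_site("P2", residues = 10:14)
  expect_true(confirm_site(mk_report(resB = 10:12), ref_b))
})

test_that("precision and recall follow their definitions", {
  refs <- lapply(1:4, function(k) reference_site("P1", residues = (10 * k):(10 * k + 3)))
  # predictions identical to two of the references
  preds <- list(mk_report(resA = 10:13), mk_report(resA = 20:23),
                mk_report(resA = 300:303))
  ev <- precision_recall(preds, refs)
  expect_equal(ev$n_output, 3)
  expect_equal(ev$n_confirmed, 2)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 4)

  perfect <- precision_recall(list(mk_report(resA = 10:13)),
                              refs[1])
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  expect_warning(none <- precision_recall(list(), refs))
  expect_equal(none$precision, 0)
  expect_equal(none$recall, 0)
})

test_that("reference sites need more than two residues to count", {
  refs <- list(reference_site("P1", residues = 1:2), # too short: excluded
               reference_site("P1", residues = 10:13))
  ev <- precision_recall(list(mk_report(resA = 10:13)), refs)
  expect_equal(ev$n_reference, 1)
  expect_equal(ev$recall, 1)
})

test_that("precision and recall are non-increasing in the sharing threshold", {
  refs <- lapply(1:3, function(k) reference_site("P1", residues = (10 * k):(10 * k + 4)))
  preds <- list(mk_report(resA = c(10, 11, 200)), mk_report(resA = 20:24),
                mk_report(resA = c(30, 400, 401)))
  prev_p <- Inf; prev_r <- Inf
  for (k in 1:4) {
    ev <- suppressWarnings(precision_recall(preds, refs, min_shared_residues = k))
    expect_lte(ev$precision, prev_p)
    expect_lte(ev$recall, prev_r)
    prev_p <- ev$precision; prev_r <- ev$recall
  }
})

test_that("gap histogram buckets and sums are exact", {
  h <- gap_histogram(list(mk_report(gaps = 0), mk_report(gaps = 0),
                          mk_report(gaps = 7)))
  expect_equal(unname(h["0"]), 2L)
  expect_equal(unname(h[">5"]), 1L)
  expect_equal(sum(h), 3L)
  expect_equal(sum(gap_histogram(list())), 0L)
  set.seed(44)
  gaps <- sample(0:9, 100, replace = TRUE)
  h2 <- gap_histogram(lapply(gaps, function(g) mk_report(gaps = g)))
  expect_equal(sum(h2), 100L)
  expect_equal(unname(h2[as.character(0:5)]),
               as.integer(table(factor(gaps[gaps <= 5], levels = 0:5))))
  expect_equal(unname(h2[">5"]), sum(gaps > 5))
})

test_that("reference tables round-trip through the TSV format", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tchain\tresidues",
               "SYNA001\tA\t19,20,21,22",
               "SYNB001\tA\t5,6,7"), path)
  refs <- read_reference_sites(path)
  expect_length(refs, 2)
  expect_equal(refs[[1]]$protein_id, "SYNA001")
  expect_equal(refs[[1]]$residues$resno, 19:22)
  expect_equal(refs[[2]]$residues$chain, rep("A", 3))
})
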