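test_that("PDB parsing keeps file order, resolves altlocs, filters chains", {
  path <- write_fixture_pdb()
  st <- read_pdb(path, chain = "A")
  expect_s3_class(st, "protein_structure")
  expect_equal(nrow(st$atoms), 13) # 4 + 5 + 4, altloc B dropped
  expect_equal(st$atoms$name[1:4], c("N", "CA", "C", "O"))
  expect_equal(unique(st$atoms$chain), "A")
  expect_false(is.unsorted(st$atoms$serial))
  # highest-occupancy altloc retained once
  ca2 <- st$atoms[st$atoms$resno == 2 & st$atoms$name == "CA", ]
  expect_equal(nrow(ca2), 1)
  expect_equal(ca2$x, 3.988, tolerance = 1e-6)
})

test_that("chain selection and HETATM exclusion", {
  path <- write_fixture_pdb()
  stB <- read_pdb(path, chain = "B")
  expect_equal(nrow(stB$atoms), 4) # HOH HETATM excluded
  expect_equal(unique(stB$atoms$chain), "B")
  st_first <- read_pdb(path)
  expect_equal(unique(st_first$atoms$chain), "A") # first chain by default
})

test_that("reader raises distinct named errors", {
  expect_error(read_pdb(tempfile(fileext = ".pdb")),
               class = "sitematch_error_missing_file")
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), empty)
  expect_error(read_pdb(empty), class = "sitematch_error_no_atoms")
  path <- write_fixture_pdb()
  expect_error(read_pdb(path, chain = "Z"),
               class = "sitematch_error_chain_absent")
})

test_that("atom sequence mirrors atom names with a strictly increasing index", {
  path <- write_fixture_pdb()
  st <- read_pdb(path, chain = "A")
  sq <- extract_atom_sequence(st)
  expect_length(sq$tokens, 13)
  expect_identical(sq$tokens, st$atoms$name)
  expect_identical(sq$tokens[sq$atom_index], st$atoms$name)
  expect_false(is.unsorted(sq$atom_index, strictly = TRUE))
  expect_identical(sq$tokens[1:9],
                   c("N", "CA", "C", "O", "N", "CA", "C", "O", "CB"))
})

test_that("synthetic structures round-trip through PDB files", {
  st <- generate_protein(12, seed = 5)
  # stress the fixed columns: large residue number, negative coordinates
  st$atoms$resno <- st$atoms$resno + 9987L
  st$atoms$x <- st$atoms$x - 60
  path <- tempfile(fileext = ".pdb")
  write_pdb(st, path)
  back <- read_pdb(path)
  expect_identical(back$atoms$name, st$atoms$name)
  expect_identical(back$atoms$resno, st$atoms$resno)
  expect_identical(back$atoms$resid, st$atoms$resid)
  expect_equal(coords(back), coords(st), tolerance = 2e-3)
  expect_identical(extract_atom_sequence(back)$tokens,
                   extract_atom_sequence(st)$tokens)
})
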