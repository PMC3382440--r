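#' @useDynLib sitematch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median runif rnorm setNames
#' @importFrom utils head tail write.table read.delim
NULL

sm_error <- function(class, msg) {
  stop(structure(class = c(class, "sitematch_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a protein chain from a PDB file
#'
#' Parses ATOM records (wwPDB fixed columns, via bio3d) into an ordered atom
#' model: the first MODEL only, one chain, alternate locations resolved to the
#' highest-occupancy copy (ties broken by file order), hydrogens and HETATM
#' records excluded by default. Atom order is file order; residue numbers and
#' insertion codes are preserved exactly as read.
#'
#' @param path Path to a PDB file.
#' @param chain Single chain identifier; `NULL` selects the first chain
#'   encountered in the file.
#' @param keep_hydrogens Keep hydrogen atoms (default `FALSE`; most X-ray
#'   entries lack them and their presence would distort the atom-name
#'   alphabet).
#' @param keep_hetatm Keep HETATM records (default `FALSE`; ligands are what
#'   sites bind, not part of the protein's atom sequence).
#' @param id Identifier for the structure; default is the file stem plus the
#'   chain (e.g. `"4VHBA"`).
#' @return A `protein_structure`: list with `id`, `atoms` (data frame with
#'   columns `serial`, `name`, `element`, `resid`, `resno`, `insert`, `chain`,
#'   `x`, `y`, `z`) and `provenance`.
#' @export
read_pdb <- function(path, chain = NULL, keep_hydrogens = FALSE,
                     keep_hetatm = FALSE, id = NULL) {
  if (!file.exists(path)) sm_error("sitematch_error_missing_file",
                                   paste0("PDB file not found: ", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) sm_error("sitematch_error_no_atoms",
                              paste0("no ATOM records in: ", path))
  if (is.null(chain)) {
    chain <- at$chain[1]
    if (is.na(chain)) chain <- " "
  } else {
    if (!chain %in% at$chain)
      sm_error("sitematch_error_chain_absent",
               paste0("chain '", chain, "' absent from: ", path))
  }
  at <- at[which(at$chain %in% chain | (is.na(at$chain) & chain == " ")), , drop = FALSE]
  if (nrow(at) == 0) sm_error("sitematch_error_no_atoms",
                              paste0("no ATOM records for chain '", chain, "' in: ", path))
  elem <- derive_element(at$elety, at$elesy)
  if (!keep_hydrogens) {
    keep <- elem != "H"
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
    if (nrow(at) == 0) sm_error("sitematch_error_no_atoms",
                                "structure contains only hydrogens")
  }
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = elem,
    resid = at$resid,
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    x = at$x, y = at$y, z = at$z,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- NULL
  atoms$occ <- NULL
  rownames(atoms) <- NULL
  if (is.null(id)) {
    stem <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
    id <- paste0(toupper(stem), trimws(chain))
  }
  new_protein_structure(id, atoms,
                        provenance = list(path = path, chain = chain,
                                          keep_hydrogens = keep_hydrogens,
                                          keep_hetatm = keep_hetatm))
}

new_protein_structure <- function(id, atoms, provenance = list()) {
  stopifnot(nrow(atoms) > 0, all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)), all(nzchar(atoms$name)))
  structure(list(id = id, atoms = atoms, provenance = provenance),
            class = "protein_structure")
}

# keep the highest-occupancy altloc per (resno, insert, name); ties -> first
resolve_altloc <- function(atoms) {
  key <- paste(atoms$resno, atoms$insert, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(match(key, unique(key)), -atoms$occ,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  # restore file order
  atoms[order(atoms$serial), , drop = FALSE]
}

# element from the explicit column when present, else from the name token:
# strip digits/primes, first alphabetic character (leading-digit names such as
# "1HB" are hydrogens)
derive_element <- function(name, elesy = NULL) {
  el <- if (is.null(elesy)) rep(NA_character_, length(name)) else trimws(elesy)
  need <- is.na(el) | el == ""
  if (any(need)) {
    nm <- trimws(name[need])
    guess <- ifelse(grepl("^[0-9]", nm), "H",
                    toupper(substr(gsub("[^A-Za-z]", "", nm), 1, 1)))
    el[need] <- guess
  }
  toupper(el)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$id, ": ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$resno, x$atoms$insert))), " residues\n", sep = "")
  invisible(x)
}

#' Coordinates of a structure as a numeric matrix
#' @param structure A `protein_structure`.
#' @return An n x 3 matrix of coordinates in Angstrom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Extract the atom-name sequence of a structure
#'
#' Translates a structure into the ordered sequence of its atom-name tokens
#' (N, CA, C, O, side-chain names ...), the representation on which the local
#' alignment stage operates. The full PDB atom-name token is the alphabet
#' symbol (so `"CG1"` and `"CG2"` are distinct), not the element.
#'
#' @param structure A `protein_structure`.
#' @return An `atom_sequence`: list with `tokens` (character) and `atom_index`
#'   (integer mapping position -> row of `structure$atoms`).
#' @export
extract_atom_sequence <- function(structure) {
  stopifnot(inherits(structure, "protein_structure"))
  if (nrow(structure$atoms) == 0)
    sm_error("sitematch_error_no_atoms", "empty structure")
  structure(list(tokens = structure$atoms$name,
                 atom_index = seq_len(nrow(structure$atoms)),
                 id = structure$id),
            class = "atom_sequence")
}

#' @export
print.atom_sequence <- function(x, ...) {
  cat("<atom_sequence> ", length(x$tokens), " tokens: ",
      paste(head(x$tokens, 8), collapse = " "),
      if (length(x$tokens) > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}
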