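# Protein structure container and PDB I/O. Parsing and writing of the
# fixed-column format go through bio3d; this layer fixes the conventions
# the rest of the package relies on: first model only, one atom per
# (chain, resno, icode, name) key via highest-occupancy altloc selection,
# author residue numbering preserved verbatim.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (PDB v3.3 fixed columns, via bio3d). Only
#' the first MODEL is kept. When alternate locations are present, the
#' highest-occupancy altloc of each atom is retained (ties broken towards
#' altloc `"A"`); the number of dropped altloc records is reported as a
#' message.
#'
#' @param path path to a PDB file.
#' @return an object of class `"protein_structure"`: list with `atom`
#'   (data frame with columns `type`, `elety`, `resid`, `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  # altloc resolution: highest occupancy, ties to the alphabetically first
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, ]
    dup <- duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|"))
    message(sum(dup), " alternate-location record(s) dropped")
    at <- at[!dup, ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  rownames(at) <- NULL
  new_structure(at[, c("type", "elety", "resid", "chain", "resno", "insert",
                       "x", "y", "z", "o", "b", "elesy")])
}

# cheap fixed-column sanity pass so malformed coordinate records are
# reported with their line number before bio3d sees the file
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d (too short): %s", i, path),
           call. = FALSE)
    }
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (anyNA(coords)) {
      stop(sprintf("malformed PDB record at line %d (bad coordinates): %s",
                   i, path), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Construct a protein structure from an atom table
#'
#' @param atom data frame with columns `type`, `elety`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy` (missing
#'   bookkeeping columns are filled with defaults).
#' @return a `"protein_structure"`.
#' @export
new_structure <- function(atom) {
  atom <- as.data.frame(atom)
  for (col in c("elety", "resid", "chain", "x", "y", "z")) {
    if (is.null(atom[[col]]) && col != "chain") {
      stop("atom table lacks column '", col, "'", call. = FALSE)
    }
  }
  if (is.null(atom$type)) atom$type <- "ATOM"
  if (is.null(atom$chain)) atom$chain <- "A"
  if (is.null(atom$insert)) atom$insert <- ""
  if (is.null(atom$o)) atom$o <- 1
  if (is.null(atom$b)) atom$b <- 0
  if (is.null(atom$elesy)) atom$elesy <- substr(trimws(atom$elety), 1L, 1L)
  if (!all(is.finite(atom$x)) || !all(is.finite(atom$y)) || !all(is.finite(atom$z))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno, icode, atom name) keys in atom table",
         call. = FALSE)
  }
  rownames(atom) <- NULL
  structure(list(atom = atom), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  at <- x$atom
  nres <- nrow(unique(at[, c("chain", "resno", "insert")]))
  cat(sprintf("Protein structure: %d atoms, %d residues, chain(s) %s\n",
              nrow(at), nres,
              paste(sort(unique(at$chain)), collapse = ", ")))
  invisible(x)
}

#' Write a protein structure to a PDB file
#'
#' Fixed-column PDB v3.3 output via bio3d. `read_pdb(write_pdb(x))` is the
#' identity on the data model.
#'
#' @param structure a `"protein_structure"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atom
  if (nrow(at) == 0L) stop("refusing to write an empty structure", call. = FALSE)
  if (any(nchar(trimws(at$elety)) > 4L)) {
    stop("atom name longer than 4 characters: ",
         at$elety[which(nchar(trimws(at$elety)) > 4L)[1L]], call. = FALSE)
  }
  bio3d::write.pdb(
    pdb = NULL, file = path,
    type = at$type,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    eleno = seq_len(nrow(at)), elety = at$elety,
    o = at$o, b = at$b, elesy = at$elesy
  )
  invisible(path)
}

#' Coordinates of one atom
#'
#' @param structure a `"protein_structure"`.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param elety atom name (e.g. `"CA"`).
#' @param icode insertion code.
#' @return numeric length-3 vector, or `NULL` if absent.
#' @export
atom_coord <- function(structure, chain, resno, elety, icode = "") {
  at <- structure$atom
  i <- which(at$chain == chain & at$resno == resno &
             at$insert == icode & at$elety == elety)
  if (length(i) == 0L) return(NULL)
  as.numeric(at[i[1L], c("x", "y", "z")])
}

# coordinate matrix + element vector for clash math
.structure_coords <- function(structure) {
  at <- structure$atom
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       element = toupper(trimws(at$elesy)))
}

#' Per-site neighbor count (burial screen)
#'
#' Number of CB atoms (CA for glycine) within `radius` of the site's CB.
#' Sites with fewer than ~10 neighbors are the exposed sites on which
#' cone-model statistics are collected.
#'
#' @param structure a `"protein_structure"`.
#' @param chain,resno,icode site address.
#' @param radius neighborhood radius in Angstrom.
#' @return integer neighbor count.
#' @export
neighbor_count <- function(structure, chain, resno, icode = "", radius = 10) {
  at <- structure$atom
  ref <- atom_coord(structure, chain, resno, "CB", icode) %||%
         atom_coord(structure, chain, resno, "CA", icode)
  if (is.null(ref)) stop("site has no CB or CA atom", call. = FALSE)
  cb <- at[at$elety == "CB" | (at$elety == "CA" & at$resid == "GLY"), ]
  self <- cb$chain == chain & cb$resno == resno & cb$insert == icode
  cb <- cb[!self, ]
  if (nrow(cb) == 0L) return(0L)
  d2 <- (cb$x - ref[1L])^2 + (cb$y - ref[2L])^2 + (cb$z - ref[3L])^2
  sum(d2 <= radius^2)
}
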