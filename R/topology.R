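# MTSSL side-chain topology: atom tree, ideal internal coordinates, and
# chi-angle definitions. The side chain is built atom-by-atom by NeRF from
# the site's N/CA/CB frame; the five rotatable torsions chi1..chi5 drive
# the linker and the nitroxide ring orientation.
#
# Atom naming (R1A-style):
#   CB-SG-SD-CE-C3 linker, 3-pyrroline ring C3=C4-C5-N1-C2(-C3),
#   nitroxide N1-O1, gem-dimethyls C6/C7 on C2 and C8/C9 on C5.
# chi1 = N-CA-CB-SG, chi2 = CA-CB-SG-SD, chi3 = CB-SG-SD-CE,
# chi4 = SG-SD-CE-C3, chi5 = SD-CE-C3-C4 (C4 is the doubly bonded ring
# carbon, so chi5's fourth atom is the sp2 partner of C3).

# raw ideal internal coordinates before tether calibration; frame columns
# name the three previously placed atoms (a, b, c) with the new atom bonded
# to c. "dihedral" is either a chi slot (1..5), a chi slot + 180 offset
# (encoded via offset column), or a fixed value.
.mtssl_raw_atoms <- function() {
  # name  elem  a     b     c     len    ang    chi offset fixed
  x <- rbind(
    c("SG", "S", "N",  "CA", "CB", 1.81, 114.0, 1, 0,   NA),
    c("SD", "S", "CA", "CB", "SG", 2.04, 104.0, 2, 0,   NA),
    c("CE", "C", "CB", "SG", "SD", 1.81, 104.0, 3, 0,   NA),
    c("C3", "C", "SG", "SD", "CE", 1.50, 112.0, 4, 0,   NA),
    c("C4", "C", "SD", "CE", "C3", 1.33, 128.0, 5, 0,   NA),
    c("C2", "C", "SD", "CE", "C3", 1.51, 120.0, 5, 180, NA),
    c("C5", "C", "C2", "C3", "C4", 1.51, 112.0, NA, 0,  0),
    c("N1", "N", "C3", "C4", "C5", 1.48, 101.7, NA, 0,  0),
    c("O1", "O", "C4", "C5", "N1", 1.28, 126.0, NA, 0,  180),
    c("C6", "C", "C4", "C3", "C2", 1.53, 111.0, NA, 0,  120),
    c("C7", "C", "C4", "C3", "C2", 1.53, 111.0, NA, 0, -120),
    c("C8", "C", "C3", "C4", "C5", 1.53, 111.0, NA, 0,  120),
    c("C9", "C", "C3", "C4", "C5", 1.53, 111.0, NA, 0, -120)
  )
  data.frame(
    name = x[, 1L], element = x[, 2L],
    a = x[, 3L], b = x[, 4L], c = x[, 5L],
    length = as.numeric(x[, 6L]), angle = as.numeric(x[, 7L]),
    chi = as.integer(x[, 8L]), offset = as.numeric(x[, 9L]),
    fixed = as.numeric(x[, 10L]),
    stringsAsFactors = FALSE
  )
}

.mtssl_bonds <- function() {
  rbind(
    c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"),
    c("CB", "SG"), c("SG", "SD"), c("SD", "CE"), c("CE", "C3"),
    c("C3", "C4"), c("C3", "C2"), c("C4", "C5"), c("C5", "N1"),
    c("N1", "C2"), c("N1", "O1"),
    c("C2", "C6"), c("C2", "C7"), c("C5", "C8"), c("C5", "C9")
  )
}

.mtssl_chi_atoms <- list(
  chi1 = c("N", "CA", "CB", "SG"),
  chi2 = c("CA", "CB", "SG", "SD"),
  chi3 = c("CB", "SG", "SD", "CE"),
  chi4 = c("SG", "SD", "CE", "C3"),
  chi5 = c("SD", "CE", "C3", "C4")
)

#' MTSSL side-chain topology
#'
#' Returns the packaged topology of the MTSSL side chain: the ordered atom
#' tree with ideal internal coordinates, the bond list, and the chi-angle
#' definitions. Bond lengths along the side chain are calibrated once by a
#' single uniform scale factor so that the fully extended (all-trans)
#' conformer places the N-O bond midpoint exactly `tether` Angstrom from CB.
#'
#' @param tether target CB to N-O midpoint distance of the fully extended
#'   conformer, in Angstrom. Default 8.5.
#' @return an object of class `"mtssl_topology"`: list with `atoms`
#'   (build-order data frame of internal coordinates), `bonds` (2-column
#'   character matrix), `chi_atoms` (list of 4 atom names per chi),
#'   `tether`, and `scale` (the calibration factor applied to the raw bond
#'   lengths).
#' @export
mtssl_topology <- function(tether = 8.5) {
  stopifnot(is.numeric(tether), length(tether) == 1L, tether > 0)
  atoms <- .mtssl_raw_atoms()
  topo <- structure(
    list(atoms = atoms, bonds = .mtssl_bonds(), chi_atoms = .mtssl_chi_atoms,
         tether = tether, scale = 1),
    class = "mtssl_topology"
  )
  d0 <- .tether_length(topo)
  topo$scale <- tether / d0
  topo$atoms$length <- atoms$length * topo$scale
  topo
}

# CB -> N-O midpoint distance of the all-trans extended conformer
.tether_length <- function(topo) {
  xyz <- build_conformer(topo, rep(180, 5L))
  mid <- no_midpoint(xyz)
  sqrt(sum((mid - xyz["CB", ])^2))
}

#' @export
print.mtssl_topology <- function(x, ...) {
  cat("MTSSL side-chain topology\n")
  cat(sprintf("  %d side-chain atoms beyond CB, %d bonds\n",
              nrow(x$atoms), nrow(x$bonds)))
  cat(sprintf("  tether calibration: %.3f A (bond-length scale %.5f)\n",
              x$tether, x$scale))
  invisible(x)
}

# canonical backbone frame used when building conformers in isolation:
# CA at origin, N along +x, C in the xy-plane, CB/O from ideal geometry.
.canonical_backbone <- function() {
  ca <- c(0, 0, 0)
  n <- c(1.458, 0, 0)
  # angle N-CA-C = 111.2, in the xy-plane with y > 0
  cc <- c(1.525 * cos(111.2 * DEG2RAD), 1.525 * sin(111.2 * DEG2RAD), 0)
  cb <- synthesize_cb(n, ca, cc)
  o <- place_atom(n, ca, cc, 1.231, 120.5, 135.0)  # carbonyl O, arbitrary psi
  rbind(N = n, CA = ca, C = cc, O = o, CB = cb)
}

#' Build MTSSL side-chain coordinates for a chi vector
#'
#' Constructs Cartesian coordinates for the MTSSL side chain (and its
#' backbone frame) by sequential internal-coordinate (NeRF) placement.
#' Measured chi1..chi5 of the result reproduce `chi` to better than 1e-4
#' degrees.
#'
#' @param topology an [mtssl_topology()].
#' @param chi numeric vector of 5 torsions in degrees, or a rotamer spec
#'   (a list with a `chi` field).
#' @param frame backbone frame coordinates: a matrix with rows named
#'   `N`, `CA`, `CB` (rows `C`/`O` are carried through if present).
#'   Default: a canonical isolated backbone.
#' @return a matrix of coordinates with one named row per atom
#'   (backbone frame rows first, then side-chain atoms in build order).
#' @export
build_conformer <- function(topology, chi, frame = NULL) {
  stopifnot(inherits(topology, "mtssl_topology"))
  if (is.list(chi)) chi <- chi$chi
  chi <- as.numeric(chi)
  if (length(chi) != 5L || !all(is.finite(chi))) {
    stop("'chi' must be 5 finite torsions in degrees", call. = FALSE)
  }
  if (is.null(frame)) frame <- .canonical_backbone()
  if (is.null(rownames(frame)) || !all(c("N", "CA", "CB") %in% rownames(frame))) {
    stop("'frame' must have rows named N, CA, CB", call. = FALSE)
  }
  at <- topology$atoms
  n_sc <- nrow(at)
  xyz <- matrix(NA_real_, nrow(frame) + n_sc, 3L,
                dimnames = list(c(rownames(frame), at$name), NULL))
  xyz[seq_len(nrow(frame)), ] <- frame
  for (i in seq_len(n_sc)) {
    dih <- if (is.na(at$chi[i])) at$fixed[i] else chi[at$chi[i]] + at$offset[i]
    xyz[at$name[i], ] <- .nerf(
      xyz[at$a[i], ], xyz[at$b[i], ], xyz[at$c[i], ],
      at$length[i], at$angle[i] * DEG2RAD, dih * DEG2RAD
    )
  }
  xyz
}

#' N-O bond midpoint of a built conformer
#'
#' The midpoint of the nitroxide N1-O1 bond is the effective location of
#' the unpaired electron.
#'
#' @param xyz conformer coordinate matrix from [build_conformer()] (or any
#'   matrix with rows `N1` and `O1`).
#' @return numeric length-3 point.
#' @export
no_midpoint <- function(xyz) {
  if (!all(c("N1", "O1") %in% rownames(xyz))) {
    stop("conformer lacks nitroxide atoms N1/O1", call. = FALSE)
  }
  (xyz["N1", ] + xyz["O1", ]) / 2
}

#' Measure chi1..chi5 of a conformer
#'
#' @param xyz conformer coordinate matrix with named rows.
#' @param topology an [mtssl_topology()] supplying the chi definitions.
#' @return numeric vector of 5 torsions in degrees, `[-180, 180)`.
#' @export
measure_chi <- function(xyz, topology = mtssl_topology()) {
  vapply(topology$chi_atoms, function(a) {
    measure_dihedral(xyz[a[1L], ], xyz[a[2L], ], xyz[a[3L], ], xyz[a[4L], ])
  }, numeric(1L))
}

#' Synthesize a CB position from backbone atoms
#'
#' Ideal tetrahedral construction used for glycine sites (and anywhere a
#' CB is missing): CB is placed off the N/C/CA frame with standard
#' L-amino-acid geometry.
#'
#' @param n,ca,c backbone N, CA and C coordinates.
#' @return CB coordinates, numeric length-3.
#' @export
synthesize_cb <- function(n, ca, c) {
  place_atom(n, c, ca, 1.53, 110.1, 122.6)
}

# ideal HA, roughly opposite CB on the CA tetrahedron; used only to
# complete the cone-model superposition atom set when hydrogens are absent
.synthesize_ha <- function(n, ca, c) {
  place_atom(n, c, ca, 1.09, 108.9, -118.3)
}
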