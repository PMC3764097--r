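# Synthetic structure and distribution generators. These provide the
# geometric situations the labeling method assumes — exposed helical
# sites, buried/occluded sites, uni- and multi-modal distance
# distributions — so every workflow runs without external data.

# ideal backbone geometry (lengths in Angstrom, angles in degrees)
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180
)

#' Build an ideal polypeptide helix (or strand)
#'
#' Backbone constructed from ideal bond geometry with constant phi/psi;
#' the measured torsions of interior residues reproduce the inputs
#' exactly. Poly-alanine by default (N, CA, C, O, CB per residue). The
#' alpha-helical defaults (-57, -47) give the canonical ~1.5 A rise per
#' residue; phi = psi = 180 gives a fully extended strand.
#'
#' @param n_residues number of residues, >= 4.
#' @param phi,psi backbone torsions in degrees.
#' @param chain chain identifier.
#' @return a `"protein_structure"`.
#' @export
make_ideal_helix <- function(n_residues = 20, phi = -57, psi = -47,
                             chain = "A") {
  if (n_residues < 4) stop("n_residues must be at least 4", call. = FALSE)
  g <- .bb_geom
  n_xyz <- matrix(NA_real_, n_residues, 3L)
  ca_xyz <- matrix(NA_real_, n_residues, 3L)
  c_xyz <- matrix(NA_real_, n_residues, 3L)
  n_xyz[1L, ] <- c(0, 0, 0)
  ca_xyz[1L, ] <- c(g$n_ca, 0, 0)
  c_xyz[1L, ] <- ca_xyz[1L, ] + g$ca_c *
    c(cos(pi - g$ang_n_ca_c * DEG2RAD), sin(pi - g$ang_n_ca_c * DEG2RAD), 0)
  for (i in seq_len(n_residues - 1L)) {
    n_xyz[i + 1L, ] <- place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                                  g$c_n, g$ang_ca_c_n, psi)
    ca_xyz[i + 1L, ] <- place_atom(ca_xyz[i, ], c_xyz[i, ], n_xyz[i + 1L, ],
                                   g$n_ca, g$ang_c_n_ca, g$omega)
    c_xyz[i + 1L, ] <- place_atom(c_xyz[i, ], n_xyz[i + 1L, ], ca_xyz[i + 1L, ],
                                  g$ca_c, g$ang_n_ca_c, phi)
  }
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    o <- place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                    g$c_o, g$ang_ca_c_o, psi + 180)
    cb <- synthesize_cb(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ])
    xyz <- rbind(N = n_xyz[i, ], CA = ca_xyz[i, ], C = c_xyz[i, ], O = o, CB = cb)
    rows[[i]] <- data.frame(
      type = "ATOM", elety = rownames(xyz), resid = "ALA", chain = chain,
      resno = i, insert = "", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      o = 1, b = 0, elesy = substr(rownames(xyz), 1L, 1L)
    )
  }
  new_structure(do.call(rbind, rows))
}

#' Two parallel ideal helices at a given separation
#'
#' The second helix (chain B) is the first translated perpendicular to its
#' axis, so the inter-axis distance equals `separation` exactly.
#'
#' @param separation inter-axis distance in Angstrom; values below 5 (which
#'   would fuse the backbones) are rejected.
#' @param n_residues residues per helix.
#' @return a `"protein_structure"` with chains A and B.
#' @export
make_two_helix_pair <- function(separation, n_residues = 20) {
  if (separation < 5) {
    stop("separation below 5 A would overlap the helices", call. = FALSE)
  }
  h <- make_ideal_helix(n_residues, chain = "A")
  ca <- as.matrix(h$atom[h$atom$elety == "CA", c("x", "y", "z")])
  centered <- sweep(ca, 2L, colMeans(ca))
  axis <- svd(centered)$v[, 1L]           # helix axis direction
  perp <- .cross3(axis, c(0, 0, 1))
  if (sqrt(sum(perp^2)) < 1e-6) perp <- .cross3(axis, c(0, 1, 0))
  perp <- perp / sqrt(sum(perp^2))
  b <- h$atom
  b$chain <- "B"
  b$x <- b$x + separation * perp[1L]
  b$y <- b$y + separation * perp[2L]
  b$z <- b$z + separation * perp[3L]
  new_structure(rbind(h$atom, b))
}

#' Spherical occluding cage around a point
#'
#' A shell of dummy carbon atoms on a Fibonacci angular grid. With a small
#' radius every label conformer at the enclosed site clashes, which is the
#' constructed analogue of a tightly packed pocket.
#'
#' @param site_center length-3 center of the shell.
#' @param radius shell radius in Angstrom.
#' @param n_points number of shell atoms (the angular grid size).
#' @param chain chain identifier for the cage atoms.
#' @param resno_start first residue number for the cage atoms.
#' @return a `"protein_structure"` of `n_points` HETATM pseudo-atoms.
#' @export
make_occluding_cage <- function(site_center, radius, n_points = 200,
                                chain = "X", resno_start = 1000) {
  site_center <- .as_point3(site_center, "site_center")
  stopifnot(radius > 0, n_points >= 1)
  k <- seq_len(n_points) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * k / n_points
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * k
  pts <- cbind(r * cos(th), r * sin(th), z) * radius
  pts <- sweep(pts, 2L, site_center, "+")
  new_structure(data.frame(
    type = "HETATM", elety = "C", resid = "CAG", chain = chain,
    resno = resno_start + seq_len(n_points) - 1L, insert = "",
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L], o = 1, b = 0, elesy = "C"
  ))
}

#' Merge structures into one
#'
#' @param ... `"protein_structure"` objects with disjoint atom keys.
#' @return a combined `"protein_structure"`.
#' @export
combine_structures <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  new_structure(do.call(rbind, lapply(parts, function(s) {
    stopifnot(inherits(s, "protein_structure"))
    s$atom
  })))
}

#' Synthetic (multi-modal) experimental distance distribution
#'
#' Normalized mixture of discretized Gaussians, standing in for a
#' regularized experimental DEER distribution.
#'
#' @param components list of `c(mu, sigma, weight)` triples (or a 3-column
#'   matrix, one row per component).
#' @param bin_width,range binning as in [gaussian_distribution()].
#' @return a [distance_distribution()].
#' @export
make_synthetic_distribution <- function(components,
                                        bin_width = .default_bin_width,
                                        range = .default_bin_range) {
  if (is.matrix(components)) components <- asplit(components, 1L)
  stopifnot(length(components) >= 1L)
  centers <- .bin_centers(bin_width, range)
  probs <- numeric(length(centers))
  for (cmp in components) {
    cmp <- as.numeric(cmp)
    if (length(cmp) != 3L) {
      stop("each component must be c(mu, sigma, weight)", call. = FALSE)
    }
    g <- gaussian_distribution(cmp[1L], cmp[2L], bin_width, range)
    probs <- probs + cmp[3L] * g$probabilities
  }
  distance_distribution(centers, probs)
}
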