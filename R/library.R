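# MTSSL rotamer library construction: enumeration of candidate chi
# combinations from the correlated-preference tables, hard-sphere internal
# clash filtering, rescue minimization (bounded chi perturbation), and
# JSON serialization of the canonical 54-member library.

# canonical m/p/t torsion values for (chi1, chi2)
.mpt_values <- c(m = -60, p = 60, t = 180)

# observed / allowed (chi1, chi2) classes
.chi12_classes <- c("mm", "mt", "tp", "tm", "tt")

# (chi4, chi5) correlation: for chi4 = 180 chi5 is +/-77; for chi4 = -75
# chi5 is -8 or +100; for chi4 = +75 chi5 is +8 or -100
.chi45_pairs <- matrix(c(
  180,  77,
  180, -77,
  -75,  -8,
  -75, 100,
   75,   8,
   75, -100
), ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("chi4", "chi5")))

# default per-chi standard deviations (degrees): rotamer-width order of
# magnitude; chi1/chi2 wider because off-rotamer sampling perturbs them
.default_chi_sd <- c(15, 15, 10, 10, 10)

#' Hard-sphere van der Waals radii (Angstrom)
#'
#' Element radii used by the clash criteria: C 1.7, N 1.55, O 1.52, S 1.8.
#'
#' @return named numeric vector of radii.
#' @export
mtssl_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

#' Default internal-clash hard-sphere scale factor
#'
#' Calibrated once against the enumerated candidate set so that exactly six
#' candidates are irrecoverably removed by the internal-clash filter with
#' rescue, leaving the canonical 54-member library.
#'
#' The scale is above 1 because it acts as a strain detector: contacts
#' modestly inside the vdW sum flag a conformation for rescue minimization
#' rather than marking a physical overlap.
#'
#' @return a single numeric scale multiplying the sum of vdW radii.
#' @export
mtssl_vdw_scale <- function() 1.10

#' Enumerate candidate MTSSL rotamers
#'
#' Builds the full Cartesian product of the correlated chi preferences:
#' five (chi1, chi2) classes (mm, mt, tp, tm, tt with m = -60, p = +60,
#' t = 180), two chi3 states (+/-90), and six correlated (chi4, chi5)
#' pairs (two chi5 options for each of three chi4 values), for
#' 5 x 2 x 3 x 2 = 60 candidates.
#'
#' @param classes subset of (chi1, chi2) classes to enumerate.
#' @param chi3_values chi3 states to enumerate (degrees).
#' @param chi45_pairs 2-column matrix of correlated (chi4, chi5) values.
#' @param sd per-chi standard deviations attached to every candidate.
#' @return list of rotamer specs; each is a list with fields `id`, `chi`
#'   (length 5, degrees), `sd` (length 5), `class` (two letters).
#' @export
enumerate_candidates <- function(classes = .chi12_classes,
                                 chi3_values = c(-90, 90),
                                 chi45_pairs = .chi45_pairs,
                                 sd = .default_chi_sd) {
  stopifnot(all(classes %in% .chi12_classes), length(sd) == 5L)
  out <- vector("list", length(classes) * length(chi3_values) * nrow(chi45_pairs))
  k <- 0L
  for (cl in classes) {
    c12 <- .mpt_values[strsplit(cl, "")[[1L]]]
    for (x3 in chi3_values) {
      for (p in seq_len(nrow(chi45_pairs))) {
        k <- k + 1L
        out[[k]] <- list(
          id = k,
          chi = unname(c(c12, x3, chi45_pairs[p, 1L], chi45_pairs[p, 2L])),
          sd = as.numeric(sd),
          class = cl
        )
      }
    }
  }
  out
}

# precompute the non-bonded atom-pair table for a conformer's row order:
# all pairs at bond-graph distance >= 4 (1-2, 1-3 and 1-4 pairs excluded),
# with their vdW radius sums
.clash_pair_table <- function(atom_names, topology) {
  n <- length(atom_names)
  adj <- matrix(FALSE, n, n, dimnames = list(atom_names, atom_names))
  bonds <- topology$bonds
  keep <- bonds[, 1L] %in% atom_names & bonds[, 2L] %in% atom_names
  for (r in which(keep)) {
    adj[bonds[r, 1L], bonds[r, 2L]] <- TRUE
    adj[bonds[r, 2L], bonds[r, 1L]] <- TRUE
  }
  adj2 <- adj %*% adj > 0
  adj3 <- (adj %*% adj %*% adj) > 0
  near <- adj | adj2 | adj3  # bond-graph distance <= 3 (up to 1-4)
  elems <- .element_of(atom_names, topology)
  radii <- mtssl_vdw_radii()[elems]
  ij <- which(upper.tri(matrix(0, n, n)) & !near, arr.ind = TRUE)
  list(i = ij[, 1L], j = ij[, 2L], rsum = radii[ij[, 1L]] + radii[ij[, 2L]])
}

.element_of <- function(atom_names, topology) {
  e <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C",
         stats::setNames(topology$atoms$element, topology$atoms$name))
  unknown <- setdiff(atom_names, names(e))
  if (length(unknown)) {
    stop("no element known for atom(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(e[atom_names])
}

#' Count internal hard-sphere clashes of a conformer
#'
#' A non-bonded atom pair clashes when its distance falls below
#' `scale * (r_i + r_j)` with element vdW radii from [mtssl_vdw_radii()].
#' Pairs at bond-graph distance 1-2, 1-3 and 1-4 are excluded: 1-4
#' contacts sit below the vdW sum at ideal geometry for any torsion, so
#' counting them would make the criterion insensitive to conformation.
#'
#' @param xyz conformer coordinate matrix with named rows
#'   (see [build_conformer()]).
#' @param topology an [mtssl_topology()] supplying bonds and elements.
#' @param scale unitless hard-sphere scale factor, >= 0.
#' @param pairs optional precomputed pair table (internal speed-up).
#' @return integer count of clashing pairs.
#' @export
internal_clash_score <- function(xyz, topology = mtssl_topology(),
                                 scale = mtssl_vdw_scale(), pairs = NULL) {
  stopifnot(is.numeric(scale), scale >= 0)
  if (is.null(pairs)) pairs <- .clash_pair_table(rownames(xyz), topology)
  d2 <- rowSums((xyz[pairs$i, , drop = FALSE] - xyz[pairs$j, , drop = FALSE])^2)
  sum(d2 < (scale * pairs$rsum)^2)
}

# intramolecular clash context: the side chain plus its anchoring N/CA/CB.
# The carbonyl C/O are dropped because their orientation relative to the
# side chain is a backbone (psi) property, not a rotamer property.
.internal_context <- function(xyz) {
  xyz[setdiff(rownames(xyz), c("C", "O")), , drop = FALSE]
}

#' Rescue a clashing rotamer by bounded distal-chi perturbation
#'
#' Minimization to relieve a flagged internal clash: searches perturbations
#' of the distal torsions chi4 and chi5 on a 5-degree grid, never moving
#' either by more than `max_chi_change`, for the smallest perturbation
#' whose conformer is clash-free. chi1-chi3 stay fixed: they define the
#' rotamer's class bin, and a rescue that moved them would turn one
#' library entry into another. Perturbations are tried in order of
#' increasing size, so an already clash-free spec is returned unchanged.
#'
#' @param spec rotamer spec (list with `chi`, see [enumerate_candidates()]).
#' @param topology an [mtssl_topology()].
#' @param scale hard-sphere scale factor for the clash criterion.
#' @param max_chi_change per-chi perturbation bound in degrees (default 30).
#' @param step grid step in degrees.
#' @return the rescued spec (chi replaced, original chi kept in
#'   `$parent_chi`), or `NULL` if no perturbation within the bound removes
#'   all clashes.
#' @export
rescue_minimize <- function(spec, topology = mtssl_topology(),
                            scale = mtssl_vdw_scale(),
                            max_chi_change = 30, step = 5) {
  offsets <- seq(-max_chi_change, max_chi_change, by = step)
  grid <- as.matrix(expand.grid(d4 = offsets, d5 = offsets,
                                KEEP.OUT.ATTRS = FALSE))
  sz <- pmax(abs(grid[, 1L]), abs(grid[, 2L]))
  grid <- grid[order(sz, rowSums(abs(grid))), , drop = FALSE]
  base <- .internal_context(build_conformer(topology, spec$chi))
  pairs <- .clash_pair_table(rownames(base), topology)
  for (r in seq_len(nrow(grid))) {
    chi <- spec$chi + c(0, 0, 0, grid[r, 1L], grid[r, 2L])
    xyz <- .internal_context(build_conformer(topology, chi))
    if (internal_clash_score(xyz, topology, scale, pairs) == 0L) {
      if (all(grid[r, ] == 0)) return(spec)  # already clash-free: unchanged
      out <- spec
      out$chi <- unname(wrap_angle(chi))
      out$parent_chi <- spec$chi
      return(out)
    }
  }
  NULL
}

#' Build the MTSSL rotamer library
#'
#' Enumerates the 60 candidate chi combinations, flags candidates with
#' internal hard-sphere clashes, attempts to rescue flagged candidates by
#' chi perturbations of at most 30 degrees, and drops the unrescued rest.
#' At the packaged calibrated scale the result is the canonical 54-member
#' library.
#'
#' @param vdw_scale hard-sphere scale factor (default: calibrated
#'   [mtssl_vdw_scale()]).
#' @param topology an [mtssl_topology()].
#' @param max_chi_change rescue bound in degrees.
#' @return an object of class `"rotamer_library"`: list with `rotamers`
#'   (list of specs) and `provenance` (enumeration count, clash counts,
#'   filter parameters, removed candidate ids).
#' @export
build_library <- function(vdw_scale = mtssl_vdw_scale(),
                          topology = mtssl_topology(),
                          max_chi_change = 30) {
  cands <- enumerate_candidates()
  base <- .internal_context(build_conformer(topology, cands[[1L]]$chi))
  pairs <- .clash_pair_table(rownames(base), topology)
  kept <- list()
  clashing <- 0L
  rescued <- 0L
  removed <- integer()
  for (spec in cands) {
    xyz <- .internal_context(build_conformer(topology, spec$chi))
    if (internal_clash_score(xyz, topology, vdw_scale, pairs) == 0L) {
      kept[[length(kept) + 1L]] <- spec
    } else {
      clashing <- clashing + 1L
      fixed <- rescue_minimize(spec, topology, vdw_scale, max_chi_change)
      if (is.null(fixed)) {
        removed <- c(removed, spec$id)
      } else {
        rescued <- rescued + 1L
        kept[[length(kept) + 1L]] <- fixed
      }
    }
  }
  structure(
    list(
      rotamers = kept,
      provenance = list(
        n_enumerated = length(cands),
        n_clashing = clashing,
        n_rescued = rescued,
        removed_ids = removed,
        vdw_scale = vdw_scale,
        max_chi_change = max_chi_change,
        tether = topology$tether
      )
    ),
    class = "rotamer_library"
  )
}

#' @export
print.rotamer_library <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("MTSSL rotamer library: %d rotamers\n", length(x$rotamers)))
  cat(sprintf("  enumerated %d, %d clashing, %d rescued, %d removed (scale %.3f)\n",
              p$n_enumerated, p$n_clashing, p$n_rescued,
              length(p$removed_ids), p$vdw_scale))
  cls <- table(vapply(x$rotamers, `[[`, "", "class"))
  cat("  (chi1,chi2) classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.rotamer_library <- function(x) length(x$rotamers)

# stable string hash (FNV-1a, 32-bit) over the topology table, recorded in
# library files so a library is never silently paired with a different
# atom tree
.topology_hash <- function(topology) {
  s <- paste(
    apply(topology$atoms, 1L, paste, collapse = ","),
    collapse = ";"
  )
  s <- paste0(s, sprintf("|tether=%.6f", topology$tether))
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Write a rotamer library to JSON
#'
#' @param library a `"rotamer_library"`.
#' @param path output file path.
#' @param topology topology whose hash is recorded in the file.
#' @return `path`, invisibly.
#' @seealso [read_library()]
#' @export
write_library <- function(library, path, topology = mtssl_topology()) {
  stopifnot(inherits(library, "rotamer_library"))
  obj <- list(
    version = 1L,
    topology_hash = .topology_hash(topology),
    provenance = library$provenance,
    rotamers = lapply(library$rotamers, function(r) {
      out <- list(id = r$id, chi = r$chi, sd = r$sd, class = r$class)
      if (!is.null(r$parent_chi)) out$parent_chi <- r$parent_chi
      out
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rotamer library from JSON
#'
#' @param path path to a file written by [write_library()].
#' @return a `"rotamer_library"`.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$version)) stop("malformed library file (no 'version' field): ", path, call. = FALSE)
  if (is.null(obj$rotamers)) stop("malformed library file (no 'rotamers' field): ", path, call. = FALSE)
  rot <- lapply(seq_along(obj$rotamers), function(k) {
    r <- obj$rotamers[[k]]
    for (f in c("id", "chi", "sd", "class")) {
      if (is.null(r[[f]])) {
        stop(sprintf("malformed library file: rotamer %d lacks field '%s'", k, f),
             call. = FALSE)
      }
    }
    chi <- as.numeric(unlist(r$chi))
    sd <- as.numeric(unlist(r$sd))
    if (length(chi) != 5L || length(sd) != 5L) {
      stop(sprintf("malformed library file: rotamer %d needs 5 chi and 5 sd values", k),
           call. = FALSE)
    }
    out <- list(id = as.integer(r$id), chi = chi, sd = sd,
                class = as.character(r$class))
    if (!is.null(r$parent_chi)) out$parent_chi <- as.numeric(unlist(r$parent_chi))
    out
  })
  structure(
    list(rotamers = rot,
         provenance = lapply(obj$provenance, function(v) unlist(v, use.names = FALSE))),
    class = "rotamer_library"
  )
}

#' The canonical packaged 54-rotamer MTSSL library
#'
#' Reads the library shipped with the package (built by [build_library()]
#' at the calibrated hard-sphere scale).
#'
#' @return a `"rotamer_library"` with 54 entries.
#' @export
mtssl_library <- function() {
  read_library(system.file("extdata", "mtssl_rotamer_library.json",
                           package = "mtsslr", mustWork = TRUE))
}
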