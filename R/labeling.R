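# Site labeling: attach MTSSL rotamers to a residue of a structure,
# score each conformer's clash with the (rigid) protein environment, and
# form a Boltzmann-weighted conformer ensemble per site. Mutation
# semantics: the site's native side chain beyond CB is ignored.

#' Site address within a structure
#'
#' @param chain chain identifier.
#' @param resno author residue number (as in the PDB file).
#' @param icode insertion code.
#' @return a `"site_spec"` list.
#' @export
site_spec <- function(chain, resno, icode = "") {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 icode = as.character(icode)),
            class = "site_spec")
}

# residue atom indices + backbone frame for a site; synthesizes CB (and,
# on request, HA) from ideal geometry when absent
.resolve_site <- function(structure, site, need_ha = FALSE) {
  stopifnot(inherits(structure, "protein_structure"), inherits(site, "site_spec"))
  at <- structure$atom
  idx <- which(at$chain == site$chain & at$resno == site$resno &
               at$insert == site$icode)
  if (length(idx) == 0L) {
    stop(sprintf("site %s:%d%s not found in structure",
                 site$chain, site$resno, site$icode), call. = FALSE)
  }
  res <- at[idx, ]
  coord <- function(name) {
    i <- which(res$elety == name)
    if (length(i) == 0L) NULL else as.numeric(res[i[1L], c("x", "y", "z")])
  }
  n <- coord("N"); ca <- coord("CA"); cc <- coord("C")
  if (is.null(n) || is.null(ca) || is.null(cc)) {
    stop(sprintf("site %s:%d%s lacks backbone atoms (N, CA, C required)",
                 site$chain, site$resno, site$icode), call. = FALSE)
  }
  cb <- coord("CB")
  if (is.null(cb)) cb <- synthesize_cb(n, ca, cc)
  out <- list(atom_idx = idx, resid = res$resid[1L],
              N = n, CA = ca, C = cc, CB = cb, O = coord("O"))
  if (need_ha) out$HA <- coord("HA") %||% .synthesize_ha(n, ca, cc)
  out
}

#' Attach one MTSSL rotamer at a site
#'
#' Builds the label side chain off the site's N/CA/CB frame. The native
#' side chain beyond CB plays no role (computational mutation); for
#' glycine a CB is synthesized from ideal geometry.
#'
#' @param structure a `"protein_structure"`.
#' @param site a [site_spec()].
#' @param spec a rotamer spec (entry of a rotamer library) or bare chi
#'   vector.
#' @param topology an [mtssl_topology()].
#' @return an object of class `"label_conformer"`: list with `chi`,
#'   `spec_id`, `xyz` (named coordinate rows: site N/CA/CB + side chain),
#'   `midpoint` (N-O bond midpoint), `clash_energy` (`NA` until scored),
#'   `weight` (`NA` until the ensemble is formed).
#' @export
attach_rotamer <- function(structure, site, spec,
                           topology = mtssl_topology()) {
  rs <- .resolve_site(structure, site)
  chi <- if (is.list(spec)) spec$chi else as.numeric(spec)
  frame <- rbind(N = rs$N, CA = rs$CA, CB = rs$CB)
  xyz <- build_conformer(topology, chi, frame)
  structure(
    list(spec_id = if (is.list(spec)) spec$id else NA_integer_,
         chi = chi, xyz = xyz, midpoint = no_midpoint(xyz),
         clash_energy = NA_real_, weight = NA_real_),
    class = "label_conformer"
  )
}

#' Soft-sphere clash energy of a conformer against its environment
#'
#' Sum over (label atom, protein atom) pairs of
#' `max(0, scale * (r_i + r_j) - d)^2` — a smooth, purely repulsive
#' overlap score. The labeled residue itself (backbone and native side
#' chain) is excluded, as is the label.
#'
#' @param conformer a `"label_conformer"`.
#' @param structure the `"protein_structure"` providing the environment.
#' @param site the labeled [site_spec()].
#' @param vdw_scale hard-sphere scale factor for the contact distance.
#' @param topology an [mtssl_topology()] (for label atom elements).
#' @return non-negative clash energy (unitless; Angstrom^2 scale).
#' @export
environment_clash <- function(conformer, structure, site,
                              vdw_scale = 0.85,
                              topology = mtssl_topology()) {
  stopifnot(inherits(conformer, "label_conformer"))
  rs <- .resolve_site(structure, site)
  env <- .structure_coords(structure)
  keep <- setdiff(seq_len(nrow(env$xyz)), rs$atom_idx)
  if (length(keep) == 0L) return(0)
  radii <- mtssl_vdw_radii()
  env_r <- unname(radii[env$element[keep]])
  env_r[is.na(env_r)] <- 1.7  # unknown elements treated as carbon
  lab_names <- topology$atoms$name
  lab_xyz <- conformer$xyz[lab_names, , drop = FALSE]
  lab_r <- unname(radii[topology$atoms$element])
  exyz <- env$xyz[keep, , drop = FALSE]
  e <- 0
  for (i in seq_along(lab_names)) {
    d <- sqrt((exyz[, 1L] - lab_xyz[i, 1L])^2 +
              (exyz[, 2L] - lab_xyz[i, 2L])^2 +
              (exyz[, 3L] - lab_xyz[i, 3L])^2)
    ov <- vdw_scale * (lab_r[i] + env_r) - d
    e <- e + sum(pmax(0, ov)^2)
  }
  e
}

#' Sample a weighted MTSSL conformer ensemble at a site
#'
#' For every library rotamer the base conformer plus its eight (chi1,
#' chi2) +/- 1 SD variants are attached and scored against the rigid
#' environment; `n_perturb` additional variants draw all five chi from
#' seeded normal perturbations. Conformers with clash energy above
#' `clash_cutoff` are discarded; the survivors get Boltzmann weights
#' proportional to `exp(-clash_energy / kT)`. With `top_fraction` set,
#' weighting is restricted to the lowest-energy fraction of survivors
#' (score-rank truncation), everything else dropped.
#'
#' @param structure a `"protein_structure"`.
#' @param site a [site_spec()].
#' @param library a `"rotamer_library"` (default: the packaged 54).
#' @param vdw_scale soft-sphere scale for [environment_clash()].
#' @param clash_cutoff survival threshold on clash energy.
#' @param kT Boltzmann temperature factor for the weights.
#' @param n_perturb extra random off-rotamer variants per rotamer.
#' @param seed integer RNG seed (recorded in the result).
#' @param top_fraction optional fraction (0, 1] of lowest-energy survivors
#'   kept before weighting.
#' @param topology an [mtssl_topology()].
#' @return an object of class `"label_ensemble"`: list with `site`,
#'   `conformers` (each with `clash_energy` and normalized `weight`),
#'   `cb` (site CB), `params`, and `reason` (`NULL`, or `"occluded site"`
#'   when no conformer survives).
#' @export
sample_site_ensemble <- function(structure, site, library = mtssl_library(),
                                 vdw_scale = 0.85, clash_cutoff = 5,
                                 kT = 1.0, n_perturb = 0L, seed = 1L,
                                 top_fraction = NULL,
                                 topology = mtssl_topology()) {
  stopifnot(inherits(library, "rotamer_library"))
  rs <- .resolve_site(structure, site)
  set.seed(as.integer(seed))
  conformers <- list()
  for (spec in library$rotamers) {
    variants <- list(spec$chi)
    for (d1 in c(-1, 0, 1) * spec$sd[1L]) {
      for (d2 in c(-1, 0, 1) * spec$sd[2L]) {
        if (d1 == 0 && d2 == 0) next
        variants[[length(variants) + 1L]] <- spec$chi + c(d1, d2, 0, 0, 0)
      }
    }
    if (n_perturb > 0L) {
      for (k in seq_len(n_perturb)) {
        variants[[length(variants) + 1L]] <-
          spec$chi + stats::rnorm(5L, 0, spec$sd / 2)
      }
    }
    for (chi in variants) {
      conf <- attach_rotamer(structure, site, list(id = spec$id, chi = chi),
                             topology)
      conf$clash_energy <- environment_clash(conf, structure, site,
                                             vdw_scale, topology)
      if (conf$clash_energy <= clash_cutoff) {
        conformers[[length(conformers) + 1L]] <- conf
      }
    }
  }
  params <- list(vdw_scale = vdw_scale, clash_cutoff = clash_cutoff, kT = kT,
                 n_perturb = as.integer(n_perturb), seed = as.integer(seed),
                 top_fraction = top_fraction)
  if (length(conformers) == 0L) {
    return(structure(list(site = site, conformers = list(), cb = rs$CB,
                          params = params, reason = "occluded site"),
                     class = "label_ensemble"))
  }
  energies <- vapply(conformers, `[[`, numeric(1L), "clash_energy")
  if (!is.null(top_fraction)) {
    stopifnot(top_fraction > 0, top_fraction <= 1)
    n_keep <- max(1L, ceiling(top_fraction * length(conformers)))
    keep <- order(energies)[seq_len(n_keep)]
    conformers <- conformers[keep]
    energies <- energies[keep]
  }
  w <- exp(-(energies - min(energies)) / kT)
  w <- w / sum(w)
  for (i in seq_along(conformers)) conformers[[i]]$weight <- w[i]
  structure(list(site = site, conformers = conformers, cb = rs$CB,
                 params = params, reason = NULL),
            class = "label_ensemble")
}

#' @export
print.label_ensemble <- function(x, ...) {
  cat(sprintf("MTSSL label ensemble at %s:%d%s: %d conformer(s)\n",
              x$site$chain, x$site$resno, x$site$icode, length(x$conformers)))
  if (!is.null(x$reason)) cat("  empty:", x$reason, "\n")
  else {
    cl <- vapply(x$conformers, `[[`, numeric(1L), "clash_energy")
    cat(sprintf("  clash energy range %.3g-%.3g, seed %d\n",
                min(cl), max(cl), x$params$seed))
  }
  invisible(x)
}

#' @export
length.label_ensemble <- function(x) length(x$conformers)

#' Write a labeled structure (residue renamed R1A)
#'
#' Replaces the site's native side chain beyond CB with the conformer's
#' label atoms and renames the residue R1A, following the usual mutant
#' naming for MTSSL-labeled sites.
#'
#' @param structure a `"protein_structure"`.
#' @param site a [site_spec()].
#' @param conformer a `"label_conformer"` built at that site.
#' @return a new `"protein_structure"` containing the label.
#' @export
label_structure <- function(structure, site, conformer) {
  stopifnot(inherits(conformer, "label_conformer"))
  rs <- .resolve_site(structure, site)
  at <- structure$atom
  res <- at[rs$atom_idx, ]
  bb <- res[res$elety %in% c("N", "CA", "C", "O", "CB", "H", "HA"), ]
  bb$resid <- "R1A"
  if (!"CB" %in% bb$elety) {
    cb_row <- bb[bb$elety == "CA", ][1L, ]
    cb_row$elety <- "CB"; cb_row$elesy <- "C"
    cb_row[, c("x", "y", "z")] <- as.list(rs$CB)
    bb <- rbind(bb, cb_row)
  }
  topo_names <- setdiff(rownames(conformer$xyz), c("N", "CA", "C", "O", "CB"))
  side <- data.frame(
    type = bb$type[1L], elety = topo_names, resid = "R1A",
    chain = site$chain, resno = site$resno, insert = site$icode,
    x = conformer$xyz[topo_names, 1L], y = conformer$xyz[topo_names, 2L],
    z = conformer$xyz[topo_names, 3L], o = 1, b = 0,
    elesy = substr(topo_names, 1L, 1L)
  )
  new_structure(rbind(at[-rs$atom_idx, ], bb, side))
}

#' Measure the chi angles of a labeled residue in a structure
#'
#' Reads the residue's own atoms; angles whose defining atoms are missing
#' come back as `NA` (unresolved).
#'
#' @param structure a `"protein_structure"`.
#' @param site a [site_spec()].
#' @param topology an [mtssl_topology()] supplying the chi definitions.
#' @return numeric length-5 chi vector in degrees (`NA` where unresolved).
#' @export
measure_site_chi <- function(structure, site, topology = mtssl_topology()) {
  stopifnot(inherits(structure, "protein_structure"), inherits(site, "site_spec"))
  vapply(topology$chi_atoms, function(atoms) {
    pts <- lapply(atoms, function(a) {
      atom_coord(structure, site$chain, site$resno, a, site$icode)
    })
    if (any(vapply(pts, is.null, logical(1L)))) return(NA_real_)
    measure_dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
  }, numeric(1L))
}

#' Write a label ensemble to JSON
#'
#' Records the site, generation parameters (including the seed), the site
#' backbone anchors, and per conformer the chi vector, weight, clash
#' energy and N-O midpoint.
#'
#' @param ensemble a `"label_ensemble"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "label_ensemble"))
  obj <- list(
    version = 1L,
    site = ensemble$site[c("chain", "resno", "icode")],
    cb = ensemble$cb,
    params = ensemble$params,
    reason = ensemble$reason,
    conformers = lapply(ensemble$conformers, function(cf) {
      list(spec_id = cf$spec_id, chi = cf$chi, weight = cf$weight,
           clash_energy = cf$clash_energy, midpoint = cf$midpoint)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a label ensemble from JSON
#'
#' Restores the fields written by [write_ensemble()] (full side-chain
#' coordinates are not stored; midpoints, weights and chi vectors are).
#'
#' @param path input path.
#' @return a `"label_ensemble"`.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$site) || is.null(obj$conformers)) {
    stop("malformed ensemble file: ", path, call. = FALSE)
  }
  conformers <- lapply(obj$conformers, function(cf) {
    structure(list(spec_id = cf$spec_id %||% NA_integer_,
                   chi = as.numeric(unlist(cf$chi)),
                   xyz = NULL,
                   midpoint = as.numeric(unlist(cf$midpoint)),
                   clash_energy = as.numeric(cf$clash_energy),
                   weight = as.numeric(cf$weight)),
              class = "label_conformer")
  })
  structure(list(site = site_spec(obj$site$chain, obj$site$resno,
                                  obj$site$icode %||% ""),
                 conformers = conformers,
                 cb = as.numeric(unlist(obj$cb)),
                 params = obj$params, reason = obj$reason),
            class = "label_ensemble")
}
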