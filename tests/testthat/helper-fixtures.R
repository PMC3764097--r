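# Shared fixtures (built once per test run) and independent oracles.

the_topology <- mtssl_topology()
the_library <- mtssl_library()

# small helix with an exposed central site, shared by labeling/cone tests
small_helix <- make_ideal_helix(14)
helix_site <- site_spec("A", 7)

.helix_ens_cache <- new.env(parent = emptyenv())
helix_ensemble <- function() {
  if (is.null(.helix_ens_cache$ens)) {
    .helix_ens_cache$ens <- sample_site_ensemble(
      small_helix, helix_site, the_library, seed = 11L,
      topology = the_topology)
  }
  .helix_ens_cache$ens
}

# independent torsion oracle (established implementation, different code path)
oracle_torsion <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)
}

# independent superposition RMSD oracle (full precision via fit.xyz)
oracle_fit_rmsd <- function(mobile, reference) {
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(reference)),
                   mobile = as.numeric(t(mobile))))
  fitted <- matrix(fitted, ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums((fitted - reference)^2)))
}

# exhaustive subset-selection oracle: best non-empty subset by the
# normalized cumulative Euclidean distance, via plain enumeration
oracle_best_subset <- function(pmat, experiment_probs) {
  n <- nrow(pmat)
  nb <- ncol(pmat)
  ce <- cumsum(experiment_probs)
  best <- list(objective = Inf, members = integer())
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    pooled <- colMeans(pmat[members, , drop = FALSE])
    obj <- sqrt(sum((cumsum(pooled) - ce)^2)) / nb
    if (obj < best$objective) best <- list(objective = obj, members = members)
  }
  best
}

# delta probability rows for a set of distances on a distribution's binning
delta_rows <- function(distances, dist) {
  nb <- length(dist$bin_centers)
  bw <- dist$bin_centers[2L] - dist$bin_centers[1L]
  lo <- dist$bin_centers[1L] - bw / 2
  idx <- pmin(pmax(ceiling((distances - lo) / bw), 1L), nb)
  m <- matrix(0, length(distances), nb)
  m[cbind(seq_along(distances), idx)] <- 1
  m
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}
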