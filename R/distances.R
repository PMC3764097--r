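# Inter-label distance distributions and the statistics used to compare a
# modeled distribution with a DEER/EPR measurement.

#' Construct a binned distance distribution
#'
#' @param bin_centers uniformly spaced bin centers in Angstrom.
#' @param probabilities non-negative weights, one per bin; normalized to
#'   sum 1.
#' @param mu,sigma summary mean / standard deviation in Angstrom. If `NULL`
#'   they are computed from the binned probabilities.
#' @return an object of class `"distance_distribution"`.
#' @export
distance_distribution <- function(bin_centers, probabilities,
                                  mu = NULL, sigma = NULL) {
  bin_centers <- as.numeric(bin_centers)
  probabilities <- as.numeric(probabilities)
  if (length(bin_centers) != length(probabilities)) {
    stop("bin_centers and probabilities must have equal length", call. = FALSE)
  }
  if (length(bin_centers) > 1L) {
    w <- diff(bin_centers)
    if (max(abs(w - w[1L])) > 1e-6) {
      stop("bin centers must be uniformly spaced", call. = FALSE)
    }
  }
  if (any(probabilities < 0) || !all(is.finite(probabilities))) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  tot <- sum(probabilities)
  if (tot <= 0) stop("probabilities sum to zero", call. = FALSE)
  probabilities <- probabilities / tot
  if (is.null(mu) || is.null(sigma)) {
    mu0 <- sum(bin_centers * probabilities)
    var0 <- sum((bin_centers - mu0)^2 * probabilities)
    if (is.null(mu)) mu <- mu0
    if (is.null(sigma)) sigma <- sqrt(max(0, var0))
  }
  structure(
    list(bin_centers = bin_centers, probabilities = probabilities,
         mu = mu, sigma = sigma),
    class = "distance_distribution"
  )
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "Distance distribution: %d bins (%.2f-%.2f A), mu = %.2f A, sigma = %.2f A\n",
    length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
    x$mu, x$sigma))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ..., xlab = "distance (A)",
                                       ylab = "probability", type = "h") {
  graphics::plot(x$bin_centers, x$probabilities, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# shared default binning: 0-100 A at 0.5 A covers the DEER working range
.default_bin_width <- 0.5
.default_bin_range <- c(0, 100)

.bin_centers <- function(bin_width, range) {
  seq(range[1L] + bin_width / 2, range[2L] - bin_width / 2, by = bin_width)
}

# drop weighted distances into bins (values outside the range land in the
# closest end bin)
.bin_weighted <- function(distances, weights, bin_width, range) {
  centers <- .bin_centers(bin_width, range)
  idx <- pmin(pmax(ceiling((distances - range[1L]) / bin_width), 1L),
              length(centers))
  probs <- vapply(seq_along(centers),
                  function(k) sum(weights[idx == k]), numeric(1L))
  list(centers = centers, probs = probs)
}

#' Distance between the unpaired-electron positions of two conformers
#'
#' The unpaired electron of the nitroxide sits at the midpoint of the N-O
#' bond; the inter-label distance is the Euclidean distance between the two
#' midpoints.
#'
#' @param conf_a,conf_b label conformers (see [attach_rotamer()]) or bare
#'   length-3 midpoint coordinates.
#' @return distance in Angstrom.
#' @export
midpoint_distance <- function(conf_a, conf_b) {
  pa <- if (is.list(conf_a)) conf_a$midpoint else conf_a
  pb <- if (is.list(conf_b)) conf_b$midpoint else conf_b
  if (is.null(pa) || is.null(pb)) {
    stop("conformer carries no N-O midpoint", call. = FALSE)
  }
  sqrt(sum((.as_point3(pa, "midpoint A") - .as_point3(pb, "midpoint B"))^2))
}

#' Inter-label distance distribution of two site ensembles
#'
#' Forms all conformer pairs between the ensembles, weights each pair by
#' the product of the conformer weights, and bins the midpoint distances.
#' The summary mu and sigma are the weighted mean and standard deviation of
#' the unbinned distances, so they carry no binning bias. With
#' `mode = "paired"` the ensembles are read as parallel model sets (one
#' distance per model index) instead of the full cross product.
#'
#' @param ens_a,ens_b label ensembles (see [sample_site_ensemble()]).
#' @param bin_width bin width in Angstrom.
#' @param range two-element distance range in Angstrom.
#' @param mode `"pairwise"` (cross product, weight products) or `"paired"`
#'   (index-matched conformers, mean pair weight).
#' @param use_cb substitute the site CB positions for the N-O midpoints
#'   (the crude backbone-only approximation, for comparison).
#' @return a [distance_distribution()].
#' @export
pair_distribution <- function(ens_a, ens_b,
                              bin_width = .default_bin_width,
                              range = .default_bin_range,
                              mode = c("pairwise", "paired"),
                              use_cb = FALSE) {
  mode <- match.arg(mode)
  for (e in list(ens_a, ens_b)) {
    if (!inherits(e, "label_ensemble")) {
      stop("inputs must be label ensembles", call. = FALSE)
    }
    if (length(e$conformers) == 0L) {
      stop("empty ensemble (reason: ", e$reason %||% "unknown", ")", call. = FALSE)
    }
  }
  point_of <- function(ens, conf) {
    if (use_cb) ens$cb else conf$midpoint
  }
  pa <- t(vapply(ens_a$conformers, function(cf) point_of(ens_a, cf), numeric(3L)))
  pb <- t(vapply(ens_b$conformers, function(cf) point_of(ens_b, cf), numeric(3L)))
  wa <- vapply(ens_a$conformers, `[[`, numeric(1L), "weight")
  wb <- vapply(ens_b$conformers, `[[`, numeric(1L), "weight")
  if (mode == "pairwise") {
    dmat <- sqrt(pmax(0, outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)))
    d <- as.numeric(dmat)
    w <- as.numeric(outer(wa, wb))
  } else {
    n <- min(nrow(pa), nrow(pb))
    d <- sqrt(rowSums((pa[seq_len(n), , drop = FALSE] -
                       pb[seq_len(n), , drop = FALSE])^2))
    w <- (wa[seq_len(n)] + wb[seq_len(n)]) / 2
  }
  w <- w / sum(w)
  mu <- sum(w * d)
  sigma <- sqrt(max(0, sum(w * (d - mu)^2)))
  b <- .bin_weighted(d, w, bin_width, range)
  distance_distribution(b$centers, b$probs, mu = mu, sigma = sigma)
}

#' Discretized Gaussian distance distribution
#'
#' The standard stand-in for an experimental DEER distribution reported
#' only as a mean and standard deviation. `sigma = 0` gives a delta at the
#' bin nearest `mu`.
#'
#' @param mu mean distance in Angstrom.
#' @param sigma standard deviation in Angstrom, >= 0.
#' @param bin_width,range binning as in [pair_distribution()].
#' @return a [distance_distribution()].
#' @export
gaussian_distribution <- function(mu, sigma,
                                  bin_width = .default_bin_width,
                                  range = .default_bin_range) {
  stopifnot(is.numeric(mu), is.numeric(sigma), sigma >= 0)
  centers <- .bin_centers(bin_width, range)
  if (sigma == 0) {
    probs <- numeric(length(centers))
    probs[which.min(abs(centers - mu))] <- 1
  } else {
    probs <- stats::dnorm(centers, mean = mu, sd = sigma)
    if (sum(probs) == 0) {
      stop("Gaussian mass falls entirely outside the binning range", call. = FALSE)
    }
  }
  distance_distribution(centers, probs)
}

#' Comparison statistics between model and experimental values
#'
#' MAE = mean |m - e|, RMSD = sqrt(mean (m - e)^2), R = Pearson
#' correlation. MAE <= RMSD always (Jensen's inequality).
#'
#' @param model,experiment paired numeric vectors (e.g. per-mutant mean
#'   distances), equal length.
#' @param statistics which statistics to compute. Computing `"r"` requires
#'   at least two pairs and non-zero variance on both sides.
#' @return named list with the requested entries `mae`, `rmsd`, `r`.
#' @export
compare_stats <- function(model, experiment,
                          statistics = c("mae", "rmsd", "r")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  model <- as.numeric(model)
  experiment <- as.numeric(experiment)
  if (length(model) != length(experiment)) {
    stop("model and experiment must have equal length", call. = FALSE)
  }
  if (length(model) < 1L) stop("at least one pair is required", call. = FALSE)
  out <- list()
  if ("mae" %in% statistics) out$mae <- mean(abs(model - experiment))
  if ("rmsd" %in% statistics) out$rmsd <- sqrt(mean((model - experiment)^2))
  if ("r" %in% statistics) {
    if (length(model) < 2L) {
      stop("Pearson R needs at least two pairs", call. = FALSE)
    }
    if (stats::sd(model) == 0 || stats::sd(experiment) == 0) {
      stop("Pearson R undefined for zero-variance input", call. = FALSE)
    }
    out$r <- stats::cor(model, experiment)
  }
  out
}

#' Broad-distribution exclusion rule
#'
#' A distance measurement is excluded from benchmarking when its standard
#' deviation exceeds half its mean: such breadth suggests the distribution
#' does not fall entirely within the usable DEER range.
#'
#' @param mu_epr measured mean distance in Angstrom, > 0.
#' @param sigma_epr measured standard deviation in Angstrom.
#' @return `"exclude"` if `sigma_epr > 0.5 * mu_epr`, else `"keep"`.
#' @export
exclusion_filter <- function(mu_epr, sigma_epr) {
  if (!is.numeric(mu_epr) || any(mu_epr <= 0)) {
    stop("mu_epr must be positive", call. = FALSE)
  }
  ifelse(sigma_epr > 0.5 * mu_epr, "exclude", "keep")
}

#' Write a distance distribution as tab-separated text
#'
#' Two columns, `distance_A` and `probability`, one row per bin.
#'
#' @param dist a [distance_distribution()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  df <- data.frame(distance_A = dist$bin_centers,
                   probability = dist$probabilities)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance distribution from tab-separated text
#'
#' Expects columns `distance_A` and `probability` (header required); lines
#' starting with `#` are ignored. Probabilities are renormalized to sum 1.
#'
#' @param path input path.
#' @return a [distance_distribution()].
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE)
  need <- c("distance_A", "probability")
  if (!all(need %in% names(df))) {
    stop("distribution file needs columns 'distance_A' and 'probability': ",
         path, call. = FALSE)
  }
  distance_distribution(df$distance_A, df$probability)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
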