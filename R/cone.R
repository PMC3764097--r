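# Implicit spin-label cone model: the explicit conformer ensemble at a
# site is summarized by an effective spin-label position SL_ef (mean N-O
# midpoint), a distance d = |CB -> SL_ef|, a tilt angle CA-CB-SL_ef, and
# a cone opening angle (the widest angle between any two conformer
# midpoints seen from CB). The model then treats each label as a point at
# distance d from CB in a randomly oriented direction, which yields a
# characteristic distribution of D_SL - D_Cbeta differences.

#' Effective spin-label position (SL_ef)
#'
#' The mean of the conformer N-O midpoints. Conformers of a single-site
#' ensemble already share a frame; point sets from separate models can be
#' brought into one frame first with [kabsch_superpose()] on the backbone
#' CA/HA/C/N/CB atoms.
#'
#' @param ensemble a `"label_ensemble"`, or an n x 3 matrix of midpoints.
#' @param weighted use the ensemble weights instead of a plain mean.
#' @return numeric length-3 SL_ef position.
#' @export
effective_position <- function(ensemble, weighted = FALSE) {
  if (inherits(ensemble, "label_ensemble")) {
    if (length(ensemble$conformers) == 0L) {
      stop("empty ensemble has no effective position", call. = FALSE)
    }
    mids <- t(vapply(ensemble$conformers, `[[`, numeric(3L), "midpoint"))
    w <- if (weighted) {
      vapply(ensemble$conformers, `[[`, numeric(1L), "weight")
    } else rep(1, nrow(mids))
  } else {
    mids <- .as_pointset(ensemble, "midpoints")
    if (nrow(mids) == 0L) stop("no midpoints given", call. = FALSE)
    w <- rep(1, nrow(mids))
  }
  as.numeric(colSums(mids * w) / sum(w))
}

#' Derive cone-model parameters from an explicit ensemble
#'
#' `d` is the CB to SL_ef distance; `tilt` the CA-CB-SL_ef angle;
#' `opening` the maximum pairwise angle between conformer midpoints with
#' vertex CB.
#'
#' @param ensemble a `"label_ensemble"` (midpoints + site CB), or an
#'   n x 3 midpoint matrix.
#' @param ca,cb site CA and CB coordinates; defaults come from the
#'   ensemble where available.
#' @param tether tether length recorded on the result (Angstrom).
#' @return an object of class `"cone_parameters"`: list with `d`, `tilt`,
#'   `opening`, `tether`.
#' @export
derive_cone_parameters <- function(ensemble, ca = NULL, cb = NULL,
                                   tether = 8.5) {
  if (inherits(ensemble, "label_ensemble")) {
    if (length(ensemble$conformers) == 0L) {
      stop("empty ensemble", call. = FALSE)
    }
    mids <- t(vapply(ensemble$conformers, `[[`, numeric(3L), "midpoint"))
    if (is.null(cb)) cb <- ensemble$cb
    if (is.null(ca) && !is.null(ensemble$conformers[[1L]]$xyz)) {
      ca <- ensemble$conformers[[1L]]$xyz["CA", ]
    }
  } else {
    mids <- .as_pointset(ensemble, "midpoints")
  }
  if (is.null(cb)) stop("CB coordinates are required", call. = FALSE)
  cb <- .as_point3(cb, "cb")
  slef <- effective_position(mids)
  d <- sqrt(sum((slef - cb)^2))
  tilt <- NA_real_
  if (!is.null(ca)) {
    if (d < 1e-9) stop("SL_ef coincides with CB; tilt undefined", call. = FALSE)
    tilt <- measure_angle(.as_point3(ca, "ca"), cb, slef)
  }
  opening <- 0
  if (nrow(mids) > 1L) {
    v <- sweep(mids, 2L, cb)
    nv <- sqrt(rowSums(v^2))
    if (any(nv < 1e-9)) stop("conformer midpoint coincides with CB", call. = FALSE)
    u <- v / nv
    cosang <- tcrossprod(u)
    cosang[] <- pmin(1, pmax(-1, cosang))
    opening <- max(acos(cosang[upper.tri(cosang)])) * RAD2DEG
  }
  structure(list(d = d, tilt = tilt, opening = opening, tether = tether),
            class = "cone_parameters")
}

#' @export
print.cone_parameters <- function(x, ...) {
  cat("Implicit spin-label cone parameters\n")
  cat(sprintf("  d (CB -> SL_ef): %.2f A\n", x$d))
  cat(sprintf("  tilt (CA-CB-SL_ef): %s\n",
              if (is.na(x$tilt)) "undetermined" else sprintf("%.1f deg", x$tilt)))
  cat(sprintf("  opening angle: %.1f deg (tether %.1f A)\n", x$opening, x$tether))
  invisible(x)
}

#' Cone-model d from tether length and opening angle
#'
#' The trigonometric relation of the implicit model: a label tether of
#' length L swinging inside a cone of opening angle omega projects the
#' effective position to `d = L * cos(omega / 2)` from CB. With the
#' canonical tether 8.5 A and opening 90 degrees this gives d of 6 A.
#'
#' @param tether tether length in Angstrom.
#' @param opening cone opening angle in degrees.
#' @return d in Angstrom.
#' @export
cone_d_from_opening <- function(tether = 8.5, opening = 90) {
  stopifnot(tether >= 0, opening >= 0, opening <= 180)
  tether * cos(opening / 2 * DEG2RAD)
}

#' Simulate the D_SL - D_Cbeta difference histogram
#'
#' Draws synthetic residue pairs: CB separations uniform in `sep_range`
#' and, per the model's random-orientation assumption, an isotropic random
#' direction for each label's SL_ef at distance `d` from its CB. Records
#' `D_SL - D_Cb` per pair and bins the fractions. Every difference is
#' bounded by `2 d` in magnitude (triangle inequality); the simulator
#' asserts this.
#'
#' @param params a `"cone_parameters"` (only `d` enters the isotropic
#'   simulation), or a single numeric d.
#' @param n_pairs number of simulated pairs, >= 1.
#' @param seed integer RNG seed.
#' @param sep_range range of CB-CB separations in Angstrom.
#' @param bin_width histogram bin width in Angstrom.
#' @return an object of class `"difference_histogram"`: list with
#'   `breaks` (bin edges), `fractions` (sum 1), `d`, `seed`, `n_pairs`.
#' @export
simulate_difference_histogram <- function(params, n_pairs = 10000L, seed = 1L,
                                          sep_range = c(10, 60),
                                          bin_width = 1) {
  d <- if (inherits(params, "cone_parameters")) params$d else as.numeric(params)
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0, n_pairs >= 1)
  set.seed(as.integer(seed))
  sep <- stats::runif(n_pairs, sep_range[1L], sep_range[2L])
  u1 <- .random_directions(n_pairs)
  u2 <- .random_directions(n_pairs)
  # CB1 at origin, CB2 at (sep, 0, 0); SL_i = CB_i + d * u_i
  dx <- sep + d * (u2[, 1L] - u1[, 1L])
  dy <- d * (u2[, 2L] - u1[, 2L])
  dz <- d * (u2[, 3L] - u1[, 3L])
  diff <- sqrt(dx^2 + dy^2 + dz^2) - sep
  stopifnot(all(abs(diff) <= 2 * d + 1e-9))
  lo <- floor(-2 * d / bin_width) * bin_width
  hi <- ceiling(2 * d / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(diff, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, fractions = h$counts / n_pairs,
                 d = d, seed = as.integer(seed), n_pairs = as.integer(n_pairs)),
            class = "difference_histogram")
}

.random_directions <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @export
print.difference_histogram <- function(x, ...) {
  cat(sprintf(
    "D_SL - D_Cb difference histogram: %d pairs, d = %.2f A, %d bins\n",
    x$n_pairs, x$d, length(x$fractions)))
  invisible(x)
}

#' @export
plot.difference_histogram <- function(x, ...,
                                      xlab = "D_SL - D_Cb (A)",
                                      ylab = "fraction") {
  mids <- (x$breaks[-1L] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mids, x$fractions, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
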