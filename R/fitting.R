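# Monte-Carlo selection of a model sub-ensemble whose pooled distance
# distribution matches an experimental one, scored by the normalized
# cumulative Euclidean distance between the binned distributions.

#' Cumulative Euclidean distance between two binned distributions
#'
#' The Euclidean norm of the difference between the running (cumulative)
#' sums of two probability vectors on identical binning:
#' `D_E = sqrt( sum_u ( sum_{i<=u} (p_i - q_i) )^2 )`, plus the
#' bin-count-normalized value `D_E / N`.
#'
#' @param p,q [distance_distribution()] objects (or bare probability
#'   vectors of equal length).
#' @return list with `de` and `normalized` (`de / N`, `N` = bin count).
#' @export
cumulative_euclidean <- function(p, q) {
  pp <- if (inherits(p, "distance_distribution")) p$probabilities else as.numeric(p)
  qq <- if (inherits(q, "distance_distribution")) q$probabilities else as.numeric(q)
  if (inherits(p, "distance_distribution") && inherits(q, "distance_distribution")) {
    if (length(p$bin_centers) != length(q$bin_centers) ||
        max(abs(p$bin_centers - q$bin_centers)) > 1e-9) {
      stop("distributions are on different binnings", call. = FALSE)
    }
  } else if (length(pp) != length(qq)) {
    stop("probability vectors differ in length", call. = FALSE)
  }
  de <- sqrt(sum(cumsum(pp - qq)^2))
  list(de = de, normalized = de / length(pp))
}

#' Fit a model sub-ensemble to an experimental distance distribution
#'
#' Greedy Monte-Carlo subset selection: starting from `start` (default
#' empty, in which case the first move must be an addition), each iteration
#' proposes adding a random non-member or removing a random member, and the
#' move is accepted only if the objective — the normalized cumulative
#' Euclidean distance between the equal-weight pooled member distribution
#' and the experiment — strictly decreases. Ties and uphill moves are
#' rejected; the run stops at `max_iter` proposals or after `patience`
#' consecutive rejections.
#'
#' @param candidates either a numeric vector of inter-label distances (one
#'   per model; each becomes a delta distribution on the experiment's
#'   binning) or a list of [distance_distribution()] objects on the
#'   experiment's binning.
#' @param experiment the target [distance_distribution()].
#' @param seed integer seed for the proposal stream.
#' @param max_iter maximum number of proposals.
#' @param start integer indices of the starting member set.
#' @param patience consecutive rejections before early stop.
#' Because only downhill moves are accepted, a single pass can stall in a
#' local optimum; when a pass stalls with proposal budget left, the search
#' restarts from `start` with a fresh proposal stream and the best
#' sub-ensemble over all passes is returned.
#'
#' @return an object of class `"mtssl_fit"`: list with `members` (selected
#'   candidate indices), `objective` (final normalized D_E), `trace`
#'   (objective after each accepted move of the best pass), `seed`,
#'   `iterations` (total proposals), `restarts`, `distribution` (the
#'   fitted pooled distribution).
#' @export
fit_ensemble_mc <- function(candidates, experiment, seed = 1L,
                            max_iter = 10000L, start = integer(0),
                            patience = 1000L) {
  stopifnot(inherits(experiment, "distance_distribution"))
  nb <- length(experiment$bin_centers)
  if (is.numeric(candidates)) {
    if (length(candidates) == 0L) stop("empty candidate set", call. = FALSE)
    bw <- experiment$bin_centers[2L] - experiment$bin_centers[1L]
    lo <- experiment$bin_centers[1L] - bw / 2
    idx <- pmin(pmax(ceiling((candidates - lo) / bw), 1L), nb)
    pmat <- matrix(0, length(candidates), nb)
    pmat[cbind(seq_along(candidates), idx)] <- 1
  } else if (is.list(candidates)) {
    if (length(candidates) == 0L) stop("empty candidate set", call. = FALSE)
    pmat <- t(vapply(candidates, function(d) {
      stopifnot(inherits(d, "distance_distribution"))
      if (length(d$bin_centers) != nb ||
          max(abs(d$bin_centers - experiment$bin_centers)) > 1e-9) {
        stop("candidate binning differs from the experiment's", call. = FALSE)
      }
      d$probabilities
    }, numeric(nb)))
  } else {
    stop("candidates must be distances or a list of distributions", call. = FALSE)
  }
  n <- nrow(pmat)
  cmat <- t(apply(pmat, 1L, cumsum))      # candidate CDFs
  ce <- cumsum(experiment$probabilities)  # experiment CDF
  objective_of <- function(members) {
    if (length(members) == 0L) return(Inf)
    csum <- colSums(cmat[members, , drop = FALSE]) / length(members)
    sqrt(sum((csum - ce)^2)) / nb
  }
  start <- as.integer(start)
  if (anyDuplicated(start) || any(start < 1L | start > n)) {
    stop("invalid start set", call. = FALSE)
  }
  set.seed(as.integer(seed))
  iter <- 0L
  restarts <- -1L
  best <- NULL
  repeat {
    restarts <- restarts + 1L
    members <- start
    inset <- logical(n)
    inset[members] <- TRUE
    obj <- objective_of(members)
    trace <- if (is.finite(obj)) obj else numeric(0)
    rejects <- 0L
    while (iter < max_iter && rejects < patience) {
      iter <- iter + 1L
      k <- length(members)
      add <- if (k == 0L) TRUE else if (k == n) FALSE else stats::runif(1) < 0.5
      if (add) {
        pick <- which(!inset)
        cand <- pick[sample.int(length(pick), 1L)]
        prop <- c(members, cand)
      } else {
        drop_i <- sample.int(k, 1L)
        cand <- members[drop_i]
        prop <- members[-drop_i]
      }
      pobj <- objective_of(prop)
      if (pobj < obj) {         # only favorable moves; ties rejected
        members <- prop
        inset[cand] <- add
        obj <- pobj
        trace <- c(trace, obj)
        rejects <- 0L
      } else {
        rejects <- rejects + 1L
      }
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(members = members, objective = obj, trace = trace)
    }
    if (iter >= max_iter || best$objective == 0) break
  }
  fitted <- if (length(best$members)) {
    distance_distribution(
      experiment$bin_centers,
      colSums(pmat[best$members, , drop = FALSE]) / length(best$members))
  } else NULL
  structure(
    list(members = sort(best$members), objective = best$objective,
         trace = best$trace, seed = as.integer(seed), iterations = iter,
         restarts = restarts, distribution = fitted),
    class = "mtssl_fit"
  )
}

#' @export
print.mtssl_fit <- function(x, ...) {
  cat("Monte-Carlo sub-ensemble fit\n")
  cat(sprintf("  members: %d  objective (D_E/N): %.6g  proposals: %d  seed: %d\n",
              length(x$members), x$objective, x$iterations, x$seed))
  invisible(x)
}

#' @export
summary.mtssl_fit <- function(object, ...) {
  cat("Monte-Carlo sub-ensemble fit\n")
  cat(sprintf("  selected members (%d): %s\n", length(object$members),
              paste(object$members, collapse = ", ")))
  cat(sprintf("  final objective D_E/N: %.6g\n", object$objective))
  cat(sprintf("  accepted moves: %d of %d proposals\n",
              length(object$trace), object$iterations))
  if (!is.null(object$distribution)) {
    cat(sprintf("  fitted distribution: mu = %.2f A, sigma = %.2f A\n",
                object$distribution$mu, object$distribution$sigma))
  }
  invisible(object)
}

#' @export
plot.mtssl_fit <- function(x, experiment = NULL, ...) {
  if (is.null(x$distribution)) {
    stop("fit has no members; nothing to plot", call. = FALSE)
  }
  d <- x$distribution
  graphics::plot(d$bin_centers, d$probabilities, type = "l",
                 xlab = "distance (A)", ylab = "probability", ...)
  if (!is.null(experiment)) {
    graphics::lines(experiment$bin_centers, experiment$probabilities,
                    lty = 2, col = "grey40")
    graphics::legend("topright", legend = c("fit", "experiment"),
                     lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}
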