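make_point_ensemble <- function(midpoints, weights = NULL, cb = c(0, 0, 0)) {
  n <- nrow(midpoints)
  if (is.null(weights)) weights <- rep(1 / n, n)
  conformers <- lapply(seq_len(n), function(i) {
    structure(list(spec_id = i, chi = rep(0, 5), xyz = NULL,
                   midpoint = as.numeric(midpoints[i, ]),
                   clash_energy = 0, weight = weights[i]),
              class = "label_conformer")
  })
  structure(list(site = site_spec("A", 1), conformers = conformers, cb = cb,
                 params = list(seed = 1L), reason = NULL),
            class = "label_ensemble")
}

test_that("midpoint distances are Euclidean norms", {
  expect_equal(midpoint_distance(c(0, 0, 0), c(0, 0, 10)), 10)
  expect_equal(midpoint_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(3)
  for (i in 1:10) {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    expect_equal(midpoint_distance(a, b),
                 sqrt(sum((a - b)^2)), tolerance = 1e-12)
  }
})

test_that("pair distributions match exhaustive enumeration", {
  # two single-conformer ensembles 10 A apart: a delta at 10
  e1 <- make_point_ensemble(matrix(c(0, 0, 0), 1L))
  e2 <- make_point_ensemble(matrix(c(0, 0, 10), 1L))
  dd <- pair_distribution(e1, e2)
  expect_equal(dd$mu, 10)
  expect_equal(dd$sigma, 0)
  expect_equal(sum(dd$probabilities > 0), 1L)
  expect_equal(dd$bin_centers[which.max(dd$probabilities)], 9.75)

  # 2x2 conformers with hand-set midpoints: exhaustive 4-pair oracle
  ma <- rbind(c(0, 0, 0), c(0, 0, 2))
  mb <- rbind(c(0, 0, 10), c(0, 3, 12))
  wa <- c(0.25, 0.75); wb <- c(0.5, 0.5)
  dd2 <- pair_distribution(make_point_ensemble(ma, wa),
                           make_point_ensemble(mb, wb))
  d <- c(); w <- c()
  for (i in 1:2) for (j in 1:2) {
    d <- c(d, sqrt(sum((ma[i, ] - mb[j, ])^2)))
    w <- c(w, wa[i] * wb[j])
  }
  mu <- sum(w * d) / sum(w)
  sg <- sqrt(sum(w * (d - mu)^2) / sum(w))
  expect_equal(dd2$mu, mu, tolerance = 1e-12)
  expect_equal(dd2$sigma, sg, tolerance = 1e-12)

  # symmetric two-peak construction: mean at the midpoint of the peaks
  e3 <- make_point_ensemble(rbind(c(0, 0, -5), c(0, 0, 5)))
  e4 <- make_point_ensemble(matrix(c(0, 0, 25), 1L))
  dd3 <- pair_distribution(e3, e4)
  expect_equal(dd3$mu, 25, tolerance = 1e-12)
})

test_that("pair distribution mean is invariant under joint rigid motion", {
  ens <- helix_ensemble()
  dd0 <- pair_distribution(ens, ens)
  set.seed(17)
  rot <- random_rotation()
  shift <- c(5, -3, 11)
  moved <- ens
  for (i in seq_along(moved$conformers)) {
    moved$conformers[[i]]$midpoint <-
      as.numeric(rot %*% moved$conformers[[i]]$midpoint + shift)
  }
  moved$cb <- as.numeric(rot %*% moved$cb + shift)
  dd1 <- pair_distribution(moved, moved)
  expect_equal(dd1$mu, dd0$mu, tolerance = 1e-9)
  expect_equal(dd1$sigma, dd0$sigma, tolerance = 1e-9)
})

test_that("paired mode reads ensembles as parallel model sets", {
  ma <- rbind(c(0, 0, 0), c(0, 0, 2))
  mb <- rbind(c(0, 0, 10), c(0, 0, 30))
  dd <- pair_distribution(make_point_ensemble(ma), make_point_ensemble(mb),
                          mode = "paired")
  expect_equal(dd$mu, mean(c(10, 28)))
})

test_that("the CB approximation flag substitutes CB coordinates", {
  e1 <- make_point_ensemble(matrix(c(0, 0, 6), 1L), cb = c(0, 0, 0))
  e2 <- make_point_ensemble(matrix(c(0, 0, 14), 1L), cb = c(0, 0, 20))
  expect_equal(pair_distribution(e1, e2)$mu, 8)
  expect_equal(pair_distribution(e1, e2, use_cb = TRUE)$mu, 20)
})

test_that("discretized Gaussians have the right peak, delta limit and moments", {
  g <- gaussian_distribution(30, 2)
  expect_equal(sum(g$probabilities), 1, tolerance = 1e-12)
  expect_equal(g$bin_centers[which.max(g$probabilities)], 30, tolerance = 0.25)
  expect_equal(g$mu, 30, tolerance = 0.5)
  expect_equal(g$sigma, 2, tolerance = 0.5)

  d <- gaussian_distribution(30, 0)
  expect_identical(sum(d$probabilities > 0), 1L)
  expect_equal(d$bin_centers[d$probabilities > 0], 29.75)
})

test_that("comparison statistics match hand calculation", {
  ident <- compare_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mae, 0)
  expect_equal(ident$rmsd, 0)
  expect_equal(ident$r, 1)

  st <- compare_stats(c(1, 2, 3), c(2, 2, 5))
  expect_equal(st$mae, 1.0)
  expect_equal(st$rmsd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(st$r, 1.5 / sqrt(3), tolerance = 1e-12)

  single <- compare_stats(3, 7, statistics = c("mae", "rmsd"))
  expect_equal(single$mae, 4)
  expect_equal(single$rmsd, 4)
  expect_error(compare_stats(3, 7), "at least two")
  expect_error(compare_stats(c(1, 1), c(1, 2)), "zero-variance")
  expect_error(compare_stats(1:3, 1:4), "equal length")
})

test_that("MAE never exceeds RMSD", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(2:30, 1L)
    m <- stats::rnorm(n, 30, 8)
    e <- m + stats::rnorm(n, 0, 4)
    st <- compare_stats(m, e, statistics = c("mae", "rmsd"))
    expect_lte(st$mae, st$rmsd + 1e-12)
  }
})

test_that("the breadth exclusion rule reproduces the excluded measurements", {
  expect_identical(exclusion_filter(6.5, 4.0), "exclude")
  expect_identical(exclusion_filter(19.0, 10.0), "exclude")
  expect_identical(exclusion_filter(9.0, 8.0), "exclude")
  expect_identical(exclusion_filter(13.0, 7.0), "exclude")
  expect_identical(exclusion_filter(40.0, 3.0), "keep")
  expect_identical(exclusion_filter(10, 5), "keep")  # boundary: not greater
  expect_error(exclusion_filter(0, 1), "positive")
})

test_that("every produced distribution is normalized", {
  dists <- list(
    gaussian_distribution(30, 2),
    gaussian_distribution(30, 0),
    make_synthetic_distribution(list(c(20, 2, 0.3), c(45, 5, 0.7))),
    pair_distribution(helix_ensemble(), helix_ensemble())
  )
  for (d in dists) expect_equal(sum(d$probabilities), 1, tolerance = 1e-9)
})

test_that("distribution files round-trip and tolerate comments", {
  d <- make_synthetic_distribution(list(c(25, 3, 1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(d, path)
  lines <- readLines(path)
  expect_identical(lines[1L], "distance_A\tprobability")
  writeLines(c("# a comment", lines), path)
  back <- read_distribution(path)
  expect_equal(back$probabilities, d$probabilities, tolerance = 1e-12)
  expect_equal(back$mu, d$mu, tolerance = 1e-9)
  expect_error(read_distribution(withr::local_tempfile()), "no such file")
})

test_that("empty ensembles are rejected by pair_distribution", {
  empty <- structure(list(site = site_spec("A", 1), conformers = list(),
                          cb = c(0, 0, 0), params = list(), reason = "occluded site"),
                     class = "label_ensemble")
  expect_error(pair_distribution(empty, helix_ensemble()), "occluded")
})
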