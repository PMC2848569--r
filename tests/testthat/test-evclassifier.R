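test_that("space distances follow Jaccard and Euclidean definitions", {
  expect_equal(space_distance(c(1L, 2L, 3L), c(1L, 2L, 3L), "binary"), 0)
  expect_equal(space_distance(c(1L, 2L), c(5L, 9L), "binary"), 1)
  expect_equal(space_distance(c(1L, 2L, 3L), c(2L, 3L, 4L), "binary"), 0.5)
  expect_equal(space_distance(integer(0), integer(0), "binary"), 0)
  expect_equal(space_distance(c(0, 3), c(4, 0), "continuous"), 5)
  expect_error(space_distance(c(1, 2), c(1, 2, 3), "continuous"), "mismatch")
})

test_that("pairwise and one-to-many Jaccard agree with the scalar definition", {
  set.seed(4)
  sets <- lapply(1:8, function(i) sort(sample(1:30, sample(0:6, 1))))
  D <- sublocr:::pairwise_jaccard(sets)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(D[i, j], space_distance(sets[[i]], sets[[j]], "binary"))
  }
  d1 <- sublocr:::jaccard_to_sets(sets[[1]], sets)
  expect_equal(d1, D[1, ])
})

test_that("neighbor masses follow alpha * exp(-gamma d^2) with frame remainder", {
  nb <- tibble::tibble(distance = c(0, 1, 1e6), class = c("a", "b", "a"))
  m <- neighbor_masses(nb, alpha = 0.95, gammas = c(a = 1, b = 1))
  expect_equal(unname(m[[1]]$singleton_masses), 0.95)
  expect_equal(m[[1]]$frame_mass, 0.05)
  expect_equal(unname(m[[2]]$singleton_masses), 0.95 * exp(-1))
  expect_equal(unname(m[[2]]$singleton_masses), 0.34946, tolerance = 1e-4)
  expect_lt(unname(m[[3]]$singleton_masses), 1e-300)
  expect_error(neighbor_masses(tibble::tibble(distance = Inf, class = "a")), "finite")
})

test_that("Dempster combination equals brute-force focal enumeration", {
  set.seed(99)
  for (rep in 1:60) {
    K <- sample(1:4, 1)
    classes <- sample(c("c1", "c2", "c3"), K, replace = TRUE)
    s <- runif(K, 0.01, 0.95)
    got <- combine_masses(neighbor_masses(
      tibble::tibble(distance = sqrt(-log(s / 0.95)), class = classes),
      alpha = 0.95, gammas = 1
    ))
    want <- brute_dempster(classes, s)
    expect_equal(as.numeric(got[names(want$belief)]), unname(want$belief),
                 tolerance = 1e-10)
    expect_equal(attr(got, "frame_mass"), want$frame, tolerance = 1e-10)
  }
})

test_that("combining a single assignment is the identity; agreement reinforces", {
  one <- neighbor_masses(tibble::tibble(distance = 0.5, class = "a"))
  cm <- combine_masses(one)
  expect_equal(as.numeric(cm["a"]), unname(one[[1]]$singleton_masses[1]))

  two <- neighbor_masses(tibble::tibble(distance = c(0.5, 0.6), class = "a"))
  joint <- combine_masses(two)
  expect_gte(as.numeric(joint["a"]), max(
    unname(two[[1]]$singleton_masses), unname(two[[2]]$singleton_masses)
  ))
})

test_that("combination order does not change the result", {
  nb <- tibble::tibble(distance = c(0.2, 0.7, 0.4), class = c("a", "b", "b"))
  m <- neighbor_masses(nb, gammas = c(a = 2, b = 0.5))
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    expect_equal(combine_masses(m[perm]), combine_masses(m), tolerance = 1e-12)
  }
})

test_that("the evidential vote follows the combined belief argmax", {
  lib <- reference_library(
    matrix(c(0.1, 0.2, 0.9), ncol = 1),
    c("A", "B", "B"), space = "continuous"
  )
  g <- c(A = 1, B = 1)
  # query at 0: distances 0.1, 0.2, 0.9
  for (K in 1:3) {
    got <- etknn_vote(0, lib, K = K, alpha = 0.95, gammas = g)
    d <- c(0.1, 0.2, 0.9)[1:K]
    cls <- c("A", "B", "B")[1:K]
    want <- brute_dempster(cls, 0.95 * exp(-d^2), c("A", "B"))
    expect_equal(got, names(which.max(want$belief)))
  }
})

test_that("K = 1 returns the nearest label and homogeneous neighborhoods their class", {
  lib <- toy_binary_library()
  expect_equal(etknn_vote(c(1:8, 21L), lib, K = 1), "inner")
  expect_equal(etknn_vote(c(11:18, 41L), lib, K = 5,
                          gammas = c(inner = 1, outer = 1)), "outer")
  expect_error(etknn_vote(c(1L), lib, K = 99), "outside")
})

test_that("library order only matters through the documented tie-break", {
  set.seed(5)
  M <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 5), 10, 2))
  lab <- rep(c("A", "B"), each = 10)
  lib <- reference_library(M, lab, space = "continuous")
  perm <- sample(20)
  lib2 <- reference_library(M[perm, ], lab[perm], space = "continuous")
  q <- c(0.3, -0.2)
  g <- fit_gammas(lib)
  expect_equal(etknn_vote(q, lib, 5, gammas = g), etknn_vote(q, lib2, 5, gammas = g))
})

test_that("with near-unit alpha and equal gammas the vote reduces to majority KNN", {
  set.seed(6)
  M <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2), matrix(rnorm(30, 6, 0.3), 15, 2))
  lab <- rep(c("near", "far"), each = 15)
  lib <- reference_library(M, lab, space = "continuous")
  for (q in list(c(0, 0), c(6, 6), c(2, 2))) {
    d <- sublocr:::euclid_to_rows(q, M)
    for (K in c(1, 3, 7)) {
      knn_major <- names(which.max(table(lab[order(d)[1:K]])))
      expect_equal(
        etknn_vote(q, lib, K, alpha = 0.999, gammas = c(far = 0.05, near = 0.05)),
        knn_major
      )
    }
  }
})

test_that("gamma fitting follows the inverse mean squared nearest-neighbor rule", {
  set.seed(7)
  M <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 4), 10, 2))
  lab <- rep(c("A", "B"), each = 10)
  lib <- reference_library(M, lab, space = "continuous")
  g <- fit_gammas(lib)
  # oracle: explicit nearest-neighbor computation per class
  for (cl in c("A", "B")) {
    rows <- which(lab == cl)
    nn <- vapply(rows, function(i) {
      min(sqrt(rowSums(sweep(M[setdiff(rows, i), , drop = FALSE], 2, M[i, ])^2)))
    }, numeric(1))
    expect_equal(unname(g[cl]), 1 / mean(nn^2))
  }
  # doubling all coordinates doubles distances and quarters every gamma
  g2 <- fit_gammas(reference_library(2 * M, lab, space = "continuous"))
  expect_equal(unname(g2), unname(g) / 4, tolerance = 1e-12)
})

test_that("degenerate classes fall back to the global scale", {
  M <- rbind(c(0, 0), c(0, 0), c(5, 5), c(6, 6))
  lib <- reference_library(M, c("dup", "dup", "ok", "ok"), space = "continuous")
  g <- fit_gammas(lib)
  # duplicated class has zero NN distance; falls back to the other class's scale
  expect_equal(unname(g["dup"]), unname(g["ok"]))
  expect_true(all(is.finite(g) & g > 0))

  solo <- reference_library(matrix(rnorm(10), 5, 2), rep("only", 5),
                            space = "continuous")
  gs <- fit_gammas(solo)
  expect_true(is.finite(gs["only"]) && gs["only"] > 0)
  expect_equal(etknn_vote(c(0, 0), solo, 3), "only")
})

test_that("library serialization round-trips features, labels and gammas", {
  lib <- toy_binary_library()
  d <- withr::local_tempdir()
  write_library(lib, d)
  back <- read_library(d)
  expect_equal(back$features, lib$features)
  expect_equal(as.character(back$labels), as.character(lib$labels))
  expect_equal(attr(back, "gammas"), fit_gammas(lib))

  cont <- reference_library(matrix(rnorm(20), 10, 2), rep(c("A", "B"), 5),
                            space = "continuous")
  d2 <- withr::local_tempdir()
  write_library(cont, d2)
  back2 <- read_library(d2)
  expect_equal(unname(back2$features), unname(cont$features), tolerance = 1e-9)
})
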