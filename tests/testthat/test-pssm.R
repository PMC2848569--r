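test_that("ASCII PSSM parsing recovers the residue column and score matrix", {
  set.seed(1)
  sc <- matrix(sample(-9:9, 60, replace = TRUE), 3, 20)
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down",
    paste(" ", paste(aa20, collapse = "  ")),
    sprintf("    1 M  %s", paste(sc[1, ], collapse = " ")),
    sprintf("    2 K  %s", paste(sc[2, ], collapse = " ")),
    sprintf("    3 A  %s", paste(sc[3, ], collapse = " "))
  )
  f <- withr::local_tempfile(fileext = ".pssm")
  writeLines(lines, f)
  p <- read_ascii_pssm(f)
  expect_s3_class(p, "pssm_profile")
  expect_equal(p$sequence, "MKA")
  expect_equal(unname(p$scores), sc)
})

test_that("columns beyond the 20 log-odds scores are ignored", {
  sc <- matrix(rep(1:20, each = 2), 2, 20, byrow = FALSE)
  sc[] <- seq_len(40) - 21L
  sentinel <- matrix(77L, 2, 20)  # fake weighted-percentage block
  rows <- vapply(1:2, function(i) {
    paste(c(i, "G", sc[i, ], sentinel[i, ], "0.35", "1.02"), collapse = " ")
  }, character(1))
  p <- read_ascii_pssm(c("header", rows))
  expect_equal(unname(p$scores), sc)
  expect_false(any(p$scores == 77L))
})

test_that("the amino-acid header fixes column order for PSI-BLAST layouts", {
  psiblast_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  vals <- 1:20  # score for psiblast_order[j] is j
  lines <- c(
    "Last position-specific scoring matrix computed",
    paste(" ", paste(psiblast_order, collapse = " ")),
    paste(c("1 M", vals), collapse = " ")
  )
  p <- read_ascii_pssm(lines)
  # column for each canonical amino acid must hold its PSI-BLAST position
  expect_equal(unname(p$scores[1, ]), match(aa20, psiblast_order))
})

test_that("malformed PSSM input is rejected with line context", {
  expect_error(read_ascii_pssm(c("header only", "another header")), "empty|not an ASCII")
  bad <- c("header", paste(c("1 M", 1:20), collapse = " "),
           paste(c("2 K", 1:12), collapse = " "))
  expect_error(read_ascii_pssm(bad), "line 3")
})

test_that("writer and reader round-trip the integer matrix exactly", {
  p <- random_profile(25, seed = 7)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_ascii_pssm(p, f)
  q <- read_ascii_pssm(f)
  expect_equal(q$sequence, p$sequence)
  expect_equal(q$scores, p$scores)
})

test_that("row standardization has zero mean, unit population spread, and handles degeneracy", {
  p <- pssm_profile("x", "MKW", rbind(
    rep(1L, 20),              # zero variance -> all-zero row
    c(1L, -1L, rep(0L, 18)),
    sample(-5:14, 20)
  ))
  z <- normalize_profile(p)
  expect_equal(z$values[1, ], setNames(rep(0, 20), aa20))
  expect_equal(unname(z$values[2, 1:2]), c(1, -1) / sqrt(0.1), tolerance = 1e-12)
  expect_equal(unname(z$values[2, 1]), 3.16227766, tolerance = 1e-7)
  expect_true(all(abs(rowMeans(z$values)) < 1e-9))
  nondeg <- 2:3
  expect_true(all(abs(sqrt(rowMeans(z$values[nondeg, ]^2)) - 1) < 1e-9))
})

test_that("standardization is idempotent and affine-invariant", {
  for (seed in 1:20) {
    p <- random_profile(8, seed = seed)
    z <- normalize_profile(p)
    z2 <- normalize_profile(z)
    expect_lt(max(abs(z2$values - z$values)), 1e-9)
    a <- runif(1, 0.1, 5)
    b <- runif(1, -10, 10)
    p2 <- pssm_profile("x", p$sequence, a * p$scores + b)
    expect_lt(max(abs(normalize_profile(p2)$values - z$values)), 1e-9)
  }
})

test_that("mean profile scores are column means", {
  one <- normalize_profile(random_profile(1, seed = 3))
  expect_equal(mean_profile_scores(one), one$values[1, ])

  r <- rnorm(20)
  z <- structure(list(protein_id = "x", values = rbind(r, -r)), class = "pssm_norm")
  expect_equal(unname(mean_profile_scores(z)), rep(0, 20))

  p <- normalize_profile(random_profile(12, seed = 9))
  expect_equal(mean_profile_scores(p), colMeans(p$values))
})

test_that("pseudo-PSSM degenerates to the mean vector at lag zero", {
  z <- normalize_profile(random_profile(30, seed = 11))
  v0 <- psepssm_vector(z, xi = 0)
  expect_length(v0, 20)
  expect_equal(unname(as.numeric(v0)), unname(mean_profile_scores(z)))
})

test_that("pseudo-PSSM matches the naive double-loop oracle", {
  for (seed in 1:15) {
    L <- sample(3:12, 1)
    z <- normalize_profile(random_profile(L, seed = 100 + seed))
    xi <- sample(seq_len(L - 1), 1)
    got <- as.numeric(psepssm_vector(z, xi = xi))
    expect_equal(got, unname(naive_psepssm(z$values, xi)), tolerance = 1e-12)
    expect_length(got, 40)
    expect_true(all(got[21:40] >= 0))
  }
})

test_that("constant score columns give zero correlation factors", {
  sc <- matrix(rep(seq(-9.5, 9.5, by = 1), each = 6), 6, 20)
  z <- normalize_profile(pssm_profile("c", "MKAWLY", sc))
  for (xi in 1:5) {
    expect_equal(unname(as.numeric(psepssm_vector(z, xi))[21:40]), rep(0, 20))
  }
})

test_that("out-of-range lags are errors, not silently capped", {
  z <- normalize_profile(random_profile(5, seed = 2))
  expect_error(psepssm_vector(z, 5), "L = 5")
  expect_error(psepssm_vector(z, 50), "0 <= xi <= 49")
  expect_error(psepssm_vector(z, -1), "0 <= xi <= 49")
})

test_that("batch featurization is a tidy table with 20 or 40 feature columns", {
  profs <- list(random_profile(10, seed = 1, id = "A"), random_profile(12, seed = 2, id = "B"))
  t0 <- psepssm_features(profs, xi = 0)
  expect_equal(dim(t0), c(2L, 22L))
  t5 <- psepssm_features(profs, xi = 5)
  expect_equal(dim(t5), c(2L, 42L))
  expect_equal(t5$protein_id, c("A", "B"))
})
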