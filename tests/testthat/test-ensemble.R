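test_that("the theta band selects vote shares near the maximum", {
  t1 <- vote_tally(c(A = 6, B = 3, C = 1), 10)
  expect_equal(multilabel_select(t1, 0.3), c("A", "B"))
  expect_equal(multilabel_select(t1, 0), "A")

  tie <- vote_tally(c(A = 5, B = 5, C = 0), 10)
  expect_equal(multilabel_select(tie, 0), c("A", "B"))

  # zero-vote locations never enter, even with a maximal band
  wide <- vote_tally(c(A = 10, B = 0), 10)
  expect_equal(multilabel_select(wide, 0.95), "A")

  expect_error(multilabel_select(t1, 1), "theta")
  expect_error(vote_tally(c(A = 5, B = 3), 10), "n_members")
})

test_that("the predicted set grows monotonically with theta", {
  set.seed(8)
  for (i in 1:200) {
    votes <- stats::rmultinom(1, 10, prob = runif(4))[, 1]
    names(votes) <- c("w", "x", "y", "z")
    tl <- vote_tally(votes, 10)
    thetas <- sort(runif(3, 0, 0.99))
    sets <- lapply(thetas, function(th) multilabel_select(tl, th))
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
    expect_true(length(sets[[1]]) >= 1)
  }
})

test_that("the GO engine casts exactly one vote per K and conserves votes", {
  lib <- toy_binary_library(n_per = 6)
  p <- go_engine_predict(go_stub(c(1:8, 25L)), lib, theta = 0.2)
  expect_s3_class(p, "loc_prediction")
  expect_equal(p$engine, "GO")
  expect_equal(p$tally$n_members, 10L)
  expect_equal(sum(p$tally$votes), 10L)
  # query inside the first cluster: unanimous prediction
  expect_equal(unname(p$tally$votes["inner"]), 10L)
  expect_equal(p$predicted_locations, "inner")
})

test_that("GO engine member count follows k_max and replays explicit votes", {
  lib <- toy_binary_library(n_per = 4)
  g <- fit_gammas(lib)
  q <- c(1:5, 11:13)  # straddles the two clusters
  p <- go_engine_predict(go_stub(q), lib, theta = 0, gammas = g, k_max = 7L)
  expect_equal(p$tally$n_members, 7L)
  manual <- vapply(1:7, function(K) etknn_vote(q, lib, K, gammas = g), character(1))
  expect_equal(unname(p$tally$votes),
               as.integer(table(factor(manual, levels = levels(lib$labels)))))
})

test_that("the SEQ engine fuses 500 members for chains of 50+ residues", {
  sl <- toy_seq_library(n_per = 5, L = 55, seed = 21)
  q <- toy_seq_query(sl, label = 1, seed = 22)
  p <- seq_engine_predict(q$fund, q$norm, sl$library, theta = 0.2)
  expect_equal(p$engine, "SEQ")
  expect_equal(p$tally$n_members, 500L)
  expect_equal(sum(p$tally$votes), 500L)
  expect_equal(p$predicted_locations, levels(sl$library$labels)[1])
})

test_that("a single-location SEQ library wins every member", {
  sl <- toy_seq_library(n_per = 10, L = 52, seed = 31, single_class = TRUE)
  q <- toy_seq_query(sl, label = 1, seed = 32)
  p <- seq_engine_predict(q$fund, q$norm, sl$library)
  expect_equal(unname(p$tally$votes[1]), 500L)
})

test_that("short chains truncate the lag range with a warning", {
  sl <- toy_seq_library(n_per = 5, L = 60, seed = 41)
  q <- toy_seq_query(sl, label = 2, seed = 42, L = 30)
  expect_warning(p <- seq_engine_predict(q$fund, q$norm, sl$library), "truncat")
  expect_equal(p$tally$n_members, 10L * 30L)
})

test_that("routing follows the productive-GO flowchart", {
  bm <- make_benchmark(synth_config(n_proteins = 30, n_locations = 3,
                                    orphan_frac = 0.3, max_len = 70, seed = 5))
  object <- loc_predictor(bm)
  res <- predict(object)
  feats <- object$features
  tgi <- training_go_index(object)
  for (j in seq_len(nrow(res))) {
    productive <- length(feats$go[[j]]) > 0 && any(feats$go[[j]] %in% tgi)
    expect_equal(res$engine[j], if (productive) "GO" else "SEQ")
  }
  # orphans have empty homology sets, hence SEQ
  expect_true(any(res$engine == "SEQ"))
  expect_true(any(res$engine == "GO"))
})

test_that("fragments are rejected and missing profiles are named", {
  bm <- make_benchmark(synth_config(n_proteins = 20, n_locations = 2,
                                    max_len = 60, seed = 6))
  object <- loc_predictor(bm)
  expect_error(
    predict_protein(object, strrep("A", 30)),
    "30 residues.*fragment|fragment"
  )
  # an orphan query without profile reaches the SEQ engine and errors cleanly
  expect_error(
    predict_protein(object, strrep("ACDEFGHIKL", 6), protein_id = "NOPSSM"),
    "NOPSSM.*no PSSM"
  )
})

test_that("prediction is deterministic for identical inputs", {
  bm <- make_benchmark(synth_config(n_proteins = 24, n_locations = 2,
                                    max_len = 60, seed = 7))
  object <- loc_predictor(bm)
  r1 <- predict(object)
  r2 <- predict(object)
  expect_identical(r1$locations, r2$locations)
  expect_identical(r1$engine, r2$engine)
})

test_that("tuned theta maximizes the penalized training score profile", {
  bm <- make_benchmark(synth_config(n_proteins = 30, n_locations = 3,
                                    max_len = 60, seed = 8))
  object <- loc_predictor(bm)
  th <- tune_theta(object)
  prof <- attr(th, "profile")
  expect_equal(max(prof$score), prof$score[prof$theta == as.numeric(th)])
  expect_true(th >= 0 && th < 1)
  expect_equal(object$theta, as.numeric(th), ignore_attr = TRUE)
})

test_that("prediction results tidy into share tables", {
  lib <- toy_binary_library()
  p <- go_engine_predict(go_stub(c(1:8, 21L)), lib)
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$votes), 10L)
  expect_true(all(td$share >= 0 & td$share <= 1))
  expect_s3_class(autoplot(p), "ggplot")
})
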