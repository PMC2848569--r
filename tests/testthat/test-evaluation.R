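test_that("virtual-sample accounting is the multiplicity-weighted sum", {
  vc <- virtual_counts(c(6687, 1029, 48, 2))
  expect_equal(vc$n_distinct, 7766)
  expect_equal(vc$n_virtual, 8897)
  expect_equal(vc$histogram$n, c(6687, 1029, 48, 2))

  expect_equal(virtual_counts(c(10, 0, 0))$n_virtual, 10)

  toy <- tibble::tibble(
    protein_id = c("a", "b", "c"),
    locations = list("L1", c("L1", "L2"), c("L1", "L2", "L3"))
  )
  vc3 <- virtual_counts(toy)
  expect_equal(vc3$n_distinct, 3)
  expect_equal(vc3$n_virtual, 6)

  bm <- tiny_benchmark(seed = 2)
  expect_equal(virtual_counts(bm)$n_virtual,
               sum(lengths(bm$proteins$locations)))
})

test_that("exact predictions score 1.0 in both conventions", {
  truth <- list(p1 = "A", p2 = c("A", "B"), p3 = "B")
  for (mode in c("locative", "penalized")) {
    r <- score_predictions(truth, truth, c("A", "B"), mode)
    expect_equal(r$overall_rate, 1)
    expect_true(all(r$per_location$rate == 1))
  }
})

test_that("the penalized convention shrinks credit for over- and under-prediction", {
  truth <- list(p = "A")
  pred <- list(p = c("A", "B"))
  loc <- score_predictions(truth, pred, c("A", "B"), "locative")
  pen <- score_predictions(truth, pred, c("A", "B"), "penalized")
  expect_equal(loc$per_location$correct[1], 1)
  expect_equal(pen$per_location$correct[1], 0.5)  # Jaccard 1/2

  # under-prediction: T = {A,B}, P = {A} credits the A sample 1/2, B nothing
  r <- score_predictions(list(p = c("A", "B")), list(p = "A"), c("A", "B"), "penalized")
  expect_equal(r$per_location$correct, c(0.5, 0))
  expect_error(score_predictions(truth, list(q = "A"), c("A", "B")), "same protein")
})

test_that("penalized rate never exceeds the locative rate", {
  set.seed(12)
  locs <- c("L1", "L2", "L3")
  for (rep in 1:25) {
    truth <- pred <- list()
    for (i in 1:8) {
      truth[[paste0("p", i)]] <- sample(locs, sample(1:3, 1))
      pred[[paste0("p", i)]] <- sample(locs, sample(1:3, 1))
    }
    l <- score_predictions(truth, pred, locs, "locative")
    p <- score_predictions(truth, pred, locs, "penalized")
    expect_lte(p$overall_rate, l$overall_rate + 1e-12)
    expect_equal(sum(l$per_location$total), sum(lengths(truth)))
  }
})

test_that("reports aggregate correct/total with the summed-total convention", {
  pl <- tibble::tibble(
    location = c("A", "B", "C"),
    correct = c(3, 1, 0),
    total = c(4L, 2L, 1L)
  )
  r <- loc_report(pl)
  expect_equal(r$overall_rate, 4 / 7)
  expect_equal(r$n_virtual, 7)
  expect_equal(glance(r)$overall_rate, 4 / 7)
  expect_equal(tidy(r)$rate, c(0.75, 0.5, 0))
  expect_error(loc_report(dplyr::mutate(pl, correct = total + 1)), "exceeds")
  expect_equal(format_rate(318, 385), "318/385 = 82.60%")
})

test_that("jackknife on separable single-location data is perfect and deterministic", {
  bm <- make_benchmark(synth_config(
    n_proteins = 24, n_locations = 3, multiplicity_probs = c(1, 0, 0, 0),
    max_len = 70, seed = 13
  ))
  jk1 <- jackknife(bm)
  expect_equal(jk1$locative$overall_rate, 1)
  expect_equal(jk1$penalized$overall_rate, 1)
  jk2 <- jackknife(bm)
  expect_identical(jk1$predictions$predicted, jk2$predictions$predicted)
  expect_equal(sum(jk1$locative$per_location$total), virtual_counts(bm)$n_virtual)
})

test_that("folds that lose a whole location are evaluated with a warning", {
  bm <- make_benchmark(synth_config(
    n_proteins = 12, n_locations = 2, multiplicity_probs = c(1, 0, 0, 0),
    orphan_frac = 0, max_len = 60, seed = 14
  ))
  # shrink one location to a single protein
  keep <- c(which(vapply(bm$proteins$locations, `[[`, "", 1) == bm$locations[1]),
            which(vapply(bm$proteins$locations, `[[`, "", 1) == bm$locations[2])[1])
  bm2 <- benchmark_dataset(
    proteins = bm$proteins[keep, ],
    locations = bm$locations,
    blast_hits = bm$blast_hits,
    go_annotations = bm$go_annotations,
    domain_hits = bm$domain_hits,
    profiles = bm$profiles[bm$proteins$protein_id[keep]],
    go_dimension = bm$go_dimension,
    fund_dimension = bm$fund_dimension
  )
  jk <- jackknife(bm2, loc_config(theta = 0))
  expect_true(any(grepl("lost location", jk$warnings)))
  expect_equal(nrow(jk$predictions), length(keep))
})

test_that("reports serialize to a tabular file plus JSON summary", {
  bm <- make_benchmark(synth_config(
    n_proteins = 16, n_locations = 2, multiplicity_probs = c(1, 0, 0, 0),
    max_len = 60, seed = 15
  ))
  jk <- jackknife(bm)
  d <- withr::local_tempdir()
  write_report(jk, file.path(d, "rep.tsv"), file.path(d, "rep.json"))
  tab <- readr::read_tsv(file.path(d, "rep.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("locative_correct", "penalized_correct", "total") %in% names(tab)))
  js <- jsonlite::read_json(file.path(d, "rep.json"))
  expect_equal(js$n_virtual, jk$locative$n_virtual)
  expect_s3_class(autoplot(jk), "ggplot")
})
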