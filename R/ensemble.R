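#' Construct a vote tally
#'
#' @param votes Named non-negative integer vector, one entry per location
#'   that received at least zero votes; the sum must equal `n_members`.
#' @param n_members Total number of ensemble members that voted.
#' @return An object of class `vote_tally`.
#' @export
vote_tally <- function(votes, n_members) {
  votes <- setNames(as.integer(votes), names(votes))
  if (any(votes < 0L)) abort("Vote counts must be non-negative.")
  if (sum(votes) != n_members) {
    abort(sprintf("Votes sum to %d but n_members = %d.", sum(votes), n_members))
  }
  structure(list(votes = votes, n_members = as.integer(n_members)),
            class = "vote_tally")
}

#' @export
print.vote_tally <- function(x, ...) {
  nz <- x$votes[x$votes > 0L]
  cat(sprintf(
    "<vote_tally> %d members: %s\n", x$n_members,
    paste(sprintf("%s %d", names(nz), nz), collapse = ", ")
  ))
  invisible(x)
}

#' Threshold-based multi-label decision
#'
#' Turns an ensemble vote tally into the set of predicted locations: with
#' vote shares `v(l) = votes(l) / n_members` and maximal share `v*`, every
#' location with at least one vote and share `v(l) >= v* - theta` is
#' predicted. `theta` therefore controls the count of reported location
#' sites: `theta = 0` returns the argmax set (all tied maxima), larger
#' `theta` admits runners-up within the band, and the predicted set grows
#' monotonically with `theta`. Zero-vote locations are never predicted.
#'
#' @param tally A [vote_tally()].
#' @param theta Band width below the maximal vote share, in `[0, 1)`.
#' @return Character vector of predicted locations (never empty).
#' @export
#' @examples
#' t <- vote_tally(c(A = 6, B = 3, C = 1), 10)
#' multilabel_select(t, theta = 0.3)  # A and B
multilabel_select <- function(tally, theta) {
  stopifnot(inherits(tally, "vote_tally"))
  if (theta < 0 || theta >= 1) abort("`theta` must lie in [0, 1).")
  if (tally$n_members < 1L) abort("Tally has no members.")
  shares <- tally$votes / tally$n_members
  vmax <- max(shares)
  names(tally$votes)[tally$votes >= 1L & shares >= vmax - theta]
}

.new_prediction <- function(protein_id, engine, tally, theta, truncated_xi = NULL) {
  structure(
    list(
      protein_id = protein_id,
      engine = engine,
      predicted_locations = multilabel_select(tally, theta),
      tally = tally,
      theta = theta,
      truncated_xi = truncated_xi
    ),
    class = "loc_prediction"
  )
}

#' @export
print.loc_prediction <- function(x, ...) {
  cat(sprintf(
    "<loc_prediction> %s [%s engine]: %s\n",
    x$protein_id, x$engine, paste(x$predicted_locations, collapse = "; ")
  ))
  invisible(x)
}

#' @export
#' @method tidy loc_prediction
tidy.loc_prediction <- function(x, ...) {
  tibble(
    protein_id = x$protein_id,
    location = names(x$tally$votes),
    votes = as.integer(x$tally$votes),
    share = as.numeric(x$tally$votes) / x$tally$n_members,
    predicted = names(x$tally$votes) %in% x$predicted_locations
  ) |> arrange(dplyr::desc(.data$votes), .data$location)
}

#' @export
#' @method autoplot loc_prediction
autoplot.loc_prediction <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$location, .data$share),
                                  y = .data$share, fill = .data$predicted)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = max(d$share) - object$theta, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "vote share",
      title = sprintf("%s (%s engine)", object$protein_id, object$engine),
      subtitle = sprintf("theta = %g band below the maximal share", object$theta)
    )
}

# Tally votes over a fixed location level set.
.tally_votes <- function(winners, levels, n_members) {
  v <- table(factor(winners, levels = levels))
  vote_tally(setNames(as.integer(v), levels), n_members)
}

#' GO-engine ensemble prediction
#'
#' The gene-ontology prediction engine: ten evidential KNN voters, one per
#' neighborhood size K = 1..`k_max`, each casting a single class vote on the
#' GO indicator space; the votes are fused into a tally and passed through
#' the `theta` multi-label decision.
#'
#' @param vec A [go_vector()] query.
#' @param library A binary-space [reference_library()] over the same GO
#'   dimension.
#' @param theta Multi-label band, see [multilabel_select()].
#' @param alpha,gammas Voter parameters, see [etknn_vote()].
#' @param k_max Largest neighborhood size (members K = 1..k_max, at most 10).
#' @return A `loc_prediction` with `engine = "GO"`.
#' @export
go_engine_predict <- function(vec, library, theta = 0.2, alpha = 0.95,
                              gammas = NULL, k_max = 10L) {
  stopifnot(inherits(library, "reference_library"))
  if (library$space != "binary") abort("The GO engine needs a binary-space library.")
  if (inherits(vec, "loc_indicator") && vec$dimension != library$dimension) {
    abort("GO vector and library dimensions differ.")
  }
  if (k_max < 1L || k_max > 10L) abort("`k_max` must lie in [1, 10].")
  q <- if (inherits(vec, "loc_indicator")) vec$idx else as.integer(vec)
  d <- jaccard_to_sets(q, library$features)
  gammas <- gammas %||% fit_gammas(library)
  winners <- vapply(seq_len(min(k_max, length(d))), function(K) {
    .vote_from_distances(d, library$labels, K, alpha, gammas)
  }, character(1))
  tally <- .tally_votes(winners, levels(library$labels), length(winners))
  pid <- if (inherits(vec, "loc_indicator")) vec$protein_id else "query"
  .new_prediction(pid, "GO", tally, theta)
}

#' Construct the sequence-evolution reference library set
#'
#' The training side of the sequence-evolution (SEQ) engine: per-protein
#' functional-domain index sets plus the pseudo-PSSM descriptor matrices for
#' every lag xi, expanded to virtual samples.
#'
#' @param fund List of domain index sets, one per virtual sample.
#' @param pse List over lags (element xi + 1 for lag xi) of numeric matrices
#'   with one row per virtual sample (NA rows where a lag is unavailable).
#' @param labels Location label per virtual sample.
#' @param protein_id Source protein id per virtual sample.
#' @param fund_dimension Dimension of the domain space.
#' @return An object of class `seq_reference_library`.
#' @export
seq_reference_library <- function(fund, pse, labels, protein_id = NULL,
                                  fund_dimension = 17402L) {
  n <- length(fund)
  stopifnot(is.list(pse), length(labels) == n,
            all(vapply(pse, nrow, integer(1)) == n))
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = sort(unique(labels)))
  structure(
    list(
      fund = fund,
      pse = pse,
      labels = labels,
      protein_id = as.character(protein_id %||% paste0("S", seq_len(n))),
      fund_dimension = as.integer(fund_dimension)
    ),
    class = "seq_reference_library"
  )
}

#' @export
print.seq_reference_library <- function(x, ...) {
  cat(sprintf(
    "<seq_reference_library> %d virtual samples, %d classes, lags 0..%d\n",
    length(x$labels), nlevels(x$labels), length(x$pse) - 1L
  ))
  invisible(x)
}

#' Sequence-evolution ensemble prediction
#'
#' The SEQ prediction engine for proteins that cannot be meaningfully
#' expressed in GO space: an ensemble indexed by the neighborhood size
#' K = 1..`k_max` and the pseudo-PSSM lag xi = 0..`xi_max` — 10 x 50 = 500
#' members at the defaults for any chain of at least 50 residues. Each
#' member casts one evidential KNN vote; with `joint_space = TRUE` (default)
#' member (K, xi) votes on the joint functional-domain + Pse-PSSM(xi) space,
#' whose distance is the convex combination
#' `d = w * d_FunD + (1 - w) * d_Pse / s` with `s` the mean training
#' Pse-PSSM distance at that lag; with `joint_space = FALSE` the domain
#' space and each lag space vote separately (K x (1 + number of lags)
#' members). Chains shorter than `xi_max + 1` residues truncate the usable
#' lag range to xi < L with a recorded warning.
#'
#' @param fund A [fund_vector()] query.
#' @param norm The query's standardized profile ([normalize_profile()]).
#' @param library A [seq_reference_library()].
#' @param theta Multi-label band.
#' @param alpha Evidential commitment parameter.
#' @param w Weight of the domain-space distance in the joint space.
#' @param k_max,xi_max Ensemble ranges (K = 1..k_max, xi = 0..xi_max).
#' @param power Pseudo-PSSM coupling exponent.
#' @param joint_space Joint-space members (default) or per-space voting.
#' @return A `loc_prediction` with `engine = "SEQ"`.
#' @export
seq_engine_predict <- function(fund, norm, library, theta = 0.2, alpha = 0.95,
                               w = 0.5, k_max = 10L, xi_max = 49L, power = 2,
                               joint_space = TRUE) {
  stopifnot(inherits(library, "seq_reference_library"), inherits(norm, "pssm_norm"))
  q_fund <- if (inherits(fund, "loc_indicator")) fund$idx else as.integer(fund)
  pid <- if (inherits(fund, "loc_indicator")) fund$protein_id else norm$protein_id
  L <- nrow(norm$values)
  xi_max <- min(xi_max, length(library$pse) - 1L)
  xis <- 0:xi_max
  if (L <= xi_max) {
    xis <- 0:(L - 1L)
    warn(sprintf(
      "Chain length %d truncates the pseudo-PSSM lag range to xi = 0..%d.",
      L, L - 1L
    ))
  }
  d_fund <- jaccard_to_sets(q_fund, library$fund)
  lv <- levels(library$labels)

  fund_pd <- NULL
  winners <- character(0)
  for (xi in xis) {
    M <- library$pse[[xi + 1L]]
    valid <- which(!is.na(M[, 1L]))
    qv <- as.numeric(psepssm_vector(norm, xi = xi, power = power))
    d_pse <- euclid_to_rows(qv, M[valid, , drop = FALSE])
    pse_pd <- as.matrix(dist(M[valid, , drop = FALSE]))
    s <- mean(pse_pd[upper.tri(pse_pd)])
    if (!is.finite(s) || s <= 0) s <- 1
    labs <- droplevels(library$labels[valid])
    if (joint_space) {
      if (is.null(fund_pd)) fund_pd <- pairwise_jaccard(library$fund)
      dq <- w * d_fund[valid] + (1 - w) * d_pse / s
      Dc <- w * fund_pd[valid, valid, drop = FALSE] + (1 - w) * pse_pd / s
      gam <- .gammas_from_dist(Dc, labs)
      for (K in seq_len(min(k_max, length(valid)))) {
        winners <- c(winners, .vote_from_distances(dq, labs, K, alpha, gam))
      }
    } else {
      gam <- .gammas_from_dist(pse_pd / s, labs)
      for (K in seq_len(min(k_max, length(valid)))) {
        winners <- c(winners, .vote_from_distances(d_pse / s, labs, K, alpha, gam))
      }
    }
  }
  if (!joint_space) {
    # one block of domain-space voters alongside the per-lag voters
    fund_pd <- pairwise_jaccard(library$fund)
    gam <- .gammas_from_dist(fund_pd, library$labels)
    for (K in seq_len(min(k_max, length(d_fund)))) {
      winners <- c(winners, .vote_from_distances(d_fund, library$labels, K, alpha, gam))
    }
  }
  tally <- .tally_votes(winners, lv, length(winners))
  .new_prediction(pid, "SEQ", tally, theta,
                  truncated_xi = if (length(xis) <= xi_max && L <= xi_max) max(xis) else NULL)
}

#' Fit the routing predictor on a benchmark
#'
#' Builds the full prediction pipeline from a labeled benchmark: featurizes
#' every protein (GO vector through homology transfer, functional-domain
#' vector, pseudo-PSSM descriptors at every lag), expands proteins into
#' virtual samples (one per location label), precomputes the pairwise
#' distance structure of every feature space, and fits the per-class
#' evidential scales. The resulting object routes queries between the GO and
#' SEQ engines exactly as [predict_protein()] describes.
#'
#' @param benchmark A [benchmark_dataset()].
#' @param config A [loc_config()].
#' @return An object of class `loc_predictor`.
#' @export
loc_predictor <- function(benchmark, config = loc_config()) {
  stopifnot(inherits(benchmark, "loc_benchmark"))
  feats <- featurize_benchmark(benchmark, config)
  vs <- virtual_samples(benchmark)
  p_idx <- match(vs$protein_id, feats$protein_id)
  label <- factor(vs$location, levels = benchmark$locations)

  go_pd <- pairwise_jaccard(feats$go)
  fund_pd <- pairwise_jaccard(feats$fund)
  pse_pd <- map(feats$pse, function(M) {
    valid <- !is.na(M[, 1L])
    D <- matrix(NA_real_, nrow(M), nrow(M))
    if (any(valid)) D[valid, valid] <- as.matrix(dist(M[valid, , drop = FALSE]))
    D
  })

  object <- structure(
    list(
      features = feats,
      vs = tibble(protein_idx = p_idx, label = label),
      truth = setNames(benchmark$proteins$locations, benchmark$proteins$protein_id),
      locations = benchmark$locations,
      config = config,
      theta = config$theta,
      annotations = benchmark$go_annotations,
      go_dimension = benchmark$go_dimension,
      fund_dimension = benchmark$fund_dimension,
      pairwise = list(go = go_pd, fund = fund_pd, pse = pse_pd)
    ),
    class = "loc_predictor"
  )
  if (is.null(object$theta)) object$theta <- as.numeric(tune_theta(object))
  object
}

#' Optimize the multi-label band on the training set
#'
#' The band `theta` exists to control the count of reported location sites
#' and to optimize the predicted results; this tunes it on the reference
#' data itself. The ensemble tallies of every training protein are computed
#' once (resubstitution), then each candidate `theta` is scored by the
#' penalized (Jaccard-weighted) overall success rate of the induced label
#' sets against the training truth; the smallest `theta` attaining the
#' maximum wins, so the band never grows without measurable benefit.
#'
#' @param object A [loc_predictor()].
#' @param grid Candidate values in `[0, 1)`. Default `seq(0, 0.95, 0.05)`.
#' @param mode Scoring convention to optimize, see [score_predictions()].
#'   Default `"penalized"`, which punishes both over- and under-prediction.
#' @return The selected `theta` (scalar), with the per-candidate score
#'   profile in attribute `profile`.
#' @export
tune_theta <- function(object, grid = seq(0, 0.95, by = 0.05),
                       mode = "penalized") {
  stopifnot(inherits(object, "loc_predictor"))
  res <- predict(object, theta = 0)
  tallies <- map(res$prediction, "tally")
  truth <- object$truth[res$protein_id]
  scores <- vapply(grid, function(th) {
    predl <- map(tallies, multilabel_select, theta = th)
    names(predl) <- res$protein_id
    score_predictions(truth, predl, object$locations, mode)$overall_rate
  }, numeric(1))
  best <- grid[which.max(scores)]
  attr(best, "profile") <- tibble(theta = grid, score = scores)
  best
}

#' @export
print.loc_predictor <- function(x, ...) {
  cat(sprintf(
    "<loc_predictor> %d training proteins (%d virtual samples), %d locations\n",
    length(x$features$protein_id), nrow(x$vs), length(x$locations)
  ))
  cat(sprintf("  thresholds: identity >= %g%%, E(GO) <= %g, E(FunD) <= %g\n",
              x$config$identity_min, x$config$evalue_max_go, x$config$evalue_max_fund))
  cat(sprintf("  engine: alpha = %g, theta = %g%s, K = 1..%d, xi = 0..%d, w = %g\n",
              x$config$alpha, x$theta, if (is.null(x$config$theta)) " (tuned)" else "",
              x$config$k_max, x$config$xi_max, x$config$w))
  invisible(x)
}

#' @export
#' @method glance loc_predictor
glance.loc_predictor <- function(x, ...) {
  tibble(
    n_proteins = length(x$features$protein_id),
    n_virtual = nrow(x$vs),
    n_locations = length(x$locations),
    go_dimension = x$go_dimension,
    fund_dimension = x$fund_dimension,
    theta = x$theta,
    alpha = x$config$alpha
  )
}

#' GO indices represented in a predictor's training library
#'
#' @param object A [loc_predictor()].
#' @param train_proteins Optional integer indices restricting the training
#'   proteins (used by the jackknife folds).
#' @return Sorted integer vector of GO indices.
#' @export
training_go_index <- function(object, train_proteins = NULL) {
  idx <- object$features$go
  if (!is.null(train_proteins)) idx <- idx[train_proteins]
  sort(unique(unlist(idx)))
}

# --- internal routing core -------------------------------------------------

# Predict one query given its distances to the training proteins.
# q: list(protein_id, go_idx, fund_idx, norm, length,
#         d_go, d_fund, d_pse = list per xi or NULL)
# train: integer indices of training proteins (columns of the distance rows).
.route_and_predict <- function(q, object, train, theta = NULL) {
  cfg <- object$config
  theta <- theta %||% object$theta %||% 0.2
  if (q$length < cfg$min_length) {
    abort(sprintf(
      "Sequence %s has %d residues; sequences with less than %d amino acid residues are deemed fragments and are rejected.",
      q$protein_id, q$length, cfg$min_length
    ))
  }
  vs_keep <- which(object$vs$protein_idx %in% train)
  vs_p <- object$vs$protein_idx[vs_keep]
  vs_lab <- object$vs$label[vs_keep]

  productive <- length(q$go_idx) > 0L &&
    any(q$go_idx %in% training_go_index(object, train))

  if (productive) {
    d_vs <- q$d_go[match(vs_p, train)]
    gam <- .gammas_from_vs(object$pairwise$go, vs_p, vs_lab)
    winners <- vapply(seq_len(min(cfg$k_max, length(d_vs))), function(K) {
      .vote_from_distances(d_vs, vs_lab, K, cfg$alpha, gam)
    }, character(1))
    tally <- .tally_votes(winners, levels(vs_lab), length(winners))
    return(.new_prediction(q$protein_id, "GO", tally, theta))
  }

  if (is.null(q$norm)) {
    abort(sprintf(
      "Protein %s routes to the sequence-evolution engine but has no PSSM profile.",
      q$protein_id
    ))
  }
  xi_hi <- min(cfg$xi_max, q$length - 1L)
  if (xi_hi < cfg$xi_max) {
    warn(sprintf(
      "Chain length %d truncates the pseudo-PSSM lag range to xi = 0..%d.",
      q$length, xi_hi
    ))
  }
  w <- cfg$w
  winners <- character(0)
  for (xi in 0:xi_hi) {
    P <- object$pairwise$pse[[xi + 1L]]
    valid_tr <- train[!is.na(diag(P)[train])]
    if (!length(valid_tr)) next
    sub <- P[valid_tr, valid_tr, drop = FALSE]
    s <- mean(sub[upper.tri(sub)])
    if (!is.finite(s) || s <= 0) s <- 1
    keep2 <- which(vs_p %in% valid_tr)
    vsp2 <- vs_p[keep2]
    lab2 <- vs_lab[keep2]
    d_pse_q <- q$d_pse[[xi + 1L]]
    pos <- match(vsp2, train)
    if (cfg$joint_space) {
      dq <- w * q$d_fund[pos] + (1 - w) * d_pse_q[pos] / s
      Dc <- w * object$pairwise$fund[valid_tr, valid_tr, drop = FALSE] + (1 - w) * sub / s
      gam <- .gammas_from_vs(Dc, match(vsp2, valid_tr), lab2, is_sub = TRUE)
      for (K in seq_len(min(cfg$k_max, length(keep2)))) {
        winners <- c(winners, .vote_from_distances(dq, lab2, K, cfg$alpha, gam))
      }
    } else {
      gam <- .gammas_from_vs(sub / s, match(vsp2, valid_tr), lab2, is_sub = TRUE)
      for (K in seq_len(min(cfg$k_max, length(keep2)))) {
        winners <- c(winners, .vote_from_distances(d_pse_q[pos] / s, lab2, K, cfg$alpha, gam))
      }
    }
  }
  if (!cfg$joint_space) {
    gam <- .gammas_from_vs(object$pairwise$fund, vs_p, vs_lab)
    for (K in seq_len(min(cfg$k_max, length(vs_p)))) {
      winners <- c(winners,
                   .vote_from_distances(q$d_fund[match(vs_p, train)], vs_lab, K, cfg$alpha, gam))
    }
  }
  tally <- .tally_votes(winners, levels(vs_lab), length(winners))
  .new_prediction(q$protein_id, "SEQ", tally, theta,
                  truncated_xi = if (xi_hi < cfg$xi_max) xi_hi else NULL)
}

# Per-class gammas from a protein-level distance matrix and the virtual
# samples (protein index, label). With is_sub = TRUE the first argument is
# already restricted and vs_p indexes into it directly.
.gammas_from_vs <- function(pd, vs_p, vs_lab, is_sub = FALSE) {
  lv <- levels(vs_lab)
  nn2 <- rep(NA_real_, length(lv))
  names(nn2) <- lv
  for (k in seq_along(lv)) {
    rows <- vs_p[vs_lab == lv[k]]
    if (length(rows) >= 2L) {
      sub <- pd[rows, rows, drop = FALSE]
      diag(sub) <- Inf
      nn2[k] <- mean(apply(sub, 1L, min)^2)
    }
  }
  global <- mean(nn2[!is.na(nn2) & nn2 > 0])
  if (!is.finite(global) || global <= 0) global <- 1
  nn2[is.na(nn2) | nn2 <= 0] <- global
  1 / nn2
}

# Build the query structure for training protein i against training set
# `train` using the precomputed pairwise matrices.
.internal_query <- function(object, i, train) {
  f <- object$features
  list(
    protein_id = f$protein_id[i],
    go_idx = f$go[[i]],
    fund_idx = f$fund[[i]],
    norm = f$norm[[i]],
    length = f$lengths[i],
    d_go = object$pairwise$go[i, train],
    d_fund = object$pairwise$fund[i, train],
    d_pse = map(object$pairwise$pse, function(P) P[i, train])
  )
}

#' Predict the locations of a single protein record
#'
#' Convenience wrapper around [predict.loc_predictor()] for one query given
#' its raw feature resources. The routing follows the prediction flowchart:
#' fragment check first, then the GO engine if the homology-transferred GO
#' vector is productive for the training library, otherwise the
#' sequence-evolution engine (which requires the PSSM profile).
#'
#' @param object A fitted [loc_predictor()].
#' @param sequence Query residue string.
#' @param blast_hits BLAST hit tibble for the query (against the reference
#'   set); may be empty.
#' @param domain_hits Domain hit tibble (`domain_index`, `evalue`); may be
#'   empty.
#' @param profile The query's [pssm_profile()], or `NULL`.
#' @param protein_id Query identifier.
#' @param theta Optional multi-label band override.
#' @return A `loc_prediction`.
#' @export
predict_protein <- function(object, sequence,
                            blast_hits = NULL, domain_hits = NULL,
                            profile = NULL, protein_id = "query", theta = NULL) {
  stopifnot(inherits(object, "loc_predictor"))
  bh <- blast_hits %||% tibble(qseqid = character(), sseqid = character(),
                               pident = numeric(), evalue = numeric())
  dh <- domain_hits %||% tibble(domain_index = integer(), evalue = numeric())
  if (!"protein_id" %in% names(dh)) dh$protein_id <- protein_id
  profs <- list()
  if (!is.null(profile)) profs[[protein_id]] <- profile
  qb <- benchmark_dataset(
    proteins = tibble(protein_id = protein_id, sequence = as.character(sequence),
                      locations = list(object$locations[1])),
    locations = object$locations,
    blast_hits = bh,
    domain_hits = dh,
    profiles = profs,
    go_dimension = object$go_dimension,
    fund_dimension = object$fund_dimension
  )
  res <- predict(object, newdata = qb, theta = theta)
  res$prediction[[1]]
}

#' Predict subcellular locations for new proteins
#'
#' Routes each query through the two-engine flowchart: a query whose GO
#' vector is a productive descriptor for the training library is classified
#' by the GO engine; a query with an empty homology set, or whose GO terms no
#' training sample shares, falls through to the sequence-evolution engine
#' (functional-domain + pseudo-PSSM ensemble). Sequences shorter than the
#' fragment threshold (50 residues by default) are rejected.
#'
#' @param object A fitted [loc_predictor()].
#' @param newdata A [benchmark_dataset()] holding the query proteins, their
#'   BLAST hits against the reference set, domain hits and PSSM profiles.
#'   `NULL` predicts the training proteins themselves (resubstitution).
#' @param theta Optional override of the configured multi-label band.
#' @param ... Unused.
#' @return A tibble with one row per query: `protein_id`, `engine`,
#'   `locations` (list column), `n_locations`, and `prediction` (list column
#'   of `loc_prediction` objects carrying the full tallies).
#' @export
predict.loc_predictor <- function(object, newdata = NULL, theta = NULL, ...) {
  cfg <- object$config
  train <- seq_along(object$features$protein_id)
  if (is.null(newdata)) {
    preds <- map(train, function(i) .route_and_predict(.internal_query(object, i, train), object, train, theta))
  } else {
    stopifnot(inherits(newdata, "loc_benchmark"))
    ann <- distinct(bind_rows(object$annotations, newdata$go_annotations))
    qb <- newdata
    qb$go_annotations <- ann
    qfeats <- featurize_benchmark(qb, cfg)
    preds <- map(seq_along(qfeats$protein_id), function(j) {
      q <- list(
        protein_id = qfeats$protein_id[j],
        go_idx = qfeats$go[[j]],
        fund_idx = qfeats$fund[[j]],
        norm = qfeats$norm[[j]],
        length = qfeats$lengths[j],
        d_go = jaccard_to_sets(qfeats$go[[j]], object$features$go),
        d_fund = jaccard_to_sets(qfeats$fund[[j]], object$features$fund),
        d_pse = map(seq_along(object$pairwise$pse), function(xik) {
          xi <- xik - 1L
          M <- object$features$pse[[xik]]
          if (is.null(qfeats$norm[[j]]) || qfeats$lengths[j] <= xi) return(rep(NA_real_, nrow(M)))
          qv <- as.numeric(psepssm_vector(qfeats$norm[[j]], xi = xi, power = cfg$power))
          out <- rep(NA_real_, nrow(M))
          valid <- !is.na(M[, 1L])
          out[valid] <- euclid_to_rows(qv, M[valid, , drop = FALSE])
          out
        })
      )
      .route_and_predict(q, object, train, theta)
    })
  }
  tibble(
    protein_id = map_chr(preds, "protein_id"),
    engine = map_chr(preds, "engine"),
    locations = map(preds, "predicted_locations"),
    n_locations = lengths(map(preds, "predicted_locations")),
    prediction = preds
  )
}
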