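# Shared fixture builders and independent oracles.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_profile <- function(L = 10, seed = NULL, id = "P1") {
  if (!is.null(seed)) set.seed(seed)
  pssm_profile(id,
               paste(sample(aa20, L, replace = TRUE), collapse = ""),
               matrix(sample(-8:8, L * 20, replace = TRUE), L, 20))
}

# Naive double-loop pseudo-PSSM oracle (means + squared-difference lags).
naive_psepssm <- function(E, xi) {
  L <- nrow(E)
  means <- numeric(20)
  for (j in 1:20) means[j] <- sum(E[, j]) / L
  if (xi == 0) return(means)
  G <- numeric(20)
  for (j in 1:20) {
    acc <- 0
    for (i in 1:(L - xi)) acc <- acc + (E[i, j] - E[i + xi, j])^2
    G[j] <- acc / (L - xi)
  }
  c(means, G)
}

# Brute-force Dempster combination over all 2^K focal-set products.
brute_dempster <- function(classes, s, all_classes = sort(unique(classes))) {
  K <- length(s)
  bel <- stats::setNames(numeric(length(all_classes)), all_classes)
  frame <- 0
  conflict <- 0
  for (choice in 0:(2^K - 1)) {
    bits <- as.integer(intToBits(choice))[seq_len(K)]
    mass <- prod(ifelse(bits == 1, s, 1 - s))
    chosen <- unique(classes[bits == 1])
    if (length(chosen) == 0) {
      frame <- frame + mass
    } else if (length(chosen) == 1) {
      bel[chosen] <- bel[chosen] + mass
    } else {
      conflict <- conflict + mass
    }
  }
  tot <- sum(bel) + frame
  list(belief = bel / tot, frame = frame / tot)
}

# Two well-separated binary clusters for classifier tests.
toy_binary_library <- function(n_per = 5, dimension = 100) {
  feats <- c(
    lapply(seq_len(n_per), function(i) sort(c(1:8, 20L + i))),
    lapply(seq_len(n_per), function(i) sort(c(11:18, 40L + i)))
  )
  reference_library(feats, rep(c("inner", "outer"), each = n_per),
                    space = "binary", dimension = dimension)
}

# Minimal in-memory benchmark with hand-placed features.
tiny_benchmark <- function(n_per = 4, seed = 42, n_locations = 2, noise = 0,
                           orphan_frac = 0.25, n = NULL) {
  make_benchmark(synth_config(
    n_proteins = n %||% (n_per * n_locations * 2L),
    n_locations = n_locations,
    noise = noise, orphan_frac = orphan_frac,
    max_len = 80L, seed = seed
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A GO-vector-shaped stub over a small dimension.
go_stub <- function(idx, dimension = 100L, id = "query") {
  structure(list(protein_id = id, dimension = as.integer(dimension),
                 idx = sort(unique(as.integer(idx)))),
            class = c("go_vector", "loc_indicator"))
}

# Two-class (or one-class) sequence-evolution library built from synthetic
# profiles with class-specific PSSM signatures and disjoint domain blocks.
toy_seq_library <- function(n_per = 3, L = 55, seed = 1, single_class = FALSE) {
  set.seed(seed)
  sigs <- list(rnorm(20), rnorm(20))
  classes <- if (isTRUE(single_class)) 1L else 1:2
  profs <- list(); fund <- list(); labels <- character(0)
  for (cl in classes) {
    for (i in seq_len(n_per)) {
      sc <- round(matrix(rnorm(L * 20, sd = 2), L, 20) +
                    4 * matrix(sigs[[cl]], L, 20, byrow = TRUE))
      id <- sprintf("c%d_%d", cl, i)
      profs[[id]] <- pssm_profile(id, paste(sample(aa20, L, TRUE), collapse = ""), sc)
      fund[[id]] <- sort(((cl - 1L) * 10L + 1L):((cl - 1L) * 10L + 6L))
      labels <- c(labels, paste0("class", cl))
    }
  }
  norms <- lapply(profs, normalize_profile)
  pse <- lapply(0:49, function(xi) {
    do.call(rbind, lapply(norms, function(z) as.numeric(psepssm_vector(z, xi))))
  })
  list(
    library = seq_reference_library(unname(fund), pse, labels,
                                    protein_id = names(profs),
                                    fund_dimension = 50L),
    sigs = sigs
  )
}

toy_seq_query <- function(sl, label = 1, seed = 2, L = NULL) {
  set.seed(seed)
  L <- L %||% 55L
  sc <- round(matrix(rnorm(L * 20, sd = 2), L, 20) +
                4 * matrix(sl$sigs[[label]], L, 20, byrow = TRUE))
  prof <- pssm_profile("query", paste(sample(aa20, L, TRUE), collapse = ""), sc)
  list(
    fund = sort(((label - 1L) * 10L + 1L):((label - 1L) * 10L + 6L)),
    norm = normalize_profile(prof)
  )
}
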