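#' Construct a reference library of virtual samples
#'
#' A reference library holds the training side of one evidential KNN voter:
#' one feature vector per virtual sample (a protein appears once per location
#' it belongs to) together with its single location label. Two feature-space
#' kinds are supported: `"binary"` (sparse indicator vectors, e.g. GO or
#' functional-domain space, compared by Jaccard distance) and `"continuous"`
#' (dense numeric vectors, e.g. pseudo-PSSM descriptors, compared by
#' Euclidean distance).
#'
#' @param features For `space = "binary"`, a list of sorted integer index
#'   vectors; for `"continuous"`, a numeric matrix with one row per sample.
#' @param labels Location label of each sample (character or factor);
#'   coerced to a factor whose level order fixes all tie-breaks.
#' @param protein_id Optional source protein id per sample.
#' @param space `"binary"` or `"continuous"`.
#' @param dimension Dimension of the feature space (required for binary
#'   features; inferred from the matrix otherwise).
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(features, labels,
                              protein_id = NULL,
                              space = c("binary", "continuous"),
                              dimension = NULL) {
  space <- match.arg(space)
  if (space == "binary") {
    stopifnot(is.list(features))
    n <- length(features)
    if (is.null(dimension)) {
      abort("`dimension` is required for a binary-space library.")
    }
  } else {
    features <- as.matrix(features)
    n <- nrow(features)
    dimension <- ncol(features)
  }
  if (n < 1L) abort("A reference library needs at least one sample.")
  if (length(labels) != n) abort("`labels` length must match the number of samples.")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = unique(labels) |> sort())
  structure(
    list(
      features = features,
      labels = labels,
      protein_id = as.character(protein_id %||% paste0("S", seq_len(n))),
      space = space,
      dimension = as.integer(dimension)
    ),
    class = "reference_library"
  )
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf(
    "<reference_library> %d virtual samples, %d classes, %s space (dim %d)\n",
    length(x$labels), nlevels(x$labels), x$space, x$dimension
  ))
  invisible(x)
}

#' @export
#' @method tidy reference_library
tidy.reference_library <- function(x, ...) {
  tibble(
    sample = seq_along(x$labels),
    protein_id = x$protein_id,
    label = as.character(x$labels),
    n_features = if (x$space == "binary") lengths(x$features) else x$dimension
  )
}

#' @export
#' @method glance reference_library
glance.reference_library <- function(x, ...) {
  tibble(
    n_samples = length(x$labels),
    n_classes = nlevels(x$labels),
    space = x$space,
    dimension = x$dimension
  )
}

# Jaccard distance between two sorted index sets; both empty -> 0.
.jaccard_idx <- function(a, b) {
  if (!length(a) && !length(b)) return(0)
  i <- length(intersect(a, b))
  1 - i / (length(a) + length(b) - i)
}

#' Distance between two feature vectors in a named space
#'
#' Binary indicator spaces (GO, functional domain) use the Jaccard distance
#' on the nonzero index sets, `1 - |a n b| / |a u b|`, defined as 0 when both
#' vectors are empty. Continuous spaces (pseudo-PSSM) use the Euclidean
#' distance.
#'
#' @param a,b Feature vectors: `loc_indicator` objects or integer index
#'   vectors for `space = "binary"`; numeric vectors for `"continuous"`.
#' @param space `"binary"` or `"continuous"`.
#' @return A non-negative scalar distance.
#' @export
#' @examples
#' space_distance(c(1L, 2L, 3L), c(2L, 3L, 4L), "binary")  # 0.5
space_distance <- function(a, b, space = c("binary", "continuous")) {
  space <- match.arg(space)
  if (space == "binary") {
    if (inherits(a, "loc_indicator")) {
      if (inherits(b, "loc_indicator") && b$dimension != a$dimension) {
        abort("Dimension mismatch between indicator vectors.")
      }
      a <- a$idx
    }
    if (inherits(b, "loc_indicator")) b <- b$idx
    .jaccard_idx(as.integer(a), as.integer(b))
  } else {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) != length(b)) abort("Dimension mismatch between feature vectors.")
    sqrt(sum((a - b)^2))
  }
}

# Pairwise distance matrix of a library (dense n x n).
library_distances <- function(library) {
  if (library$space == "continuous") {
    as.matrix(dist(library$features))
  } else {
    pairwise_jaccard(library$features)
  }
}

# Pairwise Jaccard distances of a list of index sets via sparse cross products.
pairwise_jaccard <- function(idx_list) {
  n <- length(idx_list)
  sizes <- lengths(idx_list)
  if (all(sizes == 0L)) return(matrix(0, n, n))
  ii <- unlist(idx_list)
  jj <- rep.int(seq_len(n), sizes)
  m <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(max(ii), n))
  inter <- as.matrix(Matrix::crossprod(m))
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0  # both sets empty
  diag(d) <- 0
  d
}

# Jaccard distances from one index set to each set in a list.
jaccard_to_sets <- function(q, idx_list) {
  q <- as.integer(q)
  sizes <- lengths(idx_list)
  inter <- vapply(idx_list, function(s) length(intersect(q, s)), integer(1))
  uni <- length(q) + sizes - inter
  d <- 1 - inter / uni
  d[uni == 0L] <- 0
  d
}

# Euclidean distances from a query vector to each row of a matrix.
euclid_to_rows <- function(q, M) {
  sqrt(rowSums(sweep(M, 2L, q)^2))
}

#' Basic belief masses contributed by a set of neighbors
#'
#' Each neighbor at distance d with class c contributes a simple belief
#' structure over the frame of classes: mass `alpha * exp(-gamma_c * d^2)` on
#' the singleton `{c}` and the remainder on the whole frame (ignorance). A
#' zero-distance neighbor therefore commits exactly `alpha` to its class, and
#' a very distant one commits almost nothing.
#'
#' @param neighbors A data frame with columns `distance` (non-negative,
#'   finite) and `class`.
#' @param alpha Maximal commitment of a single neighbor, in (0, 1).
#'   Default 0.95.
#' @param gammas Named positive numeric vector of per-class scale parameters
#'   (see [fit_gammas()]); a single unnamed value is recycled to all classes.
#' @return A list of `mass_assignment` objects (fields `singleton_masses`, a
#'   named numeric, and `frame_mass`), one per neighbor.
#' @export
neighbor_masses <- function(neighbors, alpha = 0.95, gammas = 1) {
  stopifnot(is.data.frame(neighbors), nrow(neighbors) >= 1L)
  if (any(!is.finite(neighbors$distance))) {
    abort("Non-finite neighbor distance.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  cls <- as.character(neighbors$class)
  g <- if (is.null(names(gammas))) {
    rep_len(unname(gammas), length(cls))
  } else {
    unname(gammas[cls])
  }
  if (any(is.na(g) | g <= 0)) abort("Missing or non-positive gamma for a neighbor class.")
  s <- alpha * exp(-g * neighbors$distance^2)
  map2(cls, s, function(cl, si) {
    structure(
      list(singleton_masses = setNames(si, cl), frame_mass = 1 - si),
      class = "mass_assignment"
    )
  })
}

#' Combine belief masses by Dempster's rule
#'
#' Combines simple belief structures (mass on class singletons plus mass on
#' the full frame) with the normalized Dempster rule: products of masses land
#' on the intersection of their focal sets, mass on the empty intersection
#' (conflict) is discarded, and the remainder is renormalized. The
#' combination is associative and commutative; with singleton-plus-frame
#' inputs every combined focal set is again a singleton or the frame, so the
#' returned singleton masses are exactly the beliefs of the classes.
#'
#' @param masses A list of `mass_assignment` objects over one frame (see
#'   [neighbor_masses()]).
#' @param normalize If `FALSE`, returns the unnormalized (conflict-retaining)
#'   combination instead; the discarded conflict then shows up as masses not
#'   summing to one.
#' @return Named numeric vector of combined singleton beliefs, with the
#'   frame's residual mass in attribute `frame_mass`.
#' @export
combine_masses <- function(masses, normalize = TRUE) {
  stopifnot(is.list(masses), length(masses) >= 1L)
  classes <- sort(unique(unlist(map(masses, function(m) names(m$singleton_masses)))))
  bel <- setNames(numeric(length(classes)), classes)
  m1 <- bel
  sm <- masses[[1]]$singleton_masses
  m1[names(sm)] <- sm
  f1 <- masses[[1]]$frame_mass
  for (k in seq_along(masses)[-1]) {
    m2 <- setNames(numeric(length(classes)), classes)
    sm <- masses[[k]]$singleton_masses
    m2[names(sm)] <- sm
    f2 <- masses[[k]]$frame_mass
    new_m <- m1 * m2 + m1 * f2 + f1 * m2
    new_f <- f1 * f2
    m1 <- new_m
    f1 <- new_f
  }
  total <- sum(m1) + f1
  if (normalize) {
    if (total <= 0) {
      abort("Total conflict in Dempster combination: all mass cancelled; check alpha/gamma parameters.")
    }
    m1 <- m1 / total
    f1 <- f1 / total
  }
  structure(m1, frame_mass = f1)
}

# Fast path used by the engines: distances + integer class codes -> belief
# vector over class levels (same math as neighbor_masses + combine_masses).
.belief_from_neighbors <- function(d, class_codes, n_classes, alpha, gammas_by_code) {
  s <- alpha * exp(-gammas_by_code[class_codes] * d^2)
  q <- 1 - s
  # product of (1 - s_k) within each class, and over all neighbors
  logq <- log(pmax(q, .Machine$double.xmin))
  by_class <- rep(0, n_classes)
  agg <- tapply(logq, factor(class_codes, levels = seq_len(n_classes)), sum)
  agg[is.na(agg)] <- 0
  P <- exp(as.numeric(agg))          # prod over class-c neighbors of (1 - s)
  Pall <- prod(q)
  m <- (1 - P) * Pall / P            # (1 - P_c) * prod_{c' != c} P_{c'}
  m[P == 0] <- 0                     # some neighbor fully committed elsewhere?
  # exact handling when some P_c == 0 (a neighbor with s = 1): alpha < 1 forbids it
  total <- sum(m) + Pall
  if (total <= 0) {
    abort("Total conflict in Dempster combination: all mass cancelled.")
  }
  m / total
}

#' Fit per-class scale parameters of the evidential KNN
#'
#' The "optimized" step of the evidence-theoretic KNN: each class c gets a
#' scale `gamma_c = 1 / mean(d_nn^2)`, the reciprocal mean squared distance
#' from class-c samples to their nearest same-class neighbor, so that a
#' typical within-class neighbor commits close to `alpha` belief. Classes
#' with a single sample, or whose same-class neighbors coincide (zero mean),
#' fall back to the global mean rule over all classes; if that is degenerate
#' too, gamma is 1.
#'
#' With `refine = TRUE` a scalar multiplier on all gammas is grid-searched
#' (powers of 2 from 1/8 to 8) to minimize the leave-one-out error of the
#' single `K`-NN voter on the library, the smallest multiplier winning ties.
#'
#' @param library A [reference_library()].
#' @param refine Grid-refine a global multiplier by leave-one-out? Default
#'   `FALSE`.
#' @param alpha,K Voter parameters used only by the refinement search.
#' @return Named positive numeric vector, one gamma per class level.
#' @export
fit_gammas <- function(library, refine = FALSE, alpha = 0.95, K = 3L) {
  D <- library_distances(library)
  g <- .gammas_from_dist(D, library$labels)
  if (refine) {
    grid <- 2^seq(-3, 3)
    errs <- vapply(grid, function(mult) {
      .loo_error(D, library$labels, K = K, alpha = alpha, gammas = g * mult)
    }, numeric(1))
    g <- g * grid[which.min(errs)]
  }
  g
}

.gammas_from_dist <- function(D, labels) {
  lv <- levels(labels)
  nn2 <- rep(NA_real_, length(lv))
  names(nn2) <- lv
  for (k in seq_along(lv)) {
    rows <- which(labels == lv[k])
    if (length(rows) >= 2L) {
      sub <- D[rows, rows, drop = FALSE]
      diag(sub) <- Inf
      nn2[k] <- mean(apply(sub, 1L, min)^2)
    }
  }
  global <- mean(nn2[!is.na(nn2) & nn2 > 0])
  if (!is.finite(global) || global <= 0) global <- 1
  nn2[is.na(nn2) | nn2 <= 0] <- global
  1 / nn2
}

.loo_error <- function(D, labels, K, alpha, gammas) {
  n <- length(labels)
  codes <- as.integer(labels)
  gb <- unname(gammas[levels(labels)])
  wrong <- 0L
  for (i in seq_len(n)) {
    d <- D[i, -i]
    cl <- codes[-i]
    o <- order(d)[seq_len(min(K, n - 1L))]
    bel <- .belief_from_neighbors(d[o], cl[o], nlevels(labels), alpha, gb)
    if (which.max(bel) != codes[i]) wrong <- wrong + 1L
  }
  wrong / n
}

#' Single evidential K-nearest-neighbor vote
#'
#' Finds the K training samples nearest the query (distance ties broken by
#' ascending sample index), lets each contribute its belief mass via
#' [neighbor_masses()], combines them with [combine_masses()], and returns
#' the class of maximal belief (belief ties broken by the smallest class
#' level).
#'
#' @param query Feature vector in the library's space (index set or
#'   `loc_indicator` for binary, numeric vector for continuous).
#' @param library A [reference_library()].
#' @param K Number of neighbors, `1 <= K <=` library size.
#' @param alpha Neighbor commitment parameter, see [neighbor_masses()].
#' @param gammas Per-class scales; defaults to [fit_gammas()] on the library.
#' @return A single class label (character).
#' @export
etknn_vote <- function(query, library, K, alpha = 0.95, gammas = NULL) {
  stopifnot(inherits(library, "reference_library"))
  n <- length(library$labels)
  if (K < 1L || K > n) abort(sprintf("K = %d outside [1, %d].", K, n))
  d <- if (library$space == "binary") {
    if (inherits(query, "loc_indicator")) query <- query$idx
    jaccard_to_sets(query, library$features)
  } else {
    if (inherits(query, "loc_indicator")) abort("Continuous-space library given a binary query.")
    if (length(query) != library$dimension) abort("Dimension mismatch between query and library.")
    euclid_to_rows(as.numeric(query), library$features)
  }
  gammas <- gammas %||% fit_gammas(library)
  .vote_from_distances(d, library$labels, K, alpha, gammas)
}

# Shared by etknn_vote and the ensemble engines: distances -> winning label.
.vote_from_distances <- function(d, labels, K, alpha, gammas) {
  o <- order(d, seq_along(d))[seq_len(K)]
  bel <- .belief_from_neighbors(
    d[o], as.integer(labels)[o], nlevels(labels), alpha,
    unname(gammas[levels(labels)])
  )
  levels(labels)[which.max(bel)]
}
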