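#' Assemble a labeled benchmark dataset
#'
#' Bundles everything the pipeline needs about a set of proteins: sequences,
#' one or more location labels per protein, the BLAST hit table used for
#' homology transfer, the accession-to-GO annotation table, the domain hit
#' table, and the per-protein PSSM profiles.
#'
#' @param proteins Tibble with columns `protein_id` (unique), `sequence`, and
#'   `locations` (list column of character label vectors, each of size >= 1).
#' @param locations Ordered character vector of all location names; every
#'   label must be one of them.
#' @param blast_hits Tibble with `qseqid`, `sseqid`, `pident`, `evalue`.
#' @param go_annotations Tibble with `accession`, `go_index`.
#' @param domain_hits Tibble with `protein_id`, `domain_index`, `evalue`.
#' @param profiles Named list of [pssm_profile()] objects keyed by protein id
#'   (entries may be missing; the sequence-evolution engine then errors for
#'   those proteins).
#' @param go_dimension,fund_dimension Sizes of the GO and domain indicator
#'   spaces.
#' @return An object of class `loc_benchmark`.
#' @export
benchmark_dataset <- function(proteins, locations,
                              blast_hits = tibble(qseqid = character(), sseqid = character(),
                                                  pident = numeric(), evalue = numeric()),
                              go_annotations = tibble(accession = character(), go_index = integer()),
                              domain_hits = tibble(protein_id = character(), domain_index = integer(),
                                                   evalue = numeric()),
                              profiles = list(),
                              go_dimension = 60020L,
                              fund_dimension = 17402L) {
  stopifnot(is.data.frame(proteins))
  if (anyDuplicated(proteins$protein_id)) abort("Duplicate protein_id in `proteins`.")
  if (!is.list(proteins$locations)) abort("`proteins$locations` must be a list column.")
  sizes <- lengths(proteins$locations)
  if (any(sizes < 1L)) abort("Every protein needs at least one location label.")
  bad <- setdiff(unlist(proteins$locations), locations)
  if (length(bad)) {
    abort(sprintf("Unknown location label(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      proteins = as_tibble(proteins),
      locations = as.character(locations),
      blast_hits = as_tibble(blast_hits),
      go_annotations = as_tibble(go_annotations),
      domain_hits = as_tibble(domain_hits),
      profiles = profiles,
      go_dimension = as.integer(go_dimension),
      fund_dimension = as.integer(fund_dimension)
    ),
    class = "loc_benchmark"
  )
}

#' @export
print.loc_benchmark <- function(x, ...) {
  vc <- virtual_counts(x)
  cat(sprintf(
    "<loc_benchmark> %d proteins (%d virtual samples) over %d locations\n",
    vc$n_distinct, vc$n_virtual, length(x$locations)
  ))
  invisible(x)
}

#' Virtual-sample table of a benchmark
#'
#' Expands each protein into its virtual (locative) samples: one
#' (protein, location) pair per label the protein carries.
#'
#' @param benchmark A [benchmark_dataset()].
#' @return Tibble with columns `protein_id`, `location`.
#' @export
virtual_samples <- function(benchmark) {
  stopifnot(inherits(benchmark, "loc_benchmark"))
  tibble(
    protein_id = rep(benchmark$proteins$protein_id, lengths(benchmark$proteins$locations)),
    location = unlist(benchmark$proteins$locations)
  )
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the prediction pipeline with its
#' default. Thresholds: `identity_min` (percent identity for the homology
#' set), `evalue_max_go` (BLAST expect value), `evalue_max_fund` (domain hit
#' significance). Engine: `alpha` (evidential commitment), `theta`
#' (multi-label vote-share band, in `[0, 1)`; the default `NULL` optimizes
#' theta on the training set at fit time, see [tune_theta()] — the band
#' exists precisely to control the count of reported location sites and is
#' meant to be optimized), `k_max` (neighbors K = 1..k_max,
#' at most 10), `xi_max` (largest pseudo-PSSM lag, at most 49), `w` (weight of
#' the domain-space distance in the joint sequence-evolution space), `power`
#' (pseudo-PSSM coupling exponent), `joint_space` (joint FunD + Pse-PSSM
#' space per member, versus separate per-space voters), `refine_gammas`
#' (leave-one-out grid refinement of the class scales), `min_length`
#' (sequences shorter than this are rejected as fragments).
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `loc_config`.
#' @export
#' @examples
#' loc_config(theta = 0.3)$theta
loc_config <- function(...) {
  cfg <- list(
    identity_min = 60,
    evalue_max_go = 1e-3,
    evalue_max_fund = 1e-3,
    alpha = 0.95,
    theta = NULL,
    k_max = 10L,
    xi_max = 49L,
    w = 0.5,
    power = 2,
    joint_space = TRUE,
    refine_gammas = FALSE,
    min_length = 50L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration field(s): %s.", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  if (!is.null(cfg$theta) && (cfg$theta < 0 || cfg$theta >= 1)) {
    abort("`theta` must lie in [0, 1).")
  }
  if (cfg$k_max < 1L || cfg$k_max > 10L) abort("`k_max` must lie in [1, 10].")
  if (cfg$xi_max < 0L || cfg$xi_max > 49L) abort("`xi_max` must lie in [0, 49].")
  structure(cfg, class = "loc_config")
}

# Featurize every protein of a benchmark under one configuration.
# Returns protein-indexed feature blocks used by the predictor and the
# jackknife: GO and FunD index sets, normalized profiles, and the
# pseudo-PSSM descriptor matrix per lag (NA rows where a profile is missing
# or too short).
featurize_benchmark <- function(benchmark, config = loc_config()) {
  stopifnot(inherits(benchmark, "loc_benchmark"))
  ids <- benchmark$proteins$protein_id
  n <- length(ids)

  go <- map(ids, function(id) {
    hs <- build_homology_set(benchmark$blast_hits, id,
                             identity_min = config$identity_min,
                             evalue_max = config$evalue_max_go)
    go_vector(hs, benchmark$go_annotations, dimension = benchmark$go_dimension)$idx
  })

  dh <- benchmark$domain_hits
  fund <- map(ids, function(id) {
    rows <- dh[dh$protein_id == id, , drop = FALSE]
    fund_vector(rows, evalue_max = config$evalue_max_fund,
                dimension = benchmark$fund_dimension, protein_id = id)$idx
  })

  norm <- map(ids, function(id) {
    p <- benchmark$profiles[[id]]
    if (is.null(p)) NULL else normalize_profile(p)
  })
  lens <- map_int(norm, function(x) if (is.null(x)) 0L else nrow(x$values))

  pse <- map(0:config$xi_max, function(xi) {
    p <- if (xi == 0L) 20L else 40L
    M <- matrix(NA_real_, n, p)
    for (i in seq_len(n)) {
      if (!is.null(norm[[i]]) && lens[i] > xi) {
        M[i, ] <- as.numeric(psepssm_vector(norm[[i]], xi = xi, power = config$power))
      }
    }
    M
  })

  list(protein_id = ids, go = go, fund = fund, norm = norm,
       lengths = nchar(benchmark$proteins$sequence), pse = pse)
}
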