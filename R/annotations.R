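#' Read a BLAST tabular hit file
#'
#' Reads the tab-separated `-outfmt 6` layout (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Files with only the four contractually used columns (qseqid, sseqid,
#' pident, evalue) are also accepted.
#'
#' @param file Path to the tabular file.
#' @return A tibble with at least `qseqid`, `sseqid`, `pident`, `evalue`.
#' @export
read_blast_hits <- function(file) {
  x <- readr::read_tsv(file, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) >= 12L) {
    names(x)[1:12] <- c(
      "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
      "qstart", "qend", "sstart", "send", "evalue", "bitscore"
    )
  } else if (ncol(x) == 4L) {
    names(x) <- c("qseqid", "sseqid", "pident", "evalue")
  } else {
    abort(sprintf(
      "BLAST tabular file has %d columns; expected 12 (outfmt 6) or 4 (qseqid, sseqid, pident, evalue).",
      ncol(x)
    ))
  }
  x$pident <- as.numeric(x$pident)
  x$evalue <- as.numeric(x$evalue)
  as_tibble(x)
}

#' Build the homology set of a query protein
#'
#' Filters a BLAST hit table down to the subjects that can stand as
#' representative proteins of the query: expect value at most `evalue_max`
#' and percent identity at least `identity_min` (both comparisons inclusive).
#' Self hits (subject equal to the query id) are excluded. An empty result is
#' legitimate and drives the routing decision towards the sequence-evolution
#' engine.
#'
#' @param hits A BLAST hit tibble (see [read_blast_hits()]) with columns
#'   `qseqid`, `sseqid`, `pident`, `evalue`.
#' @param query_id Query protein identifier.
#' @param identity_min Minimum percent identity in `[0, 100]`. Default 60.
#' @param evalue_max Maximum expect value (> 0). Default 0.001.
#' @return An object of class `homology_set`: list with `query_id`,
#'   `accessions` (character, sorted, possibly empty), `identity_min`,
#'   `evalue_max`.
#' @export
#' @examples
#' hits <- tibble::tibble(
#'   qseqid = "Q", sseqid = c("A", "B", "C", "D"),
#'   pident = c(80, 61, 59, 90), evalue = 1e-20
#' )
#' build_homology_set(hits, "Q", identity_min = 60)$accessions
build_homology_set <- function(hits, query_id, identity_min = 60, evalue_max = 1e-3) {
  stopifnot(is.data.frame(hits))
  if (identity_min < 0 || identity_min > 100) {
    abort("`identity_min` must lie in [0, 100].")
  }
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    abort("`evalue_max` must be a positive expect value.")
  }
  keep <- hits$qseqid == query_id &
    hits$sseqid != query_id &
    hits$evalue <= evalue_max &
    hits$pident >= identity_min
  structure(
    list(
      query_id = as.character(query_id),
      accessions = sort(unique(as.character(hits$sseqid[keep]))),
      identity_min = identity_min,
      evalue_max = evalue_max
    ),
    class = "homology_set"
  )
}

#' @export
print.homology_set <- function(x, ...) {
  cat(sprintf(
    "<homology_set> %s: %d representative protein(s) (identity >= %g%%, E <= %g)\n",
    x$query_id, length(x$accessions), x$identity_min, x$evalue_max
  ))
  invisible(x)
}

.new_indicator <- function(protein_id, idx, dimension, class) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) && (idx[1] < 1L || idx[length(idx)] > dimension)) {
    abort(sprintf("Index outside [1, %d] in %s.", dimension, class))
  }
  structure(
    list(
      protein_id = as.character(protein_id),
      dimension = as.integer(dimension),
      idx = idx
    ),
    class = c(class, "loc_indicator")
  )
}

#' @export
print.loc_indicator <- function(x, ...) {
  cat(sprintf(
    "<%s> %s: %d / %d components set\n",
    class(x)[1], x$protein_id, length(x$idx), x$dimension
  ))
  invisible(x)
}

#' Read a GO annotation table and its index manifest
#'
#' The annotation table is a two-column TSV (accession, GO id such as
#' `GO:0005737`); the manifest is a two-column TSV (GO id, integer column
#' index) fixing the position of each GO number in the indicator space.
#' Annotation rows whose GO id is absent from the manifest are dropped.
#'
#' @param file Annotation TSV path.
#' @param index_file Manifest TSV path mapping GO ids to indices, or `NULL`
#'   if the second column of `file` already holds integer indices.
#' @return A tibble with columns `accession`, `go_index`.
#' @export
read_go_annotations <- function(file, index_file = NULL) {
  x <- readr::read_tsv(file, col_names = c("accession", "term"),
                       show_col_types = FALSE, progress = FALSE)
  if (is.null(index_file)) {
    out <- tibble(accession = as.character(x$accession), go_index = as.integer(x$term))
  } else {
    man <- readr::read_tsv(index_file, col_names = c("term", "go_index"),
                           show_col_types = FALSE, progress = FALSE)
    out <- x |>
      dplyr::inner_join(man, by = "term") |>
      dplyr::transmute(accession = as.character(.data$accession),
                       go_index = as.integer(.data$go_index))
  }
  distinct(out)
}

#' Gene Ontology indicator vector of a query protein
#'
#' Expresses the query in GO space through its representative proteins: the
#' i-th component is 1 exactly when at least one accession of the homology
#' set is annotated with the GO number occupying index i, else 0. Accessions
#' absent from the annotation table contribute nothing; an empty homology set
#' yields the all-zero vector.
#'
#' @param hset A [build_homology_set()] result.
#' @param annotations Tibble mapping `accession` to `go_index` (see
#'   [read_go_annotations()]).
#' @param dimension Size of the GO indicator space. Default 60020, the number
#'   of GO numbers in the GO database release this method family was built
#'   against.
#' @return An object of class `go_vector` (a sparse binary indicator:
#'   `protein_id`, `dimension`, sorted `idx`).
#' @export
go_vector <- function(hset, annotations, dimension = 60020L) {
  stopifnot(inherits(hset, "homology_set"), is.data.frame(annotations))
  if (nrow(annotations) && max(annotations$go_index) > dimension) {
    abort("`dimension` is smaller than the largest GO index in the table.")
  }
  idx <- annotations$go_index[annotations$accession %in% hset$accessions]
  .new_indicator(hset$query_id, idx, dimension, "go_vector")
}

#' Is a GO vector a productive descriptor for a given training library?
#'
#' A query can be classified in GO space only if its GO vector carries
#' information that the training data can act on: at least one of its set
#' components must also occur among the GO indices present in the reference
#' library. All-zero vectors, and vectors whose terms no training sample
#' shares, are unproductive and are routed to the sequence-evolution engine
#' instead.
#'
#' @param vec A [go_vector()].
#' @param training_go_index Integer vector of GO indices occurring in the
#'   training library (e.g. `training_go_index()` of a fitted predictor).
#' @return `TRUE` or `FALSE`.
#' @export
is_productive <- function(vec, training_go_index) {
  stopifnot(inherits(vec, "go_vector"))
  length(vec$idx) > 0L && any(vec$idx %in% as.integer(training_go_index))
}

#' Read a functional-domain hit table
#'
#' A TSV of RPS-BLAST-style domain hits, either (domain id, evalue) with a
#' manifest mapping domain ids to indices, or (domain_index, evalue)
#' directly. A third leading column of protein ids is accepted for batch
#' files, giving (protein_id, domain, evalue).
#'
#' @param file Hit TSV path.
#' @param index_file Optional manifest TSV (domain id, integer index).
#' @return A tibble with columns `domain_index`, `evalue` and, for batch
#'   files, `protein_id`.
#' @export
read_domain_hits <- function(file, index_file = NULL) {
  x <- readr::read_tsv(file, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) == 3L) {
    names(x) <- c("protein_id", "domain", "evalue")
  } else if (ncol(x) == 2L) {
    names(x) <- c("domain", "evalue")
  } else {
    abort("Domain hit file must have 2 or 3 tab-separated columns.")
  }
  if (is.null(index_file)) {
    x$domain_index <- as.integer(x$domain)
  } else {
    man <- readr::read_tsv(index_file, col_names = c("domain", "domain_index"),
                           show_col_types = FALSE, progress = FALSE)
    x <- dplyr::inner_join(x, man, by = "domain")
  }
  x$evalue <- as.numeric(x$evalue)
  cols <- intersect(c("protein_id", "domain_index", "evalue"), names(x))
  as_tibble(x[cols])
}

#' Functional-domain indicator vector
#'
#' Expresses a protein in conserved-domain space: component i is 1 exactly
#' when some alignment against domain i reached an expect value at most
#' `evalue_max` (a "hit"), else 0. Duplicate hits on one domain are
#' idempotent.
#'
#' @param hits Tibble with columns `domain_index`, `evalue` (the rows for one
#'   protein).
#' @param evalue_max Significance threshold for a hit (> 0). Default 0.001.
#' @param dimension Size of the domain space. Default 17402, the number of
#'   characteristic domains in the conserved-domain database release this
#'   method family was built against.
#' @param protein_id Identifier for the resulting vector.
#' @return An object of class `fund_vector` (sparse binary indicator).
#' @export
fund_vector <- function(hits, evalue_max = 1e-3, dimension = 17402L, protein_id = "query") {
  stopifnot(is.data.frame(hits))
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    abort("`evalue_max` must be a positive expect value.")
  }
  if (nrow(hits) && (min(hits$domain_index) < 1L || max(hits$domain_index) > dimension)) {
    abort(sprintf("Domain index outside [1, %d].", dimension))
  }
  idx <- hits$domain_index[hits$evalue <= evalue_max]
  .new_indicator(protein_id, idx, dimension, "fund_vector")
}
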