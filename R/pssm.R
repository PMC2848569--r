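#' Construct a position-specific scoring matrix profile
#'
#' A `pssm_profile` holds the per-residue evolutionary log-odds scores of one
#' protein: an L x 20 integer matrix whose row i scores the substitution of
#' the residue at sequence position i by each of the 20 canonical amino acids,
#' in alphabetical single-letter order (A, C, D, ..., Y).
#'
#' @param protein_id Identifier of the protein.
#' @param sequence Residue string of length L (L >= 1). Non-canonical letters
#'   (B, Z, X, U, ...) are retained; their score rows are used as-is.
#' @param scores Numeric L x 20 matrix of raw log-odds scores, columns in the
#'   canonical alphabetical amino-acid order.
#' @return An object of class `pssm_profile` with fields `protein_id`,
#'   `sequence`, `scores` and `alphabet`.
#' @seealso [read_ascii_pssm()], [normalize_profile()]
#' @export
#' @examples
#' p <- pssm_profile("P1", "MKA", matrix(rep(1:20, each = 3), 3, 20))
#' p$alphabet[1:5]
pssm_profile <- function(protein_id, sequence, scores) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || nchar(sequence) < 1L) {
    abort("`sequence` must be a single non-empty residue string.")
  }
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    abort(sprintf("`scores` must have 20 columns, got %d.", ncol(scores)))
  }
  if (nrow(scores) != nchar(sequence)) {
    abort(sprintf(
      "`scores` has %d rows but `sequence` has %d residues.",
      nrow(scores), nchar(sequence)
    ))
  }
  dimnames(scores) <- list(NULL, AA_ALPHABET)
  structure(
    list(
      protein_id = as.character(protein_id),
      sequence = sequence,
      scores = scores,
      alphabet = AA_ALPHABET
    ),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf(
    "<pssm_profile> %s: %d residues x 20 amino acids\n",
    x$protein_id, nrow(x$scores)
  ))
  invisible(x)
}

#' @export
print.pssm_norm <- function(x, ...) {
  cat(sprintf(
    "<pssm_norm> %s: %d standardized rows x 20 amino acids\n",
    x$protein_id, nrow(x$values)
  ))
  invisible(x)
}

# Matches a PSSM body row: position index, residue letter, then numbers.
.pssm_row_pattern <- "^\\s*\\d+\\s+[A-Za-z]\\s+-?\\d"

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the plain-text profile that PSI-BLAST writes via
#' `-out_ascii_pssm`: header lines, an amino-acid column header, then one row
#' per sequence position holding the position index, the residue letter, 20
#' integer log-odds scores and (optionally) further columns such as weighted
#' percentages, which are ignored. Both the legacy and current header
#' variants are accepted; only the residue letter and the first 20 integer
#' columns are contractually read.
#'
#' If an amino-acid header line is present, its ordering is used to map the
#' score columns onto the canonical alphabetical ordering (PSI-BLAST itself
#' prints A R N D C Q E G H I L K M F P S T W Y V); files without a
#' recognisable header are assumed to already be in alphabetical order.
#'
#' @param file Path to the ASCII PSSM file, or a character vector of lines.
#' @param protein_id Identifier for the resulting profile; defaults to the
#'   file base name (or `"query"` for literal lines).
#' @return A [pssm_profile()] whose `sequence` concatenates the residue
#'   column and whose `scores` are the 20 log-odds columns in file row order.
#' @export
#' @examples
#' lines <- c(
#'   "",
#'   "Last position-specific scoring matrix computed",
#'   paste(c("", sublocr:::AA_ALPHABET), collapse = "  "),
#'   paste(c("1 M", as.character(1:20)), collapse = " "),
#'   paste(c("2 K", as.character(21:40)), collapse = " ")
#' )
#' read_ascii_pssm(lines)$sequence
read_ascii_pssm <- function(file, protein_id = NULL) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(protein_id)) {
      protein_id <- sub("\\.[^.]*$", "", basename(file))
    }
  } else {
    lines <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
    protein_id <- protein_id %||% "query"
  }

  body <- grepl(.pssm_row_pattern, lines)
  if (!any(body)) {
    abort("No PSSM rows found: the file body is empty or not an ASCII PSSM.")
  }

  # Column ordering from the amino-acid header line, when one precedes the body.
  col_order <- seq_len(20L)
  header_region <- lines[seq_len(which(body)[1] - 1L)]
  for (h in rev(header_region)) {
    toks <- strsplit(trimws(h), "\\s+")[[1]]
    if (length(toks) >= 20L && all(toks %in% AA_ALPHABET)) {
      first20 <- toks[seq_len(20L)]
      if (!anyDuplicated(first20)) {
        col_order <- match(AA_ALPHABET, first20)
        break
      }
    }
  }

  rows <- which(body)
  residues <- character(length(rows))
  scores <- matrix(0L, length(rows), 20L)
  for (k in seq_along(rows)) {
    toks <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1]]
    residues[k] <- toks[2]
    vals <- suppressWarnings(as.integer(toks[-c(1L, 2L)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20L) {
      abort(sprintf(
        "PSSM line %d has %d parsable log-odds values; 20 are required.",
        rows[k], length(vals)
      ))
    }
    scores[k, ] <- vals[seq_len(20L)]
  }

  pssm_profile(protein_id, paste(residues, collapse = ""), scores[, col_order, drop = FALSE])
}

#' Write a profile as an ASCII PSSM file
#'
#' Emits the PSI-BLAST `-out_ascii_pssm` dialect with columns in the
#' canonical alphabetical amino-acid order, so that [read_ascii_pssm()]
#' round-trips the integer score matrix exactly. Used by the synthetic
#' benchmark generator and useful for building fixtures.
#'
#' @param profile A [pssm_profile()].
#' @param file Path to write, or `NULL` to return the lines invisibly.
#' @return The character vector of lines, invisibly.
#' @export
write_ascii_pssm <- function(profile, file = NULL) {
  stopifnot(inherits(profile, "pssm_profile"))
  sc <- profile$scores
  res <- strsplit(profile$sequence, "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", AA_ALPHABET), collapse = " "))
  )
  rows <- vapply(seq_len(nrow(sc)), function(i) {
    paste0(
      sprintf("%5d %s  ", i, res[i]),
      paste(sprintf("%3d", as.integer(sc[i, ])), collapse = " ")
    )
  }, character(1))
  lines <- c(header, rows, "")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Row-standardize a PSSM profile
#'
#' Converts raw log-odds scores to standardized scores: each position row is
#' centred on its mean over the 20 amino acids and divided by its population
#' standard deviation, so every row has zero mean and (when non-degenerate)
#' unit variance. The conversion is idempotent: applying it to an already
#' standardized profile reproduces it. Rows with zero variance (all 20 scores
#' identical) map to the all-zero row, the limit consistent with zero-mean
#' centring.
#'
#' @param profile A [pssm_profile()] or an object of class `pssm_norm` (which
#'   is re-standardized, a no-op up to rounding).
#' @return An object of class `pssm_norm` with fields `protein_id` and
#'   `values` (L x 20 real matrix).
#' @export
#' @examples
#' p <- pssm_profile("P1", "MK", rbind(c(1, -1, rep(0, 18)), rep(2, 20)))
#' normalize_profile(p)$values[, 1:3]
normalize_profile <- function(profile) {
  if (inherits(profile, "pssm_norm")) {
    x <- profile$values
    id <- profile$protein_id
  } else {
    stopifnot(inherits(profile, "pssm_profile"))
    x <- profile$scores
    id <- profile$protein_id
  }
  storage.mode(x) <- "double"
  m <- rowMeans(x)
  centred <- x - m
  s <- sqrt(rowMeans(centred^2))  # population standard deviation
  keep <- s > 0
  out <- matrix(0, nrow(x), 20L, dimnames = list(NULL, AA_ALPHABET))
  out[keep, ] <- centred[keep, , drop = FALSE] / s[keep]
  structure(
    list(protein_id = id, values = out),
    class = "pssm_norm"
  )
}

#' Column means of a standardized profile
#'
#' The average standardized score of the protein's residues being substituted
#' by each amino acid type over evolution: a fixed-length 20-vector summary
#' of the profile that discards all sequence-order information.
#'
#' @param norm A `pssm_norm` object from [normalize_profile()].
#' @return Named numeric vector of length 20 (names are the amino acids).
#' @export
mean_profile_scores <- function(norm) {
  stopifnot(inherits(norm, "pssm_norm"))
  colMeans(norm$values)
}

#' Pseudo-PSSM descriptor of a standardized profile
#'
#' The fixed-length sequential-evolution descriptor: the 20 mean standardized
#' scores of [mean_profile_scores()] followed, when the lag `xi >= 1`, by 20
#' lag correlation factors that retain sequence-order information,
#' \deqn{G_j(\xi) = \frac{1}{L-\xi} \sum_{i=1}^{L-\xi}
#'   (E_{i,j} - E_{i+\xi,j})^{power},}
#' the coupling of scores `xi` positions apart along the chain for amino acid
#' type j. With the default even `power = 2` every factor is non-negative and
#' constant score columns give exactly zero. At `xi = 0` the correlation term
#' vanishes by definition and the descriptor degenerates to the 20 mean
#' scores alone.
#'
#' The lag must satisfy `0 <= xi <= 49` and `xi < L`: the averaging
#' denominator L - xi must stay positive, and lags of 50 or more exceed the
#' shortest chain the predictor is designed for (sequences under 50 residues
#' are treated as fragments).
#'
#' @param norm A `pssm_norm` object.
#' @param xi Non-negative integer lag.
#' @param power Exponent of the coupling term; even values keep the factors
#'   non-negative. Default 2 (squared difference).
#' @return Named numeric vector of length 20 (`xi = 0`) or 40 (`xi >= 1`),
#'   with attributes `protein_id` and `xi`; names are `mean_<aa>` then
#'   `lag_<aa>`.
#' @export
#' @examples
#' p <- pssm_profile("P1", "MKAW", matrix(rnorm(80), 4, 20))
#' length(psepssm_vector(normalize_profile(p), xi = 0))
#' length(psepssm_vector(normalize_profile(p), xi = 2))
psepssm_vector <- function(norm, xi, power = 2) {
  stopifnot(inherits(norm, "pssm_norm"))
  xi <- as.integer(xi)
  L <- nrow(norm$values)
  if (xi < 0L || xi > 49L) {
    abort(sprintf("Lag xi = %d out of range: xi must satisfy 0 <= xi <= 49.", xi))
  }
  if (xi >= L) {
    abort(sprintf(
      "Lag xi = %d not smaller than the chain length L = %d: the averaging denominator L - xi must be positive.",
      xi, L
    ))
  }
  means <- mean_profile_scores(norm)
  names(means) <- paste0("mean_", AA_ALPHABET)
  if (xi == 0L) {
    vals <- means
  } else {
    E <- norm$values
    d <- E[seq_len(L - xi), , drop = FALSE] - E[seq_len(L - xi) + xi, , drop = FALSE]
    G <- colMeans(d^power)
    names(G) <- paste0("lag_", AA_ALPHABET)
    vals <- c(means, G)
  }
  structure(vals, protein_id = norm$protein_id, xi = xi)
}

#' Batch pseudo-PSSM featurization
#'
#' Computes the pseudo-PSSM descriptor of each profile at one lag and stacks
#' them into a feature table, one row per protein.
#'
#' @param profiles A list of [pssm_profile()] or `pssm_norm` objects.
#' @param xi Lag passed to [psepssm_vector()].
#' @param power Coupling exponent, see [psepssm_vector()].
#' @return A tibble with columns `protein_id`, `xi`, then 20 (`xi = 0`) or 40
#'   feature columns.
#' @export
psepssm_features <- function(profiles, xi, power = 2) {
  if (inherits(profiles, c("pssm_profile", "pssm_norm"))) profiles <- list(profiles)
  bind_rows(map(profiles, function(p) {
    if (inherits(p, "pssm_profile")) p <- normalize_profile(p)
    v <- psepssm_vector(p, xi = xi, power = power)
    dplyr::bind_cols(
      tibble(protein_id = attr(v, "protein_id"), xi = as.integer(xi)),
      as_tibble_row(as.list(v))
    )
  }))
}
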