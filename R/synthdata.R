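#' Configuration of the synthetic benchmark generator
#'
#' Describes a fully synthetic multi-label localization benchmark with
#' controllable class structure. Each location owns an exclusive block of GO
#' terms, an exclusive block of conserved domains, and a 20-dimensional PSSM
#' column-bias signature; a protein mixes the signatures of all locations it
#' belongs to. `separation` scales the PSSM signal strength, `noise` is the
#' probability that an annotation is dropped, crossed over to another
#' location's signature, or spuriously added. A configurable fraction of
#' proteins ("orphans") receive only sub-threshold BLAST identities, so
#' their homology sets are empty and they exercise the sequence-evolution
#' routing branch.
#'
#' The default multiplicity distribution follows the empirical label-count
#' histogram of the curated 22-location eukaryotic benchmark this method
#' family is evaluated on (proteins with 1/2/3/4 locations in proportions
#' 6687 : 1029 : 48 : 2, none with five or more).
#'
#' @param n_proteins Number of distinct proteins. Default 200.
#' @param n_locations Number of locations (>= 2, at most 22). Default 5.
#' @param multiplicity_probs Probabilities of a protein carrying 1, 2, 3, 4
#'   labels; must sum to 1.
#' @param separation PSSM signature strength (>= 0). Default 4.
#' @param noise Annotation corruption probability in `[0, 1]`. Default 0.
#' @param orphan_frac Fraction of proteins without usable homologs.
#'   Default 0.25.
#' @param go_dimension,fund_dimension Indicator space sizes. Defaults 400
#'   and 300 (compact spaces; the real GO and domain spaces are far larger
#'   but carry the same sparse binary structure).
#' @param go_terms_per_location,domains_per_location Exclusive signature
#'   block sizes. Defaults 8 and 6.
#' @param min_len,max_len Sequence length bounds; `min_len` defaults to 50,
#'   the fragment threshold, so every lag up to 49 is exercised.
#' @param seed Integer random seed; everything the generator emits is a
#'   deterministic function of the configuration including the seed.
#' @return A named list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 200L,
                         n_locations = 5L,
                         multiplicity_probs = c(6687, 1029, 48, 2) / 7766,
                         separation = 4,
                         noise = 0,
                         orphan_frac = 0.25,
                         go_dimension = 400L,
                         fund_dimension = 300L,
                         go_terms_per_location = 8L,
                         domains_per_location = 6L,
                         min_len = 50L,
                         max_len = 150L,
                         seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_locations = as.integer(n_locations),
    multiplicity_probs = as.numeric(multiplicity_probs),
    separation = separation,
    noise = noise,
    orphan_frac = orphan_frac,
    go_dimension = as.integer(go_dimension),
    fund_dimension = as.integer(fund_dimension),
    go_terms_per_location = as.integer(go_terms_per_location),
    domains_per_location = as.integer(domains_per_location),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    seed = as.integer(seed)
  )
  if (cfg$n_locations < 2L || cfg$n_locations > 22L) {
    abort("`n_locations` must lie in [2, 22].")
  }
  if (abs(sum(cfg$multiplicity_probs) - 1) > 1e-8 || any(cfg$multiplicity_probs < 0)) {
    abort("`multiplicity_probs` must be non-negative and sum to 1.")
  }
  if (cfg$min_len > cfg$max_len) abort("`min_len` must not exceed `max_len`.")
  if (cfg$noise < 0 || cfg$noise > 1) abort("`noise` must lie in [0, 1].")
  if (cfg$n_locations * cfg$go_terms_per_location > cfg$go_dimension ||
      cfg$n_locations * cfg$domains_per_location > cfg$fund_dimension) {
    abort("Signature blocks do not fit in the requested indicator dimensions.")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic ASCII PSSM fixture
#'
#' Builds a PSSM for one sequence whose columns carry a location-specific
#' bias: integer scores are independent draws around `separation` times the
#' 20-dimensional `location_signature`, identical for every chain position,
#' plus residue-level noise. The emitted text parses with
#' [read_ascii_pssm()] back to exactly the generated integer matrix.
#'
#' @param sequence Residue string (non-empty).
#' @param location_signature Numeric 20-vector signature of the location
#'   (mix of signatures for a multi-location protein).
#' @param seed Integer seed.
#' @param separation Signature strength. Default 4.
#' @param base_sd Standard deviation of the residue-level integer noise.
#'   Default 2.
#' @param protein_id Identifier embedded in the returned profile.
#' @return Character vector of file lines, with the generated
#'   [pssm_profile()] in attribute `profile`.
#' @export
make_pssm_fixture <- function(sequence, location_signature, seed,
                              separation = 4, base_sd = 2, protein_id = "query") {
  stopifnot(nchar(sequence) >= 1L, length(location_signature) == 20L)
  L <- nchar(sequence)
  scores <- withr::with_seed(seed, {
    base <- matrix(rnorm(L * 20L, sd = base_sd), L, 20L)
    round(base + separation * matrix(location_signature, L, 20L, byrow = TRUE))
  })
  prof <- pssm_profile(protein_id, sequence, scores)
  lines <- write_ascii_pssm(prof)
  attr(lines, "profile") <- prof
  lines
}

# Location signatures: exclusive index blocks and standardized 20-vectors.
.location_signatures <- function(cfg) {
  locs <- eukaryotic_locations()[seq_len(cfg$n_locations)]
  go_blocks <- map(seq_len(cfg$n_locations), function(k) {
    ((k - 1L) * cfg$go_terms_per_location + 1L):(k * cfg$go_terms_per_location)
  })
  fund_blocks <- map(seq_len(cfg$n_locations), function(k) {
    ((k - 1L) * cfg$domains_per_location + 1L):(k * cfg$domains_per_location)
  })
  pssm_sigs <- map(seq_len(cfg$n_locations), function(k) {
    v <- rnorm(20L)
    (v - mean(v)) / sd(v)
  })
  list(locations = locs, go = go_blocks, fund = fund_blocks, pssm = pssm_sigs)
}

#' Generate a synthetic multi-label localization benchmark
#'
#' Emulates everything the prediction pipeline consumes: protein sequences,
#' per-protein ASCII PSSM profiles with location-biased columns, a BLAST hit
#' table in which homologs are same-location proteins, a GO annotation table
#' whose terms cluster by location, a domain hit table, and multi-label
#' ground truth with the configured multiplicity distribution. The output is
#' a deterministic function of the configuration; when `dir` is given the
#' same files are written to disk (FASTA, per-protein PSSMs, TSV tables,
#' index manifests and a JSON manifest) so the file-based readers and the
#' command-line interface can be exercised offline.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory to write the benchmark into (created if
#'   needed).
#' @return A [benchmark_dataset()], with the configuration in attribute
#'   `synth_config` and, when written, the directory in attribute `dir`.
#' @export
#' @examples
#' bm <- make_benchmark(synth_config(n_proteins = 20, n_locations = 3, seed = 7))
#' virtual_counts(bm)$n_virtual
make_benchmark <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  bm <- withr::with_seed(cfg$seed, .generate_benchmark(cfg))
  attr(bm, "synth_config") <- cfg
  if (!is.null(dir)) {
    write_benchmark_dir(bm, dir)
    attr(bm, "dir") <- dir
  }
  bm
}

.generate_benchmark <- function(cfg) {
  sig <- .location_signatures(cfg)
  n <- cfg$n_proteins
  ids <- sprintf("SP%04d", seq_len(n))

  mult <- sample.int(length(cfg$multiplicity_probs), n, replace = TRUE,
                     prob = cfg$multiplicity_probs)
  mult <- pmin(mult, cfg$n_locations)
  locsets <- map(mult, function(m) sort(sample(sig$locations, m)))
  lens <- sample(cfg$min_len:cfg$max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
  orphan <- runif(n) < cfg$orphan_frac

  loc_of <- function(lab) match(lab, sig$locations)

  # Private accession-specific terms (a protein's idiosyncratic molecular
  # functions) keep same-family feature vectors close but never identical.
  bg_lo <- cfg$n_locations * cfg$go_terms_per_location + 1L
  private_go <- map(seq_len(n), function(i) {
    if (bg_lo + 2L > cfg$go_dimension) return(integer(0))
    sample(bg_lo:cfg$go_dimension, 3L)
  })

  # --- annotations: every protein is also an accession in the GO table ----
  go_rows <- map(seq_len(n), function(i) {
    ks <- loc_of(locsets[[i]])
    terms <- c(unlist(sig$go[ks]), private_go[[i]])
    terms <- terms[runif(length(terms)) >= cfg$noise]            # dropouts
    others <- setdiff(seq_len(cfg$n_locations), ks)
    for (k in others) {                                          # crossovers
      cross <- sig$go[[k]][runif(cfg$go_terms_per_location) < cfg$noise * 0.2]
      terms <- c(terms, cross)
    }
    n_bg <- rpois(1, cfg$noise * 5)                              # background
    if (n_bg > 0) terms <- c(terms, sample.int(cfg$go_dimension, n_bg))
    unique(terms)
  })
  go_annotations <- tibble(
    accession = rep(ids, lengths(go_rows)),
    go_index = as.integer(unlist(go_rows))
  )

  # --- domain hits --------------------------------------------------------
  dom_lo <- cfg$n_locations * cfg$domains_per_location + 1L
  private_dom <- map(seq_len(n), function(i) {
    if (dom_lo + 1L > cfg$fund_dimension) return(integer(0))
    sample(dom_lo:cfg$fund_dimension, 2L)
  })
  dom_rows <- map(seq_len(n), function(i) {
    ks <- loc_of(locsets[[i]])
    doms <- c(unlist(sig$fund[ks]), private_dom[[i]])
    keep <- runif(length(doms)) >= cfg$noise
    rows <- tibble(domain_index = as.integer(doms[keep]),
                   evalue = 10^-runif(sum(keep), 5, 30))
    others <- setdiff(seq_len(cfg$n_locations), ks)
    for (k in others) {
      cross <- sig$fund[[k]][runif(cfg$domains_per_location) < cfg$noise * 0.2]
      if (length(cross)) {
        rows <- bind_rows(rows, tibble(domain_index = as.integer(cross),
                                       evalue = 10^-runif(length(cross), 5, 30)))
      }
    }
    n_bg <- rpois(1, cfg$noise * 3)
    if (n_bg > 0) {
      rows <- bind_rows(rows, tibble(
        domain_index = sample.int(cfg$fund_dimension, n_bg),
        evalue = 10^-runif(n_bg, 5, 30)
      ))
    }
    rows
  })
  domain_hits <- bind_rows(map2(ids, dom_rows, function(id, r) mutate(r, protein_id = id))) |>
    select("protein_id", "domain_index", "evalue")

  # --- BLAST hits: homologs are the protein's family, i.e. the proteins
  # carrying exactly the same location set (close relatives share both the
  # compartments and the annotations), capped at 15 subjects. Orphans get
  # the same subjects but only at sub-threshold identities, and every query
  # also draws a few spurious low-identity subjects.
  setkey <- map_chr(locsets, paste, collapse = "|")
  family <- split(seq_len(n), setkey)
  blast_rows <- map(seq_len(n), function(i) {
    subj <- setdiff(family[[setkey[i]]], i)
    if (length(subj) > 15L) subj <- sort(sample(subj, 15L))
    # Spurious homology: with probability `noise` a hit points at a random
    # unrelated protein at full identity, so wrong-location annotations get
    # transferred — the dominant failure mode of homology-based GO transfer.
    if (cfg$noise > 0 && length(subj)) {
      flip <- runif(length(subj)) < cfg$noise
      pool <- setdiff(seq_len(n), c(i, family[[setkey[i]]]))
      if (any(flip) && length(pool)) {
        subj[flip] <- sample(pool, sum(flip), replace = length(pool) < sum(flip))
      }
    }
    spurious <- sample(setdiff(seq_len(n), c(i, subj)), min(3L, n - 1L - length(subj)))
    pid <- c(
      if (orphan[i]) runif(length(subj), 30, 55) else runif(length(subj), 62, 95),
      runif(length(spurious), 25, 45)
    )
    all_subj <- c(subj, spurious)
    if (!length(all_subj)) return(NULL)
    tibble(
      qseqid = ids[i], sseqid = ids[all_subj],
      pident = round(pid, 1), evalue = 10^-runif(length(all_subj), 20, 100)
    )
  })
  blast_hits <- bind_rows(blast_rows)
  if (!nrow(blast_hits)) {
    blast_hits <- tibble(qseqid = character(), sseqid = character(),
                         pident = numeric(), evalue = numeric())
  }

  # --- PSSM profiles ------------------------------------------------------
  profiles <- map(seq_len(n), function(i) {
    ks <- loc_of(locsets[[i]])
    sig20 <- Reduce(`+`, sig$pssm[ks]) / length(ks)
    base <- matrix(rnorm(lens[i] * 20L, sd = 2), lens[i], 20L)
    scores <- round(base + cfg$separation * matrix(sig20, lens[i], 20L, byrow = TRUE))
    pssm_profile(ids[i], seqs[i], scores)
  })
  names(profiles) <- ids

  benchmark_dataset(
    proteins = tibble(protein_id = ids, sequence = seqs, locations = locsets),
    locations = sig$locations,
    blast_hits = blast_hits,
    go_annotations = go_annotations,
    domain_hits = domain_hits,
    profiles = profiles,
    go_dimension = cfg$go_dimension,
    fund_dimension = cfg$fund_dimension
  )
}

#' Write a benchmark as a self-contained directory
#'
#' Emits the standard plain-text inputs the pipeline's readers consume:
#' `proteins.fasta`, `labels.tsv` (protein_id, semicolon-joined locations),
#' `blast_hits.tsv` (4-column tabular), `go_annotations.tsv` +
#' `go_index.tsv`, `domain_hits.tsv` + `domain_index.tsv`, one
#' `pssm/<id>.pssm` per protein, and `manifest.json` recording dimensions,
#' locations and the generating configuration (with its hash) when present.
#'
#' @param benchmark A [benchmark_dataset()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark_dir <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "loc_benchmark"))
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)

  seqs <- Biostrings::AAStringSet(setNames(benchmark$proteins$sequence,
                                           benchmark$proteins$protein_id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.fasta"), width = 80L)

  readr::write_tsv(
    tibble(protein_id = benchmark$proteins$protein_id,
           locations = map_chr(benchmark$proteins$locations, paste, collapse = ";")),
    file.path(dir, "labels.tsv")
  )
  readr::write_tsv(
    benchmark$blast_hits |> select("qseqid", "sseqid", "pident", "evalue"),
    file.path(dir, "blast_hits.tsv"), col_names = FALSE
  )
  readr::write_tsv(
    benchmark$go_annotations |>
      mutate(term = sprintf("GO:%07d", .data$go_index)) |>
      select("accession", "term"),
    file.path(dir, "go_annotations.tsv"), col_names = FALSE
  )
  go_ids <- sort(unique(benchmark$go_annotations$go_index))
  readr::write_tsv(
    tibble(term = sprintf("GO:%07d", go_ids), go_index = go_ids),
    file.path(dir, "go_index.tsv"), col_names = FALSE
  )
  readr::write_tsv(
    benchmark$domain_hits |>
      mutate(domain = sprintf("CDD:%05d", .data$domain_index),
             evalue = format(.data$evalue, digits = 6)) |>
      select("protein_id", "domain", "evalue"),
    file.path(dir, "domain_hits.tsv"), col_names = FALSE
  )
  dom_ids <- sort(unique(benchmark$domain_hits$domain_index))
  readr::write_tsv(
    tibble(domain = sprintf("CDD:%05d", dom_ids), domain_index = dom_ids),
    file.path(dir, "domain_index.tsv"), col_names = FALSE
  )
  for (id in benchmark$proteins$protein_id) {
    p <- benchmark$profiles[[id]]
    if (!is.null(p)) write_ascii_pssm(p, file.path(dir, "pssm", paste0(id, ".pssm")))
  }

  cfg <- attr(benchmark, "synth_config")
  manifest <- list(
    format = "sublocr-benchmark/1",
    locations = benchmark$locations,
    go_dimension = benchmark$go_dimension,
    fund_dimension = benchmark$fund_dimension,
    n_proteins = nrow(benchmark$proteins),
    config = if (!is.null(cfg)) unclass(cfg) else NULL,
    config_hash = if (!is.null(cfg)) rlang::hash(unclass(cfg)) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a benchmark directory back into memory
#'
#' Counterpart of [write_benchmark_dir()]: reads the FASTA, label, hit and
#' annotation tables and every ASCII PSSM, reconstructing the
#' [benchmark_dataset()].
#'
#' @param dir Benchmark directory containing `manifest.json`.
#' @return A [benchmark_dataset()].
#' @export
read_benchmark_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) abort(sprintf("No manifest.json in %s.", dir))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)

  seqs <- Biostrings::readAAStringSet(file.path(dir, "proteins.fasta"))
  labels <- readr::read_tsv(file.path(dir, "labels.tsv"), show_col_types = FALSE,
                            progress = FALSE)
  ord <- match(names(seqs), labels$protein_id)
  proteins <- tibble(
    protein_id = labels$protein_id[ord],
    sequence = unname(as.character(seqs)),
    locations = strsplit(labels$locations[ord], ";", fixed = TRUE)
  )
  profiles <- map(proteins$protein_id, function(id) {
    f <- file.path(dir, "pssm", paste0(id, ".pssm"))
    if (file.exists(f)) read_ascii_pssm(f, protein_id = id) else NULL
  })
  names(profiles) <- proteins$protein_id
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]

  benchmark_dataset(
    proteins = proteins,
    locations = as.character(man$locations),
    blast_hits = read_blast_hits(file.path(dir, "blast_hits.tsv")),
    go_annotations = read_go_annotations(file.path(dir, "go_annotations.tsv"),
                                         file.path(dir, "go_index.tsv")),
    domain_hits = read_domain_hits(file.path(dir, "domain_hits.tsv"),
                                   file.path(dir, "domain_index.tsv")),
    profiles = profiles,
    go_dimension = man$go_dimension,
    fund_dimension = man$fund_dimension
  )
}
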