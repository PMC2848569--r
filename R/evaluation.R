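#' Virtual-sample accounting of a multi-label benchmark
#'
#' A protein residing in m locations is counted as m virtual (locative)
#' samples even though the sequences are identical, so the virtual total is
#' the multiplicity-weighted sum
#' \deqn{N_{vir} = \sum_m m \, N_m,} where `N_m` is the number of proteins
#' with exactly m locations, while the distinct total is `sum(N_m)`.
#'
#' @param x Either a [benchmark_dataset()], a data frame with a `locations`
#'   list column, or a bare numeric multiplicity histogram `c(N1, N2, ...)`
#'   giving the counts of proteins with 1, 2, ... locations.
#' @return A list with `n_distinct`, `n_virtual`, and `histogram` (tibble
#'   with columns `m`, `n`).
#' @export
#' @examples
#' virtual_counts(c(6687, 1029, 48, 2))
virtual_counts <- function(x) {
  if (inherits(x, "loc_benchmark")) {
    sizes <- lengths(x$proteins$locations)
  } else if (is.data.frame(x)) {
    if (!is.list(x$locations)) abort("Data frame input needs a `locations` list column.")
    sizes <- lengths(x$locations)
  } else if (is.numeric(x)) {
    n_m <- as.numeric(x)
    if (any(n_m < 0)) abort("Multiplicity counts must be non-negative.")
    m <- seq_along(n_m)
    return(list(
      n_distinct = sum(n_m),
      n_virtual = sum(m * n_m),
      histogram = tibble(m = m, n = n_m)
    ))
  } else {
    abort("`x` must be a benchmark, a data frame with `locations`, or a multiplicity histogram.")
  }
  hist <- tibble(m = seq_len(max(sizes)),
                 n = as.numeric(tabulate(sizes, nbins = max(sizes))))
  list(n_distinct = length(sizes), n_virtual = sum(sizes), histogram = hist)
}

#' Assemble a per-location success-rate report
#'
#' The standard reporting layout for a multi-label localization benchmark:
#' one row per location with the (possibly fractional) correct count over
#' the location's virtual-sample total, and the overall rate as summed
#' correct over summed totals — so the overall row follows exactly the same
#' correct/total convention as each location row.
#'
#' @param per_location Tibble with columns `location`, `correct` (>= 0,
#'   real), `total` (integer >= 0).
#' @param mode Scoring convention the counts were produced under:
#'   `"locative"` or `"penalized"`.
#' @return An object of class `loc_report` with fields `per_location`
#'   (tibble gaining a `rate` column), `overall_rate`, `n_virtual`, `mode`.
#' @export
loc_report <- function(per_location, mode = c("locative", "penalized")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(per_location),
            all(c("location", "correct", "total") %in% names(per_location)))
  if (any(per_location$correct < 0) || any(per_location$total < 0)) {
    abort("Correct and total counts must be non-negative.")
  }
  if (any(per_location$correct > per_location$total)) {
    abort("Correct count exceeds a location's virtual-sample total.")
  }
  pl <- as_tibble(per_location) |>
    mutate(rate = ifelse(.data$total > 0, .data$correct / .data$total, NA_real_))
  structure(
    list(
      per_location = pl,
      overall_rate = sum(pl$correct) / sum(pl$total),
      n_virtual = sum(pl$total),
      mode = mode
    ),
    class = "loc_report"
  )
}

#' @export
print.loc_report <- function(x, ...) {
  cat(sprintf("<loc_report> %s scoring, %d virtual samples\n", x$mode, x$n_virtual))
  pl <- x$per_location
  for (i in seq_len(nrow(pl))) {
    cat(sprintf("  %-24s %s\n", pl$location[i],
                format_rate(pl$correct[i], pl$total[i])))
  }
  cat(sprintf("  %-24s %s\n", "Total",
              format_rate(sum(pl$correct), sum(pl$total))))
  invisible(x)
}

#' Format a correct/total pair in the report convention
#'
#' @param correct,total Counts.
#' @param digits Decimal places of the percentage. Default 2.
#' @return A string `"correct/total = XX.XX%"`.
#' @export
#' @examples
#' format_rate(318, 385)
format_rate <- function(correct, total, digits = 2) {
  sprintf(paste0("%s/%d = %.", digits, "f%%"),
          format(correct, trim = TRUE), as.integer(total),
          100 * correct / total)
}

#' @export
#' @method tidy loc_report
tidy.loc_report <- function(x, ...) {
  x$per_location |> mutate(mode = x$mode)
}

#' @export
#' @method glance loc_report
glance.loc_report <- function(x, ...) {
  tibble(
    overall_rate = x$overall_rate,
    n_virtual = x$n_virtual,
    n_locations = nrow(x$per_location),
    mode = x$mode
  )
}

#' @export
#' @method autoplot loc_report
autoplot.loc_report <- function(object, ...) {
  d <- object$per_location
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$location, .data$rate),
                                  y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall_rate, linetype = 2) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "jackknife success rate",
      title = sprintf("Per-location success (%s scoring)", object$mode),
      subtitle = sprintf("overall %s", format_rate(sum(d$correct), sum(d$total)))
    )
}

#' Score multi-label predictions against the truth
#'
#' Scores per virtual sample: each (protein, location) pair of the truth is
#' one unit of the location's total. In `"locative"` mode a virtual sample
#' (p, l) earns credit 1 exactly when l is among the predicted locations of
#' p. In `"penalized"` mode over- and under-predictions reduce the credit:
#' the sample earns `[l in P(p)] * |T(p) n P(p)| / |T(p) u P(p)|`, the
#' Jaccard agreement between the true set T(p) and predicted set P(p), so
#' predicting extra locations (false positives) or missing some (false
#' negatives) shrinks the score. The penalized overall rate can therefore
#' never exceed the locative one.
#'
#' @param truth Named list mapping protein id to its true location set.
#' @param predicted Named list mapping protein id to its predicted set; must
#'   have exactly the same protein ids.
#' @param locations Ordered character vector of all report locations.
#' @param mode `"locative"` or `"penalized"`.
#' @return A [loc_report()].
#' @export
#' @examples
#' truth <- list(p1 = "A", p2 = c("A", "B"))
#' pred <- list(p1 = c("A", "B"), p2 = c("A", "B"))
#' glance(score_predictions(truth, pred, c("A", "B"), mode = "penalized"))
score_predictions <- function(truth, predicted, locations,
                              mode = c("locative", "penalized")) {
  mode <- match.arg(mode)
  if (!setequal(names(truth), names(predicted))) {
    abort("`truth` and `predicted` must cover exactly the same protein ids.")
  }
  correct <- setNames(numeric(length(locations)), locations)
  total <- setNames(integer(length(locations)), locations)
  for (p in names(truth)) {
    Tset <- unique(as.character(truth[[p]]))
    Pset <- unique(as.character(predicted[[p]]))
    jac <- length(intersect(Tset, Pset)) / length(union(Tset, Pset))
    for (l in Tset) {
      total[l] <- total[l] + 1L
      hit <- l %in% Pset
      correct[l] <- correct[l] + if (mode == "locative") as.numeric(hit) else as.numeric(hit) * jac
    }
  }
  loc_report(
    tibble(location = locations, correct = unname(correct), total = unname(total)),
    mode = mode
  )
}

#' Leave-one-protein-out jackknife evaluation
#'
#' The most objective of the standard cross-validation protocols for this
#' problem: each distinct protein is withheld in turn — all of its virtual
#' samples leave every reference library together, so no identical feature
#' vector stays behind — the per-class evidential scales are refit on the
#' remaining proteins, the withheld protein is predicted through the normal
#' two-engine routing, and the predictions are scored against the true
#' label sets in both the locative and the penalized convention.
#'
#' Folds whose training set loses an entire location are still evaluated,
#' with a recorded warning.
#'
#' @param benchmark A [benchmark_dataset()].
#' @param config A [loc_config()].
#' @param theta Optional multi-label band override.
#' @return An object of class `loc_jackknife`: a list with `predictions`
#'   (tibble: `protein_id`, `engine`, `truth`, `predicted` list columns),
#'   `locative` and `penalized` ([loc_report()]s), and `warnings`.
#' @export
jackknife <- function(benchmark, config = loc_config(), theta = NULL) {
  stopifnot(inherits(benchmark, "loc_benchmark"))
  n <- nrow(benchmark$proteins)
  if (n < 2L) abort("The jackknife needs at least two distinct proteins.")
  object <- loc_predictor(benchmark, config)
  all_idx <- seq_len(n)
  notes <- character(0)

  preds <- vector("list", n)
  for (i in all_idx) {
    train <- all_idx[-i]
    lost <- setdiff(unlist(benchmark$proteins$locations),
                    unlist(benchmark$proteins$locations[train]))
    if (length(lost)) {
      notes <- c(notes, sprintf(
        "Fold %s: training set lost location(s) %s.",
        benchmark$proteins$protein_id[i], paste(lost, collapse = ", ")
      ))
    }
    preds[[i]] <- withCallingHandlers(
      .route_and_predict(.internal_query(object, i, train), object, train, theta),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  predictions <- tibble(
    protein_id = benchmark$proteins$protein_id,
    engine = map_chr(preds, "engine"),
    truth = benchmark$proteins$locations,
    predicted = map(preds, "predicted_locations")
  )
  truth <- setNames(as.list(predictions$truth), predictions$protein_id)
  predl <- setNames(as.list(predictions$predicted), predictions$protein_id)
  structure(
    list(
      predictions = predictions,
      locative = score_predictions(truth, predl, benchmark$locations, "locative"),
      penalized = score_predictions(truth, predl, benchmark$locations, "penalized"),
      warnings = notes
    ),
    class = "loc_jackknife"
  )
}

#' @export
print.loc_jackknife <- function(x, ...) {
  cat(sprintf(
    "<loc_jackknife> %d proteins | locative %s | penalized %s\n",
    nrow(x$predictions),
    format_rate(sum(x$locative$per_location$correct), x$locative$n_virtual),
    format_rate(round(sum(x$penalized$per_location$correct), 2), x$penalized$n_virtual)
  ))
  if (length(x$warnings)) cat(sprintf("  %d warning(s) recorded\n", length(x$warnings)))
  invisible(x)
}

#' @export
#' @method tidy loc_jackknife
tidy.loc_jackknife <- function(x, mode = c("locative", "penalized"), ...) {
  tidy(x[[match.arg(mode)]])
}

#' @export
#' @method glance loc_jackknife
glance.loc_jackknife <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$predictions),
    n_virtual = x$locative$n_virtual,
    locative_rate = x$locative$overall_rate,
    penalized_rate = x$penalized$overall_rate,
    n_go = sum(x$predictions$engine == "GO"),
    n_seq = sum(x$predictions$engine == "SEQ"),
    n_warnings = length(x$warnings)
  )
}

#' @export
#' @method autoplot loc_jackknife
autoplot.loc_jackknife <- function(object, mode = c("locative", "penalized"), ...) {
  autoplot(object[[match.arg(mode)]], ...)
}

#' Write a report as a tab-separated table plus JSON summary
#'
#' @param x A [loc_report()] or [loc_jackknife()].
#' @param tsv_file,json_file Output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_report <- function(x, tsv_file = NULL, json_file = NULL) {
  if (inherits(x, "loc_jackknife")) {
    tab <- x$locative$per_location |>
      select("location", locative_correct = "correct", total = "total") |>
      mutate(
        penalized_correct = x$penalized$per_location$correct,
        locative_percent = sprintf("%.2f", 100 * .data$locative_correct / pmax(.data$total, 1)),
        penalized_percent = sprintf("%.2f", 100 * .data$penalized_correct / pmax(.data$total, 1))
      )
    summary <- list(
      n_proteins = nrow(x$predictions),
      n_virtual = x$locative$n_virtual,
      locative_rate = x$locative$overall_rate,
      penalized_rate = x$penalized$overall_rate,
      engines = as.list(table(x$predictions$engine)),
      warnings = x$warnings
    )
  } else {
    stopifnot(inherits(x, "loc_report"))
    tab <- x$per_location |>
      mutate(percent = sprintf("%.2f", 100 * .data$rate))
    summary <- list(
      mode = x$mode, n_virtual = x$n_virtual, overall_rate = x$overall_rate
    )
  }
  if (!is.null(tsv_file)) readr::write_tsv(tab, tsv_file)
  if (!is.null(json_file)) {
    jsonlite::write_json(summary, json_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(x)
}
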