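#' Count intransitive triples in one subject's tournament
#'
#' A subject's thresholded outcomes define a tournament over the options:
#' for each unordered pair at most one relation (a win in either direction,
#' or a tie). Among the 8 possible orientations of a triple of options,
#' exactly 2 form a directed cycle (A beats B beats C beats A, or the
#' reverse); such cyclic triples break any linear ranking. Triples with a
#' tie or a missing relation are never counted as cyclic. The denominator is
#' the full `choose(n, 3)` over the option catalog, so ratios remain
#' comparable across thresholds that generate different numbers of ties.
#'
#' @param tournament Outcome rows for a single subject (columns `option_a`,
#'   `option_b`, `result`).
#' @param options Option catalog defining the triple universe; defaults to
#'   the catalog carried by (or the labels present in) `tournament`.
#' @return A list with integer elements `cyclic` and `total`.
#' @export
count_intransitive_triples <- function(tournament, options = NULL) {
  tournament <- as_outcome_data(tournament)
  if (length(unique(tournament$subject)) > 1) {
    stop_validation("tournament must contain a single subject; ",
                    "see intransitivity_ratio() for pooling")
  }
  options <- options %||% choice_options(tournament)
  n <- length(options)
  total <- if (n >= 3) choose(n, 3) else 0
  if (n < 3 || nrow(tournament) == 0) {
    return(list(cyclic = 0L, total = as.integer(total)))
  }
  beats <- beats_matrix(tournament, options)
  trip <- utils::combn(n, 3)
  cyc <- 0L
  for (k in seq_len(ncol(trip))) {
    a <- trip[1, k]; b <- trip[2, k]; c <- trip[3, k]
    if ((beats[a, b] && beats[b, c] && beats[c, a]) ||
        (beats[b, a] && beats[c, b] && beats[a, c])) {
      cyc <- cyc + 1L
    }
  }
  list(cyclic = cyc, total = as.integer(total))
}

beats_matrix <- function(tournament, options) {
  n <- length(options)
  beats <- matrix(FALSE, n, n, dimnames = list(options, options))
  ia <- match(tournament$option_a, options)
  ib <- match(tournament$option_b, options)
  win_a <- tournament$result == "A_WINS"
  win_b <- tournament$result == "B_WINS"
  beats[cbind(ia[win_a], ib[win_a])] <- TRUE
  beats[cbind(ib[win_b], ia[win_b])] <- TRUE
  beats
}

#' Intransitivity ratio of a set of subject tournaments
#'
#' Pools cyclic and total triple counts over subjects and reports
#' `100 * cyclic / total`, a percentage in `[0, 100]`; 0 means every
#' subject's choices are fully transitive, and percent transitivity is its
#' complement `100 - I-ratio`.
#'
#' @param outcomes An outcome tibble covering one or more subjects.
#' @param options Option catalog; defaults to the catalog of `outcomes`.
#' @return The intransitivity ratio as a percentage.
#' @export
intransitivity_ratio <- function(outcomes, options = NULL) {
  outcomes <- as_outcome_data(outcomes)
  options <- options %||% choice_options(outcomes)
  if (length(options) < 3) {
    stop_validation("intransitivity is undefined for fewer than 3 options")
  }
  counts <- outcomes |>
    dplyr::group_split(.data$subject) |>
    purrr::map(count_intransitive_triples, options = options)
  cyclic <- sum(purrr::map_int(counts, "cyclic"))
  total <- sum(purrr::map_int(counts, "total"))
  if (total == 0) stop_validation("no triples available: undefined statistic")
  100 * cyclic / total
}

#' Consensus error: scaled inter-subject disagreement
#'
#' For each unordered option pair, let `n_a` and `n_b` be the numbers of
#' subjects preferring each side (tied subjects express no direction and are
#' excluded by default). The pair's disagreement is
#' `d = 200 * min(n_a, n_b) / (n_a + n_b)`, so a unanimous pair scores 0 and
#' an even split scores 100. Each option's consensus error is the mean
#' disagreement over its pairs, and the overall consensus error is the mean
#' over options. 0% means every subject agrees on every ranked position;
#' 100% means every pair splits the subjects in half.
#'
#' @param outcomes An outcome tibble.
#' @param tie_split If `TRUE`, tied subjects contribute half a subject to
#'   each side of the pair instead of being excluded (sensitivity check).
#' @return A list with `overall` (percentage), `per_option` (tibble of
#'   option, consensus error, number of contributing pairs) and `per_pair`
#'   (tibble of pair-level disagreement).
#' @export
consensus_error <- function(outcomes, tie_split = FALSE) {
  outcomes <- as_outcome_data(outcomes)
  options <- choice_options(outcomes)
  if (length(options) < 2) stop_validation("at least 2 options required")
  if (length(choice_subjects(outcomes)) < 1) {
    stop_validation("at least 1 subject required")
  }
  pair <- outcomes |>
    dplyr::group_by(.data$option_a, .data$option_b) |>
    dplyr::summarise(
      n_a = sum(.data$result == "A_WINS"),
      n_b = sum(.data$result == "B_WINS"),
      n_tie = sum(.data$result == "TIE"),
      .groups = "drop"
    )
  if (tie_split) {
    pair$n_a <- pair$n_a + pair$n_tie / 2
    pair$n_b <- pair$n_b + pair$n_tie / 2
  }
  pair$decided <- pair$n_a + pair$n_b
  undecided <- pair$decided == 0
  if (any(undecided)) {
    warning(sum(undecided),
            " pair(s) with no decided subjects excluded from consensus error")
  }
  pair$disagreement <- ifelse(pair$decided == 0, NA_real_,
                              200 * pmin(pair$n_a, pair$n_b) / pair$decided)
  long <- dplyr::bind_rows(
    dplyr::select(pair, option = "option_a", "disagreement"),
    dplyr::select(pair, option = "option_b", "disagreement")
  )
  per_option <- long |>
    dplyr::filter(!is.na(.data$disagreement)) |>
    dplyr::group_by(.data$option) |>
    dplyr::summarise(consensus_error = mean(.data$disagreement),
                     n_pairs = dplyr::n(), .groups = "drop")
  per_option <- per_option[match(options, per_option$option), , drop = FALSE]
  per_option <- per_option[!is.na(per_option$option), , drop = FALSE]
  list(overall = mean(per_option$consensus_error),
       per_option = per_option,
       per_pair = pair)
}

#' Bundle the two quality measures of a ranking
#'
#' Computes the overall and per-option consensus error and the
#' intransitivity ratio (with raw triple counts) for one set of thresholded
#' outcomes, the companion quality summary to a fitted worth scale.
#'
#' @inheritParams consensus_error
#' @param options Option catalog; defaults to the catalog of `outcomes`.
#' @return An object of class `quality_report`; `tidy()` gives the
#'   per-option consensus errors, `glance()` the overall numbers.
#' @examples
#' d <- generate_choices(worth = c(a = 0.5, b = 0.3, c = 0.2),
#'                       n_subjects = 12, seed = 42)
#' d |> aggregate_sessions() |> apply_threshold(0.65) |> quality_report()
#' @export
quality_report <- function(outcomes, options = NULL, tie_split = FALSE) {
  outcomes <- as_outcome_data(outcomes)
  options <- options %||% choice_options(outcomes)
  ce <- consensus_error(outcomes, tie_split = tie_split)
  counts <- outcomes |>
    dplyr::group_split(.data$subject) |>
    purrr::map(count_intransitive_triples, options = options)
  cyclic <- sum(purrr::map_int(counts, "cyclic"))
  total <- sum(purrr::map_int(counts, "total"))
  structure(list(
    consensus_error_overall = ce$overall,
    consensus_error_per_option = ce$per_option,
    intransitivity_ratio = if (total > 0) 100 * cyclic / total else NA_real_,
    intransitive_triples = cyclic,
    total_triples = total,
    n_subjects = length(choice_subjects(outcomes)),
    options = options
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Ranking quality\n")
  cat(sprintf("  consensus error (CE): %.2f%%\n", x$consensus_error_overall))
  cat(sprintf("  intransitivity ratio (I-ratio): %.2f%% (%d of %d triples)\n",
              x$intransitivity_ratio, x$intransitive_triples, x$total_triples))
  cat("  per-option CE:\n")
  po <- x$consensus_error_per_option
  for (i in seq_len(nrow(po))) {
    cat(sprintf("    %-18s %6.2f%%\n", po$option[i], po$consensus_error[i]))
  }
  invisible(x)
}

#' @method tidy quality_report
#' @export
tidy.quality_report <- function(x, ...) x$consensus_error_per_option

#' @method glance quality_report
#' @export
glance.quality_report <- function(x, ...) {
  tibble::tibble(
    consensus_error = x$consensus_error_overall,
    intransitivity_ratio = x$intransitivity_ratio,
    intransitive_triples = x$intransitive_triples,
    total_triples = x$total_triples,
    n_subjects = x$n_subjects,
    n_options = length(x$options)
  )
}

#' Plot per-option consensus errors
#'
#' @param object A `quality_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-option consensus error with the overall
#'   value as a dashed line.
#' @method autoplot quality_report
#' @method autoplot quality_report
#' @method autoplot quality_report
#' @method autoplot quality_report
#' @export
autoplot.quality_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$option,
                                  y = .data$consensus_error)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$consensus_error_overall,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "consensus error (%)") +
    ggplot2::theme_minimal()
}

#' Export a quality report
#'
#' JSON carries full precision; the text summary mirrors the printed report
#' with percentages to 2 decimal places.
#'
#' @param report A `quality_report`.
#' @param path Output path.
#' @param format `"json"` or `"txt"`.
#' @return `path`, invisibly.
#' @export
write_quality <- function(report, path, format = c("json", "txt")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "quality_report"))
  if (format == "json") {
    jsonlite::write_json(list(
      consensus_error_overall = report$consensus_error_overall,
      consensus_error_per_option = report$consensus_error_per_option,
      intransitivity_ratio = report$intransitivity_ratio,
      intransitive_triples = report$intransitive_triples,
      total_triples = report$total_triples
    ), path, auto_unbox = TRUE, digits = NA)
  } else {
    txt <- utils::capture.output(print(report))
    writeLines(txt, path)
  }
  invisible(path)
}
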