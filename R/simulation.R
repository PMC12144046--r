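#' Randomly complete a target option's missing comparisons
#'
#' Every missing subject-by-pair cell involving `target` is filled with a
#' fair coin flip between the two win directions (ties are included as a
#' third equally likely outcome only when `randomize_ties = TRUE`). Observed
#' cells are never touched. Randomizing at the subject level keeps
#' per-subject tournaments well defined, so the intransitivity ratio of a
#' completed dataset remains computable.
#'
#' @param outcomes An outcome tibble in which the target has observed
#'   comparisons against a subset of options and no others.
#' @param target Option label whose missing comparisons are completed.
#' @param tested_against Optional character vector declaring which partners
#'   are supposed to be observed; a declared partner with missing cells
#'   raises a configuration error.
#' @param randomize_ties Include `TIE` as a third equally likely outcome.
#' @param seed Optional seed for a reproducible completion.
#' @return An outcome tibble with all target cells present.
#' @export
randomize_unknowns <- function(outcomes, target, tested_against = NULL,
                               randomize_ties = FALSE, seed = NULL) {
  outcomes <- as_outcome_data(outcomes)
  options <- choice_options(outcomes)
  if (!target %in% options) {
    stop_validation("unknown target option: ", target)
  }
  missing <- target_missing_cells(outcomes, target)
  if (!is.null(tested_against)) {
    overlap <- intersect(tested_against,
                         unique(c(missing$option_a, missing$option_b)))
    overlap <- setdiff(overlap, target)
    if (length(overlap) > 0) {
      stop_validation("tested_against option(s) with missing outcomes: ",
                      paste(overlap, collapse = ", "))
    }
  }
  draw <- function() fill_cells(outcomes, missing, randomize_ties)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

target_missing_cells <- function(outcomes, target) {
  missing <- completeness_report(outcomes)
  missing[missing$option_a == target | missing$option_b == target, ,
          drop = FALSE]
}

fill_cells <- function(outcomes, cells, randomize_ties) {
  if (nrow(cells) == 0) return(outcomes)
  pool <- if (randomize_ties) c("A_WINS", "B_WINS", "TIE") else
    c("A_WINS", "B_WINS")
  cells$result <- sample(pool, nrow(cells), replace = TRUE)
  out <- dplyr::bind_rows(outcomes, cells)
  attr(out, "options") <- choice_options(outcomes)
  attr(out, "subjects") <- choice_subjects(outcomes)
  class(out) <- c("outcome_tbl", setdiff(class(out), "outcome_tbl"))
  out
}

#' Position a new option by randomized completion of its comparisons
#'
#' Repeats the loop *randomize missing target cells, refit worth values,
#' rank, score quality* `runs` times, summarizing where the target lands
#' when only a subset of its pairwise comparisons has been observed. In
#' `"informed"` mode, completions whose intransitivity ratio exceeds
#' `intransitivity_cutoff` are discarded (the count of discarded runs is
#' reported); `"uninformed"` keeps every completion.
#'
#' If the supplied outcomes are complete, the target's comparisons against
#' options outside `tested_against` are removed first and the full data
#' provide the ground-truth position used for true-positive accounting;
#' otherwise pass `true_position` yourself (or leave it `NA`).
#'
#' @param outcomes An outcome tibble (complete, or already missing the
#'   target's unobserved comparisons).
#' @param target Option whose position is simulated.
#' @param tested_against Options the target has really been compared to.
#' @param runs Number of randomized completions (default 200).
#' @param mode `"uninformed"` or `"informed"`.
#' @param intransitivity_cutoff Maximum tolerated intransitivity ratio (a
#'   fraction in `[0, 1]`) for informed mode; default 0.1.
#' @param seed Integer seed making the whole simulation reproducible.
#' @param randomize_ties Passed to [randomize_unknowns()].
#' @param tie_handling Passed to [fit_worth()].
#' @param true_position Known ground-truth rank of the target; computed
#'   from the full data when they are complete.
#' @return An object of class `position_sim`: per-run results (`tidy()`),
#'   summary (`glance()`), per-option worth CIs, position frequencies, and
#'   true-positive accounting.
#' @examples
#' d <- generate_choices(worth = c(a = 8, b = 4, c = 2, d = 1),
#'                       n_subjects = 10, seed = 3)
#' oc <- d |> aggregate_sessions() |> apply_threshold(0.5)
#' sim <- simulate_positions(oc, target = "c", tested_against = c("a", "b"),
#'                           runs = 50, seed = 9)
#' glance(sim)
#' @export
simulate_positions <- function(outcomes, target, tested_against,
                               runs = 200L,
                               mode = c("uninformed", "informed"),
                               intransitivity_cutoff = 0.1, seed = NULL,
                               randomize_ties = FALSE,
                               tie_handling = "half_win",
                               true_position = NULL) {
  mode <- match.arg(mode)
  outcomes <- as_outcome_data(outcomes)
  options <- choice_options(outcomes)
  stopifnot(runs >= 1, intransitivity_cutoff >= 0, intransitivity_cutoff <= 1)
  if (!target %in% options) stop_validation("unknown target option: ", target)
  if (target %in% tested_against) {
    stop_validation("tested_against must not contain the target")
  }
  if (!all(tested_against %in% options)) {
    stop_validation("unknown option(s) in tested_against: ",
                    paste(setdiff(tested_against, options), collapse = ", "))
  }

  complete_input <- nrow(completeness_report(outcomes)) == 0
  if (complete_input) {
    if (is.null(true_position)) {
      full_fit <- fit_worth(outcomes, tie_handling = tie_handling)
      true_position <- full_fit$worth$position[full_fit$options == target]
    }
    drop <- (outcomes$option_a == target &
               !outcomes$option_b %in% tested_against) |
      (outcomes$option_b == target & !outcomes$option_a %in% tested_against)
    observed <- outcomes[!drop, , drop = FALSE]
    attr(observed, "options") <- options
    attr(observed, "subjects") <- choice_subjects(outcomes)
    class(observed) <- c("outcome_tbl", setdiff(class(observed), "outcome_tbl"))
  } else {
    observed <- outcomes
    true_position <- true_position %||% NA_integer_
  }
  missing <- target_missing_cells(observed, target)
  overlap <- setdiff(intersect(tested_against,
                               unique(c(missing$option_a, missing$option_b))),
                     target)
  if (length(overlap) > 0) {
    stop_validation("tested_against option(s) with missing outcomes: ",
                    paste(overlap, collapse = ", "))
  }

  one_run <- function(r) {
    completed <- fill_cells(observed, missing, randomize_ties)
    fit <- fit_worth(completed, tie_handling = tie_handling)
    qr <- quality_report(completed, options = options)
    tibble::tibble(
      run = r,
      position = fit$worth$position[fit$options == target],
      i_ratio = qr$intransitivity_ratio / 100,
      ce = qr$consensus_error_overall,
      worth = list(rlang::set_names(fit$worth$worth, fit$options))
    )
  }
  body <- function() dplyr::bind_rows(purrr::map(seq_len(runs), one_run))
  run_tbl <- if (is.null(seed)) body() else withr::with_seed(seed, body())

  run_tbl$retained <- if (mode == "informed") {
    run_tbl$i_ratio <= intransitivity_cutoff
  } else rep(TRUE, nrow(run_tbl))
  kept <- run_tbl[run_tbl$retained, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop(rlang::error_cnd(
      class = "prefrank_empty_result",
      message = paste0("informed simulation retained no runs at cutoff ",
                       intransitivity_cutoff,
                       "; raise the cutoff or increase runs")))
  }
  worths <- tidyr::unnest_longer(
    dplyr::select(kept, "run", "worth"),
    "worth", values_to = "worth", indices_to = "option")

  pos_freq <- kept |>
    dplyr::count(.data$position, name = "count") |>
    dplyr::mutate(frequency = .data$count / nrow(kept))
  tp_count <- if (is.na(true_position)) NA_integer_ else
    sum(kept$position == true_position)

  structure(list(
    runs = dplyr::select(run_tbl, -"worth"),
    worths = worths,
    position_frequencies = pos_freq,
    ci = if (nrow(kept) >= 2) summarize_ci(worths) else NULL,
    true_position = true_position,
    true_positive_count = tp_count,
    true_positive_frequency = if (is.na(true_position)) NA_real_ else
      tp_count / nrow(kept),
    discarded_runs = sum(!run_tbl$retained),
    target = target, tested_against = tested_against,
    options = options, mode = mode,
    intransitivity_cutoff = intransitivity_cutoff,
    runs_requested = runs, seed = seed
  ), class = "position_sim")
}

#' 95% confidence intervals of per-option worth across runs
#'
#' Normal-approximation intervals `mean +- z * sd / sqrt(k)` over the
#' retained runs, with a flag marking options whose interval overlaps any
#' other option's (overlapping intervals mean the ranking does not separate
#' those options at the chosen level).
#'
#' @param runs A long tibble with columns `run`, `option`, `worth` (as
#'   stored in a `position_sim`), or a `position_sim` itself.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `option`, `mean`, `sd`, `lower`, `upper`,
#'   `overlaps_any`.
#' @export
summarize_ci <- function(runs, level = 0.95) {
  if (inherits(runs, "position_sim")) runs <- runs$worths
  stopifnot(level > 0, level < 1)
  k <- length(unique(runs$run))
  if (k < 2) stop_validation("at least 2 retained runs required for a CI")
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- runs |>
    dplyr::group_by(.data$option) |>
    dplyr::summarise(mean = mean(.data$worth), sd = stats::sd(.data$worth),
                     .groups = "drop") |>
    dplyr::mutate(lower = .data$mean - z * .data$sd / sqrt(k),
                  upper = .data$mean + z * .data$sd / sqrt(k))
  ci$overlaps_any <- vapply(seq_len(nrow(ci)), function(i) {
    any(ci$lower[-i] <= ci$upper[i] & ci$upper[-i] >= ci$lower[i])
  }, logical(1))
  ci
}

#' Best run under the quality-first ordering
#'
#' Returns the retained run that is minimal under the lexicographic key
#' (intransitivity ratio, consensus error), ties broken by run index — the
#' run a results table reports as the best-achieved simulation.
#'
#' @param result A `position_sim`.
#' @return One-row tibble: `run`, `position`, `i_ratio`, `ce`.
#' @export
select_best_run <- function(result) {
  stopifnot(inherits(result, "position_sim"))
  kept <- result$runs[result$runs$retained, , drop = FALSE]
  if (nrow(kept) == 0) stop_validation("no retained runs")
  kept <- kept[order(kept$i_ratio, kept$ce, kept$run), , drop = FALSE]
  dplyr::select(kept[1, , drop = FALSE], -"retained")
}

#' Number of randomization runs needed for a stable position
#'
#' Grows the number of randomized completions on a doubling schedule
#' (2, 4, 8, ..., `max_runs`) and, at each checkpoint, regresses per-run
#' worth on option identity across the accumulated runs, testing the
#' separation of the target from every other option (Holm-adjusted
#' pairwise contrasts). The procedure stops at the smallest run count where
#' every adjusted p-value is at most 0.05 *and* the target's confidence
#' interval overlaps no other option's; if `max_runs` is reached without
#' separation the target's position is flagged as ambiguous.
#'
#' @inheritParams simulate_positions
#' @param max_runs Largest run count to try (at least 2).
#' @param level Confidence level for the interval check.
#' @return A list: `cutoff_runs`, `ambiguous`, and the per-checkpoint
#'   diagnostics table `trace`.
#' @export
determine_cutoff <- function(outcomes, target, tested_against,
                             max_runs = 512L, seed = NULL,
                             randomize_ties = FALSE,
                             tie_handling = "half_win", level = 0.95) {
  stopifnot(max_runs >= 2)
  outcomes <- as_outcome_data(outcomes)
  options <- choice_options(outcomes)
  if (!target %in% options) stop_validation("unknown target option: ", target)

  complete_input <- nrow(completeness_report(outcomes)) == 0
  observed <- if (complete_input) {
    drop <- (outcomes$option_a == target &
               !outcomes$option_b %in% tested_against) |
      (outcomes$option_b == target & !outcomes$option_a %in% tested_against)
    o <- outcomes[!drop, , drop = FALSE]
    attr(o, "options") <- options
    attr(o, "subjects") <- choice_subjects(outcomes)
    class(o) <- c("outcome_tbl", setdiff(class(o), "outcome_tbl"))
    o
  } else outcomes
  missing <- target_missing_cells(observed, target)
  if (nrow(missing) == 0) {
    return(list(cutoff_runs = 1L, ambiguous = FALSE,
                trace = tibble::tibble()))
  }

  checkpoints <- unique(c(2^seq(1, ceiling(log2(max_runs))), max_runs))
  checkpoints <- checkpoints[checkpoints <= max_runs]
  others <- setdiff(options, target)

  body <- function() {
    worth_rows <- vector("list", max_runs)
    trace <- list()
    done <- NULL
    n_drawn <- 0L
    for (k in checkpoints) {
      while (n_drawn < k) {
        n_drawn <- n_drawn + 1L
        completed <- fill_cells(observed, missing, randomize_ties)
        fit <- fit_worth(completed, tie_handling = tie_handling)
        worth_rows[[n_drawn]] <- tibble::tibble(
          run = n_drawn, option = fit$options, worth = fit$worth$worth)
      }
      long <- dplyr::bind_rows(worth_rows[seq_len(k)])
      lm_fit <- stats::lm(worth ~ 0 + option, data = long)
      mu <- stats::coef(lm_fit)
      names(mu) <- sub("^option", "", names(mu))
      sigma <- suppressWarnings(summary(lm_fit))$sigma
      df <- lm_fit$df.residual
      if (sigma < 1e-10) {
        # degenerate: the accumulated completions are identical, so there is
        # no run-to-run variance to attest separation with
        trace[[length(trace) + 1]] <- tibble::tibble(
          runs = k, max_adjusted_p = NA_real_, separated = FALSE)
        next
      }
      se <- sigma * sqrt(2 / k)
      tstat <- (mu[target] - mu[others]) / se
      p <- stats::p.adjust(2 * stats::pt(-abs(tstat), df), method = "holm")
      ci <- summarize_ci(long, level = level)
      t_row <- ci[ci$option == target, ]
      o_rows <- ci[ci$option != target, ]
      no_overlap <- all(t_row$lower > o_rows$upper |
                          t_row$upper < o_rows$lower)
      sep <- all(p <= 0.05) && no_overlap
      trace[[length(trace) + 1]] <- tibble::tibble(
        runs = k, max_adjusted_p = max(p), separated = sep)
      if (sep) {
        done <- k
        break
      }
    }
    list(done = done, trace = dplyr::bind_rows(trace))
  }
  res <- if (is.null(seed)) body() else withr::with_seed(seed, body())
  list(cutoff_runs = res$done %||% as.integer(max_runs),
       ambiguous = is.null(res$done),
       trace = res$trace)
}

#' @export
print.position_sim <- function(x, ...) {
  kept <- sum(x$runs$retained)
  cat(sprintf("Position simulation for '%s' (%s, %d runs, %d retained)\n",
              x$target, x$mode, x$runs_requested, kept))
  cat("  tested against:", paste(x$tested_against, collapse = ", "), "\n")
  if (!is.na(x$true_position)) {
    cat(sprintf("  true position: %d; frequency of true positives: %.2f\n",
                x$true_position, x$true_positive_frequency))
  }
  best <- select_best_run(x)
  cat(sprintf("  best run: position %d (I-ratio %.2f, CE %.2f%%)\n",
              best$position, best$i_ratio, best$ce))
  invisible(x)
}

#' @method tidy position_sim
#' @export
tidy.position_sim <- function(x, ...) x$runs

#' @method glance position_sim
#' @export
glance.position_sim <- function(x, ...) {
  best <- select_best_run(x)
  tibble::tibble(
    target = x$target, mode = x$mode,
    runs = x$runs_requested, retained_runs = sum(x$runs$retained),
    discarded_runs = x$discarded_runs,
    modal_position = x$position_frequencies$position[
      which.max(x$position_frequencies$frequency)],
    best_position = best$position, best_i_ratio = best$i_ratio,
    best_ce = best$ce,
    true_position = x$true_position,
    true_positive_count = x$true_positive_count,
    true_positive_frequency = x$true_positive_frequency
  )
}

#' Results-table row for a simulation
#'
#' One row in the conventional simulation-results layout: Item, Simulated
#' position, Worth value, I-ratio, CE (%), Frequency of true positives,
#' No. of true positives, Tested against. Values come from the best
#' retained run (lowest intransitivity ratio, then lowest consensus error).
#'
#' @param sim A `position_sim` (or a list of them, one row each).
#' @return A tibble in the results-table column layout.
#' @export
simulation_table <- function(sim) {
  if (inherits(sim, "position_sim")) sim <- list(sim)
  purrr::map_dfr(sim, function(s) {
    best <- select_best_run(s)
    kept <- s$runs[s$runs$retained, , drop = FALSE]
    best_worth <- s$worths$worth[s$worths$run == best$run &
                                   s$worths$option == s$target]
    tibble::tibble(
      item = s$target,
      simulated_position = best$position,
      worth_value = best_worth,
      i_ratio = best$i_ratio,
      ce_pct = best$ce,
      true_positive_frequency = s$true_positive_frequency,
      true_positive_count = s$true_positive_count,
      tested_against = paste(s$tested_against, collapse = ", ")
    )
  })
}

#' Plot simulated worth values with confidence intervals
#'
#' @param object A `position_sim` with at least 2 retained runs.
#' @param ... Unused.
#' @return A ggplot: per-option mean worth across retained runs with
#'   confidence intervals, the simulated target highlighted.
#' @method autoplot position_sim
#' @method autoplot position_sim
#' @method autoplot position_sim
#' @method autoplot position_sim
#' @export
autoplot.position_sim <- function(object, ...) {
  ci <- object$ci
  if (is.null(ci)) stop_validation("need >= 2 retained runs to plot CIs")
  ci$role <- ifelse(ci$option == object$target, "simulated", "observed")
  ci$option <- stats::reorder(ci$option, -ci$mean)
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$option, y = .data$mean,
                                   colour = .data$role)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2) +
    ggplot2::scale_colour_manual(values = c(simulated = "firebrick",
                                            observed = "grey30")) +
    ggplot2::labs(x = NULL, y = "worth value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export a simulation result
#'
#' JSON carries all runs and the summary at full precision; TSV writes the
#' results-table row (see [simulation_table()]).
#'
#' @param sim A `position_sim`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "position_sim"))
  if (format == "tsv") {
    readr::write_tsv(simulation_table(sim), path)
  } else {
    jsonlite::write_json(list(
      summary = as.list(glance(sim)),
      runs = sim$runs,
      worths = sim$worths,
      position_frequencies = sim$position_frequencies,
      ci = sim$ci
    ), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
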