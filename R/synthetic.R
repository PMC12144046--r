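#' Generate choice data with known ground truth
#'
#' Simulates the two study designs the package targets. `"forced_choice"`
#' emulates a picture-rating task: each subject sees every option pair
#' `trials_per_pair` times and picks one side, encoded as quantities
#' `(1, 0)` / `(0, 1)` per trial (trials are stored as sessions, so
#' [aggregate_sessions()] recovers per-pair counts). `"consumption"`
#' emulates two-bottle liquid tests: each subject-pair gets a pair of
#' non-negative counts whose expected ratio follows the same Bradley-Terry
#' probability, with overdispersion injected through a gamma-mixed Poisson
#' so the realized ratios spread around their expectation.
#'
#' Choices follow the Bradley-Terry rule: option `i` is picked over `j`
#' with probability `w_i / (w_i + w_j)` for the supplied ground-truth worth
#' vector (normalized internally).
#'
#' @param worth Named positive weights, one per option; names become option
#'   labels (unnamed vectors get labels `o1, o2, ...`).
#' @param n_subjects Number of subjects.
#' @param trials_per_pair Forced-choice trials per subject-pair (sessions).
#' @param tie_rate Probability that a forced-choice trial records equal
#'   quantities `(1, 1)` instead of a pick (no direction expressed).
#' @param noise Overdispersion for `"consumption"`: 0 gives plain Poisson
#'   counts, larger values spread the consumption ratios (gamma mixing with
#'   variance `noise`).
#' @param style `"forced_choice"` or `"consumption"`.
#' @param total_consumption Expected total count per consumption pair.
#' @param seed Integer seed; the generator is reproducible given the seed
#'   and leaves the global RNG state untouched.
#' @return A validated choice tibble.
#' @examples
#' d <- generate_choices(worth = c(juice = 4, water = 2, nacl = 1),
#'                       n_subjects = 6, style = "consumption", seed = 1)
#' head(d)
#' @export
generate_choices <- function(worth, n_subjects, trials_per_pair = 1L,
                             tie_rate = 0, noise = 0,
                             style = c("forced_choice", "consumption"),
                             total_consumption = 100, seed = NULL) {
  style <- match.arg(style)
  stopifnot(is.numeric(worth), all(worth > 0), length(worth) >= 2,
            n_subjects >= 1, trials_per_pair >= 1,
            tie_rate >= 0, tie_rate < 1, noise >= 0, total_consumption > 0)
  if (is.null(names(worth))) {
    names(worth) <- paste0("o", seq_along(worth))
  }
  stopifnot(!anyDuplicated(names(worth)))
  worth <- worth / sum(worth)
  options <- names(worth)
  subjects <- paste0("s", seq_len(n_subjects))
  pairs <- utils::combn(options, 2)

  draw <- function() {
    rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      p <- worth[[a]] / (worth[[a]] + worth[[b]])
      if (style == "forced_choice") {
        n_cells <- n_subjects * trials_per_pair
        is_tie <- stats::runif(n_cells) < tie_rate
        pick_a <- stats::runif(n_cells) < p
        qa <- ifelse(is_tie, 1, as.numeric(pick_a))
        qb <- ifelse(is_tie, 1, as.numeric(!pick_a))
        tibble::tibble(
          subject = rep(subjects, each = trials_per_pair),
          option_a = a, option_b = b,
          quantity_a = qa, quantity_b = qb,
          session = rep(seq_len(trials_per_pair), times = n_subjects)
        )
      } else {
        g_a <- if (noise > 0) {
          stats::rgamma(n_subjects, shape = 1 / noise, scale = noise)
        } else rep(1, n_subjects)
        g_b <- if (noise > 0) {
          stats::rgamma(n_subjects, shape = 1 / noise, scale = noise)
        } else rep(1, n_subjects)
        qa <- stats::rpois(n_subjects, total_consumption * p * g_a)
        qb <- stats::rpois(n_subjects, total_consumption * (1 - p) * g_b)
        tibble::tibble(
          subject = subjects, option_a = a, option_b = b,
          quantity_a = as.numeric(qa), quantity_b = as.numeric(qb),
          session = 1L
        )
      }
    })
    dplyr::bind_rows(rows)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- out[order(match(out$subject, subjects)), ]
  as_choice_data(out)
}

#' Preset generator scenarios for the valence-range contrast
#'
#' Returns a generator specification for two study conditions that differ
#' only in how widely the ground-truth worth values are spread: a
#' `"wide_valence"` set (geometric decay factor 0.45 between successive
#' options, clearly separated) and a `"narrow_valence"` set (decay factor
#' 0.9, options nearly equivalent). Both use 7 options and 25 forced-choice
#' subjects, one trial per pair, mirroring a picture-rating design. The
#' hypothesis these scenarios probe is that narrow valence ranges produce
#' higher consensus error and a larger intransitivity ratio.
#'
#' @param name `"wide_valence"` or `"narrow_valence"`.
#' @param seed Integer seed stored in the spec.
#' @param n_options,n_subjects Scenario size (defaults 7 and 25).
#' @return A named list of `generate_choices()` arguments (a generator
#'   spec); run it with `do.call(generate_choices, scenario(...))`.
#' @export
scenario <- function(name = c("wide_valence", "narrow_valence"), seed = NULL,
                     n_options = 7L, n_subjects = 25L) {
  name <- match.arg(name)
  decay <- switch(name, wide_valence = 0.45, narrow_valence = 0.9)
  w <- decay^(seq_len(n_options) - 1)
  names(w) <- paste0("opt", seq_len(n_options))
  list(worth = w / sum(w), n_subjects = as.integer(n_subjects),
       trials_per_pair = 1L, tie_rate = 0, noise = 0,
       style = "forced_choice", seed = seed)
}
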