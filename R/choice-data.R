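#' Assemble and validate a choice dataset
#'
#' A choice dataset is a tibble with one row per subject x option-pair x
#' session, holding the two option labels and the non-negative quantity
#' recorded for each side (amount consumed, number of visits, or 1/0 for a
#' forced pick). `as_choice_data()` checks the invariants and returns the
#' data as a validated tibble; option and subject catalogs (ordered by first
#' appearance) are attached as attributes and can be read back with
#' [choice_options()] and [choice_subjects()].
#'
#' @param x A data frame with columns `subject`, `option_a`, `option_b`,
#'   `quantity_a`, `quantity_b` and optionally `session`.
#' @param dialect Optional named character vector mapping the standard column
#'   names to the names used in `x`, e.g.
#'   `c(subject = "animal", quantity_a = "ml_left")`.
#' @return A tibble of class `choice_tbl` with the standard columns.
#' @examples
#' raw <- tibble::tibble(
#'   subject = c("s1", "s1"), option_a = c("water", "water"),
#'   option_b = c("juice", "nacl"), quantity_a = c(30, 80),
#'   quantity_b = c(70, 20)
#' )
#' as_choice_data(raw)
#' @export
as_choice_data <- function(x, dialect = NULL) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (!is.null(dialect)) {
    bad <- setdiff(unname(dialect), names(x))
    if (length(bad) > 0) {
      stop_format("column(s) ", paste0("'", bad, "'", collapse = ", "),
                  " named in the dialect are absent from the data")
    }
    x <- dplyr::rename(x, !!!rlang::set_names(unname(dialect), names(dialect)))
  }
  required <- c("subject", "option_a", "option_b", "quantity_a", "quantity_b")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_format("required column(s) missing: ",
                paste0("'", missing_cols, "'", collapse = ", "))
  }
  if (!"session" %in% names(x)) x$session <- 1L
  x <- dplyr::select(x, dplyr::all_of(c(required, "session")))
  x$subject <- as.character(x$subject)
  x$option_a <- as.character(x$option_a)
  x$option_b <- as.character(x$option_b)
  x$quantity_a <- as.numeric(x$quantity_a)
  x$quantity_b <- as.numeric(x$quantity_b)

  self_pair <- which(x$option_a == x$option_b)
  if (length(self_pair) > 0) {
    stop_validation("option_a equals option_b on row(s) ",
                    paste(self_pair, collapse = ", "))
  }
  neg <- which(is.na(x$quantity_a) | is.na(x$quantity_b) |
                 x$quantity_a < 0 | x$quantity_b < 0)
  if (length(neg) > 0) {
    stop_validation("negative or unparseable quantity on row(s) ",
                    paste(neg, collapse = ", "))
  }
  key <- paste(x$subject,
               pmin(x$option_a, x$option_b),
               pmax(x$option_a, x$option_b),
               x$session, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_validation("duplicate subject/pair/session on row(s) ",
                    paste(dup, collapse = ", "),
                    " (use distinct session ids for repeats)")
  }

  attr(x, "options") <- first_appearance(c(rbind(x$option_a, x$option_b)))
  attr(x, "subjects") <- first_appearance(x$subject)
  class(x) <- c("choice_tbl", class(x))
  x
}

first_appearance <- function(x) unique(as.character(x))

stop_validation <- function(...) {
  stop(rlang::error_cnd(class = "prefrank_validation_error",
                        message = paste0(...)))
}
stop_format <- function(...) {
  stop(rlang::error_cnd(class = "prefrank_format_error",
                        message = paste0(...)))
}

#' Option and subject catalogs of a choice dataset
#'
#' Catalogs are ordered by first appearance in the data, so a dataset read
#' back from disk reproduces the original ordering.
#'
#' @param x A choice tibble or an outcome tibble.
#' @return Character vector of option labels / subject ids.
#' @export
choice_options <- function(x) {
  opts <- attr(x, "options")
  if (!is.null(opts)) return(opts)
  first_appearance(c(rbind(as.character(x$option_a), as.character(x$option_b))))
}

#' @rdname choice_options
#' @export
choice_subjects <- function(x) {
  subj <- attr(x, "subjects")
  if (!is.null(subj)) return(subj)
  first_appearance(as.character(x$subject))
}

#' Read a delimited choice table
#'
#' Reads a long-format table (CSV by default) with one row per subject x
#' option-pair x session and validates it via [as_choice_data()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Optional column-name mapping, see [as_choice_data()].
#' @param delim Field delimiter, default `","`.
#' @return A validated choice tibble.
#' @export
read_choices <- function(path, dialect = NULL, delim = ",") {
  if (!file.exists(path)) stop_format("file not found: ", path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_choice_data(raw, dialect = dialect)
}

#' Write a choice table to a delimited file
#'
#' @param x A choice tibble.
#' @param path Output file path.
#' @param delim Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_choices <- function(x, path, delim = ",") {
  x <- as_choice_data(x)
  readr::write_delim(as.data.frame(x), path, delim = delim)
  invisible(path)
}

#' Collapse side-switched repeat sessions
#'
#' Two-bottle tests are usually repeated with the sides switched to cancel
#' side bias; the repeats describe one comparison, so their quantities are
#' summed per subject and unordered pair before thresholding. Pairs are
#' aligned to the canonical orientation (lexicographic order of the two
#' labels) in the output.
#'
#' @param x A choice tibble.
#' @return A choice tibble with one row per subject x unordered pair.
#' @export
aggregate_sessions <- function(x) {
  x <- as_choice_data(x)
  opts <- choice_options(x)
  subj <- choice_subjects(x)
  swap <- canonical_swap(x$option_a, x$option_b)
  out <- tibble::tibble(
    subject = x$subject,
    option_a = ifelse(swap, x$option_b, x$option_a),
    option_b = ifelse(swap, x$option_a, x$option_b),
    quantity_a = ifelse(swap, x$quantity_b, x$quantity_a),
    quantity_b = ifelse(swap, x$quantity_a, x$quantity_b)
  )
  out <- out |>
    dplyr::group_by(.data$subject, .data$option_a, .data$option_b) |>
    dplyr::summarise(quantity_a = sum(.data$quantity_a),
                     quantity_b = sum(.data$quantity_b),
                     .groups = "drop")
  out$session <- 1L
  out <- out[order(match(out$subject, subj),
                   match(out$option_a, opts),
                   match(out$option_b, opts)), ]
  attr(out, "options") <- opts
  attr(out, "subjects") <- subj
  class(out) <- c("choice_tbl", class(out))
  out
}

# TRUE where the pair must be flipped to reach lexicographic orientation;
# radix sort order (C locale) keeps the comparison locale-independent
canonical_swap <- function(a, b) {
  pairwise_gt(a, b)
}

pairwise_gt <- function(a, b) {
  n <- length(a)
  lv <- sort(unique(c(a, b)), method = "radix")
  m <- match(c(a, b), lv)
  m[seq_len(n)] > m[n + seq_len(n)]
}

#' Threshold quantities into win/loss/tie outcomes
#'
#' For each subject-pair let `r = quantity_a / (quantity_a + quantity_b)`.
#' With preference threshold `theta` (a proportion in `[0.5, 1)`), `r > theta`
#' is a win for the first option, `r < 1 - theta` a win for the second, and
#' everything in the closed window `[1 - theta, theta]` a tie. At
#' `theta = 0.5` only an exact 50:50 split ties; at `theta = 0.65` every split
#' between 35:65 and 65:35 ties. Pairs where nothing was consumed
#' (`quantity_a + quantity_b == 0`) carry no direction and are recorded as
#' ties, with a warning.
#'
#' @param x A session-aggregated choice tibble (see [aggregate_sessions()]).
#' @param theta Preference threshold as a proportion in `[0.5, 1)`.
#' @return A tibble of class `outcome_tbl` with columns `subject`,
#'   `option_a`, `option_b` (canonical orientation) and `result`
#'   (one of `"A_WINS"`, `"B_WINS"`, `"TIE"`).
#' @export
apply_threshold <- function(x, theta = 0.5) {
  x <- as_choice_data(x)
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0.5, theta < 1)
  key <- paste(x$subject, pmin(x$option_a, x$option_b),
               pmax(x$option_a, x$option_b), sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation("multiple sessions per subject/pair present; ",
                    "call aggregate_sessions() first")
  }
  swap <- canonical_swap(x$option_a, x$option_b)
  qa <- ifelse(swap, x$quantity_b, x$quantity_a)
  qb <- ifelse(swap, x$quantity_a, x$quantity_b)
  tot <- qa + qb
  if (any(tot == 0)) {
    warning(sum(tot == 0), " pair(s) with zero total quantity recorded as ties")
  }
  r <- ifelse(tot == 0, 0.5, qa / tot)
  result <- dplyr::case_when(r > theta ~ "A_WINS",
                             r < 1 - theta ~ "B_WINS",
                             TRUE ~ "TIE")
  out <- tibble::tibble(
    subject = x$subject,
    option_a = ifelse(swap, x$option_b, x$option_a),
    option_b = ifelse(swap, x$option_a, x$option_b),
    result = result
  )
  attr(out, "options") <- choice_options(x)
  attr(out, "subjects") <- choice_subjects(x)
  attr(out, "theta") <- theta
  class(out) <- c("outcome_tbl", class(out))
  out
}

as_outcome_data <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("subject", "option_a", "option_b", "result")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_format("required outcome column(s) missing: ",
                paste0("'", missing_cols, "'", collapse = ", "))
  }
  bad <- setdiff(unique(x$result), c("A_WINS", "B_WINS", "TIE"))
  if (length(bad) > 0) {
    stop_validation("unknown result code(s): ", paste(bad, collapse = ", "))
  }
  opts <- choice_options(x)
  subj <- choice_subjects(x)
  swap <- canonical_swap(as.character(x$option_a), as.character(x$option_b))
  out <- tibble::tibble(
    subject = as.character(x$subject),
    option_a = ifelse(swap, as.character(x$option_b), as.character(x$option_a)),
    option_b = ifelse(swap, as.character(x$option_a), as.character(x$option_b)),
    result = ifelse(swap & x$result == "A_WINS", "B_WINS",
                    ifelse(swap & x$result == "B_WINS", "A_WINS", x$result))
  )
  key <- paste(out$subject, out$option_a, out$option_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation("more than one outcome for a subject/pair")
  }
  attr(out, "options") <- opts
  attr(out, "subjects") <- subj
  attr(out, "theta") <- attr(x, "theta")
  class(out) <- c("outcome_tbl", setdiff(class(tibble::tibble()), "outcome_tbl"))
  out
}

#' Number of unordered option pairs
#'
#' `n` options yield `choose(n, 2) = n (n - 1) / 2` binary comparisons; with
#' 7 options a subject faces 21 choices.
#'
#' @param n Number of options, a positive integer.
#' @return `n * (n - 1) / 2`.
#' @export
count_pairs <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    stop_validation("n must be a positive integer")
  }
  n * (n - 1) / 2
}

#' List missing subject-by-pair cells
#'
#' Enumerates every subject x unordered option pair for which no outcome is
#' present; an empty result means the design is complete. The missing cells
#' are exactly what the simulation module randomizes.
#'
#' @param outcomes An outcome tibble from [apply_threshold()].
#' @param options,subjects Catalogs to check against; default to the
#'   catalogs carried by `outcomes`.
#' @return A tibble with columns `subject`, `option_a`, `option_b`.
#' @export
completeness_report <- function(outcomes, options = NULL, subjects = NULL) {
  outcomes <- as_outcome_data(outcomes)
  options <- options %||% choice_options(outcomes)
  subjects <- subjects %||% choice_subjects(outcomes)
  grid <- all_pairs_grid(options, subjects)
  seen <- paste(outcomes$subject, outcomes$option_a, outcomes$option_b,
                sep = "\r")
  grid[!paste(grid$subject, grid$option_a, grid$option_b, sep = "\r") %in%
         seen, , drop = FALSE]
}

all_pairs_grid <- function(options, subjects) {
  if (length(options) < 2) {
    return(tibble::tibble(subject = character(), option_a = character(),
                          option_b = character()))
  }
  pr <- utils::combn(sort(options, method = "radix"), 2)
  tibble::tibble(
    subject = rep(subjects, each = ncol(pr)),
    option_a = rep(pr[1, ], times = length(subjects)),
    option_b = rep(pr[2, ], times = length(subjects))
  )
}

#' Reshape outcomes to one line per subject
#'
#' The classical design-matrix convention for paired-comparison models puts
#' each subject on a single row with one column per option pair. The cell
#' code is `1` when the pair's first (canonically ordered) option won, `-1`
#' when the second won, `0` for a tie and `NA` for a missing comparison.
#'
#' @param outcomes An outcome tibble.
#' @return A wide tibble, one row per subject, columns named `"A:B"`.
#' @export
pivot_single_line <- function(outcomes) {
  outcomes <- as_outcome_data(outcomes)
  subjects <- choice_subjects(outcomes)
  wide <- outcomes |>
    dplyr::mutate(
      pair = paste(.data$option_a, .data$option_b, sep = ":"),
      code = dplyr::case_when(.data$result == "A_WINS" ~ 1L,
                              .data$result == "B_WINS" ~ -1L,
                              TRUE ~ 0L)
    ) |>
    dplyr::select("subject", "pair", "code") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "code")
  wide[match(subjects, wide$subject), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
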