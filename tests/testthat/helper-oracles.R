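# Fixture builders and independent oracles used across the suite.

# Outcome tibble for a single subject from a relation matrix:
# rel[i, j] = 1 (i beats j), -1, or 0 (tie); NA above the diagonal = missing.
tournament_from_matrix <- function(rel, options = rownames(rel),
                                   subject = "s1") {
  if (is.null(options)) options <- paste0("o", seq_len(nrow(rel)))
  rows <- list()
  for (i in seq_len(nrow(rel))) for (j in seq_len(ncol(rel))) {
    if (i >= j || is.na(rel[i, j])) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject = subject, option_a = options[i], option_b = options[j],
      result = c("B_WINS", "TIE", "A_WINS")[rel[i, j] + 2]
    )
  }
  dplyr::bind_rows(rows)
}

# Outcomes from aggregated pair counts: one synthetic subject per win/tie.
# counts: data.frame(option_a, option_b, n_a, n_b, n_tie)
outcomes_from_counts <- function(counts) {
  counts$n_tie <- counts$n_tie %||% 0
  rows <- list()
  sid <- 0
  for (k in seq_len(nrow(counts))) {
    reps <- c(rep("A_WINS", counts$n_a[k]), rep("B_WINS", counts$n_b[k]),
              rep("TIE", counts$n_tie[k]))
    for (r in reps) {
      sid <- sid + 1
      rows[[sid]] <- tibble::tibble(
        subject = paste0("s", sid), option_a = counts$option_a[k],
        option_b = counts$option_b[k], result = r)
    }
  }
  dplyr::bind_rows(rows)
}

# Independent cyclic-triple counter: a 3-subset is cyclic iff all three of
# its relations are decided and every vertex has out-degree exactly 1
# within the sub-tournament (a formulation deliberately different from the
# package's pattern match).
oracle_count_cycles <- function(rel) {
  n <- nrow(rel)
  if (n < 3) return(0L)
  subsets <- utils::combn(n, 3)
  cyc <- 0L
  for (k in seq_len(ncol(subsets))) {
    s <- subsets[, k]
    sub <- rel[s, s]
    vals <- sub[upper.tri(sub)]
    if (any(is.na(vals)) || any(vals == 0)) next
    outdeg <- vapply(1:3, function(i) {
      sum(vapply(1:3, function(j) {
        if (i == j) return(0L)
        v <- if (i < j) sub[i, j] else -sub[j, i]
        as.integer(v == 1)
      }, integer(1)))
    }, integer(1))
    if (all(outdeg == 1L)) cyc <- cyc + 1L
  }
  cyc
}

# Random single-subject relation matrix with optional ties/missing cells.
random_relation <- function(n, p_tie = 0.2, p_missing = 0) {
  rel <- matrix(NA_integer_, n, n)
  labels <- paste0("o", seq_len(n))
  dimnames(rel) <- list(labels, labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- stats::runif(1)
    rel[i, j] <- if (u < p_missing) NA_integer_ else
      sample(c(-1L, 0L, 1L), 1, prob = c((1 - p_tie) / 2, p_tie,
                                         (1 - p_tie) / 2))
  }
  rel
}

# Two-stage grid maximization of the Bradley-Terry log-likelihood for
# 3 options; W[i, j] = wins of i over j. Independent of the package fitter.
grid_mle_3 <- function(W) {
  ll <- function(w1, w2) {
    w3 <- 1 - w1 - w2
    W[1, 2] * log(w1 / (w1 + w2)) + W[2, 1] * log(w2 / (w1 + w2)) +
      W[1, 3] * log(w1 / (w1 + w3)) + W[3, 1] * log(w3 / (w1 + w3)) +
      W[2, 3] * log(w2 / (w2 + w3)) + W[3, 2] * log(w3 / (w2 + w3))
  }
  best <- c(1 / 3, 1 / 3)
  step <- 0.01
  for (stage in 1:3) {
    g1 <- seq(max(step, best[1] - 60 * step), min(1 - 2 * step, best[1] + 60 * step),
              by = step)
    g2 <- seq(max(step, best[2] - 60 * step), min(1 - 2 * step, best[2] + 60 * step),
              by = step)
    grid <- expand.grid(w1 = g1, w2 = g2)
    grid <- grid[grid$w1 + grid$w2 < 1 - step / 2, ]
    vals <- mapply(ll, grid$w1, grid$w2)
    best <- unlist(grid[which.max(vals), ])
    step <- step / 50
  }
  c(best[[1]], best[[2]], 1 - best[[1]] - best[[2]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small consumption-style CSV written to a temp file.
write_toy_csv <- function(path, rows) {
  readr::write_csv(rows, path)
  path
}
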