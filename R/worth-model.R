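#' Fit a Bradley-Terry worth model to binary outcomes
#'
#' Estimates per-option abilities under the Bradley-Terry model, in which
#' option `i` beats option `j` with probability `w_i / (w_i + w_j)`, and
#' returns them as *worth values*: abilities normalized to sum to 1, so a
#' worth value is the probability-scale position of the option within the
#' ranking. The log-abilities (`lambda`) are identified by a sum-to-zero
#' constraint, keeping the output symmetric in the option catalog.
#'
#' Ties can be folded in as half a win for each side (`"half_win"`, the
#' default, robust with few subjects), modelled explicitly with a Davidson
#' tie parameter `nu` (`"davidson"`: the probability of a tie between `i` and
#' `j` is proportional to `nu * sqrt(w_i w_j)`), or discarded (`"drop"`).
#'
#' If an option wins or loses every decided comparison the maximum-likelihood
#' ability is infinite (complete separation); in that case a damping
#' pseudo-count of 0.5 is added to every ordered pair cell unless `damping`
#' was given explicitly. The damping actually used is always reported in the
#' fitted object.
#'
#' @param outcomes An outcome tibble from [apply_threshold()], or any data
#'   frame with columns `subject`, `option_a`, `option_b`, `result`.
#' @param tie_handling `"half_win"`, `"davidson"` or `"drop"`.
#' @param damping Pseudo-count added to every ordered pair cell; `NULL`
#'   (default) means 0, or 0.5 when separation is detected.
#' @param tol Convergence tolerance on the worth vector.
#' @param max_iter Iteration cap.
#' @return An object of class `worth_fit`; use [tidy()] for the per-option
#'   table (option, lambda, worth, position), [glance()] for fit metadata,
#'   and [autoplot.worth_fit()] for a worth-value plot.
#' @examples
#' d <- generate_choices(worth = c(a = 0.5, b = 0.3, c = 0.2),
#'                       n_subjects = 20, seed = 1)
#' fit <- d |> aggregate_sessions() |> apply_threshold(0.5) |> fit_worth()
#' tidy(fit)
#' @export
fit_worth <- function(outcomes,
                      tie_handling = c("half_win", "davidson", "drop"),
                      damping = NULL, tol = 1e-10, max_iter = 10000L) {
  tie_handling <- match.arg(tie_handling)
  stopifnot(is.null(damping) || (is.numeric(damping) && damping >= 0),
            tol > 0, max_iter >= 1)
  outcomes <- as_outcome_data(outcomes)
  options <- choice_options(outcomes)
  n <- length(options)
  if (n < 2) stop_validation("at least 2 options are required")

  cts <- outcome_counts(outcomes, options)
  wins <- cts$wins      # wins[i, j] = number of subjects with i beating j
  ties <- cts$ties      # symmetric tie counts

  # effective win matrix for the non-Davidson likelihoods
  W <- switch(tie_handling,
              half_win = wins + ties / 2,
              davidson = wins,
              drop = wins)

  separated <- any(rowSums(W) + (tie_handling == "davidson") * rowSums(ties) == 0) ||
    any(colSums(W) + (tie_handling == "davidson") * colSums(ties) == 0)
  if (is.null(damping)) damping <- if (separated) 0.5 else 0
  if (damping > 0) W <- W + damping * (1 - diag(n))

  if (damping == 0) {
    decided <- W + t(W) + if (tie_handling == "davidson") ties else 0
    comp <- graph_components(decided > 0)
    if (max(comp) > 1) {
      grp <- split(options, comp)
      stop(rlang::error_cnd(
        class = "prefrank_estimation_error",
        message = paste0(
          "comparison graph is disconnected; components: ",
          paste(vapply(grp, function(g) paste0("{", paste(g, collapse = ", "), "}"),
                       character(1)), collapse = " "),
          ". Supply damping > 0 or add comparisons.")))
    }
  }

  if (tie_handling == "davidson") {
    fit <- fit_davidson(W, ties, tol, max_iter)
  } else {
    fit <- fit_mm(W, tol, max_iter)
  }
  worth <- unname(fit$pi / sum(fit$pi))
  lambda <- log(worth) - mean(log(worth))
  ranked <- rank_from_worth(worth)

  structure(list(
    worth = tibble::tibble(option = options, lambda = lambda, worth = worth,
                           position = ranked$position,
                           tied = ranked$tied),
    options = options,
    wins = wins, ties = ties,
    tie_handling = tie_handling, damping = damping, nu = fit$nu,
    iterations = fit$iterations, converged = fit$converged,
    log_lik = fit$log_lik,
    n_subjects = length(choice_subjects(outcomes)),
    n_outcomes = nrow(outcomes)
  ), class = "worth_fit")
}

outcome_counts <- function(outcomes, options) {
  n <- length(options)
  wins <- matrix(0, n, n, dimnames = list(options, options))
  ties <- matrix(0, n, n, dimnames = list(options, options))
  ia <- match(outcomes$option_a, options)
  ib <- match(outcomes$option_b, options)
  for (k in seq_len(nrow(outcomes))) {
    res <- outcomes$result[k]
    if (res == "A_WINS") {
      wins[ia[k], ib[k]] <- wins[ia[k], ib[k]] + 1
    } else if (res == "B_WINS") {
      wins[ib[k], ia[k]] <- wins[ib[k], ia[k]] + 1
    } else {
      ties[ia[k], ib[k]] <- ties[ia[k], ib[k]] + 1
      ties[ib[k], ia[k]] <- ties[ib[k], ia[k]] + 1
    }
  }
  list(wins = wins, ties = ties)
}

# minorization-maximization iteration for the Bradley-Terry likelihood;
# monotone in the likelihood, so convergence is on the worth vector
fit_mm <- function(W, tol, max_iter) {
  n <- nrow(W)
  N <- W + t(W)
  pi <- rep(1 / n, n)
  total_wins <- rowSums(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- vapply(seq_len(n), function(i) {
      sum(N[i, -i] / (pi[i] + pi[-i]))
    }, numeric(1))
    new_pi <- total_wins / denom
    new_pi[!is.finite(new_pi)] <- 0
    new_pi <- new_pi / sum(new_pi)
    if (max(abs(new_pi - pi / sum(pi))) < tol) {
      pi <- new_pi
      converged <- TRUE
      break
    }
    pi <- new_pi
  }
  if (!converged) {
    # near-boundary likelihoods make plain MM painfully slow; polish the MM
    # iterate with quasi-Newton steps on the same objective
    lam0 <- log(pmax(pi, 1e-12))
    lam0 <- lam0 - lam0[n]
    obj <- function(l) -bt_log_lik(c(l, 0), W)
    grf <- function(l) -bt_gradient(c(l, 0), W)[seq_len(n - 1)]
    res <- stats::optim(lam0[seq_len(n - 1)], obj, grf, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-15))
    lam <- c(res$par, 0)
    pi <- exp(lam - max(lam))
    pi <- pi / sum(pi)
    it <- it + res$counts[["function"]]
    # gradient scale follows the total comparison count
    converged <- sqrt(sum(bt_gradient(lam, W)^2)) < 1e-6 * max(1, sum(W))
  }
  ll <- bt_log_lik(log(pi), W)
  if (!converged) {
    g <- bt_gradient(log(pi), W)
    stop(rlang::error_cnd(
      class = "prefrank_convergence_error",
      message = sprintf(
        "worth fit did not converge in %d iterations (gradient norm %.3g)",
        max_iter, sqrt(sum(g^2)))))
  }
  list(pi = pi, nu = NA_real_, iterations = it, converged = converged,
       log_lik = ll)
}

bt_log_lik <- function(lambda, W) {
  n <- length(lambda)
  ll <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) {
      ll <- ll + W[i, j] * (lambda[i] - log(exp(lambda[i]) + exp(lambda[j])))
    }
  }
  ll
}

bt_gradient <- function(lambda, W) {
  n <- length(lambda)
  g <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    nij <- W[i, j] + W[j, i]
    if (nij == 0) next
    p <- exp(lambda[i]) / (exp(lambda[i]) + exp(lambda[j]))
    g[i] <- g[i] + W[i, j] - nij * p
  }
  g
}

davidson_log_lik <- function(lambda, log_nu, W, ties) {
  n <- length(lambda)
  nu <- exp(log_nu)
  ll <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    d <- log(exp(lambda[i]) + exp(lambda[j]) +
               nu * exp((lambda[i] + lambda[j]) / 2))
    if (W[i, j] > 0) ll <- ll + W[i, j] * (lambda[i] - d)
    if (W[j, i] > 0) ll <- ll + W[j, i] * (lambda[j] - d)
    if (ties[i, j] > 0) {
      ll <- ll + ties[i, j] * (log_nu + (lambda[i] + lambda[j]) / 2 - d)
    }
  }
  ll
}

fit_davidson <- function(W, ties, tol, max_iter) {
  n <- nrow(W)
  has_ties <- sum(ties) > 0
  obj <- function(par) {
    lambda <- c(par[seq_len(n - 1)], -sum(par[seq_len(n - 1)]))
    log_nu <- if (has_ties) par[n] else -Inf
    -davidson_log_lik(lambda, log_nu, W, ties)
  }
  start <- c(rep(0, n - 1), if (has_ties) 0)
  res <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  lambda <- c(res$par[seq_len(n - 1)], -sum(res$par[seq_len(n - 1)]))
  list(pi = exp(lambda) / sum(exp(lambda)),
       nu = if (has_ties) exp(res$par[n]) else 0,
       iterations = res$counts[["function"]],
       converged = res$convergence == 0, log_lik = -res$value)
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Log-likelihood of a worth scale for given outcomes
#'
#' Evaluates the exact objective maximized by [fit_worth()] (including tie
#' terms and damping) at an arbitrary worth vector, which makes independent
#' optimality checks of the fitter possible.
#'
#' @param outcomes An outcome tibble.
#' @param worth Named numeric vector of positive abilities (need not sum
#'   to 1), covering every option in `outcomes`.
#' @inheritParams fit_worth
#' @param nu Davidson tie parameter (ignored unless
#'   `tie_handling = "davidson"`).
#' @return The log-likelihood, a scalar; 0 for an empty outcome set.
#' @export
log_likelihood <- function(outcomes, worth,
                           tie_handling = c("half_win", "davidson", "drop"),
                           damping = 0, nu = 1) {
  tie_handling <- match.arg(tie_handling)
  outcomes <- as_outcome_data(outcomes)
  if (nrow(outcomes) == 0) return(0)
  options <- choice_options(outcomes)
  unknown <- setdiff(options, names(worth))
  if (length(unknown) > 0) {
    stop_validation("worth does not cover option(s): ",
                    paste(unknown, collapse = ", "))
  }
  cts <- outcome_counts(outcomes, options)
  lambda <- unname(log(worth[options]))
  if (tie_handling == "davidson") {
    return(davidson_log_lik(lambda, log(nu), cts$wins, cts$ties))
  }
  W <- if (tie_handling == "half_win") cts$wins + cts$ties / 2 else cts$wins
  if (damping > 0) W <- W + damping * (1 - diag(length(options)))
  bt_log_lik(lambda, W)
}

#' Dense rank positions from worth values
#'
#' Position 1 is the most preferred option; exact worth ties share a
#' position (dense ranking) and are flagged.
#'
#' @param worth Numeric vector of worth values (or a `worth_fit`).
#' @return A list with integer `position` and logical `tied` per option.
#' @export
rank_from_worth <- function(worth) {
  if (inherits(worth, "worth_fit")) worth <- worth$worth$worth
  lev <- sort(unique(worth), decreasing = TRUE)
  position <- match(worth, lev)
  tied <- duplicated(worth) | duplicated(worth, fromLast = TRUE)
  list(position = position, tied = tied)
}

#' @export
print.worth_fit <- function(x, ...) {
  cat("Bradley-Terry worth fit (", x$tie_handling,
      ", damping = ", format(x$damping), ")\n", sep = "")
  tab <- x$worth[order(x$worth$position), ]
  cat(sprintf("  %-18s %8s %8s %4s\n", "option", "lambda", "worth", "pos"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-18s %8.4f %8.4f %4d%s\n", tab$option[i], tab$lambda[i],
                tab$worth[i], tab$position[i],
                if (tab$tied[i]) " (tied)" else ""))
  }
  cat("log-likelihood:", format(x$log_lik), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy worth_fit
#' @export
tidy.worth_fit <- function(x, ...) x$worth

#' @method glance worth_fit
#' @export
glance.worth_fit <- function(x, ...) {
  tibble::tibble(
    n_options = length(x$options), n_subjects = x$n_subjects,
    n_outcomes = x$n_outcomes, tie_handling = x$tie_handling,
    damping = x$damping, nu = x$nu, iterations = x$iterations,
    converged = x$converged, log_lik = x$log_lik
  )
}

#' @export
logLik.worth_fit <- function(object, ...) {
  structure(object$log_lik, df = length(object$options) - 1, class = "logLik")
}

#' Plot worth values of a fitted ranking
#'
#' @param object A `worth_fit`.
#' @param ... Unused.
#' @return A ggplot object: options on the x axis ordered by position,
#'   worth value on the y axis.
#' @method autoplot worth_fit
#' @method autoplot worth_fit
#' @method autoplot worth_fit
#' @method autoplot worth_fit
#' @export
autoplot.worth_fit <- function(object, ...) {
  d <- tidy(object)
  d$option <- stats::reorder(d$option, d$position)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$option, y = .data$worth)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$option, yend = 0),
                          linewidth = 0.3, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "worth value") +
    ggplot2::theme_minimal()
}

#' Export a worth fit to TSV or JSON
#'
#' The TSV holds the per-option table (option, lambda, worth, position);
#' the JSON additionally carries fit metadata (tie handling, damping,
#' iterations, convergence flag).
#'
#' @param fit A `worth_fit`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_worth <- function(fit, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(fit, "worth_fit"))
  if (format == "tsv") {
    readr::write_tsv(tidy(fit), path)
  } else {
    jsonlite::write_json(
      list(worth = tidy(fit), fit = as.list(glance(fit))),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
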