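#' Duplication-divergence model parameters
#'
#' The stochastic duplication-divergence (DD) model is governed by two
#' time-independent probabilities — `alpha`, the chance that each offspring
#' of a duplication retains an existing interaction, and `beta`, the chance
#' that it gains an interaction de novo — plus one `f` per evolutionary
#' level: the fraction of group pairs that interacted in the ancestral
#' network at that level (the mixture prior).
#'
#' @param alpha Retention probability per offspring per duplication, in
#'   \[0, 1\].
#' @param beta De novo gain probability, in \[0, 1\].
#' @param f Named numeric vector of ancestral interacting fractions, one
#'   per level, each in \[0, 1\].
#' @return An object of class `dd_params`.
#' @export
dd_params <- function(alpha, beta, f = numeric(0)) {
  for (v in c(alpha, beta, f)) {
    if (is.na(v) || v < 0 || v > 1) abort("DD parameters must lie in [0, 1]")
  }
  if (alpha <= beta) {
    warn(sprintf(
      "alpha (%.3g) <= beta (%.3g): retention weaker than de novo gain is biologically implausible",
      alpha, beta
    ))
  }
  structure(list(alpha = alpha, beta = beta, f = f), class = "dd_params")
}

#' @export
print.dd_params <- function(x, ...) {
  cat(sprintf("<dd_params> alpha = %.4g, beta = %.4g\n", x$alpha, x$beta))
  if (length(x$f) > 0) {
    cat("  f:", paste(sprintf("%s = %.4g", names(x$f), x$f), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @rdname dd_params
#' @param x A `dd_params` object.
#' @param ... Unused.
#' @export
tidy.dd_params <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = c("alpha", "beta"),
                   level = NA_character_,
                   estimate = c(x$alpha, x$beta)),
    if (length(x$f) > 0) {
      tibble::tibble(term = "f", level = names(x$f),
                     estimate = unname(x$f))
    }
  )
}

#' Pair interaction probability after T duplications (recursion)
#'
#' One duplication along either lineage updates the interaction probability
#' of a descendant pair as `q_{k+1} = alpha * q_k + beta * (1 - q_k)`:
#' an existing link is retained with probability `alpha`, a missing link is
#' gained with probability `beta`. `q_0 = delta` encodes whether the
#' ancestral pair interacted.
#'
#' @param params A [dd_params()] object.
#' @param delta Initial condition: 1 when the ancestral pair interacted,
#'   0 otherwise.
#' @param T Total number of duplications along the two lineages (>= 0).
#' @return The probability `q_T`.
#' @export
qT_recursive <- function(params, delta, T) {
  if (T < 0) abort("T must be >= 0")
  q <- delta
  if (T >= 1) {
    for (k in seq_len(T)) {
      q <- params$alpha * q + params$beta * (1 - q)
    }
  }
  q
}

#' Pair interaction probability after T duplications (closed form)
#'
#' Solves the recursion exactly:
#' `q_T = q* + (alpha - beta)^T * (delta - q*)` with fixed point
#' `q* = beta / (1 - alpha + beta)`. The degenerate case
#' `alpha - beta = 1` (pure duplication, `alpha = 1, beta = 0`) gives
#' `q_T = delta` for all `T`.
#'
#' @inheritParams qT_recursive
#' @return The probability `q_T`.
#' @export
qT_closed <- function(params, delta, T) {
  if (T < 0) abort("T must be >= 0")
  r <- params$alpha - params$beta
  if (r == 1) return(delta)
  q_star <- params$beta / (1 - params$alpha + params$beta)
  q_star + r^T * (delta - q_star)
}

#' Binomial-mixture probability of the observed interaction count
#'
#' For two orthologous groups with `n_A` and `n_B` present-day members there
#' are `n = n_A * n_B` possible inter-group interactions, each descending
#' from the single ancestral pair through `T = n_A + n_B - 2` duplications.
#' Conditional on the ancestral state, the `n` descendant pairs interact
#' independently with probability `q_T(delta)`, so the count `m` of observed
#' interactions is binomial; marginally it is the two-component mixture
#' `P(m|n) = f * Binom(m; n, q_T(1)) + (1 - f) * Binom(m; n, q_T(0))`
#' with the ancestral interacting fraction `f` at that level as the prior.
#'
#' @param m Observed interaction count (0..n).
#' @param n_A,n_B Present-day cluster sizes (>= 1).
#' @param params A [dd_params()] object.
#' @param level Level name indexing `params$f`, or a bare numeric `f`.
#' @return `P(m | n)` under the mixture.
#' @export
mixture_pmf <- function(m, n_A, n_B, params, level) {
  stopifnot(n_A >= 1, n_B >= 1)
  n <- n_A * n_B
  if (any(m < 0 | m > n)) abort("m must lie in [0, n_A * n_B]")
  T <- n_A + n_B - 2
  f <- resolve_f(params, level)
  q1 <- qT_closed(params, 1, T)
  q0 <- qT_closed(params, 0, T)
  f * dbinom(m, n, q1) + (1 - f) * dbinom(m, n, q0)
}

resolve_f <- function(params, level) {
  if (is.numeric(level)) return(level)
  if (!level %in% names(params$f)) {
    abort(sprintf("no f fitted for level '%s'", level))
  }
  unname(params$f[[level]])
}

#' Posterior probability of an ancestral link
#'
#' Bayes' rule on the binomial mixture: given that two groups show `m` of
#' `n` possible present-day interactions,
#' `P_link = f * Binom(m; n, q1) / [f * Binom(m; n, q1) + (1-f) * Binom(m; n, q0)]`
#' is the probability that their ancestral pair interacted.
#'
#' @inheritParams mixture_pmf
#' @return The posterior link probability.
#' @export
link_posterior <- function(m, n_A, n_B, params, level) {
  f <- resolve_f(params, level)
  n <- n_A * n_B
  T <- n_A + n_B - 2
  q1 <- qT_closed(params, 1, T)
  q0 <- qT_closed(params, 0, T)
  num <- f * dbinom(m, n, q1)
  den <- num + (1 - f) * dbinom(m, n, q0)
  if (any(den == 0)) {
    abort("both mixture branches assign probability 0 to this observation")
  }
  num / den
}

#' Pair-count histograms of group-pair interaction evidence
#'
#' For one evolutionary level, partitions the present-day network into
#' orthologous groups and, for every unordered group pair, records the
#' cluster sizes `(n_A, n_B)`, the number of possible interactions
#' `n = n_A * n_B`, and the number `m` of interactions actually observed
#' between the clusters. Pairs with `m = 0` are included: the empirical
#' ratio `C(m, n) / C(n)` over *all* pairs is what the mixture model is
#' fitted to.
#'
#' @param present An igraph of the present-day (filtered) network.
#' @param om An [orthology_map()] covering every node of `present`.
#' @param level Level name.
#' @return A tibble with columns `level`, `n_A`, `n_B`, `n`, `m`,
#'   `n_pairs` (count of group pairs with that evidence signature).
#' @export
collect_pair_count_histograms <- function(present, om, level) {
  clusters <- project_to_level(present, om, level)
  pair_evidence(present, clusters, level)
}

# group-pair evidence from an explicit cluster partition
pair_evidence <- function(present, clusters, level) {
  groups <- names(clusters)
  sizes <- lengths(clusters)
  node_group <- setNames(
    rep(groups, sizes), unlist(clusters, use.names = FALSE)
  )
  el <- igraph::as_edgelist(present, names = TRUE)
  ga <- unname(node_group[el[, 1]])
  gb <- unname(node_group[el[, 2]])
  inter <- ga != gb
  key <- paste(pmin(ga[inter], gb[inter]), pmax(ga[inter], gb[inter]),
               sep = "\r")
  m_counts <- table(key)

  if (length(groups) < 2) {
    return(tibble::tibble(level = character(0), n_A = integer(0),
                          n_B = integer(0), n = integer(0), m = integer(0),
                          n_pairs = integer(0)))
  }
  idx <- utils::combn(length(groups), 2)
  na <- sizes[idx[1, ]]
  nb <- sizes[idx[2, ]]
  ka <- groups[idx[1, ]]
  kb <- groups[idx[2, ]]
  key_all <- paste(pmin(ka, kb), pmax(ka, kb), sep = "\r")
  m_all <- as.integer(m_counts[key_all])
  m_all[is.na(m_all)] <- 0L
  tibble::tibble(
    level = level,
    n_A = pmin(na, nb), n_B = pmax(na, nb),
    n = as.integer(na * nb), m = m_all
  ) |>
    dplyr::count(.data$level, .data$n_A, .data$n_B, .data$n, .data$m,
                 name = "n_pairs")
}

# model P_t(m | n) averaged over the observed (n_A, n_B) splits at that n
mixture_pmf_binned <- function(m, n, splits, params, f) {
  w <- splits$n_pairs / sum(splits$n_pairs)
  p <- 0
  for (i in seq_len(nrow(splits))) {
    p <- p + w[i] * mixture_pmf(m, splits$n_A[i], splits$n_B[i], params, f)
  }
  p
}

#' Fit the duplication-divergence parameters
#'
#' Minimizes the squared log-residuals between the binomial-mixture model
#' and the empirical pair-count ratios `C_t(m, n) / C_t(n)` over all levels,
#' all `n` in `n_range`, and all cells with `C_t(m, n) > 0`:
#' `sum [log P_t(m|n) - log(C_t(m,n)/C_t(n))]^2`.
#' Logs are used because the ratios fall off exponentially in `m`. `alpha`
#' and `beta` are shared across levels; one `f_t` is fitted per level. The
#' model probability at a bare `n` is the count-weighted average over the
#' observed `(n_A, n_B)` splits (the duplication count `T` depends on the
#' split, not on `n` alone).
#'
#' Optimization is Nelder-Mead simplex on logit-transformed parameters
#' (keeping every probability inside (0, 1) while remaining an unconstrained
#' search), with multiple deterministically-seeded restarts.
#'
#' @param histograms Tibble as returned by
#'   [collect_pair_count_histograms()], possibly row-bound over levels.
#' @param n_range Inclusive range of `n` used in the fit; the default
#'   \[2, 8\] keeps cells with meaningful sample sizes.
#' @param n_restarts Number of Nelder-Mead restarts (first start is fixed,
#'   the rest jittered with fixed seeds).
#' @param verbose Print per-restart objectives.
#' @return A [dd_params()] with attributes `objective` (best value),
#'   `converged` (logical) and `n_cells` (cells entering the fit).
#' @export
fit_dd_parameters <- function(histograms, n_range = c(2, 8),
                              n_restarts = 10, verbose = FALSE) {
  h <- histograms[histograms$n >= n_range[1] & histograms$n <= n_range[2], ]
  if (nrow(h) == 0) abort("no histogram cells inside n_range")
  levels <- sort(unique(h$level), method = "radix")

  # per (level, n): total pair count and observed splits
  cells <- h |>
    dplyr::group_by(.data$level, .data$n, .data$m) |>
    dplyr::summarise(count = sum(.data$n_pairs), .groups = "drop")
  totals <- cells |>
    dplyr::group_by(.data$level, .data$n) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  cells <- dplyr::left_join(cells, totals, by = c("level", "n"))
  splits <- h |>
    dplyr::group_by(.data$level, .data$n, .data$n_A, .data$n_B) |>
    dplyr::summarise(n_pairs = sum(.data$n_pairs), .groups = "drop") |>
    dplyr::group_by(.data$level, .data$n) |>
    dplyr::mutate(w = .data$n_pairs / sum(.data$n_pairs)) |>
    dplyr::ungroup()

  n_cells <- nrow(cells)
  underdetermined <- n_cells < 2 + length(levels)
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(z) 1 / (1 + exp(-z))

  # flatten the cell x split cross product once; each objective evaluation
  # is then a few vectorized binomial calls
  terms <- dplyr::inner_join(
    dplyr::mutate(cells, cell = dplyr::row_number()),
    splits[c("level", "n", "n_A", "n_B", "w")],
    by = c("level", "n"), relationship = "many-to-many"
  )
  t_m <- terms$m
  t_n <- terms$n
  t_T <- terms$n_A + terms$n_B - 2
  t_w <- terms$w
  t_cell <- terms$cell
  t_lvl <- match(terms$level, levels)
  log_emp <- log(cells$count / cells$total)

  objective <- function(par) {
    alpha <- inv_logit(par[1])
    beta <- inv_logit(par[2])
    f <- inv_logit(par[-(1:2)])
    r <- alpha - beta
    q_star <- if (r == 1) 0 else beta / (1 - alpha + beta)
    q1 <- if (r == 1) rep(1, length(t_T)) else q_star + r^t_T * (1 - q_star)
    q0 <- if (r == 1) rep(0, length(t_T)) else q_star * (1 - r^t_T)
    fl <- f[t_lvl]
    contrib <- t_w * (fl * dbinom(t_m, t_n, q1) +
                        (1 - fl) * dbinom(t_m, t_n, q0))
    p <- rowsum(contrib, t_cell)[, 1]
    p[p <= 0] <- 1e-300
    sum((log(p) - log_emp)^2)
  }

  start0 <- c(logit(0.5), logit(0.01), rep(logit(0.1), length(levels)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1) start0 else {
      withr::with_seed(1000 + r, start0 + stats::rnorm(length(start0), 0, 1.5))
    }
    o <- tryCatch(
      optim(start, objective, method = "Nelder-Mead",
            control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(o)) {
      if (verbose) inform(sprintf("restart %d: objective %.6g", r, o$value))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  if (is.null(best)) abort("all optimization restarts failed")
  out <- dd_params(
    alpha = inv_logit(best$par[1]),
    beta = inv_logit(best$par[2]),
    f = setNames(inv_logit(best$par[-(1:2)]), levels)
  )
  attr(out, "objective") <- best$value
  attr(out, "converged") <- best$convergence == 0 && !underdetermined
  attr(out, "n_cells") <- n_cells
  if (underdetermined) {
    warn(sprintf(
      "only %d histogram cell(s) for %d parameters: fit is underdetermined",
      n_cells, 2 + length(levels)
    ))
  }
  out
}
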