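#' Fractal (box-counting) dimension
#'
#' Covers the network with MEMB boxes at each diameter in `ell_values` and
#' fits the power law `N_B(ell_B) ~ ell_B^(-d_B)` by unweighted least
#' squares on log-log axes. A clean power law over at least a decade of
#' scales is the signature of a self-similar (fractal, "large-world")
#' network; small-world networks instead show an exponential decay of
#' `N_B`.
#'
#' @param net A connected igraph.
#' @param ell_values Odd box diameters; values above the graph diameter are
#'   dropped (a single box carries no scaling information).
#' @return A `scaling_fit` with `quantity = "d_B"`; `$points` holds
#'   `(ell_B, n_boxes)`.
#' @export
fractal_dimension <- function(net, ell_values = c(3, 5, 7, 9)) {
  diam <- igraph::diameter(net, weights = NA)
  use <- ell_values[ell_values > 1 & ell_values <= diam]
  if (length(use) < 3) {
    abort(sprintf(
      "need >= 3 box sizes with 1 < ell_B <= diameter (%d); got %d usable",
      diam, length(use)
    ))
  }
  nb <- vapply(use, function(l) memb_cover(net, l)$n_boxes, numeric(1))
  fit <- fit_power_scaling(use, nb, quantity = "d_B", sign = -1)
  names(fit$points) <- c("ell_B", "n_boxes")
  fit
}

#' Renormalization-flow phase classification
#'
#' For each score cutoff, builds the percolated backbone, then repeatedly
#' renormalizes it at fixed box diameter `ell_B`, recording at every stage
#' the cumulative box mass (original nodes per supernode) and the mean
#' degree of the renormalized network. The slope of `log <k'>` versus
#' `log <box mass>` classifies the phase: negative for fractal (large-world)
#' networks, positive for small-world networks, near zero at the
#' transition.
#'
#' @param tbl A canonical interaction tibble.
#' @param cutoffs Score cutoffs to classify.
#' @param ell_B Odd box diameter used at every renormalization stage.
#' @param tol Slope magnitude below which the network is labelled
#'   `"transition"`. Self-similar families keep an asymptotically constant
#'   mean degree under renormalization, so the fractal signal in this
#'   observable is a shallow finite-size drift; the default 0.05 resolves it.
#' @param min_nodes Stop iterating once the renormalized graph is smaller.
#' @return A tibble with one row per cutoff: `cutoff`, `slope`, `phase`
#'   (`fractal`, `small-world`, or `transition`), `n_stages`.
#' @export
renormalization_flow <- function(tbl, cutoffs, ell_B = 3, tol = 0.05,
                                 min_nodes = 8) {
  rows <- purrr::map(cutoffs, function(s) {
    g <- tryCatch(apply_threshold(tbl, s), error = function(e) NULL)
    if (is.null(g) || igraph::vcount(g) < 2) {
      warn(sprintf("cutoff %g yields a degenerate network; skipped", s))
      return(NULL)
    }
    fl <- renormalization_flow_graph(g, ell_B, min_nodes)
    tibble::tibble(cutoff = s, slope = fl$slope, n_stages = fl$n_stages)
  })
  out <- dplyr::bind_rows(rows)
  out$phase <- dplyr::case_when(
    out$slope < -tol ~ "fractal",
    out$slope > tol ~ "small-world",
    TRUE ~ "transition"
  )
  out[c("cutoff", "slope", "phase", "n_stages")]
}

#' @rdname renormalization_flow
#' @param net A connected igraph (single-network entry point).
#' @return For `renormalization_flow_graph()`: a list with `slope`,
#'   `n_stages` and the per-stage `points` tibble.
#' @export
renormalization_flow_graph <- function(net, ell_B = 3, min_nodes = 8) {
  n0 <- igraph::vcount(net)
  pts <- tibble::tibble(mass = 1, k_mean = mean(igraph::degree(net)))
  g <- net
  repeat {
    if (igraph::vcount(g) < min_nodes) break
    cover <- memb_cover(g, ell_B)
    # a near-total collapse (a handful of boxes) carries no scaling signal
    if (cover$n_boxes < 4 || cover$n_boxes >= igraph::vcount(g)) break
    g <- renormalize(g, cover)
    pts <- dplyr::bind_rows(pts, tibble::tibble(
      mass = n0 / igraph::vcount(g),
      k_mean = mean(igraph::degree(g))
    ))
  }
  if (nrow(pts) < 2) {
    return(list(slope = 0, n_stages = nrow(pts), points = pts))
  }
  f <- ls_slope(log(pts$mass), log(pts$k_mean))
  list(slope = f$slope, n_stages = nrow(pts), points = pts)
}

# Hurwitz zeta sum_{j>=0} (a + j)^(-s) by truncation + Euler-Maclaurin tail
hurwitz_zeta <- function(s, a, K = 2000L) {
  j <- 0:(K - 1)
  head <- sum((a + j)^(-s))
  aK <- a + K
  head + aK^(1 - s) / (s - 1) + 0.5 * aK^(-s) + s * aK^(-s - 1) / 12
}

#' Fit the degree distribution: power law versus exponential
#'
#' Fits two discrete models to the degree sequence by maximum likelihood:
#' a shifted power law `P(k) ~ (k + k0)^(-gamma)` (with Hurwitz-zeta
#' normalization over `k >= 1`) and a geometric/exponential law
#' `P(k) ~ exp(-k / kbar)`. The model with the lower AIC is selected —
#' scale-free networks have a diverging degree scale, exponential networks a
#' typical one.
#'
#' @param net An igraph with at least 100 nodes, or a numeric degree vector.
#' @return A `scaling_fit`: `quantity` is `"gamma"` (exponent of the power
#'   law) or `"kbar"` (degree scale); `$extra` carries `k0`, both AICs, and
#'   both fitted parameter sets.
#' @export
fit_degree_distribution <- function(net) {
  k <- if (igraph::is_igraph(net)) igraph::degree(net) else as.numeric(net)
  k <- k[k >= 1]
  if (length(k) < 100) abort("need >= 100 nodes with degree >= 1")
  if (var(k) == 0) abort("zero degree variance: no distribution to fit")
  n <- length(k)

  # exponential (geometric on k >= 1): P(k) = (1 - x) x^(k - 1), x = e^(-1/kbar)
  x_hat <- 1 - 1 / mean(k)
  ll_exp <- n * log(1 - x_hat) + (sum(k) - n) * log(x_hat)
  kbar <- -1 / log(x_hat)
  # delta method: se(kbar) from se(mean degree)
  se_mean <- sd(k) / sqrt(n)
  dk_dmu <- 1 / (mean(k)^2 * (1 - x_hat) * log(x_hat)^2)
  se_kbar <- abs(dk_dmu) * se_mean
  aic_exp <- 2 * 1 - 2 * ll_exp

  # shifted discrete power law: P(k) = (k + k0)^(-gamma) / zeta(gamma, 1 + k0).
  # k0 is a *small* cutoff degree; bounding it at 10 keeps the model from
  # drifting along the k0 -> Inf ridge where it degenerates into the
  # exponential law and model selection loses its meaning.
  nll_pl <- function(par) {
    gamma <- 1 + exp(par[1])
    k0 <- 10 * stats::plogis(par[2])
    z <- hurwitz_zeta(gamma, 1 + k0)
    if (!is.finite(z) || z <= 0) return(1e10)
    gamma * sum(log(k + k0)) + n * log(z)
  }
  best <- NULL
  for (start in list(c(log(1.5), 0), c(log(1.0), 1),
                     c(log(0.5), -1))) {
    o <- tryCatch(
      optim(start, nll_pl, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  gamma_hat <- 1 + exp(best$par[1])
  k0_hat <- 10 * stats::plogis(best$par[2])
  ll_pl <- -best$value
  aic_pl <- 2 * 2 - 2 * ll_pl
  # stderr of gamma via numerical curvature of the profile likelihood
  h <- 1e-4
  d2 <- (nll_pl(best$par + c(h, 0)) - 2 * best$value +
           nll_pl(best$par - c(h, 0))) / h^2
  se_gamma <- if (is.finite(d2) && d2 > 0) {
    exp(best$par[1]) / sqrt(d2)   # chain rule through gamma = 1 + e^t
  } else NA_real_

  hist_pts <- tibble::as_tibble(as.data.frame(table(k)))
  names(hist_pts) <- c("k", "count")
  hist_pts$k <- as.numeric(as.character(hist_pts$k))

  if (aic_pl < aic_exp) {
    new_scaling_fit(
      exponent = gamma_hat, stderr = se_gamma, points = hist_pts,
      model = "powerlaw", quantity = "gamma",
      extra = list(gamma = gamma_hat, gamma_se = se_gamma, k0 = k0_hat,
                   kbar = kbar, aic_powerlaw = aic_pl,
                   aic_exponential = aic_exp, loglik = ll_pl)
    )
  } else {
    new_scaling_fit(
      exponent = kbar, stderr = se_kbar, points = hist_pts,
      model = "exponential", quantity = "kbar",
      extra = list(gamma = gamma_hat, gamma_se = se_gamma, k0 = k0_hat,
                   aic_powerlaw = aic_pl, aic_exponential = aic_exp,
                   loglik = ll_exp)
    )
  }
}

#' Hub-degree scaling under renormalization
#'
#' For each covering, computes `s(ell_B)`: the mean over boxes of the ratio
#' between the box's supernode degree after renormalization and the maximum
#' member degree in the original network. `s(ell_B) ~ ell_B^(-d_k)` defines
#' the hub-degree exponent `d_k`, which ties the fractal dimension to the
#' degree exponent through `gamma = 1 + d_B / d_k` — the statement that the
#' degree distribution is invariant under renormalization.
#'
#' @param net A connected igraph.
#' @param covers List of `box_covering`s of `net` at distinct `ell_B`.
#' @return A `scaling_fit` with `quantity = "d_k"`; `$extra$gamma_pred`
#'   holds `1 + d_B/d_k` with `d_B` fitted from the same coverings, and
#'   `$extra$gamma_pred_se` its propagated standard error.
#' @export
hub_degree_scaling <- function(net, covers) {
  if (length(covers) < 3) abort("need >= 3 coverings (scales)")
  deg <- igraph::degree(net)
  nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  names(deg) <- nm
  rows <- purrr::map(covers, function(cv) {
    rg <- renormalize(net, cv)
    kk <- igraph::degree(rg)
    if (length(kk) == 1) {
      return(tibble::tibble(ell_B = cv$ell_B, s = 0, n_boxes = 1))
    }
    ratio <- vapply(seq_along(cv$centers), function(b) {
      members <- names(cv$assignment)[cv$assignment == b]
      kk[b] / max(deg[members])
    }, numeric(1))
    tibble::tibble(ell_B = cv$ell_B, s = mean(ratio),
                   n_boxes = cv$n_boxes)
  })
  df <- dplyr::bind_rows(rows)
  usable <- df[df$s > 0, ]
  fit <- fit_power_scaling(usable$ell_B, usable$s, quantity = "d_k",
                           sign = -1)
  names(fit$points) <- c("ell_B", "s")
  db <- fit_power_scaling(usable$ell_B, usable$n_boxes, quantity = "d_B",
                          sign = -1)
  gp <- 1 + db$exponent / fit$exponent
  gp_se <- abs(gp - 1) * sqrt((db$stderr / db$exponent)^2 +
                                (fit$stderr / fit$exponent)^2)
  fit$extra$d_B <- db$exponent
  fit$extra$gamma_pred <- gp
  fit$extra$gamma_pred_se <- gp_se
  fit
}

#' Modularity ratio of a box covering
#'
#' `M = mean_i (L_in_i / L_out_i)` over boxes, where `L_in_i` counts edges
#' with both endpoints in box `i` and `L_out_i` counts edges of box `i`
#' leading outside. Boxes without any outside link are excluded from the
#' mean and reported via the `n_isolated` attribute. Large `M` means
#' well-separated topological modules.
#'
#' @param net An igraph.
#' @param cover A `box_covering` of `net` with at least 2 boxes.
#' @return The modularity ratio (numeric) with attribute `n_isolated`.
#' @export
modularity_ratio <- function(net, cover) {
  if (cover$n_boxes < 2) abort("modularity needs >= 2 boxes")
  nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  box <- unname(cover$assignment[nm])
  el <- igraph::as_edgelist(net, names = FALSE)
  ba <- box[el[, 1]]
  bb <- box[el[, 2]]
  l_in <- tabulate(ba[ba == bb], nbins = cover$n_boxes)
  inter <- ba != bb
  l_out <- tabulate(c(ba[inter], bb[inter]), nbins = cover$n_boxes)
  keep <- l_out > 0
  if (!any(keep)) abort("all boxes are isolated: modularity undefined")
  structure(mean(l_in[keep] / l_out[keep]), n_isolated = sum(!keep))
}

#' Modularity exponent
#'
#' Fits `M(ell_B) ~ ell_B^(d_M)` over box diameters. `d_M > 1` indicates
#' stronger-than-lattice modularity (a regular d-dimensional lattice has
#' `d_M = 1`); degree-preserving randomization destroys it.
#'
#' @param net A connected igraph.
#' @param ell_values Odd box diameters (>= 3 usable required).
#' @return A `scaling_fit` with `quantity = "d_M"`; points are
#'   `(ell_B, M)`.
#' @export
modularity_exponent <- function(net, ell_values = c(3, 5, 7, 9)) {
  diam <- igraph::diameter(net, weights = NA)
  use <- ell_values[ell_values > 1 & ell_values <= diam]
  if (length(use) < 3) abort("need >= 3 usable box sizes for d_M")
  m <- vapply(use, function(l) {
    cv <- memb_cover(net, l)
    if (cv$n_boxes < 2) return(NA_real_)
    as.numeric(modularity_ratio(net, cv))
  }, numeric(1))
  fit <- fit_power_scaling(use, m, quantity = "d_M", sign = 1)
  names(fit$points) <- c("ell_B", "M")
  fit
}
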