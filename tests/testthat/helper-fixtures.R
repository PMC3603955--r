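# shared fixtures, all generated in code

# interaction tibble straight from rows
itbl <- function(a, b, s) {
  as_interaction_table(data.frame(protein_a = a, protein_b = b, score = s))
}

# igraph -> uniform-score interaction table (for flow / threshold entry points)
graph_as_table <- function(g, score = 500) {
  el <- igraph::as_edgelist(g, names = TRUE)
  suppressWarnings(itbl(el[, 1], el[, 2], score))
}

# two K5 modules at score 900 joined by one score-300 bridge
two_tier_table <- function() {
  k5 <- function(prefix) {
    idx <- utils::combn(5, 2)
    data.frame(protein_a = sprintf("%s%d", prefix, idx[1, ]),
               protein_b = sprintf("%s%d", prefix, idx[2, ]),
               score = 900)
  }
  as_interaction_table(rbind(
    k5("a"), k5("b"),
    data.frame(protein_a = "a1", protein_b = "b1", score = 300)
  ))
}

# connected named ER backbone for percolation planting
planted_backbone <- function(n = 120, p = 0.06, seed = 1) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  g <- largest_component(g)
  igraph::V(g)$name <- sprintf("p%03d", seq_len(igraph::vcount(g)))
  g
}

# pair-count histograms drawn from the binomial-mixture model itself
model_histograms <- function(alpha, beta, f_levels, n_pairs, seed) {
  p <- suppressWarnings(dd_params(alpha, beta))
  withr::with_seed(seed, {
    rows <- lapply(names(f_levels), function(lv) {
      f <- f_levels[[lv]]
      n_A <- sample(1:3, n_pairs, replace = TRUE)
      n_B <- sample(1:3, n_pairs, replace = TRUE)
      n <- n_A * n_B
      T <- n_A + n_B - 2
      delta <- runif(n_pairs) < f
      q <- mapply(function(d, t) qT_closed(p, as.numeric(d), t), delta, T)
      m <- rbinom(n_pairs, n, q)
      data.frame(level = lv, n_A = pmin(n_A, n_B), n_B = pmax(n_A, n_B),
                 n = n, m = m)
    })
    do.call(rbind, rows) |>
      dplyr::count(.data$level, .data$n_A, .data$n_B, .data$n, .data$m,
                   name = "n_pairs") |>
      tibble::as_tibble()
  })
}

# undirected edge keys for set comparison between graphs
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character(0))
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

# one full DD growth-closure run in the divergence-dominated phase
dd_growth_run <- function(seed, alpha = 0.6, beta = 2e-4) {
  seedg <- make_reference_graph("er", n = 20, p = 0.3, rng_seed = 2000 + seed)
  sim <- simulate_dd_evolution(seedg, alpha, beta, 180,
                               snapshot_epochs = c(5, 30, 80),
                               rng_seed = seed)
  present <- largest_component(sim$present)
  om <- lineage_to_orthology(sim$lineage, c("t3", "t2", "t1"),
                             ages = c(3, 2, 1))
  clusters <- lapply(stats::setNames(om$levels, om$levels), function(lv)
    project_to_level(present, om, lv))
  truth <- stats::setNames(sim$lineage$graphs[c("80", "30", "5")],
                           c("t1", "t2", "t3"))
  ls <- measure_level_series(present, truth, clusters,
                             ages = c(t1 = 1, t2 = 2, t3 = 3),
                             rng_seed = seed)
  list(sim = sim, present = present, om = om, clusters = clusters,
       truth = truth, series = ls, growth = fit_growth_rates(ls))
}

# one full reconstruction run with true parameters (retention-dominated phase)
dd_reconstruction_run <- function(seed, alpha = 0.7, beta = 0.001) {
  seedg <- make_reference_graph("er", n = 20, p = 0.3, rng_seed = 1000 + seed)
  sim <- simulate_dd_evolution(seedg, alpha, beta, 180,
                               snapshot_epochs = c(55, 105, 155),
                               rng_seed = seed)
  present <- largest_component(sim$present)
  om <- lineage_to_orthology(sim$lineage, c("old", "mid", "young"),
                             ages = c(1.5, 1.0, 0.5))
  f_true <- vapply(sim$lineage$graphs, igraph::edge_density, numeric(1))
  names(f_true) <- c("old", "mid", "young")
  params <- suppressWarnings(dd_params(alpha, beta, f = f_true))
  pres_dB <- fractal_dimension(present, c(3, 5, 7))$exponent
  epoch_of <- c(young = "155", mid = "105", old = "55")
  per_level <- list()
  for (lv in om$levels) {
    cl <- project_to_level(present, om, lv)
    anc <- score_ancestral_edges(present, cl, params, lv)
    anc <- tryCatch(calibrate_probability_cutoff(anc, pres_dB, tol = 0.2),
                    error = function(e) NULL)
    per_level[[lv]] <- list(anc = anc,
                            truth = sim$lineage$graphs[[epoch_of[[lv]]]])
  }
  list(sim = sim, present = present, om = om, params = params,
       present_dB = pres_dB, per_level = per_level)
}

# pooled precision/recall of a reconstruction run against generator truth
reconstruction_pr <- function(run) {
  tp <- 0; np <- 0; nt <- 0; failed <- 0
  for (lv in names(run$per_level)) {
    x <- run$per_level[[lv]]
    if (is.null(x$anc)) { failed <- failed + 1; next }
    pred <- edge_keys(x$anc$realized)
    tru <- edge_keys(x$truth)
    tp <- tp + sum(pred %in% tru)
    np <- np + length(pred)
    nt <- nt + length(tru)
  }
  c(precision = tp / np, recall = tp / nt, failed_levels = failed)
}
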