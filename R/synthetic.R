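#' Simulate forward duplication-divergence evolution with lineage tracking
#'
#' Grows a network by repeated duplication events. Each event picks a node A
#' uniformly at random and replaces it by two offspring; independently for
#' each offspring and each other node B, an existing A-B link is retained
#' with probability `alpha` and a non-link becomes a link with probability
#' `beta` (both offspring resample, matching the symmetric pairwise
#' recursion of the model exactly). The two offspring are never linked to
#' each other. Snapshots at requested duplication counts record the full
#' ancestral graph and the ancestry needed to map any present-day node to
#' its ancestor at that epoch.
#'
#' @param seed_graph A named igraph to start from.
#' @param alpha,beta Retention / de novo gain probabilities in \[0, 1\].
#' @param duplications Number of duplication events (each adds one node).
#' @param snapshot_epochs Ascending duplication counts at which to snapshot.
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @return A list with `present` (igraph after all duplications) and
#'   `lineage` (class `dd_lineage`): `epochs` (tibble `epoch`,
#'   `duplications`, `n_nodes`), `graphs` (list of snapshot igraphs),
#'   ancestry bookkeeping, and `params_true` (a [dd_params()]).
#' @export
simulate_dd_evolution <- function(seed_graph, alpha, beta, duplications,
                                  snapshot_epochs = integer(0),
                                  rng_seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  n0 <- igraph::vcount(seed_graph)
  if (n0 == 0) abort("seed graph must be nonempty")
  snapshot_epochs <- sort(unique(as.integer(snapshot_epochs)))
  if (length(snapshot_epochs) > 0 &&
      (min(snapshot_epochs) < 0 || max(snapshot_epochs) > duplications)) {
    abort("snapshot_epochs must lie in [0, duplications]")
  }
  n_total <- n0 + duplications
  nm0 <- igraph::V(seed_graph)$name %||% sprintf("s%04d", seq_len(n0))
  ids <- c(nm0, sprintf("d%05d", seq_len(duplications)))
  adj <- matrix(FALSE, n_total, n_total)
  el0 <- igraph::as_edgelist(seed_graph, names = FALSE)
  adj[el0] <- TRUE
  adj[el0[, c(2, 1), drop = FALSE]] <- TRUE
  parent <- integer(n_total)   # 0 = seed node
  birth <- integer(n_total)    # duplication count at which the node appeared
  snap <- function(n_alive, step) {
    alive <- seq_len(n_alive)
    igraph::graph_from_adjacency_matrix(
      `dimnames<-`(adj[alive, alive, drop = FALSE], list(ids[alive], ids[alive])),
      mode = "undirected"
    )
  }
  graphs <- list()
  withr::with_seed(rng_seed, {
    if (0L %in% snapshot_epochs) graphs[["0"]] <- snap(n0, 0L)
    n_alive <- n0
    for (d in seq_len(duplications)) {
      a <- sample.int(n_alive, 1)
      a2 <- n_alive + 1L
      parent[a2] <- a
      birth[a2] <- d
      others <- setdiff(seq_len(n_alive), a)
      nb <- adj[a, others]
      # offspring 1 reuses slot a (same id, same ancestry)
      keep1 <- ifelse(nb, runif(length(others)) < alpha,
                      runif(length(others)) < beta)
      keep2 <- ifelse(nb, runif(length(others)) < alpha,
                      runif(length(others)) < beta)
      adj[a, others] <- keep1
      adj[others, a] <- keep1
      adj[a2, others] <- keep2
      adj[others, a2] <- keep2
      adj[a, a2] <- FALSE
      adj[a2, a] <- FALSE
      n_alive <- a2
      if (d %in% snapshot_epochs) graphs[[as.character(d)]] <- snap(n_alive, d)
    }
  })
  present <- igraph::graph_from_adjacency_matrix(
    `dimnames<-`(adj, list(ids, ids)), mode = "undirected"
  )
  lineage <- structure(
    list(
      epochs = tibble::tibble(
        epoch = as.character(snapshot_epochs),
        duplications = snapshot_epochs,
        n_nodes = n0 + snapshot_epochs
      ),
      graphs = graphs,
      ids = ids, parent = parent, birth = birth, n_seed = n0,
      params_true = suppressWarnings(dd_params(alpha, beta))
    ),
    class = "dd_lineage"
  )
  list(present = present, lineage = lineage)
}

#' Ancestor of present-day nodes at an epoch
#'
#' @param lineage A `dd_lineage`.
#' @param nodes Character vector of node ids (default: all present nodes).
#' @param epoch Duplication count of the snapshot.
#' @return Named character vector: node -> ancestor id at that epoch.
#' @export
ancestor_at <- function(lineage, nodes = NULL, epoch) {
  epoch <- as.integer(epoch)
  if (is.null(nodes)) nodes <- lineage$ids
  idx <- match(nodes, lineage$ids)
  if (anyNA(idx)) abort("unknown node id(s)")
  anc <- vapply(idx, function(i) {
    while (lineage$birth[i] > epoch) i <- lineage$parent[i]
    i
  }, integer(1))
  setNames(lineage$ids[anc], nodes)
}

#' @export
print.dd_lineage <- function(x, ...) {
  cat(sprintf("<dd_lineage> %d seed + %d duplications; snapshots at: %s\n",
              x$n_seed, length(x$ids) - x$n_seed,
              paste(x$epochs$epoch, collapse = ", ")))
  invisible(x)
}

#' Convert a simulated lineage to an orthology map
#'
#' Each snapshot epoch becomes an evolutionary level; the group of a
#' present-day protein at a level is its ancestor id at that epoch, so the
#' emitted map's clusters are exactly the generator's descendant sets.
#'
#' @param lineage A `dd_lineage` with at least one snapshot.
#' @param level_names One level name per snapshot epoch (in epoch order,
#'   i.e. oldest epoch = smallest duplication count first).
#' @param ages Age in Gyr of each level, same order as `level_names`.
#' @return An [orthology_map()].
#' @export
lineage_to_orthology <- function(lineage, level_names, ages) {
  ep <- lineage$epochs$duplications
  if (length(level_names) != length(ep) || length(ages) != length(ep)) {
    abort(sprintf("need exactly %d level names and ages (one per epoch)",
                  length(ep)))
  }
  assignment <- purrr::map2(ep, level_names, function(e, lv) {
    anc <- ancestor_at(lineage, lineage$ids, e)
    tibble::tibble(protein = names(anc), level = lv, group = unname(anc))
  })
  orthology_map(
    dplyr::bind_rows(assignment),
    tibble::tibble(level = level_names, age_gyr = ages)
  )
}

#' Monte-Carlo simulation of a single descendant pair
#'
#' Follows one pair of proteins through `T` duplications under Mode I
#' (retention with probability `alpha` when the pair interacts) and Mode II
#' (de novo gain with probability `beta` when it does not), replicated many
#' times. The empirical interaction frequency converges to the analytic
#' `q_T` of [qT_closed()].
#'
#' @param params A [dd_params()] object.
#' @param delta Initial state: 1 interacting, 0 not.
#' @param T Number of duplications (>= 0).
#' @param reps Number of independent replicates.
#' @param rng_seed Integer seed.
#' @return The empirical interaction frequency after `T` steps.
#' @export
simulate_pair_dd <- function(params, delta, T, reps = 1e5, rng_seed = 1L) {
  if (T < 0) abort("T must be >= 0")
  withr::with_seed(rng_seed, {
    state <- rep(delta == 1, reps)
    if (T >= 1) {
      for (k in seq_len(T)) {
        u <- runif(reps)
        state <- ifelse(state, u < params$alpha, u < params$beta)
      }
    }
    mean(state)
  })
}

#' Scored interaction table with a planted percolation threshold
#'
#' Builds a STRING-like confidence-scored edge table whose percolation
#' threshold is `min(s_true_range)` by construction. The nodes are split
#' into `n_modules` groups; each module's spanning forest is scored in
#' breadth-first order with descending scores (so above the threshold the
#' largest component only ever grows one node at a time), remaining
#' intra-module edges score below every forest edge, and all inter-module
#' bridges score exactly the threshold — the macroscopic jump. Noise edges
#' (random non-interacting pairs) score in the disjoint lower range,
#' emulating weak ties that shortcut between modules.
#'
#' @param true_net A connected named igraph: the true backbone.
#' @param s_true_range Integer score range `c(lo, hi)` for true edges; the
#'   planted threshold is `lo`.
#' @param s_noise_range Integer score range for noise edges; must lie
#'   entirely below `s_true_range`.
#' @param noise_edge_fraction Number of noise edges as a fraction of the
#'   true edge count.
#' @param rng_seed Integer seed.
#' @param n_modules Number of planted modules (default 4).
#' @return A canonical interaction tibble with attributes `s_star` (the
#'   planted threshold) and `true_edges` (number of true edges).
#' @export
scored_table_with_noise <- function(true_net, s_true_range = c(600, 900),
                                    s_noise_range = c(100, 500),
                                    noise_edge_fraction = 0.5,
                                    rng_seed = 1L, n_modules = 4L) {
  if (max(s_noise_range) >= min(s_true_range)) {
    abort("s_noise_range must lie entirely below s_true_range")
  }
  s_min <- as.integer(min(s_true_range))
  s_max <- as.integer(max(s_true_range))
  nm <- igraph::V(true_net)$name %||% as.character(seq_len(igraph::vcount(true_net)))
  n <- length(nm)
  el <- igraph::as_edgelist(true_net, names = FALSE)
  withr::with_seed(rng_seed, {
    module <- sample(rep_len(seq_len(n_modules), n))
    intra <- module[el[, 1]] == module[el[, 2]]
    bridges <- el[!intra, , drop = FALSE]
    # per-module spanning forests in BFS visit order
    forest <- list()
    nontree <- list()
    for (mo in seq_len(n_modules)) {
      vs <- which(module == mo)
      sub <- igraph::induced_subgraph(true_net, vs)
      if (igraph::ecount(sub) == 0) next
      comp <- igraph::components(sub)
      tree_edges <- NULL
      for (ci in seq_len(comp$no)) {
        root <- which(comp$membership == ci)[1]
        b <- igraph::bfs(sub, root = root, unreachable = FALSE,
                         father = TRUE)
        ord <- as.integer(b$order)
        ord <- ord[!is.na(ord)]
        fa <- as.integer(b$father)
        kids <- ord[!is.na(fa[ord])]
        tree_edges <- rbind(tree_edges, cbind(fa[kids], kids))
      }
      sub_nm <- igraph::V(sub)$name
      if (!is.null(tree_edges) && nrow(tree_edges) > 0) {
        forest[[length(forest) + 1]] <-
          cbind(sub_nm[tree_edges[, 1]], sub_nm[tree_edges[, 2]])
      }
      sel <- igraph::as_edgelist(sub, names = TRUE)
      tk <- if (!is.null(tree_edges)) {
        paste(pmin(sub_nm[tree_edges[, 1]], sub_nm[tree_edges[, 2]]),
              pmax(sub_nm[tree_edges[, 1]], sub_nm[tree_edges[, 2]]))
      } else character(0)
      ek <- paste(pmin(sel[, 1], sel[, 2]), pmax(sel[, 1], sel[, 2]))
      nt <- sel[!(ek %in% tk), , drop = FALSE]
      if (nrow(nt) > 0) nontree[[length(nontree) + 1]] <- nt
    }
    forest <- do.call(rbind, forest)
    nontree <- if (length(nontree) > 0) do.call(rbind, nontree) else NULL
    n_f <- if (is.null(forest)) 0L else nrow(forest)
    boundary <- s_min + max(1L, (s_max - s_min) %/% 3L)
    rows <- list()
    if (n_f > 0) {
      sc_f <- floor(seq(s_max, boundary + 1, length.out = n_f))
      rows$forest <- tibble::tibble(protein_a = forest[, 1],
                                    protein_b = forest[, 2], score = sc_f)
    }
    if (!is.null(nontree) && nrow(nontree) > 0) {
      sc_nt <- sample(seq(s_min + 1L, boundary), nrow(nontree),
                      replace = TRUE)
      rows$nontree <- tibble::tibble(protein_a = nontree[, 1],
                                     protein_b = nontree[, 2], score = sc_nt)
    }
    if (nrow(bridges) > 0) {
      rows$bridges <- tibble::tibble(protein_a = nm[bridges[, 1]],
                                     protein_b = nm[bridges[, 2]],
                                     score = s_min)
    }
    n_noise <- round(noise_edge_fraction * igraph::ecount(true_net))
    if (n_noise > 0) {
      true_key <- paste(pmin(nm[el[, 1]], nm[el[, 2]]),
                        pmax(nm[el[, 1]], nm[el[, 2]]))
      got <- character(0)
      pa <- character(0); pb <- character(0)
      while (length(got) < n_noise) {
        i <- sample.int(n, n_noise * 2, replace = TRUE)
        j <- sample.int(n, n_noise * 2, replace = TRUE)
        ok <- i != j
        a <- pmin(nm[i[ok]], nm[j[ok]])
        b <- pmax(nm[i[ok]], nm[j[ok]])
        key <- paste(a, b)
        new <- !(key %in% true_key) & !(key %in% got) & !duplicated(key)
        pa <- c(pa, a[new]); pb <- c(pb, b[new])
        got <- c(got, key[new])
      }
      rows$noise <- tibble::tibble(
        protein_a = pa[seq_len(n_noise)],
        protein_b = pb[seq_len(n_noise)],
        score = sample(seq(min(s_noise_range), max(s_noise_range)),
                       n_noise, replace = TRUE)
      )
    }
  })
  out <- as_interaction_table(dplyr::bind_rows(rows))
  attr(out, "s_star") <- s_min
  attr(out, "true_edges") <- igraph::ecount(true_net)
  out
}

#' Reference graphs with known topology
#'
#' Oracles for the topology analyses: `(u,v)`-flowers are exactly
#' self-similar with fractal dimension `log(u+v)/log(min(u,v))`; ring
#' lattices with random shortcuts are small-world; Erdős–Rényi graphs and
#' square lattices provide degenerate and Euclidean baselines.
#'
#' @param kind One of `"flower"`, `"ring_shortcut"`, `"er"`, `"lattice"`.
#' @param ... Parameters per kind: flower takes `u`, `v`, `generations`;
#'   ring_shortcut takes `n`, `shortcut_fraction`; er takes `n`, `p`;
#'   lattice takes `nrow`, `ncol`.
#' @param rng_seed Integer seed (used by the random kinds).
#' @return A named igraph.
#' @export
make_reference_graph <- function(kind = c("flower", "ring_shortcut", "er",
                                          "lattice"),
                                 ..., rng_seed = 1L) {
  kind <- match.arg(kind)
  args <- list(...)
  g <- switch(
    kind,
    flower = {
      u <- args$u %||% 2L
      v <- args$v %||% 2L
      gen <- args$generations %||% 3L
      if (u < 1 || v < 1 || gen < 1) abort("flower needs u, v, generations >= 1")
      make_flower(u, v, gen)
    },
    ring_shortcut = {
      n <- args$n %||% abort("ring_shortcut needs n")
      frac <- args$shortcut_fraction %||% 0.2
      withr::with_seed(rng_seed, {
        g <- igraph::make_ring(n)
        n_sc <- round(frac * n)
        if (n_sc > 0) {
          from <- sample.int(n, n_sc, replace = TRUE)
          off <- sample(2:(n - 2), n_sc, replace = TRUE)
          to <- ((from + off - 1) %% n) + 1
          g <- igraph::add_edges(g, rbind(from, to))
        }
        igraph::simplify(g)
      })
    },
    er = {
      n <- args$n %||% abort("er needs n")
      p <- args$p %||% abort("er needs p")
      if (p < 0 || p > 1) abort("er needs p in [0, 1]")
      withr::with_seed(rng_seed, igraph::sample_gnp(n, p))
    },
    lattice = {
      nr <- args$nrow %||% abort("lattice needs nrow")
      nc <- args$ncol %||% abort("lattice needs ncol")
      igraph::make_lattice(c(nr, nc))
    }
  )
  igraph::V(g)$name <- sprintf("n%05d", seq_len(igraph::vcount(g)))
  g
}

# (u,v)-flower by iterated edge replacement, starting from a (u+v)-cycle
make_flower <- function(u, v, generations) {
  edges <- cbind(seq_len(u + v), c(2:(u + v), 1))
  n_nodes <- u + v
  for (g in seq_len(generations - 1)) {
    new_edges <- NULL
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      path_edges <- function(len) {
        if (len == 1) return(cbind(a, b))
        mids <- n_nodes + seq_len(len - 1)
        n_nodes <<- n_nodes + len - 1
        cbind(c(a, mids), c(mids, b))
      }
      new_edges <- rbind(new_edges, path_edges(u), path_edges(v))
    }
    edges <- new_edges
  }
  igraph::simplify(
    igraph::graph_from_edgelist(edges, directed = FALSE)
  )
}
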