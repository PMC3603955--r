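#' Component-size profile over score cutoffs
#'
#' Sweeps the distinct confidence scores from high to low. For each cutoff S
#' the graph of edges with `score >= S` is built over the *fixed* node
#' universe (all proteins in the table) and the sizes of the largest and
#' second-largest connected components are recorded as fractions of the node
#' universe. As the cutoff decreases edges accumulate, so the largest
#' component can only grow; a percolation transition shows up as a
#' macroscopic jump in `lcc_frac` accompanied by a peak of `slcc_frac`.
#'
#' @param tbl A canonical interaction tibble (see [as_interaction_table()]).
#' @return A tibble of class `component_profile` with columns `cutoff`
#'   (descending distinct scores), `n_edges`, `lcc_frac`, `slcc_frac`.
#' @export
component_profile <- function(tbl) {
  if (nrow(tbl) == 0) abort("empty interaction table")
  nodes <- sort(unique(c(tbl$protein_a, tbl$protein_b)), method = "radix")
  n <- length(nodes)
  cutoffs <- sort(unique(tbl$score), decreasing = TRUE)
  # incremental union-find: add edge batches as the cutoff descends
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(tbl$protein_a, nodes)
  ib <- match(tbl$protein_b, nodes)
  ord <- order(tbl$score, decreasing = TRUE)
  ia <- ia[ord]; ib <- ib[ord]; sc <- tbl$score[ord]
  res <- vector("list", length(cutoffs))
  pos <- 1L
  n_edges <- 0L
  for (k in seq_along(cutoffs)) {
    s <- cutoffs[k]
    while (pos <= length(sc) && sc[pos] >= s) {
      ra <- find(ia[pos]); rb <- find(ib[pos])
      if (ra != rb) {
        if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
        parent[rb] <- ra
        size[ra] <- size[ra] + size[rb]
      }
      pos <- pos + 1L
      n_edges <- n_edges + 1L
    }
    roots <- vapply(seq_len(n), find, integer(1))
    cs <- sort(tabulate(roots, nbins = n), decreasing = TRUE)
    res[[k]] <- c(n_edges, cs[1] / n, if (length(cs) > 1) cs[2] / n else 0)
  }
  m <- do.call(rbind, res)
  out <- tibble::tibble(
    cutoff = cutoffs,
    n_edges = as.integer(m[, 1]),
    lcc_frac = m[, 2],
    slcc_frac = m[, 3]
  )
  class(out) <- c("component_profile", class(out))
  out
}

#' Detect the percolation threshold S*
#'
#' The threshold is the highest cutoff at which the one-step increase of the
#' largest-component fraction is at least `jump_fraction` of its final value
#' (the value at the lowest cutoff) — the "first jump" criterion. As a
#' diagnostic, the function checks whether the second-largest component peaks
#' within `peak_window` cutoff steps of S*; weighted networks can show a
#' series of jumps, so a displaced peak only raises a warning.
#'
#' @param profile A [component_profile()] tibble.
#' @param jump_fraction Minimum relative size of the jump (default 0.05).
#' @param peak_window Number of cutoff steps around S* within which the
#'   second-largest-component peak is expected (default 2).
#' @return S*, the detected threshold score, with attributes `jump`
#'   (absolute LCC increase at S*) and `slcc_peak_at_threshold` (logical).
#' @export
detect_percolation_threshold <- function(profile, jump_fraction = 0.05,
                                         peak_window = 2L) {
  stopifnot(nrow(profile) >= 1)
  final <- profile$lcc_frac[nrow(profile)]
  prev <- c(0, profile$lcc_frac[-nrow(profile)])
  step <- profile$lcc_frac - prev
  big <- which(step >= jump_fraction * final)
  # the entry at the highest cutoff measures the first graph, not a step
  big <- big[big > 1L]
  if (length(big) == 0) {
    abort(paste0(
      "no largest-component step reaches jump_fraction = ", jump_fraction,
      " of the final size; lower jump_fraction"
    ))
  }
  k <- big[1]
  s_star <- profile$cutoff[k]
  peak_at <- which.max(profile$slcc_frac)
  ok <- abs(peak_at - k) <= peak_window
  if (!ok) {
    warn(sprintf(
      "second-largest component peaks at cutoff %g, not at S* = %g; weighted networks can show a multiplicity of percolation transitions",
      profile$cutoff[peak_at], s_star
    ))
  }
  structure(s_star, jump = step[k], slcc_peak_at_threshold = ok)
}

#' Filter an interaction table at a score threshold
#'
#' Keeps edges with `score >= s_star` and returns the largest connected
#' component of the resulting graph — the percolated backbone used for all
#' topological analysis.
#'
#' @param tbl A canonical interaction tibble.
#' @param s_star Score threshold; must not exceed the maximum observed score.
#' @return An igraph (largest component of the thresholded graph).
#' @export
apply_threshold <- function(tbl, s_star) {
  if (nrow(tbl) == 0) abort("empty interaction table")
  if (s_star > max(tbl$score)) {
    abort(sprintf("s_star = %g exceeds the maximum observed score %g",
                  s_star, max(tbl$score)))
  }
  keep <- tbl[tbl$score >= s_star, ]
  if (nrow(keep) == 0) abort("no edges at or above s_star")
  g <- interaction_graph(keep)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  largest_component(g)
}

#' @rdname component_profile
#' @param object A `component_profile`.
#' @param ... Unused.
#' @export
autoplot.component_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("cutoff", "lcc_frac", "slcc_frac")],
    cols = c("lcc_frac", "slcc_frac"),
    names_to = "component", values_to = "fraction"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cutoff, y = .data$fraction, colour = .data$component
  )) +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "score cutoff S", y = "fraction of nodes",
      colour = NULL,
      title = "Percolation profile over confidence-score cutoffs"
    )
}
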