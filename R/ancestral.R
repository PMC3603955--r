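#' Partition present-day nodes into orthologous groups at a level
#'
#' Several present-day proteins assigned to the same group at a level are
#' descendants of one ancestral protein — the reconstructed duplication
#' events. Cluster sizes drive the duplication counts of the DD model.
#'
#' @param present An igraph of present-day proteins.
#' @param om An [orthology_map()].
#' @param level Level name.
#' @return A named list: group id -> character vector of member proteins,
#'   groups and members sorted.
#' @export
project_to_level <- function(present, om, level) {
  stopifnot(inherits(om, "orthology_map"))
  if (!level %in% om$levels) abort(sprintf("unknown level '%s'", level))
  nodes <- igraph::V(present)$name
  asg <- om$assignment[om$assignment$level == level, ]
  grp <- setNames(asg$group, asg$protein)[nodes]
  if (anyNA(grp)) {
    abort(sprintf("node(s) without a group at level '%s': %s", level,
                  paste(utils::head(nodes[is.na(grp)], 3), collapse = ", ")))
  }
  cl <- split(nodes, unname(grp))
  cl <- lapply(cl, sort, method = "radix")
  cl[order(names(cl), method = "radix")]
}

#' Score candidate ancestral links with the DD posterior
#'
#' Every unordered group pair with at least one observed present-day
#' interaction (`m >= 1`) becomes a weighted candidate edge carrying the
#' posterior `P_link` from [link_posterior()]. Pairs with `m = 0` are never
#' realized as ancestral edges; their posteriors can be inspected through
#' [collect_pair_count_histograms()] and [link_posterior()] directly.
#'
#' @param present An igraph of present-day proteins.
#' @param clusters Partition from [project_to_level()].
#' @param params Fitted (or true) [dd_params()] with `f` for `level`.
#' @param level Level name.
#' @param age Age of the level in Gyr (optional, carried through).
#' @return An object of class `ancestral_network`: list with `level`,
#'   `age`, `nodes` (all group ids), `edges` (tibble `group_a`, `group_b`,
#'   `p_link`, `m`, `n`), and unset `p_c` / `realized` until
#'   [calibrate_probability_cutoff()] is applied.
#' @export
score_ancestral_edges <- function(present, clusters, params, level,
                                  age = NA_real_) {
  ev <- pair_evidence_edges(present, clusters)
  f <- resolve_f(params, level)
  if (nrow(ev) > 0) {
    ev$p_link <- vapply(seq_len(nrow(ev)), function(i) {
      link_posterior(ev$m[i], ev$n_A[i], ev$n_B[i], params, f)
    }, numeric(1))
  } else {
    ev$p_link <- numeric(0)
  }
  structure(
    list(
      level = level, age = age,
      nodes = names(clusters),
      cluster_sizes = lengths(clusters),
      edges = ev[c("group_a", "group_b", "p_link", "m", "n")],
      p_c = NA_real_, realized = NULL, calibration = NULL
    ),
    class = "ancestral_network"
  )
}

# per-group-pair evidence restricted to pairs with m >= 1
pair_evidence_edges <- function(present, clusters) {
  groups <- names(clusters)
  sizes <- lengths(clusters)
  node_group <- setNames(rep(groups, sizes), unlist(clusters, use.names = FALSE))
  size_of <- setNames(sizes, groups)
  el <- igraph::as_edgelist(present, names = TRUE)
  ga <- unname(node_group[el[, 1]])
  gb <- unname(node_group[el[, 2]])
  inter <- ga != gb
  if (!any(inter)) {
    return(tibble::tibble(group_a = character(0), group_b = character(0),
                          n_A = integer(0), n_B = integer(0),
                          n = integer(0), m = integer(0)))
  }
  a <- pmin(ga[inter], gb[inter])
  b <- pmax(ga[inter], gb[inter])
  tibble::tibble(group_a = a, group_b = b) |>
    dplyr::count(.data$group_a, .data$group_b, name = "m") |>
    dplyr::mutate(
      n_A = unname(size_of[.data$group_a]),
      n_B = unname(size_of[.data$group_b]),
      n = .data$n_A * .data$n_B
    ) |>
    dplyr::arrange(.data$group_a, .data$group_b)
}

#' Realized ancestral graph at a probability cutoff
#'
#' @param anc An `ancestral_network`.
#' @param p Probability cutoff; edges with `p_link >= p` are realized.
#' @return An igraph over all ancestral groups.
#' @export
realize_ancestral <- function(anc, p) {
  keep <- anc$edges[anc$edges$p_link >= p, ]
  igraph::graph_from_data_frame(
    data.frame(from = keep$group_a, to = keep$group_b,
               weight = keep$p_link),
    directed = FALSE,
    vertices = data.frame(name = anc$nodes)
  )
}

#' Calibrate the ancestral probability cutoff by fractal-dimension invariance
#'
#' Structural network features are assumed time-invariant, so the cutoff
#' `p_c` is chosen as the smallest grid value at which the largest component
#' of the realized ancestral network has the same fractal dimension as the
#' present-day network, within `tol`. The full diagnostic curve `d_B(p)` is
#' attached; above `p_c` the dimension stays approximately constant.
#'
#' @param anc An `ancestral_network` with weighted candidate edges.
#' @param present_dB Fractal dimension of the present-day network.
#' @param tol Tolerance on `|d_B - present_dB|` (default 0.2, the order of
#'   typical d_B fit uncertainties).
#' @param grid Ascending probability grid in (0, 1\].
#' @param ell_values Box diameters for the per-cutoff d_B fits.
#' @return The input `ancestral_network` with `p_c`, `realized` (largest
#'   component at `p_c`) and `calibration` (tibble `p`, `d_B`, `n_lcc`)
#'   filled in. Errors if no grid point meets the tolerance.
#' @export
calibrate_probability_cutoff <- function(anc, present_dB, tol = 0.2,
                                         grid = seq(0.05, 1, by = 0.05),
                                         ell_values = c(3, 5, 7)) {
  if (nrow(anc$edges) == 0) abort("no weighted candidate edges to calibrate")
  stopifnot(all(diff(grid) > 0), all(grid > 0), all(grid <= 1))
  curve <- purrr::map(grid, function(p) {
    g <- realize_ancestral(anc, p)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    if (igraph::vcount(g) == 0) {
      return(tibble::tibble(p = p, d_B = NA_real_, n_lcc = 0L))
    }
    lcc <- largest_component(g)
    db <- tryCatch(fractal_dimension(lcc, ell_values)$exponent,
                   error = function(e) NA_real_)
    tibble::tibble(p = p, d_B = db, n_lcc = igraph::vcount(lcc))
  })
  curve <- dplyr::bind_rows(curve)
  ok <- which(!is.na(curve$d_B) & abs(curve$d_B - present_dB) <= tol)
  if (length(ok) == 0) {
    cnd <- rlang::error_cnd(
      "paleoppin_calibration_error",
      message = sprintf(
        "no cutoff on the grid brings d_B within %.3g of the present-day value %.3g",
        tol, present_dB
      ),
      curve = curve
    )
    rlang::cnd_signal(cnd)
  }
  p_c <- curve$p[ok[1]]
  anc$p_c <- p_c
  g <- realize_ancestral(anc, p_c)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  anc$realized <- largest_component(g)
  anc$calibration <- curve
  anc
}

#' @export
print.ancestral_network <- function(x, ...) {
  cat(sprintf(
    "<ancestral_network> level %s (%.3g Gyr): %d groups, %d candidate edges%s\n",
    x$level, x$age, length(x$nodes), nrow(x$edges),
    if (!is.na(x$p_c)) {
      sprintf(", p_c = %.3g (%d realized)", x$p_c,
              igraph::ecount(x$realized))
    } else ", uncalibrated"
  ))
  invisible(x)
}

#' @rdname score_ancestral_edges
#' @param x An `ancestral_network`.
#' @param ... Unused.
#' @export
tidy.ancestral_network <- function(x, ...) {
  dplyr::mutate(x$edges, level = x$level, age = x$age,
                realized = if (is.na(x$p_c)) NA else x$edges$p_link >= x$p_c)
}

#' @rdname calibrate_probability_cutoff
#' @param object A calibrated `ancestral_network`.
#' @param ... Unused.
#' @export
autoplot.ancestral_network <- function(object, ...) {
  if (is.null(object$calibration)) abort("network is not calibrated yet")
  ggplot2::ggplot(object$calibration, ggplot2::aes(.data$p, .data$d_B)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$p_c, linetype = "dashed") +
    ggplot2::labs(
      x = "probability cutoff p", y = "fractal dimension d_B",
      title = sprintf("Cutoff calibration, level %s (p_c = %.2f)",
                      object$level, object$p_c)
    )
}

#' Reconstruct the full ancestral series
#'
#' Projects the present-day network to every level of the orthology map
#' (youngest to oldest), scores candidate edges with the DD posterior, and
#' calibrates each level's probability cutoff against the present-day
#' fractal dimension.
#'
#' @param present An igraph of present-day proteins.
#' @param om An [orthology_map()].
#' @param params [dd_params()] with an `f` per level.
#' @param present_dB Present-day fractal dimension; computed from `present`
#'   when omitted.
#' @param tol,grid,ell_values Passed to [calibrate_probability_cutoff()].
#' @return A list of calibrated `ancestral_network`s, youngest first
#'   (oldest last), named by level.
#' @export
reconstruct_series <- function(present, om, params, present_dB = NULL,
                               tol = 0.2, grid = seq(0.05, 1, by = 0.05),
                               ell_values = c(3, 5, 7)) {
  if (is.null(present_dB)) {
    present_dB <- fractal_dimension(present, ell_values)$exponent
  }
  out <- purrr::map(om$levels, function(lv) {
    cl <- project_to_level(present, om, lv)
    anc <- score_ancestral_edges(
      present, cl, params, lv,
      age = om$ages$age_gyr[om$ages$level == lv]
    )
    calibrate_probability_cutoff(anc, present_dB, tol = tol, grid = grid,
                                 ell_values = ell_values)
  })
  setNames(out, om$levels)
}

#' Overlap between two ancestral networks at the same level
#'
#' Counts shared group ids and shared realized edges — the cross-species
#' consistency check: complete, error-free present-day data would
#' reconstruct identical networks for the common ancestor.
#'
#' @param a,b Calibrated `ancestral_network`s at the same level.
#' @return A tibble with `level`, `shared_nodes`, `shared_edges`.
#' @export
network_overlap <- function(a, b) {
  if (!identical(a$level, b$level)) {
    abort(sprintf("level mismatch: '%s' vs '%s'", a$level, b$level))
  }
  if (is.null(a$realized) || is.null(b$realized)) {
    abort("both networks must be calibrated (realized) first")
  }
  shared_nodes <- length(intersect(a$nodes, b$nodes))
  ekey <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  }
  shared_edges <- length(intersect(ekey(a$realized), ekey(b$realized)))
  tibble::tibble(level = a$level, shared_nodes = shared_nodes,
                 shared_edges = shared_edges)
}
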