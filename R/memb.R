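#' MEMB box covering
#'
#' Tiles a connected network with a near-minimal number of boxes of bounded
#' topological diameter using Maximum-Excluded-Mass-Burning: centers are
#' chosen greedily as the nodes covering the most not-yet-covered mass within
#' radius `r_B = (ell_B - 1) / 2`, then every node is assigned to its nearest
#' center. Because each node lies within `r_B` of its center, any two nodes
#' of a box are at distance at most `2 r_B = ell_B - 1 < ell_B`, so the
#' diameter bound holds by construction (and is re-checked).
#'
#' MEMB as published breaks ties at random; here all ties (center choice,
#' nearest-center assignment) are broken toward the lexicographically
#' smallest node id so that coverings are reproducible.
#'
#' @param net A connected igraph.
#' @param ell_B Box diameter bound: odd integer >= 1. Distances are counted
#'   in links; a box is valid when all intra-box distances are `< ell_B`.
#' @return An object of class `box_covering`: list with `ell_B`, `n_boxes`,
#'   `assignment` (named integer vector, node -> box id), `centers`
#'   (character vector of center node ids, one per box, box id = position).
#' @export
memb_cover <- function(net, ell_B) {
  if (ell_B < 1 || ell_B %% 2 != 1) abort("ell_B must be an odd integer >= 1")
  n <- igraph::vcount(net)
  if (n == 0) abort("empty graph")
  if (igraph::components(net)$no != 1) {
    abort("MEMB requires a connected graph; take the largest component first")
  }
  nm <- igraph::V(net)$name %||% as.character(seq_len(n))
  ord <- order(nm, method = "radix")
  if (ell_B == 1) {
    assignment <- setNames(seq_len(n), nm[ord])
    return(structure(
      list(ell_B = 1L, n_boxes = n, assignment = assignment,
           centers = nm[ord]),
      class = "box_covering"
    ))
  }
  r <- (ell_B - 1L) %/% 2L
  D <- igraph::distances(net, weights = NA)
  D <- D[ord, ord, drop = FALSE]
  within <- D <= r
  covered <- rep(FALSE, n)
  centers <- integer(0)
  while (!all(covered)) {
    mass <- rowSums(within[, !covered, drop = FALSE])
    ctr <- which.max(mass)           # first max = smallest node id
    centers <- c(centers, ctr)
    covered <- covered | within[ctr, ]
  }
  # nearest-center assignment; ties toward the smallest center id
  dc <- D[centers, , drop = FALSE]
  assignment <- integer(n)
  mn <- apply(dc, 2, min)
  for (j in seq_len(n)) {
    cand <- which(dc[, j] == mn[j])
    assignment[j] <- cand[which.min(centers[cand])]
  }
  assignment <- setNames(assignment, nm[ord])
  cover <- structure(
    list(ell_B = as.integer(ell_B), n_boxes = length(centers),
         assignment = assignment, centers = nm[ord][centers]),
    class = "box_covering"
  )
  stopifnot(validate_box_covering(net, cover))
  cover
}

#' Validate a box covering
#'
#' Checks that every node is assigned exactly once and that all intra-box
#' shortest-path distances (measured on the full graph) are `< ell_B`.
#'
#' @param net The covered igraph.
#' @param cover A `box_covering`.
#' @return `TRUE`, or an error describing the violation.
#' @export
validate_box_covering <- function(net, cover) {
  nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  if (!setequal(names(cover$assignment), nm) ||
      length(cover$assignment) != length(nm)) {
    abort("covering does not assign every node exactly once")
  }
  if (cover$ell_B > 1) {
    D <- igraph::distances(net, weights = NA)
    for (b in unique(cover$assignment)) {
      members <- match(names(cover$assignment)[cover$assignment == b], nm)
      if (length(members) > 1 &&
          max(D[members, members]) >= cover$ell_B) {
        abort(sprintf("box %d violates the diameter bound", b))
      }
    }
  }
  TRUE
}

#' @export
print.box_covering <- function(x, ...) {
  cat(sprintf("<box_covering> ell_B = %d: %d nodes in %d boxes\n",
              x$ell_B, length(x$assignment), x$n_boxes))
  invisible(x)
}

#' Renormalize a network by collapsing boxes into supernodes
#'
#' Each box becomes a supernode (named after its center); two supernodes are
#' adjacent iff at least one edge of the original network runs between their
#' boxes. Self-loops and multi-edges are removed.
#'
#' @param net An igraph.
#' @param cover A [memb_cover()] covering of `net`.
#' @return The renormalized igraph, one node per box.
#' @export
renormalize <- function(net, cover) {
  nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  mapping <- unname(cover$assignment[nm])
  g <- igraph::contract(net, mapping, vertex.attr.comb = "ignore")
  igraph::V(g)$name <- cover$centers
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "ignore")
}

#' Minimum box cover by exhaustive search
#'
#' Brute-force oracle for small graphs: finds the true minimum number of
#' boxes of diameter `< ell_B` by branch-and-bound over node-to-box
#' assignments. Exponential; intended for graphs of at most ~10 nodes.
#'
#' @param net A connected igraph (small).
#' @param ell_B Odd box diameter bound.
#' @return The minimum number of boxes (integer).
#' @export
min_box_cover_exact <- function(net, ell_B) {
  n <- igraph::vcount(net)
  if (n > 12) abort("exhaustive cover limited to <= 12 nodes")
  D <- igraph::distances(net, weights = NA)
  best <- n
  assign_next <- function(i, boxes) {
    if (length(boxes) >= best) return(invisible(NULL))
    if (i > n) {
      best <<- min(best, length(boxes))
      return(invisible(NULL))
    }
    for (b in seq_along(boxes)) {
      if (all(D[boxes[[b]], i] < ell_B)) {
        boxes2 <- boxes
        boxes2[[b]] <- c(boxes2[[b]], i)
        assign_next(i + 1, boxes2)
      }
    }
    assign_next(i + 1, c(boxes, list(i)))
  }
  assign_next(2L, list(1L))
  best
}
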