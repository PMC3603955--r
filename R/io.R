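#' Canonicalize a scored interaction table
#'
#' Interaction tables are undirected: `a--b` and `b--a` are the same pair.
#' Canonical form orders each pair lexicographically, drops self-pairs and
#' zero-score rows, and collapses duplicate pairs keeping the maximum score.
#'
#' @param x A data frame with columns `protein_a`, `protein_b`, `score`
#'   (integer confidence in \[0, 1000\]).
#' @param drop_zero Drop rows with score 0 (the convention for experimental
#'   confidence scores, where 0 means "no evidence").
#' @return A tibble with columns `protein_a`, `protein_b`, `score`, one row
#'   per unordered pair, `protein_a < protein_b`.
#' @export
as_interaction_table <- function(x, drop_zero = TRUE) {
  need <- c("protein_a", "protein_b", "score")
  if (!all(need %in% names(x))) {
    abort(paste0("interaction table needs columns: ", paste(need, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(x[need])
  tbl$protein_a <- as.character(tbl$protein_a)
  tbl$protein_b <- as.character(tbl$protein_b)
  tbl$score <- as.numeric(tbl$score)
  if (anyNA(tbl$score) || any(tbl$score < 0) || any(tbl$score > 1000)) {
    bad <- which(is.na(tbl$score) | tbl$score < 0 | tbl$score > 1000)[1]
    abort(sprintf("score out of range [0, 1000] at row %d", bad))
  }
  self <- tbl$protein_a == tbl$protein_b
  if (any(self)) {
    warn(sprintf("dropping %d self-pair(s)", sum(self)))
    tbl <- tbl[!self, ]
  }
  if (drop_zero) tbl <- tbl[tbl$score > 0, ]
  if (nrow(tbl) == 0) return(tbl)
  a <- pmin(tbl$protein_a, tbl$protein_b)
  b <- pmax(tbl$protein_a, tbl$protein_b)
  tbl$protein_a <- a
  tbl$protein_b <- b
  tbl |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Read a scored interaction table from TSV
#'
#' Expects three tab-separated columns `protein_a`, `protein_b`, `score`
#' (header optional). Scores are integer confidences in \[0, 1000\]; rows with
#' score 0 are dropped, self-pairs are dropped with a warning, and duplicate
#' pairs are collapsed keeping the maximum score.
#'
#' @param path Path to the TSV file.
#' @return A canonical interaction tibble (see [as_interaction_table()]).
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readr::read_lines(path, n_max = 1)
  has_header <- length(first) == 1 &&
    grepl("protein", first, ignore.case = TRUE)
  tbl <- suppressWarnings(readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("protein_a", "protein_b", "score"),
    col_types = readr::cols(
      protein_a = readr::col_character(),
      protein_b = readr::col_character(),
      score = readr::col_double()
    ),
    progress = FALSE
  ))
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed interaction row at line %d: %s",
                  prob$row[1] + has_header, prob$expected[1]))
  }
  if (ncol(tbl) != 3) abort("interaction file must have exactly 3 columns")
  names(tbl) <- c("protein_a", "protein_b", "score")
  if (anyNA(tbl$score)) {
    abort(sprintf("unparseable score at data row %d", which(is.na(tbl$score))[1]))
  }
  as_interaction_table(tbl)
}

#' Write a scored interaction table to TSV
#'
#' @param tbl A canonical interaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Construct an orthology map
#'
#' An orthology map assigns each protein to a cluster of orthologous groups
#' (COG/NOG) at each evolutionary level, and attaches a divergence-time age
#' (Gyr before present) to every level. Levels are ordered by age, youngest
#' first; a protein is *conserved* when it has an assignment at every level.
#'
#' @param assignment Data frame with columns `protein`, `level`, `group`.
#' @param ages Data frame with columns `level`, `age_gyr`. Must cover every
#'   level appearing in `assignment`.
#' @return An object of class `orthology_map`: a list with `assignment`
#'   (tibble), `ages` (tibble ordered by increasing age) and `levels`
#'   (character vector, youngest first).
#' @export
orthology_map <- function(assignment, ages) {
  need_a <- c("protein", "level", "group")
  if (!all(need_a %in% names(assignment))) {
    abort("assignment needs columns protein, level, group")
  }
  if (!all(c("level", "age_gyr") %in% names(ages))) {
    abort("ages needs columns level, age_gyr")
  }
  assignment <- tibble::as_tibble(assignment[need_a])
  assignment$protein <- as.character(assignment$protein)
  assignment$level <- as.character(assignment$level)
  assignment$group <- as.character(assignment$group)
  ages <- tibble::as_tibble(ages[c("level", "age_gyr")])
  ages$level <- as.character(ages$level)
  ages$age_gyr <- as.numeric(ages$age_gyr)
  missing_age <- setdiff(unique(assignment$level), ages$level)
  if (length(missing_age) > 0) {
    abort(paste0("level(s) without an age: ", paste(missing_age, collapse = ", ")))
  }
  dup <- assignment |>
    dplyr::count(.data$protein, .data$level) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "protein %s assigned to multiple groups at level %s; multi-assignment is not supported",
      dup$protein[1], dup$level[1]
    ))
  }
  ages <- ages[!duplicated(ages$level), ]
  ages <- dplyr::arrange(ages, .data$age_gyr, .data$level)
  structure(
    list(assignment = assignment, ages = ages, levels = ages$level),
    class = "orthology_map"
  )
}

#' Read an orthology map from TSV files
#'
#' `path` holds the membership table (`protein  level  group`, header
#' optional); `ages_path` holds one age per level (`level  age_gyr`). Levels
#' are ordered by increasing age regardless of file order.
#'
#' @param path Membership TSV.
#' @param ages_path Level-age TSV.
#' @return An [orthology_map()] object.
#' @export
read_orthology_map <- function(path, ages_path) {
  for (p in c(path, ages_path)) {
    if (!file.exists(p)) abort(paste0("no such file: ", p))
  }
  read3 <- function(p, nms) {
    first <- readr::read_lines(p, n_max = 1)
    has_header <- grepl(nms[1], first, ignore.case = TRUE)
    tbl <- readr::read_tsv(
      p,
      col_names = if (has_header) TRUE else nms,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    if (ncol(tbl) != length(nms)) {
      abort(sprintf("%s must have exactly %d columns", p, length(nms)))
    }
    names(tbl) <- nms
    tbl
  }
  assignment <- read3(path, c("protein", "level", "group"))
  ages <- read3(ages_path, c("level", "age_gyr"))
  ages$age_gyr <- as.numeric(ages$age_gyr)
  if (anyNA(ages$age_gyr)) abort("unparseable age in ages file")
  orthology_map(assignment, ages)
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf(
    "<orthology_map> %d proteins, %d levels (%s)\n",
    dplyr::n_distinct(x$assignment$protein), length(x$levels),
    paste(sprintf("%s: %.3g Gyr", x$levels, x$ages$age_gyr), collapse = ", ")
  ))
  invisible(x)
}

#' Proteins conserved at every evolutionary level
#'
#' @param om An [orthology_map()].
#' @return Character vector of protein ids with an assignment at all levels.
#' @export
conserved_proteins <- function(om) {
  stopifnot(inherits(om, "orthology_map"))
  n_levels <- length(om$levels)
  counts <- om$assignment |>
    dplyr::distinct(.data$protein, .data$level) |>
    dplyr::count(.data$protein)
  sort(counts$protein[counts$n == n_levels], method = "radix")
}

#' Restrict an interaction table to fully conserved proteins
#'
#' Keeps only edges whose both endpoints have a group assignment at every
#' level of the orthology map — the pre-filter applied before percolation
#' analysis, so that every retained protein has a complete lineage.
#'
#' @param tbl A canonical interaction tibble.
#' @param om An [orthology_map()].
#' @return Filtered interaction tibble (possibly empty, with a warning).
#' @export
filter_conserved_proteins <- function(tbl, om) {
  keep <- conserved_proteins(om)
  out <- tbl[tbl$protein_a %in% keep & tbl$protein_b %in% keep, ]
  if (nrow(out) == 0) warn("no interactions left after conservation filter")
  out
}

#' Build an igraph from an interaction table
#'
#' All proteins appearing in the table become vertices (the node universe is
#' fixed by the table, not by the score cutoff), edges carry a `weight`
#' attribute equal to the score.
#'
#' @param tbl A canonical interaction tibble.
#' @param min_score Optional score cutoff; edges with `score >= min_score`
#'   are retained, all nodes kept.
#' @return An undirected simple igraph.
#' @export
interaction_graph <- function(tbl, min_score = NULL) {
  nodes <- sort(unique(c(tbl$protein_a, tbl$protein_b)), method = "radix")
  keep <- if (is.null(min_score)) tbl else tbl[tbl$score >= min_score, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = keep$protein_a, to = keep$protein_b,
               weight = keep$score),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component. Ties between
#' equal-sized components are broken deterministically in favour of the
#' component containing the lexicographically smallest node id.
#'
#' @param net An igraph.
#' @return The induced subgraph (an igraph).
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0) abort("empty graph has no largest component")
  comp <- igraph::components(net)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1) {
    nm <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
    min_id <- vapply(
      cand,
      function(ci) sort(nm[comp$membership == ci], method = "radix")[1],
      character(1)
    )
    cand <- cand[order(min_id, method = "radix")][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == cand))
}

#' Write a network to GraphML
#'
#' @param net An igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a network as an undirected edge-list TSV
#'
#' Columns `from`, `to` (and `weight` when the graph is weighted).
#'
#' @param net An igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  readr::write_tsv(tibble::as_tibble(el), path, progress = FALSE)
  invisible(path)
}
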