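test_that("projection to a level partitions present nodes into clusters", {
  g <- igraph::make_graph(~ P1-P2, P2-Q1)
  om <- orthology_map(
    data.frame(protein = c("P1", "P2", "Q1"), level = "L",
               group = c("F1", "F1", "F2")),
    data.frame(level = "L", age_gyr = 1)
  )
  cl <- project_to_level(g, om, "L")
  expect_equal(lengths(cl), c(F1 = 2L, F2 = 1L))

  # injective mapping: all clusters size 1
  om2 <- orthology_map(
    data.frame(protein = c("P1", "P2", "Q1"), level = "L",
               group = c("g1", "g2", "g3")),
    data.frame(level = "L", age_gyr = 1)
  )
  expect_true(all(lengths(project_to_level(g, om2, "L")) == 1))

  expect_error(project_to_level(igraph::make_graph(~ P1-XX), om, "L"),
               "without a group")
  expect_error(project_to_level(g, om, "unknown"), "unknown level")
})

test_that("candidate ancestral edges carry the DD posterior", {
  # sizes (1,2), one observed edge of two possible: the worked mixture case
  g <- igraph::make_graph(~ a1-b1, a1-b2)
  cl <- list(gA = "a1", gB = c("b1", "b2"))
  p <- dd_params(0.6, 0.1, f = c(L = 0.5))
  anc <- score_ancestral_edges(g, cl, p, "L")
  expect_equal(nrow(anc$edges), 1)
  expect_equal(anc$edges$m, 2)
  expect_equal(anc$edges$n, 2)
  expect_equal(anc$edges$p_link, 0.18 / 0.185)

  # singleton clusters with an edge: T = 0, inheritance is certain
  g2 <- igraph::make_graph(~ x1-y1)
  anc2 <- score_ancestral_edges(g2, list(gX = "x1", gY = "y1"), p, "L")
  expect_equal(anc2$edges$p_link, 1)

  # no inter-cluster edge: no weighted candidate (m = 0 pairs omitted)
  g3 <- igraph::make_graph(~ a1-a2, b1-b2)
  anc3 <- score_ancestral_edges(
    g3, list(gA = c("a1", "a2"), gB = c("b1", "b2")), p, "L"
  )
  expect_equal(nrow(anc3$edges), 0)
  expect_equal(anc3$nodes, c("gA", "gB"))
})

test_that("cutoff calibration finds the smallest invariant-dimension cutoff", {
  # certain weights on a topology that already matches: first grid point wins
  fl <- make_reference_graph("flower", u = 2, v = 2, generations = 3)
  el <- igraph::as_edgelist(fl)
  anc <- structure(
    list(level = "L", age = 1, nodes = igraph::V(fl)$name,
         cluster_sizes = NULL,
         edges = tibble::tibble(group_a = el[, 1], group_b = el[, 2],
                                p_link = 1, m = 1L, n = 1L),
         p_c = NA_real_, realized = NULL, calibration = NULL),
    class = "ancestral_network"
  )
  present_dB <- fractal_dimension(fl, c(3, 5, 7))$exponent
  cal <- calibrate_probability_cutoff(anc, present_dB, tol = 0.2)
  expect_equal(cal$p_c, 0.05)
  expect_equal(igraph::ecount(cal$realized), igraph::ecount(fl))
  expect_s3_class(autoplot(cal), "ggplot")

  # impossible tolerance raises an error carrying the diagnostic curve
  err <- tryCatch(
    calibrate_probability_cutoff(anc, present_dB + 5, tol = 0),
    error = function(e) e
  )
  expect_s3_class(err, "paleoppin_calibration_error")
  expect_true(is.data.frame(err$curve))

  # the realized largest component shrinks (weakly) as the cutoff rises
  expect_true(all(diff(cal$calibration$n_lcc) <= 0))
})

test_that("reconstructed series shrinks toward older levels with subset realization", {
  run <- dd_reconstruction_run(1)
  ok <- !vapply(run$per_level, function(x) is.null(x$anc), logical(1))
  expect_true(any(ok))
  sizes <- vapply(run$per_level[ok], function(x) length(x$anc$nodes),
                  numeric(1))
  # young, mid, old: group counts decrease into the past
  expect_true(all(diff(sizes[order(match(names(sizes),
                                         c("young", "mid", "old")))]) <= 0))
  for (x in run$per_level[ok]) {
    expect_lte(igraph::ecount(x$anc$realized), nrow(x$anc$edges))
    expect_true(all(x$anc$edges$p_link >= 0 & x$anc$edges$p_link <= 1))
  }
})

test_that("with true parameters ancestral edges are recovered accurately", {
  pr <- reconstruction_pr(dd_reconstruction_run(1))
  expect_gte(pr["precision"], 0.7)
  expect_gte(pr["recall"], 0.7)
})

test_that("network overlap counts shared groups and interactions", {
  mk <- function(edges, level = "L") {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    structure(list(level = level, age = 1,
                   nodes = igraph::V(g)$name, edges = tibble::tibble(),
                   p_c = 0.5, realized = g, calibration = NULL),
              class = "ancestral_network")
  }
  a <- mk(data.frame(from = c("g1", "g2"), to = c("g2", "g3")))
  expect_equal(network_overlap(a, a)$shared_nodes, 3)
  expect_equal(network_overlap(a, a)$shared_edges, 2)

  b <- mk(data.frame(from = "h1", to = "h2"))
  ov <- network_overlap(a, b)
  expect_equal(ov$shared_nodes, 0)
  expect_equal(ov$shared_edges, 0)

  expect_error(network_overlap(a, mk(data.frame(from = "g1", to = "g2"),
                                     level = "M")),
               "level mismatch")
})

test_that("two species grown from one ancestor share the surviving core", {
  # split one simulated history into two descendant "species" and check
  # overlap of their perfectly reconstructed ancestral networks
  seedg <- make_reference_graph("er", n = 15, p = 0.3, rng_seed = 20)
  mk_species <- function(s) {
    sim <- simulate_dd_evolution(seedg, 0.8, 0.001, 60,
                                 snapshot_epochs = c(0), rng_seed = s)
    g0 <- sim$lineage$graphs[["0"]]
    structure(list(level = "root", age = 3,
                   nodes = igraph::V(g0)$name, edges = tibble::tibble(),
                   p_c = 0.5, realized = g0, calibration = NULL),
              class = "ancestral_network")
  }
  ov <- network_overlap(mk_species(1), mk_species(2))
  # both species descend from the same seed: the shared core is the seed
  expect_equal(ov$shared_nodes, 15)
  expect_equal(ov$shared_edges, igraph::ecount(seedg))
})
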