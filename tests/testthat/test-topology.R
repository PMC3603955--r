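test_that("fractal dimension matches analytic oracles", {
  # (2,2)-flower: d_B = ln(u+v)/ln(u) = 2 exactly in the scaling limit
  fl <- make_reference_graph("flower", u = 2, v = 2, generations = 4)
  fd <- fractal_dimension(fl, c(3, 5, 7, 9, 11))
  expect_lt(abs(fd$exponent - 2), 2 * fd$stderr)

  # 2-D lattice: d_B ~ 2 within 15%
  lat <- make_reference_graph("lattice", nrow = 30, ncol = 30)
  fd2 <- fractal_dimension(lat, c(3, 5, 7, 9, 11))
  expect_lt(abs(fd2$exponent - 2) / 2, 0.15)

  # star: diameter 2, no usable scales
  star <- igraph::make_star(20, mode = "undirected")
  igraph::V(star)$name <- sprintf("s%02d", 1:20)
  expect_error(fractal_dimension(star, c(3, 5, 7)), "diameter")
})

test_that("scaling fits expose tidy/glance interfaces", {
  fl <- make_reference_graph("flower", u = 2, v = 2, generations = 3)
  fd <- fractal_dimension(fl, c(3, 5, 7))
  td <- tidy(fd)
  expect_equal(td$term, "d_B")
  expect_true(td$std.error >= 0)
  gl <- glance(fd)
  expect_equal(gl$n_points, 3)
  expect_s3_class(autoplot(fd), "ggplot")
})

test_that("renormalization flow separates fractal from small-world phases", {
  fl <- make_reference_graph("flower", u = 2, v = 2, generations = 4)
  fw <- renormalization_flow(graph_as_table(fl), 500, ell_B = 3)
  expect_equal(fw$phase, "fractal")
  expect_lt(fw$slope, 0)

  rs <- make_reference_graph("ring_shortcut", n = 400,
                             shortcut_fraction = 0.2, rng_seed = 1)
  rw <- renormalization_flow(graph_as_table(rs), 500, ell_B = 3)
  expect_equal(rw$phase, "small-world")
  expect_gt(rw$slope, 0)

  # identity scale: no coarse-graining, slope 0 by construction
  iw <- renormalization_flow(graph_as_table(fl), 500, ell_B = 1)
  expect_equal(iw$slope, 0)
  expect_equal(iw$phase, "transition")
})

test_that("degree-distribution model selection recovers planted laws", {
  # geometric degrees, scale kbar = 5
  k_exp <- withr::with_seed(5, rgeom(5000, prob = 1 - exp(-1 / 5)) + 1)
  fe <- fit_degree_distribution(k_exp)
  expect_equal(fe$model, "exponential")
  expect_lt(abs(fe$exponent - 5) / 5, 0.05)

  # discrete power law gamma = 2.5, k0 = 0
  k_pl <- withr::with_seed(6, {
    probs <- (1:10000)^(-2.5)
    sample(1:10000, 5000, replace = TRUE, prob = probs / sum(probs))
  })
  fp <- fit_degree_distribution(k_pl)
  expect_equal(fp$model, "powerlaw")
  expect_lt(abs(fp$exponent - 2.5), 0.2)

  # regular graph: no distribution to fit
  reg <- igraph::sample_k_regular(200, 4)
  expect_error(fit_degree_distribution(reg), "variance")
  expect_error(fit_degree_distribution(rep(c(2, 3), 20)), ">= 100")
})

test_that("hub-degree scaling closes the renormalization relation on flowers", {
  fl <- make_reference_graph("flower", u = 2, v = 2, generations = 4)
  covers <- lapply(c(3, 5, 7, 9, 11), function(l) memb_cover(fl, l))
  hs <- hub_degree_scaling(fl, covers)
  expect_gt(hs$exponent, 0)

  # directly fitted gamma vs 1 + d_B/d_k. The flower's degrees live on
  # powers of two, so the distribution oracle is the complementary CDF
  # regression at the support points (analytic gamma = 3).
  k <- igraph::degree(fl)
  supp <- sort(unique(k))
  ccdf <- vapply(supp, function(x) mean(k >= x), numeric(1))
  cc <- stats::lm(log(ccdf) ~ log(supp))
  gamma_fit <- 1 - unname(stats::coef(cc)[2])
  gamma_se <- summary(cc)$coefficients[2, 2]
  joint <- sqrt(gamma_se^2 + hs$extra$gamma_pred_se^2)
  expect_lt(abs(gamma_fit - hs$extra$gamma_pred), 2 * joint)

  # identity scale: supernode degree equals hub degree, s = 1
  c1 <- memb_cover(fl, 1)
  hs1 <- hub_degree_scaling(fl, list(c1, memb_cover(fl, 3),
                                     memb_cover(fl, 5)))
  expect_equal(hs1$points$s[hs1$points$ell_B == 1], 1)

  expect_error(hub_degree_scaling(fl, covers[1:2]), ">= 3")
})

test_that("modularity ratio counts intra/inter links per box", {
  tg <- igraph::make_graph(~ a-b, b-c, c-a, d-e, e-f, f-d, a-d)
  cv <- structure(
    list(ell_B = 3L, n_boxes = 2L,
         assignment = stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                                      letters[1:6]),
         centers = c("a", "d")),
    class = "box_covering"
  )
  expect_equal(as.numeric(modularity_ratio(tg, cv)), 3.0)

  # complete bipartition with no intra edges
  bi <- igraph::make_full_bipartite_graph(3, 3)
  igraph::V(bi)$name <- letters[1:6]
  cvb <- structure(
    list(ell_B = 3L, n_boxes = 2L,
         assignment = stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                                      letters[1:6]),
         centers = c("a", "d")),
    class = "box_covering"
  )
  expect_equal(as.numeric(modularity_ratio(bi, cvb)), 0)

  expect_error(modularity_ratio(tg, memb_cover(tg, 99)), ">= 2")
})

test_that("modularity ratio matches a brute-force recount on a generated graph", {
  g <- largest_component(withr::with_seed(3, igraph::sample_gnp(50, 0.08)))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
  cv <- memb_cover(g, 3)
  m <- as.numeric(modularity_ratio(g, cv))
  # independent recount straight from the edge list
  el <- igraph::as_edgelist(g, names = TRUE)
  box <- cv$assignment
  ratios <- c()
  for (b in seq_len(cv$n_boxes)) {
    members <- names(box)[box == b]
    l_in <- sum(el[, 1] %in% members & el[, 2] %in% members)
    l_out <- sum(xor(el[, 1] %in% members, el[, 2] %in% members))
    if (l_out > 0) ratios <- c(ratios, l_in / l_out)
  }
  expect_equal(m, mean(ratios))
})

test_that("modularity exponent: lattice-like scaling and randomization contrast", {
  ring <- igraph::make_ring(200)
  igraph::V(ring)$name <- sprintf("r%03d", 1:200)
  dm <- modularity_exponent(ring, c(3, 5, 7, 9, 11, 13))
  expect_lt(abs(dm$exponent - 1), 0.3)

  # a modular graph loses modularity under degree-preserving rewiring
  blocks <- lapply(0:4, function(b) {
    el <- utils::combn(10, 2)
    cbind(el[1, ] + b * 10, el[2, ] + b * 10)
  })
  bridges <- cbind(seq(1, 41, by = 10), seq(11, 51, by = 10) %% 50 + 1)
  g <- igraph::graph_from_edgelist(rbind(do.call(rbind, blocks), bridges),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("m%02d", 1:50)
  g <- largest_component(g)
  rew <- withr::with_seed(8, igraph::rewire(
    g, igraph::keeping_degseq(niter = 500)
  ))
  rew <- largest_component(rew)
  m_orig <- as.numeric(modularity_ratio(g, memb_cover(g, 3)))
  m_rew <- as.numeric(modularity_ratio(rew, memb_cover(rew, 3)))
  expect_lt(m_rew, m_orig)

  expect_error(modularity_exponent(ring, c(3, 5)), ">= 3")
})
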