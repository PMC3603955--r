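test_that("a geometric node series yields r_N = ln 2 exactly", {
  ls <- level_series(
    tibble::tibble(level = c("present", "t1", "t2"), age = c(0, 1, 2),
                   n_nodes = c(400, 200, 100))
  )
  gr <- suppressWarnings(fit_growth_rates(ls))
  r_n <- gr$rates$estimate[gr$rates$rate == "r_N"]
  expect_equal(r_n, log(2), tolerance = 1e-12)
})

test_that("planted multiplicative rates are recovered within two standard errors", {
  r_N_true <- 0.5
  r_L_true <- 0.15
  for (s in 1:5) {
    dat <- withr::with_seed(s, {
      ages <- c(1, 2, 3)
      pairs <- do.call(rbind, lapply(ages, function(a) {
        L_anc <- runif(120, 2, 8)
        data.frame(level = paste0("t", a), age = a, L_anc = L_anc,
                   L_pres = exp(r_L_true * a) * L_anc *
                     exp(rnorm(120, 0, 0.08)))
      }))
      levels <- data.frame(
        level = c("present", paste0("t", ages)), age = c(0, ages),
        n_nodes = round(800 * exp(-r_N_true * c(0, ages)) *
                          exp(rnorm(4, 0, 0.03)))
      )
      list(levels = levels, pairs = pairs)
    })
    gr <- fit_growth_rates(level_series(dat$levels, dat$pairs))
    est <- stats::setNames(gr$rates$estimate, gr$rates$rate)
    se <- stats::setNames(gr$rates$stderr, gr$rates$rate)
    expect_lt(abs(est["r_N"] - r_N_true), 2 * se["r_N"] + 0.05)
    expect_lt(abs(est["r_L"] - r_L_true), 2 * se["r_L"] + 0.02)
  }
})

test_that("pure duplication gives zero distance growth end to end", {
  seedg <- make_reference_graph("er", n = 20, p = 0.3, rng_seed = 2001)
  sim <- simulate_dd_evolution(seedg, 1, 0, 180,
                               snapshot_epochs = c(5, 30, 80), rng_seed = 1)
  present <- largest_component(sim$present)
  om <- lineage_to_orthology(sim$lineage, c("t3", "t2", "t1"),
                             ages = c(3, 2, 1))
  clusters <- lapply(stats::setNames(om$levels, om$levels), function(lv)
    project_to_level(present, om, lv))
  truth <- stats::setNames(sim$lineage$graphs[c("80", "30", "5")],
                           c("t1", "t2", "t3"))
  ls <- measure_level_series(present, truth, clusters,
                             ages = c(t1 = 1, t2 = 2, t3 = 3), rng_seed = 1)
  gr <- suppressWarnings(fit_growth_rates(ls))
  est <- stats::setNames(gr$rates$estimate, gr$rates$rate)
  expect_equal(unname(est["r_N"]), log(2), tolerance = 1e-9)
  expect_equal(unname(est["r_L"]), 0, tolerance = 1e-9)
  # generator bookkeeping: recovered N(t) equals the record exactly
  expect_equal(sort(ls$levels$n_nodes), sort(c(200, 25, 50, 100)))
})

test_that("tied hubs average distances over all maximum-degree members", {
  # group gA has two tied hubs a1, a2 at distances 1 and 3 from gB's hub b1
  g <- igraph::make_graph(~ a1-b1, a1-a3, a2-a4, a4-x, x-b1, b1-b2)
  cl <- list(gA = c("a1", "a2", "a3", "a4"), gB = c("b1", "b2"))
  anc <- igraph::make_graph(~ gA-gB)
  ls <- measure_level_series(g, list(old = anc), list(old = cl),
                             ages = c(old = 1))
  deg <- igraph::degree(g)
  # brute-force: hubs of gA are the max-degree members; average their
  # distances to gB's hub
  hub_deg <- max(deg[cl$gA])
  hubs_a <- cl$gA[deg[cl$gA] == hub_deg]
  hub_b <- cl$gB[which.max(deg[cl$gB])]
  d <- igraph::distances(g, v = hubs_a, to = hub_b, weights = NA)
  expect_equal(ls$pairs$L_pres, mean(d))
})

test_that("disconnected group pairs are skipped and counted", {
  g <- igraph::make_graph(~ a1-a2, b1-b2, c1-a1)
  cl <- list(gA = c("a1", "a2"), gB = c("b1", "b2"), gC = "c1")
  anc <- igraph::make_graph(~ gA-gC, gB-gB2)
  ls <- measure_level_series(g, list(old = anc), list(old = cl),
                             ages = c(old = 1))
  expect_gt(ls$skipped_pairs, 0)
})

test_that("consistency report compares static exponents with rate ratios", {
  gr <- structure(
    list(
      rates = tibble::tibble(
        rate = c("r_N", "r_L", "r_K", "r_M"),
        estimate = c(0.2, 0.1, 0.05, 0.08),
        stderr = c(0.01, 0.01, 0.01, 0.02),
        n_levels = 4L
      ),
      slopes = tibble::tibble(),
      predictions = tibble::tibble(
        quantity = c("d_B_pred", "gamma_pred", "d_k_pred"),
        estimate = c(2.0, 5.0, 0.5),
        stderr = c(0.3, 1.2, 0.1)
      ),
      two_levels_only = FALSE
    ), class = "growth_rates"
  )
  static <- list(d_B = paleoppin:::new_scaling_fit(
    2.1, 0.2, tibble::tibble(x = 1:3, y = 1:3), "powerlaw", "d_B"
  ))
  rep <- consistency_report(gr, static)
  expect_equal(rep$dynamic[1], 2.0)
  expect_true(rep$pass[1])

  # r_K compatible with zero: exponential degree class, gamma -> Inf
  gr$rates$estimate[3] <- 0.005
  gr$rates$stderr[3] <- 0.02
  deg_fit <- paleoppin:::new_scaling_fit(
    4.2, 0.5, tibble::tibble(x = 1:3, y = 1:3), "exponential", "kbar"
  )
  rep2 <- consistency_report(gr, list(degree = deg_fit))
  expect_true(grepl("exponential", rep2$note[1]))
  expect_true(rep2$pass[1])
})

test_that("distance regression through the origin matches the free fit", {
  # on rate-planted data the unconstrained intercept is ~0, so both slopes agree
  dat <- withr::with_seed(42, {
    L_anc <- runif(200, 2, 8)
    data.frame(L_anc = L_anc,
               L_pres = 1.3 * L_anc * exp(rnorm(200, 0, 0.05)))
  })
  through <- paleoppin:::origin_slope(dat$L_anc, dat$L_pres)
  free <- stats::lm(L_pres ~ L_anc, data = dat)
  expect_lt(abs(through$slope - stats::coef(free)[2]),
            2 * summary(free)$coefficients[2, 2])
})

test_that("degree distributions collapse under the fitted degree rate", {
  # density conservation in the regime that satisfies its premise exactly:
  # pure duplication, where degrees scale with the cluster sizes
  ks <- vapply(1:5, function(s) {
    seedg <- make_reference_graph("er", n = 50, p = 0.12, rng_seed = 2000 + s)
    sim <- simulate_dd_evolution(seedg, 1, 0, 350,
                                 snapshot_epochs = c(150), rng_seed = s)
    present <- largest_component(sim$present)
    k_anc <- igraph::degree(sim$lineage$graphs[["150"]])
    k_pres <- igraph::degree(present)
    r_K <- log(mean(k_pres) / mean(k_anc))
    suppressWarnings(
      stats::ks.test(k_anc * exp(r_K), k_pres)$statistic
    )
  }, numeric(1))
  expect_lte(median(ks), 0.15)
})
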