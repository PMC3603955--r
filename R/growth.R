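#' Measure node counts, distances, degrees and modularity across a series
#'
#' For every ancestral level, records the realized node count `N(t)` and the
#' modularity ratio `M(t)`, and pairs each sampled ancestral group pair's
#' shortest-path distance with the present-day distance between the groups'
#' hub proteins (hub = maximum-degree member; when several members tie, the
#' distance is averaged over all tied hubs). Group degrees in the ancestral
#' network are likewise paired with present-day hub degrees. The present
#' network itself enters as the age-0 level.
#'
#' @param present An igraph of present-day proteins (connected).
#' @param series Named list (by level) of calibrated `ancestral_network`s,
#'   or of plain igraphs (e.g. generator ground truth).
#' @param clusters Named list (by level) of [project_to_level()] partitions.
#' @param ages Named numeric vector of ages (Gyr) per level; taken from the
#'   `ancestral_network`s when omitted.
#' @param ell_B Box diameter for the modularity measurements.
#' @param max_pairs Use all ancestral group pairs up to this count, then a
#'   seeded uniform sample.
#' @param rng_seed Seed for pair sampling.
#' @return An object of class `level_series`: list of tibbles `levels`
#'   (`level`, `age`, `n_nodes`, `n_edges`, `modularity`), `pairs`
#'   (`level`, `age`, `L_anc`, `L_pres`), `degrees` (`level`, `age`,
#'   `group`, `K_anc`, `K_pres`), plus `skipped_pairs` counts.
#' @export
measure_level_series <- function(present, series, clusters, ages = NULL,
                                 ell_B = 3, max_pairs = 1e5, rng_seed = 1L) {
  if (length(series) == 0) abort("empty level series")
  lv_names <- names(series)
  if (is.null(lv_names)) abort("series must be named by level")
  graphs <- purrr::map(series, function(s) {
    if (inherits(s, "ancestral_network")) {
      if (is.null(s$realized)) abort("ancestral networks must be calibrated")
      s$realized
    } else s
  })
  if (is.null(ages)) {
    ages <- purrr::map_dbl(series, function(s) {
      if (inherits(s, "ancestral_network")) s$age else NA_real_
    })
    names(ages) <- lv_names
  }
  if (anyNA(ages[lv_names])) abort("ages must be known for every level")

  deg_present <- igraph::degree(present)
  pres_nm <- igraph::V(present)$name
  level_rows <- list()
  pair_rows <- list()
  degree_rows <- list()
  skipped <- 0L

  mod_of <- function(g) {
    lcc <- largest_component(g)
    if (igraph::vcount(lcc) < 2 * ell_B) return(NA_real_)
    cv <- memb_cover(lcc, ell_B)
    if (cv$n_boxes < 2) return(NA_real_)
    tryCatch(as.numeric(modularity_ratio(lcc, cv)),
             error = function(e) NA_real_)
  }

  # present-day row (age 0): distances/degrees compare to themselves
  level_rows[["present"]] <- tibble::tibble(
    level = "present", age = 0,
    n_nodes = igraph::vcount(present), n_edges = igraph::ecount(present),
    modularity = mod_of(present)
  )

  for (lv in lv_names) {
    g <- graphs[[lv]]
    age <- unname(ages[[lv]])
    cl <- clusters[[lv]]
    if (is.null(cl)) abort(sprintf("no clusters for level '%s'", lv))
    level_rows[[lv]] <- tibble::tibble(
      level = lv, age = age,
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
      modularity = mod_of(g)
    )
    # hubs per group (members restricted to the present graph)
    hubs <- purrr::map(cl, function(members) {
      members <- intersect(members, pres_nm)
      if (length(members) == 0) return(character(0))
      d <- deg_present[members]
      members[d == max(d)]
    })
    groups <- intersect(igraph::V(g)$name, names(cl))
    g_deg <- igraph::degree(g)
    for (gp in groups) {
      h <- hubs[[gp]]
      if (length(h) == 0) next
      degree_rows[[length(degree_rows) + 1]] <- tibble::tibble(
        level = lv, age = age, group = gp,
        K_anc = unname(g_deg[gp]), K_pres = unname(max(deg_present[h]))
      )
    }
    # group-pair distances
    if (length(groups) >= 2) {
      idx <- utils::combn(length(groups), 2)
      n_pairs <- ncol(idx)
      if (n_pairs > max_pairs) {
        sel <- withr::with_seed(rng_seed, sample.int(n_pairs, max_pairs))
        idx <- idx[, sel, drop = FALSE]
      }
      D_anc <- igraph::distances(g, v = groups, to = groups, weights = NA)
      all_hubs <- unique(unlist(hubs[groups]))
      D_pres <- igraph::distances(present, v = all_hubs, to = all_hubs,
                                  weights = NA)
      for (k in seq_len(ncol(idx))) {
        ga <- groups[idx[1, k]]; gb <- groups[idx[2, k]]
        la <- D_anc[ga, gb]
        ha <- hubs[[ga]]; hb <- hubs[[gb]]
        if (!is.finite(la) || length(ha) == 0 || length(hb) == 0) {
          skipped <- skipped + 1L
          next
        }
        lp <- mean(D_pres[ha, hb, drop = FALSE])
        if (!is.finite(lp)) {
          skipped <- skipped + 1L
          next
        }
        pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
          level = lv, age = age, group_a = ga, group_b = gb,
          L_anc = la, L_pres = lp
        )
      }
    }
  }
  structure(
    list(
      levels = dplyr::bind_rows(level_rows),
      pairs = dplyr::bind_rows(pair_rows),
      degrees = dplyr::bind_rows(degree_rows),
      skipped_pairs = skipped
    ),
    class = "level_series"
  )
}

#' Construct a level series from tables
#'
#' Programmatic constructor for the container produced by
#' [measure_level_series()] — useful for feeding externally measured (or
#' synthetic, rate-planted) series into [fit_growth_rates()].
#'
#' @param levels Tibble with `level`, `age`, `n_nodes` and optionally
#'   `n_edges`, `modularity`.
#' @param pairs Tibble with `level`, `age`, `L_anc`, `L_pres` (optional).
#' @param degrees Tibble with `level`, `age`, `K_anc`, `K_pres` (optional).
#' @return A `level_series` object.
#' @export
level_series <- function(levels, pairs = NULL, degrees = NULL) {
  need <- c("level", "age", "n_nodes")
  if (!all(need %in% names(levels))) {
    abort("levels needs columns level, age, n_nodes")
  }
  levels <- tibble::as_tibble(levels)
  if (!"modularity" %in% names(levels)) levels$modularity <- NA_real_
  if (!"n_edges" %in% names(levels)) levels$n_edges <- NA_integer_
  empty_pairs <- tibble::tibble(level = character(0), age = numeric(0),
                                L_anc = numeric(0), L_pres = numeric(0))
  empty_deg <- tibble::tibble(level = character(0), age = numeric(0),
                              group = character(0),
                              K_anc = numeric(0), K_pres = numeric(0))
  structure(
    list(
      levels = levels,
      pairs = if (is.null(pairs)) empty_pairs else tibble::as_tibble(pairs),
      degrees = if (is.null(degrees)) empty_deg else tibble::as_tibble(degrees),
      skipped_pairs = 0L
    ),
    class = "level_series"
  )
}

#' @export
print.level_series <- function(x, ...) {
  cat(sprintf("<level_series> %d levels, %d distance pairs, %d group degrees\n",
              nrow(x$levels), nrow(x$pairs), nrow(x$degrees)))
  print(x$levels)
  invisible(x)
}

# regression through the origin: slope, stderr
origin_slope <- function(x, y) {
  sxx <- sum(x^2)
  slope <- sum(x * y) / sxx
  n <- length(x)
  se <- if (n > 1) sqrt(sum((y - slope * x)^2) / (n - 1) / sxx) else NA_real_
  list(slope = slope, stderr = se, n = n)
}

#' Fit multiplicative growth rates
#'
#' Under multiplicative growth every quantity evolves exponentially with
#' forward time: `N(t) ~ e^(r_N t)`, per-level distance slopes
#' `b(t) = e^(r_L dt)` (from regressing present on ancestral distances
#' through the origin), degree slopes `a(t) = e^(r_K dt)` likewise, and
#' modularity `M(t) ~ e^(r_M t)`. Ages increase into the past; all rates are
#' reported per Gyr forward in time, so growth is positive.
#'
#' @param ls A [measure_level_series()] result.
#' @return An object of class `growth_rates`: tibble `rates` (`rate`,
#'   `estimate`, `stderr`, `n_levels`), per-level diagnostics `slopes`
#'   (`level`, `age`, `b`, `a`), and derived predictions in `$predictions`
#'   (`d_B_pred = r_N/r_L`, `gamma_pred = 1 + r_N/r_K`,
#'   `d_k_pred = r_K/r_L`).
#' @export
fit_growth_rates <- function(ls) {
  lv <- ls$levels[!is.na(ls$levels$age), ]
  if (nrow(lv) < 2) abort("need >= 2 levels to fit growth rates")
  two_only <- nrow(lv) == 2
  if (two_only) {
    warn("only two time levels: rates have no uncertainty estimate")
  }
  # r_N: ln N versus forward time (-age)
  fN <- ls_slope(-lv$age, log(lv$n_nodes))
  # per-level distance and degree slopes (ancestral levels only)
  anc_levels <- lv$level[lv$age > 0]
  slopes <- purrr::map(anc_levels, function(l) {
    p <- ls$pairs[ls$pairs$level == l, ]
    d <- ls$degrees[ls$degrees$level == l, ]
    tibble::tibble(
      level = l, age = lv$age[lv$level == l],
      b = if (nrow(p) >= 2) origin_slope(p$L_anc, p$L_pres)$slope else NA_real_,
      a = if (nrow(d) >= 2) origin_slope(d$K_anc, d$K_pres)$slope else NA_real_
    )
  }) |> dplyr::bind_rows()
  # rates from ln(slope) ~ 0 + age (the age-0 point is exactly 0 by definition)
  rate_from_slopes <- function(vals) {
    ok <- !is.na(vals$s) & vals$s > 0
    if (sum(ok) < 1) return(list(slope = NA_real_, stderr = NA_real_, n = 0))
    origin_slope(vals$age[ok], log(vals$s[ok]))
  }
  fL <- rate_from_slopes(tibble::tibble(age = slopes$age, s = slopes$b))
  fK <- rate_from_slopes(tibble::tibble(age = slopes$age, s = slopes$a))
  # r_M: ln M versus forward time
  mv <- lv[!is.na(lv$modularity) & lv$modularity > 0, ]
  fM <- if (nrow(mv) >= 2) {
    ls_slope(-mv$age, log(mv$modularity))
  } else list(slope = NA_real_, stderr = NA_real_)
  rates <- tibble::tibble(
    rate = c("r_N", "r_L", "r_K", "r_M"),
    estimate = c(fN$slope, fL$slope, fK$slope, fM$slope),
    stderr = c(if (two_only) NA_real_ else fN$stderr, fL$stderr,
               fK$stderr, if (two_only) NA_real_ else fM$stderr),
    n_levels = c(nrow(lv), fL$n, fK$n, nrow(mv))
  )
  est <- setNames(rates$estimate, rates$rate)
  se <- setNames(rates$stderr, rates$rate)
  ratio_se <- function(r, num, den) {
    abs(r) * sqrt((se[num] / est[num])^2 + (se[den] / est[den])^2)
  }
  predictions <- tibble::tibble(
    quantity = c("d_B_pred", "gamma_pred", "d_k_pred"),
    estimate = c(
      est["r_N"] / est["r_L"],
      if (!is.na(est["r_K"]) && est["r_K"] != 0) 1 + est["r_N"] / est["r_K"] else Inf,
      est["r_K"] / est["r_L"]
    ),
    stderr = c(
      unname(ratio_se(est["r_N"] / est["r_L"], "r_N", "r_L")),
      if (!is.na(est["r_K"]) && est["r_K"] != 0) {
        unname(ratio_se(est["r_N"] / est["r_K"], "r_N", "r_K"))
      } else NA_real_,
      unname(ratio_se(est["r_K"] / est["r_L"], "r_K", "r_L"))
    )
  )
  structure(
    list(rates = rates, slopes = slopes, predictions = predictions,
         two_levels_only = two_only),
    class = "growth_rates"
  )
}

#' @export
print.growth_rates <- function(x, ...) {
  cat("<growth_rates> per-Gyr multiplicative rates\n")
  print(x$rates)
  invisible(x)
}

#' @rdname fit_growth_rates
#' @param x A `growth_rates` object.
#' @param ... Unused.
#' @export
tidy.growth_rates <- function(x, ...) {
  dplyr::rename(x$rates, term = "rate")
}

#' @rdname fit_growth_rates
#' @export
glance.growth_rates <- function(x, ...) {
  est <- setNames(x$rates$estimate, x$rates$rate)
  tibble::tibble(
    r_N = est["r_N"], r_L = est["r_L"], r_K = est["r_K"], r_M = est["r_M"],
    d_B_pred = x$predictions$estimate[1],
    gamma_pred = x$predictions$estimate[2],
    d_k_pred = x$predictions$estimate[3]
  )
}

#' @rdname fit_growth_rates
#' @param object A `growth_rates` object.
#' @export
autoplot.growth_rates <- function(object, ...) {
  df <- tidyr::pivot_longer(object$slopes, c("b", "a"),
                            names_to = "slope_of", values_to = "value")
  df$slope_of <- dplyr::recode(df$slope_of, b = "distance slope b(t)",
                               a = "degree slope a(t)")
  ggplot2::ggplot(df, ggplot2::aes(.data$age, log(.data$value))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ 0 + x, se = FALSE) +
    ggplot2::facet_wrap(~slope_of, scales = "free_y") +
    ggplot2::labs(x = "age (Gyr)", y = "log slope")
}

#' Static-dynamic consistency report
#'
#' Tabulates the multiplicative-growth predictions against the static
#' exponents: `d_B` versus `r_N / r_L`, `gamma` versus `1 + r_N / r_K`,
#' `d_k` versus `r_K / r_L`, and `r_M` versus `d_M * r_L`. Agreement is
#' assessed at two joint standard errors. When `r_K` is compatible with 0,
#' degrees are invariant over time, `gamma_pred` diverges, and the network
#' is reported as belonging to the exponential degree class.
#'
#' @param gr A [fit_growth_rates()] result.
#' @param static Named list of static fits: `d_B` and optionally `d_k`,
#'   `d_M` (`scaling_fit`s) and `degree` (from [fit_degree_distribution()]).
#' @return A tibble: `quantity`, `static`, `static_se`, `dynamic`,
#'   `dynamic_se`, `z`, `pass`, `note`.
#' @export
consistency_report <- function(gr, static) {
  est <- setNames(gr$rates$estimate, gr$rates$rate)
  se <- setNames(gr$rates$stderr, gr$rates$rate)
  pred <- gr$predictions
  rows <- list()
  cmp <- function(quantity, s_val, s_se, d_val, d_se, note = NA_character_) {
    joint <- sqrt(ifelse(is.na(s_se), 0, s_se)^2 +
                    ifelse(is.na(d_se), 0, d_se)^2)
    z <- if (is.na(s_val) || is.na(d_val) || !is.finite(d_val) || joint == 0) {
      NA_real_
    } else (d_val - s_val) / joint
    tibble::tibble(
      quantity = quantity, static = s_val, static_se = s_se,
      dynamic = d_val, dynamic_se = d_se, z = z,
      pass = !is.na(z) & abs(z) <= 2, note = note
    )
  }
  if (!is.null(static$d_B)) {
    rows$d_B <- cmp("d_B vs r_N/r_L", static$d_B$exponent, static$d_B$stderr,
                    pred$estimate[1], pred$stderr[1])
  }
  k_invariant <- !is.na(est["r_K"]) && !is.na(se["r_K"]) &&
    abs(est["r_K"]) <= se["r_K"]
  if (!is.null(static$degree)) {
    if (k_invariant || !is.finite(pred$estimate[2])) {
      s_val <- if (static$degree$model == "powerlaw") {
        static$degree$exponent
      } else Inf
      is_exp <- static$degree$model == "exponential"
      rows$gamma <- tibble::tibble(
        quantity = "gamma vs 1 + r_N/r_K",
        static = s_val,
        static_se = NA_real_, dynamic = Inf, dynamic_se = NA_real_,
        z = NA_real_,
        pass = is_exp,
        note = "r_K ~ 0: degrees invariant, exponential degree class, gamma -> Inf"
      )
    } else if (static$degree$model == "powerlaw") {
      rows$gamma <- cmp("gamma vs 1 + r_N/r_K", static$degree$exponent,
                        static$degree$stderr, pred$estimate[2], pred$stderr[2])
    }
  }
  if (!is.null(static$d_k)) {
    rows$d_k <- cmp("d_k vs r_K/r_L", static$d_k$exponent, static$d_k$stderr,
                    pred$estimate[3], pred$stderr[3])
  }
  if (!is.null(static$d_M) && !is.na(est["r_M"])) {
    rm_pred <- static$d_M$exponent * est["r_L"]
    rm_se <- abs(rm_pred) * sqrt(
      (static$d_M$stderr / static$d_M$exponent)^2 +
        (se["r_L"] / est["r_L"])^2
    )
    rows$r_M <- cmp("r_M vs d_M * r_L", unname(rm_pred), unname(rm_se),
                    unname(est["r_M"]), unname(se["r_M"]))
  }
  dplyr::bind_rows(rows)
}
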