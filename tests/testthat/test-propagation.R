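w0 <- observation_window(1990, 2010.999)

test_that("delay collection classifies observed, censored and tied drugs", {
  ad <- adoption_table(
    drug_id = c("a", "a", "b", "c", "c", "d", "d"),
    disease_id = c("X", "Y", "X", "X", "Y", "X", "Y"),
    time = c(2000, 2003, 2005, 2001, 2001, 2008, 2006),
    window = w0)
  s <- collect_delays(ad, "X", "Y", w0)
  expect_equal(s$observed, 3)            # drug a only
  expect_equal(s$censored, 2010.999 - 2005)  # drug b; tie (drug c) excluded
  r <- collect_delays(ad, "Y", "X", w0)
  expect_equal(r$observed, 2)            # drug d: Y 2006 -> X 2008
  expect_equal(length(r$censored), 0)    # every Y adopter also adopted X
  # brute-force classification on a synthetic cascade
  cfg <- simulation_config(n_diseases = 4, drugs_per_year = 20,
                           year_span = c(1995, 2005), rng_seed = 17)
  sim <- simulate_cascades(generate_rate_matrix(cfg), cfg)
  adoptions <- sim$adoptions
  ids <- rownames(sim$ground_truth$lambda_true)
  for (i in ids[1:2]) for (j in ids[3:4]) {
    s <- collect_delays(adoptions, i, j, cfg$window)
    obs <- numeric(0); cens <- numeric(0)
    for (d in unique(adoptions$drug_id)) {
      ti <- adoptions$time[adoptions$drug_id == d & adoptions$disease_id == i]
      tj <- adoptions$time[adoptions$drug_id == d & adoptions$disease_id == j]
      if (length(ti) == 1 && length(tj) == 1 && tj > ti) obs <- c(obs, tj - ti)
      if (length(ti) == 1 && length(tj) == 0) {
        cens <- c(cens, cfg$window$t_max - ti)
      }
    }
    expect_equal(s$observed, sort(obs))
    expect_equal(s$censored, sort(cens))
  }
})

test_that("the closed-form censored-exponential MLE matches numerical maximization", {
  one <- pairwise_mle(list(observed = 2, censored = numeric(0)))
  expect_equal(one$lambda_hat, 0.5)
  expect_equal(one$T_hat, 2)

  mixed <- pairwise_mle(list(observed = c(1, 3), censored = 6))
  expect_equal(mixed$lambda_hat, 0.2)
  expect_equal(mixed$T_hat, 5)
  expect_equal(mixed$lambda_hat, numeric_censored_mle(c(1, 3), 6),
               tolerance = 1e-6)

  none <- pairwise_mle(list(observed = numeric(0), censored = c(4, 7)))
  expect_equal(none$lambda_hat, 0)
  expect_equal(none$T_hat, Inf)

  set.seed(151)
  for (trial in 1:25) {
    obs <- stats::rexp(sample(1:20, 1), rate = 0.3)
    cens <- stats::runif(sample(0:20, 1), 0, 15)
    est <- pairwise_mle(list(observed = obs, censored = cens))
    expect_equal(est$lambda_hat, numeric_censored_mle(obs, cens),
                 tolerance = 1e-6)
    # attained log-likelihood is the maximum on a surrounding grid
    grid <- est$lambda_hat * seq(0.5, 1.5, by = 0.05)
    ll <- vapply(grid, function(l)
      length(obs) * log(l) - l * (sum(obs) + sum(cens)), numeric(1L))
    expect_gte(est$log_likelihood + 1e-9, max(ll))
    # adding a censored observation never increases the estimate
    more <- pairwise_mle(list(observed = obs, censored = c(cens, 5)))
    expect_lte(more$lambda_hat, est$lambda_hat)
  }
})

test_that("multi-source estimation reduces to the pairwise closed form", {
  # single source, observed delays {2, 2}
  ad <- adoption_table(
    drug_id = rep(c("a", "b"), each = 2),
    disease_id = rep(c("X", "Y"), 2),
    time = c(2000, 2002, 2004, 2006), window = w0)
  est <- network_mle_for_target(ad, "Y", w0)
  expect_equal(est$lambda_hat[est$source == "X"], 0.5, tolerance = 1e-6)

  # every drug reaching the target has a unique prior adopter
  ad2 <- adoption_table(
    drug_id = c("a", "a", "b", "b", "c", "c", "d"),
    disease_id = c("X", "T", "X", "T", "Z", "T", "Z"),
    time = c(2000, 2001.5, 2002, 2003, 2004, 2009, 2005), window = w0)
  full <- network_mle_for_target(ad2, "T", w0, model = "hazard")
  fact <- network_mle_for_target(ad2, "T", w0, model = "factorized")
  for (src in full$source) {
    pw <- pairwise_mle(collect_delays(ad2, src, "T", w0))
    expect_equal(full$lambda_hat[full$source == src], pw$lambda_hat,
                 tolerance = 1e-5)
    expect_equal(fact$lambda_hat[fact$source == src], pw$lambda_hat,
                 tolerance = 1e-12)
  }
})

test_that("multi-source rates are recovered on simulated cascades", {
  cfg <- simulation_config(n_diseases = 3, edge_density = 1,
                           lambda_low = 0.1, lambda_high = 0.4,
                           drugs_per_year = 100, year_span = c(1990, 2010),
                           rng_seed = 19)
  sim <- simulate_dataset(cfg)
  tr <- sim$ground_truth$lambda_true
  full <- infer_network(sim$adoptions, cfg$window, model = "full")
  truth <- tr[cbind(full$source, full$target)]
  sel <- full$n_observed >= 100
  expect_gt(sum(sel), 0)
  expect_true(all(abs(full$lambda_hat[sel] - truth[sel]) / truth[sel] < 0.15))
})

test_that("network thresholding keeps delays strictly below the cut", {
  est <- data.frame(
    source = c("A", "A", "B", "C"), target = c("B", "C", "C", "A"),
    lambda_hat = c(1 / 99.9, 1 / 100, 1 / 20, 0),
    T_hat = c(99.9, 100, 20, Inf),
    stringsAsFactors = FALSE)
  g <- build_network(est, t_cut = 100)
  el <- igraph::as_data_frame(g)
  expect_setequal(paste(el$from, el$to), c("A B", "B C"))
  expect_equal(igraph::vcount(g), 3)  # C and the lambda=0 node kept as nodes

  none <- build_network(data.frame(source = "A", target = "B",
                                   lambda_hat = 0, T_hat = Inf), 100)
  expect_equal(igraph::ecount(none), 0)

  set.seed(161)
  rnd <- expand.grid(source = paste0("N", 1:5), target = paste0("N", 1:5),
                     stringsAsFactors = FALSE)
  rnd <- rnd[rnd$source != rnd$target, ]
  rnd$T_hat <- stats::runif(nrow(rnd), 0, 200)
  rnd$lambda_hat <- 1 / rnd$T_hat
  g2 <- build_network(rnd, t_cut = 100)
  expect_equal(igraph::ecount(g2), sum(rnd$T_hat < 100))
  expect_true(all(igraph::E(g2)$T_hat < 100))
})

test_that("shortest-path delays match exhaustive enumeration", {
  chain <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      lambda_hat = c(0.5, 1 / 3), T_hat = c(2, 3),
                      stringsAsFactors = FALSE)
  g <- build_network(chain, t_cut = 100)
  pm <- path_metrics(g)
  d <- igraph::distances(g, mode = "out")
  expect_equal(d["A", "C"], 5)
  expect_equal(pm$out_degree[pm$disease_id == "A"], 1L)
  expect_equal(pm$median_delay_from[pm$disease_id == "A"], Inf)

  set.seed(171)
  for (trial in 1:20) {
    n <- sample(4:6, 1)
    nodes <- paste0("N", 1:n)
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.4, ]
    if (nrow(pairs) == 0) next
    pairs$T_hat <- stats::runif(nrow(pairs), 1, 50)
    pairs$lambda_hat <- 1 / pairs$T_hat
    g <- build_network(pairs, t_cut = 1000)
    pairs$weight <- pairs$T_hat
    used <- sort(unique(c(pairs$source, pairs$target)))
    brute <- brute_shortest_paths(used, pairs)
    dj <- igraph::distances(g, mode = "out")
    dj <- dj[rownames(brute), colnames(brute)]
    expect_equal(dj, brute, tolerance = 1e-9)
  }
})

test_that("directional timing comparison reports counts, bootstrap SDs and p-values", {
  # all delays in one direction equal 4.0 -> mean 4, bootstrap SD 0
  ad <- adoption_table(
    drug_id = rep(paste0("d", 1:5), each = 2),
    disease_id = rep(c("X", "Y"), 5),
    time = as.numeric(rbind(2000:2004, 2004:2008)), window = w0)
  tc <- timing_comparison(ad, "X", "Y", w0, n_boot = 200, rng_seed = 1)
  expect_equal(tc$n_first_i, 5)
  expect_equal(tc$n_first_j, 0)
  expect_equal(tc$mean_delay_ij, 4)
  expect_equal(tc$sd_delay_ij, 0)
  expect_true(is.na(tc$mean_delay_ji))
  expect_false(tc$p_delay_defined)
  expect_true(is.na(tc$p_delay))

  # symmetric rates: near-even split, no significant delay asymmetry
  lam <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
                dimnames = list(c("D01", "D02"), c("D01", "D02")))
  cfg <- simulation_config(lambda_matrix = lam, drugs_per_year = 60,
                           year_span = c(1980, 2005),
                           seed_disease_weights = c(0.5, 0.5), rng_seed = 23)
  sim <- simulate_cascades(lam, cfg)
  tc2 <- timing_comparison(sim$adoptions, "D01", "D02", cfg$window,
                           n_boot = 500, rng_seed = 2)
  n <- tc2$n_first_i + tc2$n_first_j
  expect_gt(n, 300)
  expect_lt(abs(tc2$n_first_i / n - 0.5), 3 * 0.5 / sqrt(n))
  expect_gt(tc2$p_delay, 0.01)
  expect_gt(tc2$sd_delay_ij, 0)
  # bootstrap SD is reproducible under a fixed seed
  tc3 <- timing_comparison(sim$adoptions, "D01", "D02", cfg$window,
                           n_boot = 500, rng_seed = 2)
  expect_identical(tc2$sd_delay_ij, tc3$sd_delay_ij)
})

test_that("exponential channels cross the 19% adoption bound at T = 100", {
  expect_equal(adoption_probability(100, 20), 1 - exp(-0.2), tolerance = 1e-12)
  expect_lt(100 * adoption_probability(100, 20), 19)
  # longer delays mean lower within-horizon probability
  expect_true(all(diff(adoption_probability(c(50, 100, 200, 400), 20)) < 0))
})
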