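#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cascade generator. Drugs are born
#' as a homogeneous Poisson process over `year_span`, seeded in one disease
#' each, and then propagate disease-to-disease with exponential delays
#' governed by a latent per-year rate matrix; per-drug study histories are
#' inhomogeneous Poisson processes whose expected cumulative count at age t
#' is alpha * t^beta. Everything is right-censored at `window$t_max`.
#'
#' @param n_diseases Number of diseases in the latent network.
#' @param edge_density Probability that an ordered disease pair communicates
#'   at all (ignored when `lambda_matrix` is supplied).
#' @param lambda_low,lambda_high Range (per-year rates) from which edge rates
#'   are drawn log-uniformly. Must be positive.
#' @param lambda_matrix Optional explicit rate matrix (zero diagonal; zero =
#'   no edge); overrides the random edge model.
#' @param drugs_per_year Expected number of drug births per year.
#' @param year_span Numeric length-2: first and last birth year.
#' @param seed_disease_weights Probability vector over diseases used to pick
#'   each drug's seeding disease; default uniform.
#' @param alpha_low,alpha_high Per-drug study-scale range, sampled
#'   log-uniformly.
#' @param beta_low,beta_high Per-drug growth-exponent range, sampled
#'   uniformly. `beta_low` must be positive.
#' @param window An [observation_window()]; adoptions and studies after
#'   `window$t_max` are censored (absent).
#' @param rng_seed Integer seed; all stochastic draws flow from it in a
#'   documented order (rate matrix, then cascades, then studies).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_diseases = 10,
                              edge_density = 0.3,
                              lambda_low = 0.05,
                              lambda_high = 0.5,
                              lambda_matrix = NULL,
                              drugs_per_year = 100,
                              year_span = c(1990, 2010),
                              seed_disease_weights = NULL,
                              alpha_low = 0.5,
                              alpha_high = 4,
                              beta_low = 0.7,
                              beta_high = 1.6,
                              window = observation_window(1900, 2010.999),
                              rng_seed = 1L) {
  stopifnot(n_diseases >= 1, length(year_span) == 2L,
            year_span[1] < year_span[2], drugs_per_year > 0)
  if (is.null(lambda_matrix)) {
    if (lambda_low <= 0) stop("lambda_low must be > 0", call. = FALSE)
    stopifnot(lambda_high >= lambda_low,
              edge_density >= 0, edge_density <= 1)
  } else {
    lambda_matrix <- validate_rate_matrix(lambda_matrix)
    n_diseases <- nrow(lambda_matrix)
  }
  if (is.null(seed_disease_weights)) {
    seed_disease_weights <- rep(1 / n_diseases, n_diseases)
  }
  stopifnot(length(seed_disease_weights) == n_diseases,
            all(seed_disease_weights >= 0),
            abs(sum(seed_disease_weights) - 1) < 1e-8)
  if (beta_low <= 0) stop("beta_low must be > 0", call. = FALSE)
  stopifnot(alpha_low >= 0, alpha_high >= alpha_low, beta_high >= beta_low)
  if (alpha_high > 0 && alpha_low <= 0) {
    stop("alpha_low must be > 0 unless alpha_high is 0", call. = FALSE)
  }
  stopifnot(inherits(window, "observation_window"))
  if (year_span[2] > window$t_max) {
    stop("year_span must lie inside the observation window", call. = FALSE)
  }
  structure(list(n_diseases = n_diseases, edge_density = edge_density,
                 lambda_low = lambda_low, lambda_high = lambda_high,
                 lambda_matrix = lambda_matrix,
                 drugs_per_year = drugs_per_year, year_span = year_span,
                 seed_disease_weights = seed_disease_weights,
                 alpha_low = alpha_low, alpha_high = alpha_high,
                 beta_low = beta_low, beta_high = beta_high,
                 window = window, rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

validate_rate_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(is.finite(m)), all(m >= 0))
  if (any(diag(m) != 0)) stop("rate matrix diagonal must be 0", call. = FALSE)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- disease_ids(nrow(m))
  }
  m
}

disease_ids <- function(n) sprintf("D%02d", seq_len(n))

#' Generate a latent disease-to-disease rate matrix
#'
#' Each ordered off-diagonal pair carries an edge with probability
#' `edge_density`; edge rates are drawn log-uniformly from
#' `[lambda_low, lambda_high]`. Reproducible for a fixed `rng_seed`.
#'
#' @param config A [simulation_config()].
#' @return A `n_diseases` x `n_diseases` matrix of per-year rates with zero
#'   diagonal and disease ids as dimnames.
#' @export
generate_rate_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$lambda_matrix)) return(config$lambda_matrix)
  n <- config$n_diseases
  set.seed(config$rng_seed)
  has_edge <- matrix(stats::runif(n * n) < config$edge_density, n, n)
  rates <- if (config$lambda_low == config$lambda_high) {
    matrix(config$lambda_low, n, n)
  } else {
    matrix(exp(stats::runif(n * n, log(config$lambda_low),
                            log(config$lambda_high))), n, n)
  }
  lam <- ifelse(has_edge, rates, 0)
  diag(lam) <- 0
  dimnames(lam) <- list(disease_ids(n), disease_ids(n))
  lam
}

#' Simulate drug-adoption cascades over a disease network
#'
#' Drug births form a homogeneous Poisson process over the configured year
#' span. Each drug starts in a seed disease drawn from
#' `seed_disease_weights`. When a disease i adopts a drug at time t_i, it
#' offers the drug to every disease j not yet holding it with an exponential
#' delay of rate `lambda_true[i, j]`; a disease's adoption time is the
#' earliest arrival over all senders. Arrivals after `window$t_max` are
#' censored: no record is produced. Per-drug study-growth parameters (alpha,
#' beta) are drawn here so that the returned ground truth fully determines
#' [simulate_studies()].
#'
#' @param lambda_true Rate matrix as from [generate_rate_matrix()].
#' @param config A [simulation_config()].
#' @return A list with `adoptions` (an `adoption_table`) and `ground_truth`
#'   (class `ground_truth`: `lambda_true`, per-drug `alpha_true`,
#'   `beta_true`, `seed_assignments`, `birth_times`).
#' @export
simulate_cascades <- function(lambda_true, config) {
  stopifnot(inherits(config, "simulation_config"))
  lambda_true <- validate_rate_matrix(lambda_true)
  n_dis <- nrow(lambda_true)
  ids <- rownames(lambda_true)
  t_max <- config$window$t_max

  set.seed(config$rng_seed + 1L)
  span <- config$year_span[2] - config$year_span[1]
  n_drugs <- stats::rpois(1L, config$drugs_per_year * span)
  births <- sort(stats::runif(n_drugs, config$year_span[1],
                              config$year_span[2]))
  drug_ids <- sprintf("drug%05d", seq_len(n_drugs))
  seeds <- sample.int(n_dis, n_drugs, replace = TRUE,
                      prob = config$seed_disease_weights)
  alpha_true <- if (config$alpha_high == 0) {
    rep(0, n_drugs)
  } else {
    exp(stats::runif(n_drugs, log(config$alpha_low), log(config$alpha_high)))
  }
  beta_true <- stats::runif(n_drugs, config$beta_low, config$beta_high)

  rec_drug <- vector("list", n_drugs)
  rec_dis <- vector("list", n_drugs)
  rec_time <- vector("list", n_drugs)
  for (k in seq_len(n_drugs)) {
    adopt <- rep(Inf, n_dis)
    arrival <- rep(Inf, n_dis)
    adopt[seeds[k]] <- births[k]
    ## next-event sweep: when i adopts, draw one exponential offer per
    ## non-adopter j (in index order); j adopts at its earliest offer
    current <- seeds[k]
    repeat {
      t_i <- adopt[current]
      open <- which(!is.finite(adopt))
      targets <- open[lambda_true[current, open] > 0]
      if (length(targets) > 0L) {
        cand <- t_i + stats::rexp(length(targets),
                                  lambda_true[current, targets])
        better <- cand < arrival[targets]
        arrival[targets[better]] <- cand[better]
      }
      if (length(open) == 0L) break
      nxt <- open[which.min(arrival[open])]
      if (!is.finite(arrival[nxt]) || arrival[nxt] > t_max) break
      adopt[nxt] <- arrival[nxt]
      current <- nxt
    }
    got <- which(is.finite(adopt))
    rec_drug[[k]] <- rep(drug_ids[k], length(got))
    rec_dis[[k]] <- ids[got]
    rec_time[[k]] <- adopt[got]
  }

  adoptions <- adoption_table(unlist(rec_drug, use.names = FALSE),
                              unlist(rec_dis, use.names = FALSE),
                              unlist(rec_time, use.names = FALSE),
                              window = config$window)
  truth <- structure(list(
    lambda_true = lambda_true,
    alpha_true = stats::setNames(alpha_true, drug_ids),
    beta_true = stats::setNames(beta_true, drug_ids),
    seed_assignments = stats::setNames(ids[seeds], drug_ids),
    birth_times = stats::setNames(births, drug_ids)
  ), class = "ground_truth")
  list(adoptions = adoptions, ground_truth = truth)
}

#' Simulate per-drug study histories
#'
#' Study event ages for each drug are generated by time-rescaling a unit-rate
#' Poisson process through the cumulative intensity alpha * t^beta, so the
#' expected cumulative study count at age t is alpha * t^beta, truncated at
#' the observation end. Every drug additionally carries its birth study at
#' age 0. Each study is annotated with the diseases that have adopted the
#' drug by the study's time (at least the seed disease).
#'
#' @param adoptions An `adoption_table` as from [simulate_cascades()].
#' @param ground_truth The matching `ground_truth` object.
#' @param config The [simulation_config()] used to generate them.
#' @return A `study_table`.
#' @export
simulate_studies <- function(adoptions, ground_truth, config) {
  stopifnot(inherits(adoptions, "adoption_table"),
            inherits(ground_truth, "ground_truth"),
            inherits(config, "simulation_config"))
  set.seed(config$rng_seed + 2L)
  t_max <- config$window$t_max
  drug_ids <- names(ground_truth$birth_times)
  ad_by_drug <- split(adoptions[, c("disease_id", "time")], adoptions$drug_id)

  out <- vector("list", length(drug_ids))
  for (k in seq_along(drug_ids)) {
    dk <- drug_ids[k]
    birth <- ground_truth$birth_times[[dk]]
    alpha <- ground_truth$alpha_true[[dk]]
    beta <- ground_truth$beta_true[[dk]]
    span <- t_max - birth
    ages <- 0  # the birth study
    if (alpha > 0 && span > 0) {
      total <- alpha * span^beta
      n_extra <- stats::rpois(1L, total)
      if (n_extra > 0L) {
        u <- sort(stats::runif(n_extra)) * total
        ages <- c(0, (u / alpha)^(1 / beta))
      }
    }
    times <- birth + ages
    ad <- ad_by_drug[[dk]]
    if (is.null(ad) || nrow(ad) == 0L) {
      dis <- rep("", length(times))
    } else {
      ## prefix sets of adopters in adoption-time order
      ord <- order(ad$time, ad$disease_id)
      at <- ad$time[ord]
      ids_ord <- ad$disease_id[ord]
      prefixes <- vapply(seq_along(ids_ord), function(m)
        paste(sort(ids_ord[seq_len(m)]), collapse = ";"), character(1L))
      k_adopted <- findInterval(times, at)
      dis <- c("", prefixes)[k_adopted + 1L]
    }
    out[[k]] <- data.frame(
      drug_id = dk,
      study_id = sprintf("%s_s%04d", dk, seq_along(times)),
      time = times, diseases = dis, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  study_table(all$drug_id, all$study_id, all$time, all$diseases,
              window = config$window)
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: draws the rate matrix, the adoption cascades and the
#' study histories in that order, all from `config$rng_seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `studies` (`study_table`), `adoptions`
#'   (`adoption_table`) and `ground_truth`.
#' @export
simulate_dataset <- function(config) {
  lambda <- generate_rate_matrix(config)
  casc <- simulate_cascades(lambda, config)
  studies <- simulate_studies(casc$adoptions, casc$ground_truth, config)
  list(studies = studies, adoptions = casc$adoptions,
       ground_truth = casc$ground_truth)
}

#' Write ground truth to TSV files
#'
#' @param ground_truth A `ground_truth` object.
#' @param matrix_path Path for the rate-matrix TSV (diseases x diseases).
#' @param params_path Path for the per-drug parameter TSV (drug_id,
#'   birth_time, seed_disease, alpha, beta).
#' @return Invisibly, the two paths.
#' @export
write_ground_truth <- function(ground_truth, matrix_path, params_path) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  lam <- ground_truth$lambda_true
  mdf <- data.frame(disease_id = rownames(lam), lam, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(mdf, matrix_path)
  pdf <- data.frame(drug_id = names(ground_truth$birth_times),
                    birth_time = unname(ground_truth$birth_times),
                    seed_disease = unname(ground_truth$seed_assignments),
                    alpha = unname(ground_truth$alpha_true),
                    beta = unname(ground_truth$beta_true),
                    stringsAsFactors = FALSE)
  write_tsv(pdf, params_path)
  invisible(c(matrix_path, params_path))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d diseases, %d drugs, %d true edges\n",
              nrow(x$lambda_true), length(x$birth_times),
              sum(x$lambda_true > 0)))
  invisible(x)
}
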