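## Per-drug event ages on the integer-year grid.
##
## Age convention used throughout: a study at fractional age u (years since
## the drug's birth) contributes to cumulative counts at integer ages
## >= ceiling(u); age 0 means "by the end of the birth year".
drug_event_ages <- function(events) {
  stopifnot(nrow(events) > 0L)
  births <- tapply(events$time, events$drug_id, min)
  ages <- ceiling(events$time - births[events$drug_id])
  split(ages, events$drug_id)
}

#' Studies per drug by calendar year
#'
#' For every calendar year, counts the number of studies, the number of
#' distinct drugs mentioned, and their ratio (studies per drug). Years with
#' no drugs are omitted.
#'
#' @param events A `study_table`.
#' @return A data.frame with columns `year`, `n_studies`, `n_unique_drugs`,
#'   `studies_per_drug`.
#' @export
studies_per_drug_by_year <- function(events) {
  stopifnot(inherits(events, "study_table"))
  if (nrow(events) == 0L) {
    return(data.frame(year = integer(0), n_studies = integer(0),
                      n_unique_drugs = integer(0),
                      studies_per_drug = numeric(0)))
  }
  year <- floor(events$time)
  n_studies <- tapply(events$study_id, year, length)
  n_drugs <- tapply(events$drug_id, year, function(d) length(unique(d)))
  yrs <- as.integer(names(n_studies))
  data.frame(year = yrs,
             n_studies = as.integer(n_studies),
             n_unique_drugs = as.integer(n_drugs),
             studies_per_drug = as.numeric(n_studies) / as.numeric(n_drugs),
             row.names = NULL)
}

#' Birth-aligned average accumulation curve
#'
#' Shifts every drug so that age 0 is its birth year, then aggregates the
#' per-drug cumulative count of studies (mode `"studies"`) or of adopting
#' diseases (mode `"diseases"`) at each integer age. Following the averaging
#' conventions of the underlying analysis: the first study (or first
#' adopting disease) of each drug is excluded from the counts, drugs with a
#' single study (single disease) are dropped entirely, and a drug
#' contributes at age a only if its observed span `t_max - birth` covers a.
#' Because spans differ across drugs, the aggregate curve need not be
#' monotone.
#'
#' @param x A `study_table` (either mode) or an `adoption_table`
#'   (mode `"diseases"`).
#' @param mode Count `"studies"` per drug, or adopting `"diseases"` per drug.
#' @param aggregator `"mean"` or `"median"` across contributing drugs.
#' @param window Observation window; defaults to the one attached to `x`.
#' @return A data.frame of class `cumulative_curve` with columns `age`,
#'   `value`, `support` (number of drugs contributing at that age).
#' @export
aligned_curve <- function(x, mode = c("studies", "diseases"),
                          aggregator = c("mean", "median"),
                          window = attr(x, "window")) {
  mode <- match.arg(mode)
  aggregator <- match.arg(aggregator)
  if (is.null(window)) window <- observation_window()

  if (mode == "diseases" && inherits(x, "study_table")) {
    x <- derive_adoptions(x)
  }
  if (mode == "studies" && !inherits(x, "study_table")) {
    stop("mode 'studies' requires a study_table", call. = FALSE)
  }

  empty <- function() {
    warning("no eligible drugs for the aligned curve", call. = FALSE)
    structure(data.frame(age = integer(0), value = numeric(0),
                         support = integer(0)),
              mode = mode, aggregator = aggregator,
              class = c("cumulative_curve", "data.frame"))
  }
  if (nrow(x) == 0L) return(empty())

  births <- tapply(x$time, x$drug_id, min)
  age_list <- drug_event_ages(x)
  ## drop each drug's first event (tables are canonically ordered, so the
  ## first event of a drug is its earliest); drop single-event drugs
  age_list <- lapply(age_list, function(a) a[-1L])
  age_list <- age_list[lengths(age_list) > 0L]
  if (length(age_list) == 0L) return(empty())

  spans <- (window$t_max - births)[names(age_list)]
  max_age <- floor(max(spans))
  ages <- 0:max_age

  ## per-drug cumulative counts on the age grid, NA beyond the drug's span
  counts <- vapply(seq_along(age_list), function(k) {
    a <- age_list[[k]]
    a <- a[a <= max_age]
    cum <- cumsum(tabulate(a + 1L, nbins = max_age + 1L))
    cum[ages > spans[k]] <- NA_real_
    cum
  }, numeric(max_age + 1L))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = max_age + 1L)

  agg <- if (aggregator == "mean") {
    rowMeans(counts, na.rm = TRUE)
  } else {
    apply(counts, 1L, stats::median, na.rm = TRUE)
  }
  support <- rowSums(!is.na(counts))
  keep <- support > 0L
  structure(data.frame(age = ages[keep], value = agg[keep],
                       support = as.integer(support[keep])),
            mode = mode, aggregator = aggregator,
            class = c("cumulative_curve", "data.frame"))
}

#' Fit a power law to an accumulation curve
#'
#' Ordinary least squares of log(value) on log(age) over ages >= `min_age`
#' with strictly positive values: `value = alpha * age^beta` with R-squared
#' reported on the log scale.
#'
#' @param curve A `cumulative_curve` (or any data.frame with `age` and
#'   `value` columns).
#' @param min_age Smallest age entering the fit (default 1; age 0 has no
#'   log).
#' @return An object of class `power_law_fit` with elements `alpha`, `beta`,
#'   `r_squared`, `ages_used` and the underlying `lm` fit.
#' @export
fit_power_law <- function(curve, min_age = 1) {
  stopifnot(is.data.frame(curve), all(c("age", "value") %in% names(curve)))
  use <- curve$age >= min_age & curve$value > 0 & is.finite(curve$value)
  if (sum(use) < 3L) {
    stop("fit_power_law needs at least 3 positive values at ages >= min_age",
         call. = FALSE)
  }
  la <- log(curve$age[use])
  lv <- log(curve$value[use])
  fit <- stats::lm(lv ~ la)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((lv - mean(lv))^2)
  structure(list(alpha = exp(unname(stats::coef(fit)[1L])),
                 beta = unname(stats::coef(fit)[2L]),
                 # R^2 on the log scale; an exactly reproduced constant curve
                 # (tss = 0, rss = 0) counts as a perfect fit
                 r_squared = if (tss > 0) 1 - rss / tss else 1,
                 ages_used = range(curve$age[use]),
                 fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> value = %.4g * age^%.4g  (R^2 = %.4f, ages %d..%d)\n",
              x$alpha, x$beta, x$r_squared, x$ages_used[1L], x$ages_used[2L]))
  invisible(x)
}

## Cumulative study count of one drug at integer age `a` (first study
## included). Age 0 passed as the *lower* bound of a rate window denotes the
## birth instant, at which nothing has accumulated yet; that case is handled
## by the callers, not here.
cumulative_count_at <- function(times, birth, a) {
  sum(ceiling(times - birth) <= a)
}

#' Within-cohort quintile assignment
#'
#' Drugs born in `cohort_year` are ranked by the cumulative number of
#' studies accumulated by the horizon (all studies counted, including the
#' first; drugs studied only once are excluded) and split into five groups
#' as equal as possible, quintile 5 holding the most-studied drugs. Ties are
#' broken deterministically by earlier birth time within the year, then by
#' drug id.
#'
#' @param events A `study_table`.
#' @param cohort_year Integer calendar year of birth.
#' @param horizon Integer age at which counts are taken; `NULL` (default)
#'   counts everything up to the observation end ("accumulated by t_max").
#' @return A data.frame of class `quintile_assignment` with columns
#'   `drug_id`, `cohort_year`, `quintile`, `count_at_horizon`.
#' @export
assign_quintiles <- function(events, cohort_year, horizon = NULL) {
  stopifnot(inherits(events, "study_table"))
  births <- tapply(events$time, events$drug_id, min)
  in_cohort <- names(births)[floor(births) == cohort_year]
  n_studies <- table(events$drug_id)[in_cohort]
  eligible <- in_cohort[n_studies >= 2L]
  if (length(eligible) == 0L) {
    stop(sprintf("no eligible drugs in cohort %d", cohort_year),
         call. = FALSE)
  }
  if (length(eligible) < 5L) {
    warning(sprintf("cohort %d has only %d eligible drug(s); quintiles are degenerate",
                    cohort_year, length(eligible)), call. = FALSE)
  }
  tl <- split(events$time, events$drug_id)
  counts <- vapply(eligible, function(d) {
    if (is.null(horizon)) length(tl[[d]])
    else cumulative_count_at(tl[[d]], births[[d]], horizon)
  }, numeric(1L))
  ord <- order(counts, births[eligible], eligible)
  n <- length(eligible)
  quint <- integer(n)
  quint[ord] <- ceiling(5 * seq_len(n) / n)
  structure(data.frame(drug_id = eligible, cohort_year = cohort_year,
                       quintile = quint,
                       count_at_horizon = as.numeric(counts),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("quintile_assignment", "data.frame"))
}

#' Quintile transition ("momentum") matrix
#'
#' For each cohort, drugs observed across both age windows are ranked twice:
#' by studies accumulated by the end of window 1 (cumulative from birth) and
#' by studies falling strictly within window 2. Quintiles are assigned
#' independently per window within each cohort; transitions are pooled over
#' cohorts and row-normalized. Also reports the fraction of window-1
#' top-quintile drugs with zero window-2 studies ("slamming on the brakes").
#'
#' @param events A `study_table`.
#' @param cohort_years Integer vector of birth years to pool.
#' @param window1,window2 Integer age ranges, default ages 0-5 and 6-10.
#' @param window Observation window; defaults to the one attached to
#'   `events`.
#' @return A list of class `transition_matrix`: `matrix` (5x5 row-normalized
#'   probabilities), `counts` (raw 5x5 counts), `n` drugs pooled,
#'   `zero_rate_top` (fraction described above).
#' @export
quintile_transitions <- function(events, cohort_years,
                                 window1 = c(0, 5), window2 = c(6, 10),
                                 window = attr(events, "window")) {
  stopifnot(inherits(events, "study_table"),
            window1[1] < window1[2], window2[1] < window2[2])
  if (is.null(window)) window <- observation_window()
  births <- tapply(events$time, events$drug_id, min)
  tl <- split(events$time, events$drug_id)

  counts_tab <- matrix(0L, 5L, 5L,
                       dimnames = list(paste0("w1_q", 1:5),
                                       paste0("w2_q", 1:5)))
  n_total <- 0L
  top_total <- 0L
  top_zero <- 0L
  for (cy in cohort_years) {
    in_cohort <- names(births)[floor(births) == cy]
    ## present in both windows: the drug's observed span must cover the end
    ## of window 2; drugs studied only once are excluded throughout
    spans <- window$t_max - births[in_cohort]
    n_studies <- lengths(tl[in_cohort])
    eligible <- in_cohort[spans >= window2[2] & n_studies >= 2L]
    if (length(eligible) == 0L) next
    ages <- lapply(eligible, function(d) ceiling(tl[[d]] - births[[d]]))
    c1 <- vapply(ages, function(a) sum(a <= window1[2]), numeric(1L))
    c2 <- vapply(ages, function(a) sum(a >= window2[1] & a <= window2[2]),
                 numeric(1L))
    n <- length(eligible)
    q_of <- function(cnt) {
      ord <- order(cnt, births[eligible], eligible)
      q <- integer(n)
      q[ord] <- ceiling(5 * seq_len(n) / n)
      q
    }
    q1 <- q_of(c1)
    q2 <- q_of(c2)
    for (k in seq_len(n)) {
      counts_tab[q1[k], q2[k]] <- counts_tab[q1[k], q2[k]] + 1L
    }
    n_total <- n_total + n
    top <- q1 == 5L
    top_total <- top_total + sum(top)
    top_zero <- top_zero + sum(top & c2 == 0)
  }
  if (n_total == 0L) {
    stop("no drugs present in both windows for the given cohorts",
         call. = FALSE)
  }
  probs <- counts_tab / pmax(rowSums(counts_tab), 1L)
  structure(list(matrix = probs, counts = counts_tab, n = n_total,
                 zero_rate_top = if (top_total > 0) top_zero / top_total
                                 else NA_real_),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d drugs pooled; P(stay top) = %.3f\n",
              x$n, x$matrix[5L, 5L]))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Study rate of one drug over an age window
#'
#' The rate of studies per year between ages `age_a` and `age_b`:
#' `(C(age_b) - C(age_a)) / (age_b - age_a)`, where `C(a)` is the drug's
#' cumulative study count at integer age a, first study included. The lower
#' bound age 0 denotes the birth instant, at which the cumulative count is
#' taken as 0 — so the rate over (0, 5) for a drug with 3 studies by age 5
#' is 0.6 per year.
#'
#' @param events A `study_table`.
#' @param drug_id Drug token.
#' @param age_a,age_b Age window bounds in years, `age_a < age_b`.
#' @return Studies per year (numeric scalar).
#' @export
rate_in_window <- function(events, drug_id, age_a, age_b) {
  stopifnot(inherits(events, "study_table"), age_a < age_b)
  times <- events$time[events$drug_id == drug_id]
  if (length(times) == 0L) {
    stop(sprintf("unknown drug: %s", drug_id), call. = FALSE)
  }
  birth <- min(times)
  cc <- function(a) {
    if (a <= 0) 0 else cumulative_count_at(times, birth, a)
  }
  (cc(age_b) - cc(age_a)) / (age_b - age_a)
}
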