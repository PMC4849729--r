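# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (brute force, direct enumeration) and
# kept separate from the package's own code paths.

# A small study table with known structure.
tiny_studies <- function(window = observation_window(1990, 2010.999)) {
  study_table(
    drug_id = c("A", "A", "A", "B", "B", "C"),
    study_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    time = c(2001, 2004, 2006, 1999, 2003, 2007),
    diseases = c("X", "X;Y", "Y", "X", "", "Z"),
    window = window
  )
}

# Random study table over n_drugs/n_diseases; seeds are the caller's duty.
random_studies <- function(n_rows = 50, n_drugs = 8, n_diseases = 5,
                           window = observation_window(1990, 2010.999)) {
  drugs <- sprintf("d%02d", sample.int(n_drugs, n_rows, replace = TRUE))
  dis_pool <- sprintf("X%02d", seq_len(n_diseases))
  dis <- vapply(seq_len(n_rows), function(i) {
    k <- sample(0:3, 1L)
    paste(sample(dis_pool, k), collapse = ";")
  }, character(1L))
  study_table(
    drug_id = drugs,
    study_id = sprintf("s%03d", seq_len(n_rows)),
    time = round(runif(n_rows, 1991, 2009), 3),
    diseases = dis, window = window
  )
}

# Brute-force (drug, disease) first-pairing times from a study table.
brute_adoptions <- function(events) {
  rows <- list()
  for (r in seq_len(nrow(events))) {
    for (d in strsplit(events$diseases[r], ";", fixed = TRUE)[[1]]) {
      if (!nzchar(d)) next
      key <- paste(events$drug_id[r], d)
      t <- events$time[r]
      if (is.null(rows[[key]]) || t < rows[[key]]$time) {
        rows[[key]] <- list(drug = events$drug_id[r], dis = d, time = t)
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(x)
    data.frame(drug_id = x$drug, disease_id = x$dis, time = x$time,
               stringsAsFactors = FALSE)))
  df <- df[order(df$time, df$drug_id, df$disease_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Numerical maximizer of the censored-exponential log-likelihood
#   n log(lambda) - lambda * (sum obs + sum cens)
# on a bracketed interval, independent of the closed form.
numeric_censored_mle <- function(observed, censored) {
  ll <- function(lam) {
    length(observed) * log(lam) - lam * (sum(observed) + sum(censored))
  }
  stats::optimize(ll, interval = c(1e-8, 1e3), maximum = TRUE,
                  tol = 1e-12)$maximum
}

# Naive O(n^3) agglomerative Ward clustering via the Lance-Williams update
# on distances (the ward.D2 convention: squared-distance update, heights on
# the distance scale). Returns merge heights and the leaf partition after
# each merge, for comparison against an hclust tree.
naive_ward <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  dd <- d^2
  heights <- numeric(0)
  partitions <- list()
  cur <- dd
  repeat {
    m <- length(active)
    if (m == 1L) break
    best <- c(Inf, NA, NA)
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      if (cur[a, b] < best[1]) best <- c(cur[a, b], a, b)
    }
    a <- best[2]; b <- best[3]
    heights <- c(heights, sqrt(best[1]))
    merged <- sort(c(active[[a]], active[[b]]))
    na <- sizes[a]; nb <- sizes[b]
    newrow <- numeric(m)
    for (k in seq_len(m)) {
      if (k == a || k == b) next
      nk <- sizes[k]
      newrow[k] <- ((na + nk) * cur[a, k] + (nb + nk) * cur[b, k] -
                      nk * cur[a, b]) / (na + nb + nk)
    }
    keep <- setdiff(seq_len(m), c(a, b))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newrow[keep]),
                 c(newrow[keep], 0))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], na + nb)
    partitions <- c(partitions, list(merged))
  }
  list(heights = heights, partitions = partitions)
}

# Leaf sets of each internal merge of an hclust tree, in merge order.
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  out <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    out[[k]] <- sort(c(
      if (hc$merge[k, 1] < 0) -hc$merge[k, 1] else out[[hc$merge[k, 1]]],
      if (hc$merge[k, 2] < 0) -hc$merge[k, 2] else out[[hc$merge[k, 2]]]))
  }
  out
}

# Exhaustive shortest-path delays by simple-path enumeration (n <= 7).
brute_shortest_paths <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    adj[edges$source[r], edges$target[r]] <- edges$weight[r]
  }
  best <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(best) <- 0
  dfs <- function(path, cost, target) {
    v <- path[length(path)]
    if (v == target) {
      if (cost < best[path[1], target]) best[path[1], target] <<- cost
      return(invisible())
    }
    for (w in seq_len(n)) {
      if (is.finite(adj[v, w]) && !(w %in% path)) {
        dfs(c(path, w), cost + adj[v, w], target)
      }
    }
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t) dfs(s, 0, t)
  }
  best
}

# Adoption table holding explicit per-drug adoption sequences.
adoptions_from_list <- function(lst, window = observation_window(1990, 2010.999)) {
  drug <- rep(names(lst), vapply(lst, nrow, integer(1L)))
  df <- do.call(rbind, lst)
  adoption_table(drug, df$disease_id, df$time, window = window)
}
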