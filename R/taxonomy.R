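#' Build per-disease adopted-drug sets
#'
#' Groups adoptions by disease and keeps diseases that have adopted at least
#' `min_drugs` drugs. The drug universe is recomputed over the included
#' diseases only, so every probability downstream is relative to the drugs
#' actually in play.
#'
#' @param adoptions An `adoption_table`.
#' @param min_drugs Inclusion threshold on the number of adopted drugs
#'   (default 50, the convention for literature-scale taxonomies; lower it
#'   for small datasets).
#' @return An object of class `disease_drug_sets`: a list with `sets` (named
#'   list of character vectors, disease -> drugs) and `universe` (all drugs
#'   adopted by any included disease).
#' @export
build_drug_sets <- function(adoptions, min_drugs = 50) {
  stopifnot(inherits(adoptions, "adoption_table"), nrow(adoptions) > 0L)
  sets <- lapply(split(adoptions$drug_id, adoptions$disease_id),
                 function(d) sort(unique(d)))
  sizes <- lengths(sets)
  keep <- sizes >= min_drugs
  if (!any(keep)) {
    stop(sprintf("no disease has adopted >= %d drugs (max is %d over %d diseases)",
                 min_drugs, max(sizes), length(sets)), call. = FALSE)
  }
  sets <- sets[keep]
  sets <- sets[order(names(sets))]
  structure(list(sets = sets,
                 universe = sort(unique(unlist(sets, use.names = FALSE)))),
            class = "disease_drug_sets")
}

#' @export
print.disease_drug_sets <- function(x, ...) {
  cat(sprintf("<disease_drug_sets> %d diseases over %d drugs\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Joint Bernoulli distribution of co-adoption for a disease pair
#'
#' For diseases i and j over the drug universe d, the 2x2 table of the pair
#' of indicators (drug adopted by i, drug adopted by j): cells count drugs
#' in neither set, in i only, in j only, and in both, each divided once by
#' |d| so the table sums to 1 exactly.
#'
#' @param sets A `disease_drug_sets`.
#' @param i,j Disease ids, distinct, both included in `sets`.
#' @return A 2x2 matrix of class `bernoulli_joint`; rows index membership in
#'   i (0/1), columns membership in j (0/1).
#' @export
bernoulli_joint <- function(sets, i, j) {
  stopifnot(inherits(sets, "disease_drug_sets"))
  if (identical(i, j)) stop("i and j must differ", call. = FALSE)
  for (id in c(i, j)) {
    if (!id %in% names(sets$sets)) {
      stop(sprintf("unknown disease: %s", id), call. = FALSE)
    }
  }
  di <- sets$sets[[i]]
  dj <- sets$sets[[j]]
  n <- length(sets$universe)
  n_both <- length(intersect(di, dj))
  n_i <- length(di) - n_both
  n_j <- length(dj) - n_both
  n_neither <- n - n_both - n_i - n_j
  p <- matrix(c(n_neither, n_i, n_j, n_both) / n, nrow = 2L,
              dimnames = list(i = c("0", "1"), j = c("0", "1")))
  structure(p, class = c("bernoulli_joint", class(p)))
}

#' Mutual information of a 2x2 joint distribution
#'
#' Computes sum over cells of p * log(p / (p_row * p_col)) in natural log
#' (nats), with 0 * log 0 taken as 0. Tiny negative values from floating
#' point are clamped to 0 at tolerance 1e-12.
#'
#' @param joint A 2x2 joint probability matrix (e.g. a `bernoulli_joint`).
#' @return Mutual information in nats (numeric scalar, >= 0).
#' @export
mutual_information <- function(joint) {
  p <- unclass(joint)
  stopifnot(is.matrix(p), nrow(p) == 2L, ncol(p) == 2L, all(p >= 0),
            abs(sum(p) - 1) < 1e-9)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    if (p[a, b] > 0) {
      mi <- mi + p[a, b] * log(p[a, b] / (px[a] * py[b]))
    }
  }
  if (mi < 0 && mi > -1e-12) mi <- 0
  mi
}

binary_entropy <- function(q) {
  h <- 0
  for (p in c(q, 1 - q)) if (p > 0) h <- h - p * log(p)
  h
}

#' Pairwise mutual-information similarity matrix between diseases
#'
#' Symmetric matrix of I(D_i; D_j) in nats over all included disease pairs;
#' the diagonal carries the marginal entropy H(D_i) of each disease's
#' adoption indicator.
#'
#' @param sets A `disease_drug_sets`.
#' @return A symmetric numeric matrix with disease ids as dimnames.
#' @export
mi_matrix <- function(sets) {
  stopifnot(inherits(sets, "disease_drug_sets"))
  ids <- names(sets$sets)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    m[a, a] <- binary_entropy(length(sets$sets[[a]]) / length(sets$universe))
    if (a < n) for (b in (a + 1L):n) {
      mi <- mutual_information(bernoulli_joint(sets, ids[a], ids[b]))
      m[a, b] <- mi
      m[b, a] <- mi
    }
  }
  m
}

#' Convert a similarity matrix to a distance matrix
#'
#' The order-reversing transform d(i, j) = I_max - I(i, j), with I_max the
#' largest off-diagonal similarity, so the most similar pair sits at
#' distance 0; the diagonal is 0. An alternative normalized transform
#' d = 1 - I / min(H_i, H_j) is available; note it can change the resulting
#' tree topology.
#'
#' @param m A symmetric similarity matrix as from [mi_matrix()] (diagonal =
#'   marginal entropies, needed for `method = "normalized"`).
#' @param method `"imax_minus_i"` (default) or `"normalized"`.
#' @return A symmetric non-negative distance matrix with zero diagonal.
#' @export
mi_to_distance <- function(m, method = c("imax_minus_i", "normalized")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-9) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(m)
  if (method == "imax_minus_i") {
    off <- m
    diag(off) <- -Inf
    i_max <- max(off)
    d <- i_max - m
  } else {
    h <- diag(m)
    denom <- outer(h, h, pmin)
    denom[denom <= 0] <- 1  # a zero-entropy disease is distance 1 from all
    d <- 1 - m / denom
  }
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Ward hierarchical clustering of diseases
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`stats::hclust`, method `"ward.D2"`, which applies the Ward
#' Lance-Williams update to the distances themselves).
#'
#' @param d A square symmetric non-negative distance matrix with zero
#'   diagonal, or a `dist` object.
#' @return An `hclust` object (rooted binary merge tree with heights).
#' @export
ward_cluster <- function(d) {
  if (!inherits(d, "dist")) {
    stopifnot(is.matrix(d), nrow(d) == ncol(d))
    if (max(abs(d - t(d))) > 1e-9) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
      stop("distance matrix must be non-negative with zero diagonal",
           call. = FALSE)
    }
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "ward.D2")
}

#' Drug-exclusivity report
#'
#' A drug is exclusive to a disease if no other included disease has adopted
#' it. Reports, per disease, the number of adopted drugs, the number
#' exclusive to it and the exclusive fraction.
#'
#' @param sets A `disease_drug_sets`.
#' @return A data.frame with columns `disease_id`, `n_drugs`, `n_exclusive`,
#'   `fraction_exclusive`.
#' @export
exclusivity <- function(sets) {
  stopifnot(inherits(sets, "disease_drug_sets"))
  all_drugs <- unlist(sets$sets, use.names = FALSE)
  n_adopters <- table(all_drugs)
  res <- lapply(names(sets$sets), function(id) {
    drugs <- sets$sets[[id]]
    n_ex <- sum(n_adopters[drugs] == 1L)
    data.frame(disease_id = id, n_drugs = length(drugs),
               n_exclusive = as.integer(n_ex),
               fraction_exclusive = if (length(drugs) > 0)
                 n_ex / length(drugs) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (leaves at height 0, each
#' internal node at its merge height), so the tree is ultrametric with
#' leaf-to-root depth equal to the root merge height.
#'
#' @param dendrogram An `hclust` object as from [ward_cluster()].
#' @param path Output file path.
#' @return Invisibly, the Newick string written.
#' @export
export_newick <- function(dendrogram, path) {
  if (!inherits(dendrogram, "hclust")) {
    stop("export_newick expects an hclust object", call. = FALSE)
  }
  if (length(dendrogram$labels) < 2L) {
    stop("cannot export a tree with fewer than 2 leaves", call. = FALSE)
  }
  phy <- ape::as.phylo(dendrogram)
  ## as.phylo.hclust places nodes at height/2; rescale so edge lengths are
  ## merge-height differences
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
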