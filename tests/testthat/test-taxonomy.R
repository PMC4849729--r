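make_sets <- function(...) {
  # build a disease_drug_sets from named character vectors
  lst <- list(...)
  ad <- adoption_table(unlist(lst, use.names = FALSE),
                       rep(names(lst), lengths(lst)),
                       2000 + seq_along(unlist(lst)) / 1000)
  build_drug_sets(ad, min_drugs = 1)
}

test_that("drug-set construction filters by adoption threshold", {
  ad <- adoption_table(
    drug_id = c("a", "b", "c", "a", "b", "d"),
    disease_id = c("X", "X", "X", "Y", "Y", "Z"),
    time = 2001:2006)
  all_sets <- build_drug_sets(ad, min_drugs = 1)
  expect_equal(length(all_sets$sets), 3L)
  big <- build_drug_sets(ad, min_drugs = 2)
  expect_setequal(names(big$sets), c("X", "Y"))
  expect_setequal(big$universe, c("a", "b", "c"))  # recomputed w/o Z's drug
  expect_error(build_drug_sets(ad, min_drugs = 10), "no disease")
})

test_that("the co-adoption joint distribution enumerates set memberships", {
  s <- make_sets(X = c("a", "b"), Y = c("a", "c"), Z = "d")
  j <- bernoulli_joint(s, "X", "Y")
  expect_equal(as.numeric(j), rep(0.25, 4))  # |d| = 4: neither=d, both=a
  expect_equal(sum(j), 1)

  s2 <- make_sets(X = c("a", "b"), Y = c("a", "b"), Z = c("c", "d"))
  j2 <- bernoulli_joint(s2, "X", "Y")
  expect_equal(j2["1", "0"] + j2["0", "1"], 0)

  set.seed(71)
  pool <- letters
  sets <- lapply(1:4, function(i) sample(pool, sample(5:15, 1)))
  names(sets) <- c("P", "Q", "R", "S")
  s3 <- do.call(make_sets, sets)
  for (pair in list(c("P", "Q"), c("R", "S"), c("P", "S"))) {
    j3 <- bernoulli_joint(s3, pair[1], pair[2])
    u <- s3$universe
    di <- s3$sets[[pair[1]]]; dj <- s3$sets[[pair[2]]]
    brute <- c(sum(!(u %in% di) & !(u %in% dj)), sum(u %in% di & !(u %in% dj)),
               sum(!(u %in% di) & u %in% dj), sum(u %in% di & u %in% dj))
    expect_equal(as.numeric(unclass(j3)), brute / length(u))
    expect_equal(sum(j3), 1)
  }
  expect_error(bernoulli_joint(s, "X", "X"), "differ")
  expect_error(bernoulli_joint(s, "X", "nope"), "unknown")
})

test_that("mutual information: independence, perfect dependence, entropy oracle", {
  indep <- matrix(0.25, 2, 2)
  expect_equal(mutual_information(indep), 0)

  dep <- diag(c(0.5, 0.5))
  expect_equal(mutual_information(dep), log(2), tolerance = 1e-12)

  # oracle: I = H(X) + H(Y) - H(X,Y) from direct entropy sums
  set.seed(81)
  for (trial in 1:20) {
    p <- matrix(stats::rexp(4), 2, 2)
    p <- p / sum(p)
    h <- function(v) -sum(v[v > 0] * log(v[v > 0]))
    oracle <- h(rowSums(p)) + h(colSums(p)) - h(as.numeric(p))
    expect_equal(mutual_information(p), max(oracle, 0), tolerance = 1e-10)
    expect_gte(mutual_information(p), 0)
    expect_lte(mutual_information(p),
               min(h(rowSums(p)), h(colSums(p))) + 1e-12)
    # symmetry under transposition
    expect_equal(mutual_information(p), mutual_information(t(p)),
                 tolerance = 1e-12)
  }
})

test_that("MI similarity matrices are symmetric with entropy diagonals", {
  set.seed(91)
  sets <- lapply(1:5, function(i) sample(letters, sample(6:20, 1)))
  names(sets) <- paste0("D", 1:5)
  s <- do.call(make_sets, sets)
  m <- mi_matrix(s)
  expect_equal(m, t(m))
  expect_true(all(m >= 0))
  for (d in rownames(m)) {
    q <- length(s$sets[[d]]) / length(s$universe)
    expect_equal(m[d, d], -q * log(q) - (1 - q) * log(1 - q),
                 tolerance = 1e-12)
  }
  # clustering depends only on set cardinalities: relabel the drugs
  perm <- stats::setNames(sample(letters), letters)
  sets2 <- lapply(sets, function(x) unname(perm[x]))
  s2 <- do.call(make_sets, sets2)
  expect_equal(mi_matrix(s2), m)
})

test_that("similarity-to-distance transform reverses order and zeroes the argmax pair", {
  set.seed(101)
  sets <- lapply(1:6, function(i) sample(letters, sample(6:20, 1)))
  names(sets) <- paste0("D", 1:6)
  m <- mi_matrix(do.call(make_sets, sets))
  d <- mi_to_distance(m)
  off <- m; diag(off) <- -Inf
  expect_equal(min(d[row(d) != col(d)]), 0)
  expect_equal(d[which.max(off)], 0)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  # monotone: larger similarity means smaller distance
  ij <- which(row(m) < col(m), arr.ind = TRUE)
  sim <- m[ij]; dist <- d[ij]
  expect_true(all(diff(dist[order(sim)]) <= 1e-12))
  # an I = 0 pair would sit at distance I_max
  m0 <- m; m0[1, 2] <- m0[2, 1] <- 0
  expect_equal(mi_to_distance(m0)[1, 2], max(m0[row(m0) != col(m0)]))
})

test_that("Ward clustering matches a naive O(n^3) implementation", {
  # two identical leaves merge first
  d <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3)
  hc <- ward_cluster(d)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  # two well-separated pairs merge before the root
  d4 <- matrix(10, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 1
  d4[3, 4] <- d4[4, 3] <- 1
  diag(d4) <- 0
  hc4 <- ward_cluster(d4)
  expect_equal(sort(sapply(hclust_partitions(hc4)[1:2], paste, collapse = ",")),
               c("1,2", "3,4"))

  set.seed(111)
  for (trial in 1:5) {
    x <- matrix(stats::runif(16), 8, 2)
    dm <- as.matrix(stats::dist(x))
    dimnames(dm) <- NULL
    hc8 <- ward_cluster(dm)
    oracle <- naive_ward(dm)
    expect_equal(sort(hc8$height), sort(oracle$heights), tolerance = 1e-9)
    expect_setequal(sapply(hclust_partitions(hc8), paste, collapse = ","),
                    sapply(oracle$partitions, paste, collapse = ","))
    # Ward heights are monotone from leaves to root
    expect_true(all(diff(hc8$height) >= -1e-12))
  }
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("block-structured drug sharing is recovered by the top split", {
  # each disease adopts its group's 18-drug core plus 2 drugs of its own
  core <- list(A = paste0("coreA_", 1:18), B = paste0("coreB_", 1:18))
  sets <- c(lapply(1:3, function(i) c(core$A, paste0("ownA", i, "_", 1:2))),
            lapply(1:3, function(i) c(core$B, paste0("ownB", i, "_", 1:2))))
  names(sets) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  s <- do.call(make_sets, sets)
  hc <- ward_cluster(mi_to_distance(mi_matrix(s)))
  top <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(top[c("A1", "A2", "A3")])), 1L)
  expect_equal(length(unique(top[c("B1", "B2", "B3")])), 1L)
  expect_true(top[["A1"]] != top[["B1"]])
})

test_that("exclusivity counts drugs adopted by no other disease", {
  s <- make_sets(X = c("a", "b", "c", "d"), Y = c("d", "e"))
  ex <- exclusivity(s)
  expect_equal(ex$fraction_exclusive[ex$disease_id == "X"], 0.75)
  expect_equal(ex$fraction_exclusive[ex$disease_id == "Y"], 0.5)

  shared <- make_sets(X = c("a", "b"), Y = c("a", "b"), Z = c("a", "b"))
  expect_true(all(exclusivity(shared)$fraction_exclusive == 0))

  set.seed(131)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("D", 1:4)
  s2 <- do.call(make_sets, sets)
  ex2 <- exclusivity(s2)
  for (k in seq_len(nrow(ex2))) {
    d <- ex2$disease_id[k]
    others <- unique(unlist(sets[setdiff(names(sets), d)]))
    expect_equal(ex2$n_exclusive[k], sum(!(sets[[d]] %in% others)))
  }
})

test_that("Newick export writes merge-height branch lengths and round-trips topology", {
  d <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hc <- ward_cluster(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(hc, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(A:4,B:4\\);$")

  set.seed(141)
  x <- matrix(stats::runif(16), 8, 2)
  dm <- as.matrix(stats::dist(x))
  dimnames(dm) <- list(letters[1:8], letters[1:8])
  hc8 <- ward_cluster(dm)
  export_newick(hc8, path)
  back <- ape::read.tree(path)
  clades <- function(phy) {
    pp <- ape::prop.part(phy)
    sort(vapply(pp, function(i)
      paste(sort(attr(pp, "labels")[i]), collapse = ","), character(1L)))
  }
  expect_identical(clades(back), clades(ape::as.phylo(hc8)))
  # ultrametric: leaf depths all equal the root merge height
  depths <- ape::node.depth.edgelength(back)[seq_len(8)]
  expect_equal(depths, rep(max(hc8$height), 8), tolerance = 1e-9)

  expect_error(export_newick(stats::hclust(stats::dist(1:2))[0], path))
})
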