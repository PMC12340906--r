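## Independent Lance-Williams Ward.D2 agglomeration for the merge oracle.
lw_ward_partitions <- function(x1d) {
  n <- length(x1d)
  d <- as.matrix(dist(x1d))
  active <- as.list(seq_len(n))
  partitions <- list(lapply(active, identity))
  sizes <- rep(1, n)
  while (length(active) > 1) {
    m <- length(active)
    best <- c(Inf, 0, 0)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    ## Lance-Williams update for Ward.D2 on distances
    dn <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      dn[k] <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                       nk * d[i, j]^2) / (ni + nj + nk))
    }
    merged <- c(active[[i]], active[[j]])
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], sizes[best[2]] + sizes[best[3]])
    partitions[[length(partitions) + 1L]] <- active
  }
  partitions
}

partition_to_labels <- function(part, n) {
  lab <- integer(n)
  for (g in seq_along(part)) lab[part[[g]]] <- g
  lab
}

test_that("Ward.D2 merges match the Lance-Williams oracle on 5 points", {
  pts <- c(0, 0.9, 3.1, 7.0, 7.4)
  x <- matrix(pts, 1, 5, dimnames = list("f", paste0("s", 1:5)))
  parts <- lw_ward_partitions(pts)
  for (k in 1:5) {
    mine <- cluster_hierarchical(x, k)
    oracle <- partition_to_labels(parts[[5 - k + 1]], 5)
    expect_equal(nmi(mine, oracle), 1)   # identical up to renaming
  }
})

test_that("both algorithms recover well-separated clouds exactly", {
  cl <- make_clouds(n_per = 15, k = 3, seed = 44)
  h <- cluster_hierarchical(cl$x, 3)
  k <- cluster_kmeans(cl$x, 3, seed = 2)
  expect_equal(nmi(h, cl$labels), 1)
  expect_equal(nmi(k, cl$labels), 1)
})

test_that("clustering edge cases behave as specified", {
  cl <- make_clouds(n_per = 5, k = 2, seed = 4)
  expect_identical(unique(cluster_hierarchical(cl$x, 1)), 1L)
  expect_error(cluster_hierarchical(cl$x, 0), "k must be")
  expect_error(cluster_kmeans(cl$x, 0), "k must be")
  ## k = n: every sample its own cluster, zero within-cluster scatter
  kn <- cluster_kmeans(cl$x, ncol(cl$x), seed = 1)
  expect_equal(length(unique(kn)), ncol(cl$x))
  expect_equal(attr(kn, "wcss"), 0, tolerance = 1e-10)
  ## seed determinism
  expect_identical(as.integer(cluster_kmeans(cl$x, 2, seed = 9)),
                   as.integer(cluster_kmeans(cl$x, 2, seed = 9)))
})

test_that("NMI matches the entropy-formula oracle and its invariants", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # renaming-invariant
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)  # independent margins
  a <- c(1, 1, 2, 2, 3, 3); b <- c(1, 1, 1, 2, 2, 2)
  ## direct entropy computation
  pj <- table(a, b) / 6
  pa <- rowSums(pj); pb <- colSums(pj)
  mi <- sum(ifelse(pj > 0, pj * log(pj / outer(pa, pb)), 0))
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  expect_equal(nmi(a, b), mi / ((ha + hb) / 2), tolerance = 1e-12)
  expect_equal(nmi(a, b), nmi(b, a))
  expect_error(nmi(1:3, 1:4), "length")
  set.seed(10)
  for (i in 1:20) {
    u <- sample(1:3, 30, TRUE); v <- sample(1:4, 30, TRUE)
    expect_gte(nmi(u, v), 0); expect_lte(nmi(u, v), 1)
  }
})

test_that("elbow selection finds planted k and handles flat curves", {
  cl <- make_clouds(n_per = 15, k = 3, sep = 8, seed = 21)
  e <- elbow_select(cl$x, 1:6, "hierarchical")
  expect_equal(as.integer(e), 3L)
  expect_false(attr(e, "weak_elbow"))
  expect_named(attr(e, "wcss"), as.character(1:6))
  set.seed(77)
  noise <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(paste0("f", 1:40), paste0("s", 1:30)))
  en <- elbow_select(noise, 1:6, "hierarchical")
  expect_true(attr(en, "weak_elbow"))
  expect_error(elbow_select(cl$x, 2:3), ">= 3")
  expect_error(elbow_select(cl$x, c(1, 3, 5)), "contiguous")
})

test_that("consensus k maximizes inter-algorithm NMI with ties to smallest", {
  ## three overlapping 1-D clusters: the two algorithms agree best at the
  ## true k, where the partition is data-driven rather than arbitrary
  set.seed(3)
  n <- 45
  x <- matrix(c(rnorm(15, 0, 1), rnorm(15, 3.5, 1), rnorm(15, 7, 1)), 1, n)
  x <- rbind(x, matrix(rnorm(5 * n), 5, n))
  dimnames(x) <- list(paste0("f", 1:6), paste0("s", 1:n))
  k <- consensus_k(x, 2:5, seed = 8)
  expect_equal(as.integer(k), 3L)
  tab <- attr(k, "nmi_by_k")
  expect_named(tab, as.character(2:5))
  ## consistency with the nmi op itself
  expect_equal(unname(tab["3"]),
               nmi(cluster_hierarchical(x, 3),
                   cluster_kmeans(x, 3, seed = 8)))
  expect_equal(as.integer(consensus_k(x, 2:2, seed = 1)), 2L)
})

test_that("consensus labels align label spaces and flag disagreements", {
  hier <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  km_perm <- c(2, 2, 2, 3, 3, 3, 1, 1, 1)   # same partition, renamed
  names(hier) <- names(km_perm) <- paste0("s", 1:9)
  cons <- consensus_labels(hier, km_perm)
  expect_equal(cons$retained, 9)
  expect_true(all(cons$consensus_label != "inconsistent"))
  ## one swapped sample -> exactly that sample inconsistent
  km_swap <- km_perm; km_swap[5] <- 1
  cons2 <- consensus_labels(hier, km_swap)
  expect_identical(names(which(cons2$consensus_label == "inconsistent")),
                   "s5")
  expect_error(consensus_labels(hier, c(km_perm[-1], 9)), "different k")
})

test_that("label alignment equals brute-force trace maximization", {
  set.seed(15)
  for (k in 2:4) {
    a <- sample(seq_len(k), 40, TRUE)
    b <- sample(seq_len(k), 40, TRUE)
    names(a) <- names(b) <- paste0("s", 1:40)
    if (length(unique(a)) != k || length(unique(b)) != k) next
    cons <- consensus_labels(a, b)
    cont <- table(a, b)
    perms <- episubtype:::permutations_of(k)
    best <- max(vapply(seq_len(nrow(perms)), function(i)
      sum(cont[cbind(seq_len(k), perms[i, ])]), 0))
    expect_equal(cons$retained, best)
  }
})
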