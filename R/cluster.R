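## Samples are observations throughout: inputs are probes x samples matrices
## (the methylation convention) and are transposed internally.

as_obs <- function(x) {
  stop_if_not_matrix(x, "x")
  t(x)
}

#' Hierarchical clustering of samples (Ward.D2, Euclidean)
#'
#' @param x probes x samples numeric matrix.
#' @param k number of clusters to cut the tree at.
#' @return integer cluster labels (1..k), named by sample, canonically
#'   renumbered by decreasing cluster size.
#' @export
cluster_hierarchical <- function(x, k) {
  obs <- as_obs(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(obs)) stop("k exceeds number of samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(obs, method = "euclidean"),
                      method = "ward.D2")
  canonicalize_labels(stats::cutree(hc, k = k))
}

## k-means++ seeding: spread initial centers by squared-distance sampling.
kmeanspp_centers <- function(obs, k) {
  n <- nrow(obs)
  centers <- obs[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(obs, 1, function(r) min(colSums((t(centers) - r)^2)))
    centers <- rbind(centers,
                     obs[sample.int(n, 1, prob = pmax(d2, 1e-300)), ,
                         drop = FALSE])
  }
  centers
}

#' K-means clustering of samples
#'
#' Best of \code{n_init} restarts (k-means++ seeding) by within-cluster sum
#' of squares; deterministic given the seed.
#'
#' @param x probes x samples numeric matrix.
#' @param k cluster count.
#' @param seed RNG seed for the restarts.
#' @param n_init number of restarts.
#' @return integer labels named by sample, renumbered by decreasing size,
#'   with attribute \code{wcss}.
#' @export
cluster_kmeans <- function(x, k, seed = 1, n_init = 25) {
  obs <- as_obs(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(obs)) stop("k exceeds number of samples", call. = FALSE)
  if (k == nrow(obs)) {   # every sample its own cluster, zero scatter
    lab <- stats::setNames(seq_len(k), rownames(obs))
    attr(lab, "wcss") <- 0
    return(lab)
  }
  best <- NULL
  with_substream(seed, "kmeans", {
    for (i in seq_len(n_init)) {
      fit <- suppressWarnings(
        stats::kmeans(obs, centers = kmeanspp_centers(obs, k),
                      iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  lab <- canonicalize_labels(stats::setNames(best$cluster, rownames(obs)))
  attr(lab, "wcss") <- best$tot.withinss
  lab
}

## Deterministic canonical cluster numbering: 1 = largest cluster, ties by
## first occurrence. Replaces arbitrary (or randomized) cluster names.
canonicalize_labels <- function(labels) {
  tab <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  ord <- names(tab)[order(-as.vector(tab), as.vector(first))]
  out <- match(as.character(labels), ord)
  names(out) <- names(labels)
  out
}

wcss_of <- function(obs, labels) {
  sum(vapply(split(seq_len(nrow(obs)), labels), function(i) {
    m <- obs[i, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, 0))
}

#' Elbow selection of the cluster count
#'
#' Computes the within-cluster sum-of-squares curve over \code{k_range} for
#' one algorithm and returns the k maximizing its second difference (the
#' sharpest bend). Ties go to the smallest k; a flat curve is flagged.
#'
#' @param x probes x samples matrix.
#' @param k_range contiguous increasing integer vector, length >= 3.
#' @param method "hierarchical" or "kmeans".
#' @param seed,n_init passed to \code{\link{cluster_kmeans}}.
#' @return selected k, with attributes \code{wcss} (the audit curve, named
#'   by k) and \code{weak_elbow} (TRUE when the curve is near-flat).
#' @export
elbow_select <- function(x, k_range = 2:6, method = c("hierarchical",
                                                      "kmeans"),
                         seed = 1, n_init = 25) {
  method <- match.arg(method)
  if (length(k_range) < 3) stop("k_range must contain >= 3 values",
                                call. = FALSE)
  if (any(diff(k_range) != 1) || min(k_range) < 1) {
    stop("k_range must be contiguous with min >= 1", call. = FALSE)
  }
  obs <- as_obs(x)
  wcss <- vapply(k_range, function(k) {
    lab <- if (method == "hierarchical") cluster_hierarchical(x, k) else
      cluster_kmeans(x, k, seed = seed, n_init = n_init)
    wcss_of(obs, lab)
  }, 0)
  names(wcss) <- k_range
  d2 <- diff(wcss, differences = 2)          # at interior ks
  interior <- k_range[-c(1, length(k_range))]
  k <- interior[which.max(d2)]               # which.max ties -> smallest k
  total <- wcss_of(obs, rep(1, nrow(obs)))
  weak <- max(d2) < 0.05 * total
  structure(k, wcss = wcss, weak_elbow = weak)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the average of the two label entropies;
#' invariant to permutations of the label names.
#'
#' @param a,b label vectors of equal length.
#' @param normalization "average" (default), "min" or "max" entropy.
#' @return value in [0, 1]; defined as 1 when both labelings are constant.
#' @export
nmi <- function(a, b, normalization = c("average", "min", "max")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("label vectors differ in length",
                                   call. = FALSE)
  if (!length(a)) stop("empty labelings", call. = FALSE)
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ha <- ent(pa); hb <- ent(pb)
  mi <- sum(p[p > 0] * log(p[p > 0] /
                             (outer(pa, pb)[as.matrix(p) > 0])))
  denom <- switch(normalization,
                  average = (ha + hb) / 2,
                  min = min(ha, hb),
                  max = max(ha, hb))
  if (denom == 0) return(if (ha == 0 && hb == 0) 1 else 0)
  max(0, min(1, mi / denom))
}

#' Consensus cluster count via inter-algorithm NMI
#'
#' For each k in \code{k_range}, clusters by both algorithms and computes
#' NMI between the two partitions; returns the k with the highest NMI
#' (ties to the smallest k) plus the full NMI-by-k table.
#'
#' @inheritParams elbow_select
#' @return selected k with attribute \code{nmi_by_k}.
#' @export
consensus_k <- function(x, k_range = 2:6, seed = 1, n_init = 25) {
  vals <- vapply(k_range, function(k) {
    nmi(cluster_hierarchical(x, k),
        cluster_kmeans(x, k, seed = seed, n_init = n_init))
  }, 0)
  names(vals) <- k_range
  structure(k_range[which.max(vals)], nmi_by_k = vals)
}

## Exact maximum-trace alignment of two label spaces: brute force over all
## permutations (k <= 8, exact where an LSAP solver would approximate
## nothing anyway at this size).
align_permutation <- function(cont) {
  k <- nrow(cont)
  if (k > 8) stop("label alignment supports k <= 8", call. = FALSE)
  perms <- permutations_of(k)
  traces <- vapply(seq_len(nrow(perms)), function(i)
    sum(cont[cbind(seq_len(k), perms[i, ])]), 0)
  perms[which.max(traces), ]
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

#' Consensus labels from two clusterings
#'
#' Aligns the k-means label space to the hierarchical one by
#' maximum-agreement matching on the contingency table, then marks samples
#' whose aligned labels disagree as \code{"inconsistent"}; only consistent
#' samples carry a consensus subtype.
#'
#' @param hier,km label vectors over the same samples with the same k.
#' @return a \code{subtype_assignment} list: \code{hierarchical_labels},
#'   \code{kmeans_labels} (aligned), \code{consensus_label} (character,
#'   \code{"inconsistent"} where the algorithms disagree), \code{k},
#'   \code{retained} (count of consistent samples).
#' @export
consensus_labels <- function(hier, km) {
  if (length(hier) != length(km)) stop("length mismatch", call. = FALSE)
  k1 <- length(unique(hier)); k2 <- length(unique(km))
  if (k1 != k2) stop("clusterings have different k (", k1, " vs ", k2, ")",
                     call. = FALSE)
  cont <- as.matrix(table(factor(hier, levels = sort(unique(hier))),
                          factor(km, levels = sort(unique(km)))))
  perm <- align_permutation(cont)
  ## perm[i] = km column matched to hier row i -> rename km labels
  km_levels <- sort(unique(km))
  hier_levels <- sort(unique(hier))
  map <- stats::setNames(hier_levels, km_levels[perm])
  km_aligned <- unname(map[as.character(km)])
  names(km_aligned) <- names(km)
  consensus <- ifelse(hier == km_aligned, as.character(hier), "inconsistent")
  names(consensus) <- names(hier)
  structure(list(hierarchical_labels = hier,
                 kmeans_labels = km_aligned,
                 consensus_label = consensus,
                 k = k1,
                 retained = sum(hier == km_aligned)),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("Consensus subtype assignment: k =", x$k, "\n")
  cat("  consistent samples:", x$retained, "/",
      length(x$consensus_label), "\n")
  print(table(x$consensus_label))
  invisible(x)
}
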