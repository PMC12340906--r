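#' Per-cluster median methylation profiles
#'
#' @param beta probes x samples matrix (beta values on the shared probe
#'   set).
#' @param labels named cluster labels; only samples present in both
#'   \code{labels} and \code{colnames(beta)} are used, and labels equal to
#'   \code{exclude} are dropped.
#' @param probes optional probe subset (e.g. the clustering probe set).
#' @param exclude labels to drop (default the consensus "inconsistent"
#'   marker).
#' @return probes x clusters matrix of per-probe medians.
#' @export
median_profiles <- function(beta, labels, probes = NULL,
                            exclude = "inconsistent") {
  stop_if_not_matrix(beta, "beta")
  labels <- labels[names(labels) %in% colnames(beta)]
  labels <- labels[!(labels %in% exclude)]
  if (!length(labels)) stop("no labelled samples in beta", call. = FALSE)
  if (!is.null(probes)) beta <- beta[intersect(probes, rownames(beta)), ,
                                     drop = FALSE]
  cl <- sort(unique(as.character(labels)))
  out <- vapply(cl, function(g) {
    idx <- names(labels)[labels == g]
    if (!length(idx)) stop("empty cluster: ", g, call. = FALSE)
    apply(beta[, idx, drop = FALSE], 1, stats::median)
  }, numeric(nrow(beta)))
  dimnames(out) <- list(rownames(beta), cl)
  out
}

#' Correlate cluster median profiles and match clusters across cohorts
#'
#' Pearson correlation between every discovery/replication cluster-profile
#' pair, followed by a mutual-best one-to-one matching: a pair is matched
#' when its r is both the row and the column maximum and exceeds
#' \code{min_r}.
#'
#' @param profiles_a,profiles_b probes x clusters median-profile matrices
#'   sharing >= 2 probes.
#' @param min_r minimum correlation for an accepted match.
#' @return list with \code{r} (clusters_a x clusters_b), \code{matching}
#'   (data frame a, b, r).
#' @export
correlate_and_match <- function(profiles_a, profiles_b, min_r = 0) {
  shared <- intersect(rownames(profiles_a), rownames(profiles_b))
  if (length(shared) < 2) stop("need >= 2 shared probes", call. = FALSE)
  a <- profiles_a[shared, , drop = FALSE]
  b <- profiles_b[shared, , drop = FALSE]
  r <- suppressWarnings(stats::cor(a, b))   # NA for zero-variance profiles
  match_rows <- list()
  for (i in seq_len(nrow(r))) {
    j <- which.max(r[i, ])
    if (!length(j) || is.na(r[i, j])) next
    if (r[i, j] >= min_r && which.max(r[, j]) == i) {
      match_rows[[length(match_rows) + 1L]] <-
        data.frame(a = rownames(r)[i], b = colnames(r)[j], r = r[i, j],
                   stringsAsFactors = FALSE)
    }
  }
  matching <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(a = character(), b = character(), r = numeric())
  list(r = r, matching = matching)
}

## Point-in-convex-polygon with boundary counted inside: all cross products
## with polygon edges share a sign (within tolerance).
points_in_hull <- function(pts, hull, tol = 1e-9) {
  nh <- nrow(hull)
  if (nh < 3) return(rep(NA, nrow(pts)))
  inside <- rep(TRUE, nrow(pts))
  ## orientation of the hull polygon
  area2 <- sum(hull[, 1] * hull[c(2:nh, 1), 2] -
                 hull[c(2:nh, 1), 1] * hull[, 2])
  s <- sign(area2)
  scale <- max(abs(hull)) + 1
  for (e in seq_len(nh)) {
    p1 <- hull[e, ]; p2 <- hull[if (e == nh) 1 else e + 1, ]
    cr <- (p2[1] - p1[1]) * (pts[, 2] - p1[2]) -
      (p2[2] - p1[2]) * (pts[, 1] - p1[1])
    inside <- inside & (s * cr >= -tol * scale^2)
  }
  inside
}

#' Convex-hull projection replication test
#'
#' Projects replication-cohort samples onto the first two latent components
#' of a discovery sPLS-DA model, draws the 2-D convex hull of each
#' discovery cluster, counts replication samples falling inside each hull
#' (boundary inclusive; a sample inside several hulls counts for each), and
#' tests each (replication cluster, discovery hull) overlap with an
#' upper-tail hypergeometric test over all projected replication samples.
#'
#' @param model \code{splsda_model} fitted on the discovery cohort.
#' @param discovery_labels named cluster labels of the discovery samples.
#' @param replication_x probes x samples matrix for the replication cohort
#'   (same value type the model was fitted on).
#' @param replication_labels named cluster labels of the replication
#'   samples.
#' @return list with \code{contingency} (replication clusters x discovery
#'   hulls, plus an \code{outside} column), \code{p} (hypergeometric
#'   p-values), \code{inside_total} per hull, \code{degenerate} hull flags.
#' @export
hull_projection_test <- function(model, discovery_labels, replication_x,
                                 replication_labels) {
  disc_scores <- model$scores[, 1:2, drop = FALSE]
  rep_scores <- predict(model, replication_x)[, 1:2, drop = FALSE]
  hull_test_scores(disc_scores, discovery_labels, rep_scores,
                   replication_labels)
}

## Core hull test on already-projected 2-D scores (used directly for null
## calibration simulations).
hull_test_scores <- function(disc_scores, discovery_labels, rep_scores,
                             replication_labels) {
  if (!is.null(rownames(disc_scores)) && !is.null(names(discovery_labels))) {
    discovery_labels <- discovery_labels[rownames(disc_scores)]
  }
  dl <- sort(unique(as.character(stats::na.omit(discovery_labels))))
  rl <- sort(unique(as.character(replication_labels)))
  rep_lab <- if (!is.null(rownames(rep_scores)) &&
                 !is.null(names(replication_labels))) {
    as.character(replication_labels[rownames(rep_scores)])
  } else as.character(replication_labels)
  n <- nrow(rep_scores)
  membership <- matrix(FALSE, n, length(dl), dimnames = list(NULL, dl))
  degenerate <- stats::setNames(rep(FALSE, length(dl)), dl)
  for (g in dl) {
    pts <- disc_scores[which(discovery_labels == g), , drop = FALSE]
    pts_u <- unique(round(pts, 12))
    if (nrow(pts_u) < 3) { degenerate[g] <- TRUE; next }
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    membership[, g] <- points_in_hull(rep_scores, hull)
  }
  cont <- t(vapply(rl, function(j) {
    idx <- rep_lab == j
    c(colSums(membership[idx, , drop = FALSE]),
      outside = sum(rowSums(membership[idx, , drop = FALSE]) == 0))
  }, numeric(length(dl) + 1)))
  rownames(cont) <- rl
  inside_total <- colSums(membership)
  p <- matrix(NA_real_, length(rl), length(dl), dimnames = list(rl, dl))
  for (j in rl) {
    nj <- sum(rep_lab == j)
    for (g in dl) {
      if (degenerate[g]) next
      p[j, g] <- stats::phyper(cont[j, g] - 1, inside_total[g],
                               n - inside_total[g], nj, lower.tail = FALSE)
    }
  }
  list(contingency = cont, p = p, inside_total = inside_total,
       degenerate = degenerate)
}

## Pairwise replication report for one ordered cohort pair under one
## clustering method: correlation matching + directional hull test.
replicate_pair <- function(disc, rep_, method, keepX, ncomp = 2) {
  lab_d <- disc$labels[[method]]
  lab_r <- rep_$labels[[method]]
  prof_d <- median_profiles(disc$beta, lab_d, probes = disc$probes)
  prof_r <- median_profiles(rep_$beta, lab_r, probes = disc$probes)
  corr <- correlate_and_match(prof_d, prof_r)
  model <- splsda_fit(disc$adjusted[disc$probes, names(lab_d)], lab_d,
                      ncomp = ncomp,
                      keepX = min(keepX, length(disc$probes)))
  hull <- hull_projection_test(model, lab_d,
                               rep_$adjusted[, names(lab_r), drop = FALSE],
                               lab_r)
  list(correlation = corr, hull = hull)
}

#' Confirm subtypes across cohorts
#'
#' A subtype is confirmed only when a set of clusters, one per cohort, is
#' mutually matched by median-profile correlation and significant in the
#' convex-hull projection test in every direction, under both clustering
#' methods. Clusters in no such clique are flagged Unassigned.
#'
#' @param cohorts named list, one element per cohort, each a list with
#'   \code{adjusted} (probes x samples residuals), \code{beta} (probes x
#'   samples beta values on the shared probe set), \code{probes}
#'   (clustering probe ids), and \code{labels}, itself a list with
#'   \code{hierarchical} and \code{kmeans} named label vectors over the
#'   clustered (disease) samples.
#' @param alpha significance level for the hull tests, Bonferroni-corrected
#'   across cluster pairs within each direction.
#' @param min_r minimum correlation for a profile match.
#' @param keepX,ncomp sPLS-DA settings for the projection models.
#' @param methods clustering methods that must both validate a clique.
#' @return object of class \code{replication_report}: \code{confirmed}
#'   (list of subtype -> named cluster vector, one entry per cohort, named
#'   S1, S2, ... by decreasing total size), \code{unassigned} (data frame
#'   cohort, cluster), \code{pair_reports} (per method, per ordered pair).
#' @export
confirm_subtypes <- function(cohorts, alpha = 0.05, min_r = 0,
                             keepX = 50, ncomp = 2,
                             methods = c("hierarchical", "kmeans")) {
  if (length(cohorts) < 2) stop("need >= 2 cohorts", call. = FALSE)
  cn <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  names(cohorts) <- cn
  pair_reports <- list()
  edge <- list()   # per method: list of accepted directed matches
  for (m in methods) {
    accepted <- list()
    for (a in cn) for (b in setdiff(cn, a)) {
      rp <- replicate_pair(cohorts[[a]], cohorts[[b]], m, keepX, ncomp)
      pair_reports[[m]][[paste(a, b, sep = "->")]] <- rp
      n_tests <- sum(!is.na(rp$hull$p))
      thr <- alpha / max(n_tests, 1)
      ok <- rp$correlation$matching
      keep <- logical(nrow(ok))
      for (i in seq_len(nrow(ok))) {
        pv <- rp$hull$p[ok$b[i], ok$a[i]]   # replication cluster in disc hull
        keep[i] <- !is.na(pv) && pv < thr && ok$r[i] >= min_r
      }
      accepted[[paste(a, b, sep = "->")]] <- ok[keep, c("a", "b"),
                                               drop = FALSE]
    }
    edge[[m]] <- accepted
  }

  ## a directed pair (a:ca) -> (b:cb) survives when accepted in both
  ## directions under every method
  pair_ok <- function(a, ca, b, cb) {
    all(vapply(methods, function(m) {
      f <- edge[[m]][[paste(a, b, sep = "->")]]
      g <- edge[[m]][[paste(b, a, sep = "->")]]
      any(f$a == ca & f$b == cb) && any(g$a == cb & g$b == ca)
    }, TRUE))
  }

  clusters_of <- lapply(cohorts, function(co)
    sort(unique(as.character(co$labels[[methods[1]]]))))
  ## enumerate cliques: one cluster per cohort, all pairs mutually matched
  grids <- expand.grid(clusters_of, stringsAsFactors = FALSE)
  names(grids) <- cn
  confirmed <- list()
  used <- stats::setNames(lapply(cn, function(x) character(0)), cn)
  sizes <- numeric(0)
  for (i in seq_len(nrow(grids))) {
    tup <- unlist(grids[i, , drop = TRUE])
    ok <- TRUE
    for (a_i in seq_along(cn)) for (b_i in seq_along(cn)) {
      if (a_i >= b_i) next
      if (!pair_ok(cn[a_i], tup[a_i], cn[b_i], tup[b_i])) { ok <- FALSE
        break }
    }
    if (ok) {
      confirmed[[length(confirmed) + 1L]] <- stats::setNames(tup, cn)
      sizes <- c(sizes, sum(vapply(cn, function(a)
        sum(cohorts[[a]]$labels[[methods[1]]] == tup[a]), 0)))
    }
  }
  ## mutual-best matching makes cliques disjoint; order by total size
  if (length(confirmed)) {
    confirmed <- confirmed[order(-sizes)]
    names(confirmed) <- paste0("S", seq_along(confirmed))
    for (s in confirmed) for (a in cn) used[[a]] <- c(used[[a]], s[[a]])
  }
  unassigned <- do.call(rbind, lapply(cn, function(a) {
    left <- setdiff(clusters_of[[a]], used[[a]])
    if (length(left)) data.frame(cohort = a, cluster = left,
                                 stringsAsFactors = FALSE)
  }))
  if (is.null(unassigned)) {
    unassigned <- data.frame(cohort = character(), cluster = character())
  }
  structure(list(confirmed = confirmed, unassigned = unassigned,
                 pair_reports = pair_reports),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Cross-cohort replication:", length(x$confirmed),
      "confirmed subtype(s)\n")
  for (s in names(x$confirmed)) {
    cat("  ", s, ": ",
        paste(names(x$confirmed[[s]]), x$confirmed[[s]], sep = ":",
              collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$unassigned)) {
    cat("  Unassigned clusters:",
        paste(x$unassigned$cohort, x$unassigned$cluster, sep = ":",
              collapse = ", "), "\n")
  }
  invisible(x)
}
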