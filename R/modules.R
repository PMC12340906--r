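#' Detect co-methylation modules by correlation-distance clustering
#'
#' Average-linkage hierarchical clustering of probes on the distance
#' 1 - |Pearson r|, cut at a fixed height; clusters smaller than
#' \code{min_module_size} go to the unassigned ("grey") module "0".
#' This is a deliberately simple module detector: the package uses modules
#' only as a cross-platform robustness check, so the full weighted-network
#' machinery (soft thresholding, topological overlap) is not reproduced.
#'
#' @param adjusted probes x samples matrix.
#' @param min_module_size smallest retained module.
#' @param cut_height tree cut height on the 1 - |r| scale.
#' @return list of class \code{module_set}: \code{modules} (module id ->
#'   probe ids; "0" = unassigned), \code{membership} named vector.
#' @export
detect_modules <- function(adjusted, min_module_size = 10,
                           cut_height = 0.25) {
  stop_if_not_matrix(adjusted, "adjusted")
  r <- stats::cor(t(adjusted))
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  membership <- ifelse(as.character(raw) %in% keep, as.character(raw), "0")
  names(membership) <- rownames(adjusted)
  ## renumber retained modules by decreasing size
  kept_sizes <- sort(table(membership[membership != "0"]),
                     decreasing = TRUE)
  map <- stats::setNames(as.character(seq_along(kept_sizes)),
                         names(kept_sizes))
  membership[membership != "0"] <- map[membership[membership != "0"]]
  mods <- split(names(membership), membership)
  structure(list(modules = mods, membership = membership),
            class = "module_set")
}

#' Module eigenprobe: first principal component of a probe module
#'
#' Probes are standardized, the first right singular vector gives one
#' score per sample, sign-aligned to correlate positively with the module
#' mean profile.
#'
#' @param submatrix probes x samples matrix of one module's probes.
#' @return named per-sample score vector with attribute
#'   \code{var_explained}.
#' @export
eigenprobe <- function(submatrix) {
  stop_if_not_matrix(submatrix, "submatrix")
  z <- t(scale(t(submatrix)))
  z[is.na(z)] <- 0                     # constant probes carry no signal
  sv <- svd(z, nu = 0, nv = 1)
  score <- sv$v[, 1]
  mean_profile <- colMeans(z)
  if (stats::sd(mean_profile) > 0 &&
      stats::cor(score, mean_profile) < 0) {
    score <- -score
  }
  names(score) <- colnames(submatrix)
  structure(score, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' One-way ANOVA of an eigenprobe across cluster labels, with Tukey HSD
#'
#' @param scores named per-sample eigenprobe scores.
#' @param labels named cluster labels over the same samples.
#' @return list with \code{F}, \code{p}, \code{tukey} (pairwise table from
#'   \code{\link[stats]{TukeyHSD}}).
#' @export
module_anova <- function(scores, labels) {
  labels <- labels[names(scores)]
  df <- data.frame(score = as.numeric(scores), grp = factor(labels))
  fit <- stats::aov(score ~ grp, data = df)
  an <- summary(fit)[[1]]
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = stats::TukeyHSD(fit)$grp)
}

#' Cross-platform preservation test of cluster-associated modules
#'
#' For each module associated with the cluster labels (ANOVA p < alpha on
#' the full probe set), recomputes the eigenprobe on the probe subset
#' available on the reduced platform and declares the module preserved
#' when (i) the subset eigenprobe still separates the clusters (ANOVA
#' p < alpha) and (ii) full and subset eigenprobes do not differ within
#' any cluster (paired t-test, all p > alpha).
#'
#' @param modules a \code{\link{detect_modules}} result.
#' @param full_data probes x samples matrix (all probes).
#' @param subset_probes probe ids available on the reduced platform.
#' @param labels named cluster labels.
#' @param alpha significance level for both criteria.
#' @return data frame: module, n_probes, n_subset, p_full, p_subset,
#'   min_paired_p, preserved (NA for modules not cluster-associated).
#' @export
preservation_test <- function(modules, full_data, subset_probes, labels,
                              alpha = 0.05) {
  mods <- modules$modules
  mods <- mods[names(mods) != "0"]
  rows <- lapply(names(mods), function(mid) {
    probes <- mods[[mid]]
    sub <- intersect(probes, subset_probes)
    ep_full <- eigenprobe(full_data[probes, , drop = FALSE])
    a_full <- module_anova(ep_full, labels)
    row <- data.frame(module = mid, n_probes = length(probes),
                      n_subset = length(sub), p_full = a_full$p,
                      p_subset = NA_real_, min_paired_p = NA_real_,
                      preserved = NA, stringsAsFactors = FALSE)
    if (a_full$p >= alpha) return(row)     # not cluster-associated
    if (length(sub) < 3) { row$preserved <- FALSE; return(row) }
    ep_sub <- eigenprobe(full_data[sub, , drop = FALSE])
    ## PC sign/scale is arbitrary; align subset scores to the full ones
    if (stats::cor(ep_full, ep_sub) < 0) ep_sub <- -ep_sub
    a_sub <- module_anova(ep_sub, labels)
    lab <- labels[names(ep_full)]
    paired_p <- vapply(unique(lab), function(g) {
      i <- which(lab == g)
      if (length(i) < 3) return(NA_real_)
      stats::t.test(ep_full[i], ep_sub[i], paired = TRUE)$p.value
    }, 0)
    row$p_subset <- a_sub$p
    row$min_paired_p <- suppressWarnings(min(paired_p, na.rm = TRUE))
    row$preserved <- a_sub$p < alpha &&
      all(paired_p > alpha, na.rm = TRUE)
    row
  })
  do.call(rbind, rows)
}
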