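#' Discover and replicate methylation subtypes across cohorts
#'
#' End-to-end discovery pipeline: harmonize probes across platforms,
#' residualize on covariates, select variable probes, cluster each
#' cohort's disease samples with Ward.D2 hierarchical and k-means
#' clustering (k chosen by inter-algorithm NMI), form consensus labels,
#' and confirm subtypes across cohorts by median-profile correlation plus
#' sPLS-DA convex-hull projection under both clustering methods.
#'
#' @param beta_list named list of probes x samples beta matrices, one per
#'   cohort.
#' @param samples_list matching list of sample sheets (must contain
#'   \code{sample_id} and \code{diagnosis}; disease samples are labelled
#'   \code{"LOAD"}).
#' @param covariates covariate columns residualized out before clustering.
#' @param k_range candidate cluster counts.
#' @param top_fraction fraction of most-variable probes retained for
#'   clustering.
#' @param keepX,ncomp sPLS-DA settings for the replication projections.
#' @param alpha hull-test significance level (Bonferroni within
#'   direction).
#' @param min_r minimum profile correlation for a match.
#' @param seed RNG seed (k-means restarts).
#' @return object of class \code{subtype_result}: \code{assignments}
#'   (named subtype per disease sample: "S1", "S2", ... or "Unassigned"),
#'   \code{replication} (\code{\link{confirm_subtypes}} report),
#'   \code{cohorts} (per-cohort k, NMI-by-k table, consensus assignment,
#'   clustering probes), \code{shared_probes}.
#' @export
discover_subtypes <- function(beta_list, samples_list,
                              covariates = c("age", "sex"),
                              k_range = 1:6, top_fraction = 0.1,
                              keepX = 50, ncomp = 2, alpha = 0.05,
                              min_r = 0, seed = 1) {
  stopifnot(length(beta_list) == length(samples_list))
  cn <- names(beta_list) %||% paste0("cohort", seq_along(beta_list))
  names(beta_list) <- names(samples_list) <- cn
  shared <- harmonize_platforms(beta_list)

  cohorts <- list()
  meta <- list()
  for (co in cn) {
    st <- samples_list[[co]]
    adj <- residualize(beta_list[[co]][shared, , drop = FALSE], st,
                       covariates)
    load_ids <- intersect(colnames(adj),
                          st$sample_id[st$diagnosis == "LOAD"])
    adj_load <- adj[, load_ids, drop = FALSE]
    probes <- variance_filter(adj_load, top_fraction = top_fraction)
    xm <- adj_load[probes, , drop = FALSE]
    ## elbow per algorithm proposes candidate k's; inter-algorithm NMI
    ## arbitrates among them (ties to the smallest k)
    k_hier <- elbow_select(xm, k_range, "hierarchical")
    k_km <- elbow_select(xm, k_range, "kmeans", seed = seed)
    cands <- sort(unique(c(as.integer(k_hier), as.integer(k_km))))
    nmi_k <- consensus_k(xm, max(2, min(k_range)):max(k_range),
                         seed = seed)
    nmi_by_k <- attr(nmi_k, "nmi_by_k")
    k <- if (length(cands) == 1) cands else
      cands[which.max(nmi_by_k[as.character(cands)])]
    hier <- cluster_hierarchical(xm, k)
    km <- cluster_kmeans(xm, k, seed = seed)
    cons <- consensus_labels(hier, km)
    cohorts[[co]] <- list(
      adjusted = adj_load,
      beta = beta_list[[co]][shared, load_ids, drop = FALSE],
      probes = as.character(probes),
      labels = list(hierarchical = hier, kmeans = cons$kmeans_labels))
    meta[[co]] <- list(k = k, elbow_k = c(hierarchical = as.integer(k_hier),
                                          kmeans = as.integer(k_km)),
                       nmi_by_k = nmi_by_k,
                       consensus = cons, probes = as.character(probes))
  }

  rep_report <- confirm_subtypes(cohorts, alpha = alpha, min_r = min_r,
                                 keepX = keepX, ncomp = ncomp)

  assignments <- character(0)
  for (co in cn) {
    cons <- meta[[co]]$consensus$consensus_label
    call <- rep("Unassigned", length(cons))
    names(call) <- names(cons)
    for (s in names(rep_report$confirmed)) {
      cl <- rep_report$confirmed[[s]][[co]]
      call[cons == cl] <- s
    }
    assignments <- c(assignments, call)
  }
  structure(list(assignments = assignments, replication = rep_report,
                 cohorts = meta, shared_probes = shared),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("Methylation subtype discovery across", length(x$cohorts),
      "cohorts\n")
  for (co in names(x$cohorts)) {
    cat(sprintf("  %s: k = %d (NMI %.3f)\n", co, x$cohorts[[co]]$k,
                max(x$cohorts[[co]]$nmi_by_k)))
  }
  print(x$replication)
  cat("Sample-level calls:\n")
  print(table(x$assignments))
  invisible(x)
}

#' Subtype EWAS with empirical-null correction and meta-analysis
#'
#' Per-cohort subtype-vs-control EWAS (optionally with surrogate
#' variables), bacon-style empirical-null correction per cohort where
#' needed, inverse-variance meta-analysis across cohorts, and Bonferroni
#' DMP calling.
#'
#' @param values_list named list of probes x samples matrices (shared
#'   probe universe; typically covariate-residualized beta values).
#' @param samples_list matching sample sheets.
#' @param group_list matching named subtype labels ("HC" for controls).
#' @param contrast subtype to test (or "LOAD").
#' @param covariates covariates for the per-cohort models.
#' @param n_sv surrogate variables per cohort (0 to disable, "auto" for
#'   permutation selection).
#' @param correct apply \code{\link{empirical_null_correct}} per cohort.
#' @param method meta-analysis method ("random" REML or "fixed").
#' @param alpha Bonferroni family-wise level.
#' @return list of class \code{ewas_meta_result}: \code{per_cohort}
#'   (corrected EWAS tables with lambda attributes), \code{meta},
#'   \code{dmps}, \code{lambdas}.
#' @export
ewas_meta_pipeline <- function(values_list, samples_list, group_list,
                               contrast, covariates = character(),
                               n_sv = 0, correct = TRUE,
                               method = "random", alpha = 0.05) {
  cn <- names(values_list) %||% paste0("cohort", seq_along(values_list))
  names(values_list) <- cn
  per_cohort <- list()
  lambdas <- numeric(0)
  for (co in cn) {
    v <- values_list[[co]]
    grp <- group_list[[co]]
    sv <- NULL
    if (!identical(n_sv, 0)) {
      is_case <- grp[colnames(v)] == contrast |
        (contrast == "LOAD" & grp[colnames(v)] != "HC")
      design <- cbind(1, as.numeric(is_case))
      sv <- estimate_svs(v, design, n_sv = n_sv)
      if (ncol(sv) == 0) sv <- NULL
    }
    ew <- ewas(v, samples_list[[co]], grp, contrast,
               covariates = covariates, surrogate_vars = sv)
    lambdas[co] <- as.numeric(attr(ew, "lambda_inflation"))
    if (correct) {
      cor_ <- empirical_null_correct(ew$effect, ew$se)
      ew$effect <- cor_$effect; ew$se <- cor_$se
      ew$z <- cor_$z; ew$p <- cor_$p
      attr(ew, "bacon") <- c(mu = attr(cor_, "bias_mu"),
                             sigma = attr(cor_, "inflation_sigma"),
                             applied = attr(cor_, "applied"))
    }
    per_cohort[[co]] <- ew
  }
  probes <- Reduce(intersect, lapply(per_cohort, `[[`, "probe_id"))
  eff <- vapply(per_cohort, function(d)
    d$effect[match(probes, d$probe_id)], numeric(length(probes)))
  ses <- vapply(per_cohort, function(d)
    d$se[match(probes, d$probe_id)], numeric(length(probes)))
  rownames(eff) <- rownames(ses) <- probes
  meta <- ivw_meta(eff, ses, method = method)
  dmps <- call_dmps(meta, alpha = alpha)
  structure(list(per_cohort = per_cohort, meta = meta,
                 dmps = as.character(dmps), lambdas = lambdas),
            class = "ewas_meta_result")
}
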