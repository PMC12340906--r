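#' Low-expression gene filter
#'
#' Drops genes whose count falls below \code{min_count} in strictly more
#' than \code{max_frac} of samples.
#'
#' @param counts genes x samples integer matrix.
#' @param min_count,max_frac rule parameters (defaults: counts below 10 in
#'   over 80\% of samples).
#' @return character vector of retained gene ids.
#' @export
low_expression_filter <- function(counts, min_count = 10, max_frac = 0.80) {
  stop_if_not_matrix(counts, "counts")
  frac_low <- rowMeans(counts < min_count)
  rownames(counts)[frac_low <= max_frac]
}

#' TMM normalization and logCPM transformation
#'
#' Trimmed-mean-of-M-values scale factors (30\% M-trim, 5\% A-trim,
#' reference library closest to the upper-quartile mean) and log2
#' counts-per-million with a 0.5 prior count against effective library
#' sizes, via edgeR.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return genes x samples log2-CPM matrix with attribute
#'   \code{norm_factors}.
#' @export
tmm_logcpm <- function(counts) {
  stop_if_not_matrix(counts, "counts")
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(colSums(counts) == 0)) stop("zero library size", call. = FALSE)
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  out <- edgeR::cpm(dge, log = TRUE, prior.count = 0.5)
  attr(out, "norm_factors") <- dge$samples$norm.factors
  out
}

## Inverse of trigamma by Newton iteration (for the moments fit of the
## variance prior df).
trigamma_inv <- function(x) {
  if (x <= 0) return(Inf)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Moderated differential expression on log-expression values
#'
#' Per-gene OLS of log2 expression on a group indicator plus covariates
#' and optional surrogate variables, with residual variances shrunk toward
#' a common prior by a method-of-moments fit of a scaled
#' inverse-chi-square (prior df d0, scale s0^2); the moderated t has
#' d_residual + d0 degrees of freedom. \code{prior_df = 0} reproduces the
#' ordinary t; \code{prior_df = Inf} the fully pooled variance.
#'
#' @param logcpm genes x samples log-expression matrix.
#' @param samples sample sheet with sample_id.
#' @param group named labels per sample.
#' @param contrast label of the test group.
#' @param reference label of the reference group (samples in neither group
#'   are excluded).
#' @param covariates covariate column names in \code{samples}.
#' @param surrogate_vars optional samples x k matrix (rows follow
#'   \code{colnames(logcpm)}).
#' @param prior_df NULL (estimate, default), 0, a positive value, or Inf.
#' @param bacon if TRUE, apply \code{\link{empirical_null_correct}} to the
#'   resulting z-scores.
#' @return data frame: gene_id, log2FC, se, t, df_total, p (class
#'   \code{de_result}; attributes \code{d0}, \code{s0_2}).
#' @export
de_moderated <- function(logcpm, samples, group, contrast, reference,
                         covariates = character(), surrogate_vars = NULL,
                         prior_df = NULL, bacon = FALSE) {
  stop_if_not_matrix(logcpm, "logcpm")
  group <- group[colnames(logcpm)]
  keep <- which(group %in% c(contrast, reference))
  if (sum(group == contrast, na.rm = TRUE) < 3 ||
      sum(group == reference, na.rm = TRUE) < 3) {
    stop("contrast groups must each have >= 3 samples", call. = FALSE)
  }
  v <- logcpm[, keep, drop = FALSE]
  ind <- as.numeric(group[keep] == contrast)
  design <- cbind(`(Intercept)` = 1, group = ind)
  if (length(covariates)) {
    st <- samples[match(colnames(v), samples$sample_id), , drop = FALSE]
    mm <- stats::model.matrix(stats::reformulate(covariates), data = st)
    design <- cbind(design, mm[, -1, drop = FALSE])
  }
  if (!is.null(surrogate_vars)) {
    design <- cbind(design, surrogate_vars[keep, , drop = FALSE])
  }
  fit <- fit_ols_matrix(v, design, coef_idx = 2L)
  d <- fit$df
  s2 <- fit$sigma2

  if (is.null(prior_df)) {
    ## method of moments on log s^2 (Fisher-z style): var(e) in excess of
    ## trigamma(d/2) is attributed to the prior
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    ev <- stats::var(e) - trigamma(d / 2)
    if (is.na(ev) || ev <= 0) {
      d0 <- Inf
      s0_2 <- mean(s2)
    } else {
      d0 <- 2 * trigamma_inv(ev)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    d0 <- prior_df
    s0_2 <- if (is.finite(d0) && d0 > 0) exp(mean(log(s2))) else mean(s2)
  }
  s2_mod <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    if (d0 == 0) s2 else (d0 * s0_2 + d * s2) / (d0 + d)
  df_total <- min(d + d0, length(s2) * d)   # capped at the pooled df
  se_mod <- fit$se * sqrt(s2_mod / s2)
  tmod <- fit$effect / se_mod
  p <- 2 * stats::pt(-abs(tmod), df_total)
  out <- data.frame(gene_id = rownames(v), log2FC = fit$effect,
                    se = se_mod, t = tmod, df_total = df_total, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (bacon) {
    corr <- empirical_null_correct(out$log2FC, out$se)
    out$log2FC <- corr$effect; out$se <- corr$se
    out$t <- corr$z; out$p <- corr$p
    attr(out, "bacon") <- c(mu = attr(corr, "bias_mu"),
                            sigma = attr(corr, "inflation_sigma"))
  }
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  class(out) <- c("de_result", class(out))
  out
}

#' Cross-cohort consistency filter for differentially expressed genes
#'
#' A gene is selected when its nominal p is below \code{p_thresh} in every
#' cohort, its fold change exceeds \code{fc_thresh} in at least one
#' cohort, and the direction of effect is identical across cohorts.
#'
#' @param de_tables named list of per-cohort \code{\link{de_moderated}}
#'   tables (inner-joined on gene_id; genes missing anywhere are dropped).
#' @param p_thresh nominal p cutoff applied in all cohorts.
#' @param fc_thresh fold-change cutoff (linear scale) required in >= 1
#'   cohort; applied as |log2FC| > log2(fc_thresh).
#' @return data frame (class \code{deg_table}): gene_id, per-cohort
#'   log2FC and p columns, pass_p_all, pass_fc_any, consistent_sign,
#'   selected.
#' @export
cross_cohort_deg_filter <- function(de_tables, p_thresh = 0.05,
                                    fc_thresh = 1.5) {
  if (length(de_tables) < 2) stop("need >= 2 cohorts", call. = FALSE)
  cn <- names(de_tables) %||% paste0("cohort", seq_along(de_tables))
  genes <- Reduce(intersect, lapply(de_tables, `[[`, "gene_id"))
  lfc <- vapply(de_tables, function(d) d$log2FC[match(genes, d$gene_id)],
                numeric(length(genes)))
  pv <- vapply(de_tables, function(d) d$p[match(genes, d$gene_id)],
               numeric(length(genes)))
  colnames(lfc) <- paste0("log2FC_", cn)
  colnames(pv) <- paste0("p_", cn)
  pass_p_all <- rowSums(pv < p_thresh) == ncol(pv)
  pass_fc_any <- rowSums(abs(lfc) > log2(fc_thresh)) >= 1
  consistent_sign <- apply(sign(lfc), 1, function(s)
    all(s == s[1]) && all(s != 0))
  out <- data.frame(gene_id = genes, lfc, pv,
                    pass_p_all = pass_p_all, pass_fc_any = pass_fc_any,
                    consistent_sign = consistent_sign,
                    selected = pass_p_all & pass_fc_any & consistent_sign,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("deg_table", class(out))
  out
}

#' Pseudobulk aggregation of single-cell counts per cell state
#'
#' Sums counts over all cells of each sample within each state (exact
#' integer identity) and flags states for inclusion: every compared group
#' must have at least \code{min_cells} cells per sample on average and at
#' least \code{min_depth} summed counts per sample on average.
#'
#' @param counts genes x cells integer matrix.
#' @param cells data frame with cell_id, sample_id, state (rows cover
#'   \code{colnames(counts)}).
#' @param groups named sample-level group labels (used for the inclusion
#'   rule; optional).
#' @param min_cells,min_depth inclusion thresholds.
#' @return list of class \code{pseudobulk_set}: per state a list with
#'   \code{counts} (genes x samples summed), \code{cells_per_sample},
#'   \code{included} flag; attribute \code{included_states}.
#' @export
pseudobulk <- function(counts, cells, groups = NULL, min_cells = 10,
                       min_depth = 1000) {
  stop_if_not_matrix(counts, "counts")
  cells <- cells[match(colnames(counts), cells$cell_id), ]
  states <- sort(unique(cells$state))
  out <- list()
  for (s in states) {
    idx <- which(cells$state == s)
    samp <- cells$sample_id[idx]
    agg <- t(rowsum(t(counts[, idx, drop = FALSE]), group = samp))
    nc <- table(samp)
    nc <- stats::setNames(as.integer(nc), names(nc))
    included <- TRUE
    check_groups <- if (is.null(groups)) list(all = names(nc)) else
      split(names(nc), groups[names(nc)])
    for (g in check_groups) {
      if (!length(g) || mean(nc[g]) < min_cells ||
          mean(colSums(agg[, g, drop = FALSE])) < min_depth) {
        included <- FALSE
      }
    }
    out[[s]] <- list(counts = agg, cells_per_sample = nc,
                     included = included)
  }
  structure(out, included_states = states[vapply(out, `[[`, TRUE,
                                                 "included")],
            class = "pseudobulk_set")
}

#' Subtype-specific gene selection from per-state differential expression
#'
#' Within each cell state, a gene is selected when it is significant in the
#' subtype-vs-subtype comparison and also significant versus controls in at
#' least one subtype; the pooled list is deduplicated across states.
#'
#' @param state_de named list (per state) of lists with elements
#'   \code{s1_vs_s2}, \code{s1_vs_hc}, \code{s2_vs_hc}, each a data frame
#'   with gene_id and p.
#' @param p_thresh significance threshold.
#' @return list with \code{per_state} (gene vectors) and \code{pooled}
#'   (unique genes across states).
#' @export
state_deg_selection <- function(state_de, p_thresh = 0.05) {
  per_state <- lapply(state_de, function(d) {
    sig <- function(tb) tb$gene_id[!is.na(tb$p) & tb$p < p_thresh]
    s12 <- sig(d$s1_vs_s2)
    vs_hc <- union(sig(d$s1_vs_hc), sig(d$s2_vs_hc))
    sort(intersect(s12, vs_hc))
  })
  list(per_state = per_state,
       pooled = sort(unique(unlist(per_state, use.names = FALSE))))
}
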