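#' Simulation configuration for the multi-cohort generator
#'
#' Builds the configuration object consumed by all synthetic-data generators.
#' Defaults describe the study conditions the package is designed around:
#' three independent brain cohorts profiled on EPIC-like arrays (the last
#' cohort on a 450K-like probe subset), two latent disease subtypes shared by
#' all cohorts, and one additional cluster present in a single cohort.
#'
#' Methylation is simulated on the logit (M-value-like) scale with Gaussian
#' noise and inverse-logit transformed, so beta values stay in (0,1) while
#' covariate and subtype effects are exactly linear on the modelling scale.
#'
#' @param n_cohorts number of cohorts.
#' @param n_samples_per_cohort disease (LOAD) samples per cohort.
#' @param n_controls healthy-control samples per cohort.
#' @param n_probes CpG probes simulated per cohort (before platform masking).
#' @param n_shared_subtypes latent subtypes present in every cohort.
#' @param cohort_specific_cluster if TRUE, cohort 1 carries an extra latent
#'   cluster absent from the other cohorts (the "Unassigned" phenomenon).
#' @param cohort_specific_fraction fraction of cohort 1's disease samples in
#'   the cohort-specific cluster.
#' @param frac_subtype_cpgs fraction of probes differentially methylated in
#'   each subtype (disjoint sets across subtypes).
#' @param delta_beta methylation-fraction shift at causal CpGs (beta scale).
#' @param noise_sd residual SD on the logit scale.
#' @param covariate_effects named list of logit-scale slopes for age, sex,
#'   cell proportion and batch effects.
#' @param platform_mask fraction of probes present on the 450K-like array
#'   (the last cohort is restricted to this subset).
#' @param n_genes,n_causal_genes,fold_change,nb_dispersion bulk RNA settings:
#'   gene count, causal genes per subtype, planted fold change, and
#'   negative-binomial dispersion.
#' @param n_states microglial cell states for the single-cell generator.
#' @param cells_per_state mean cells per sample and state (the last two
#'   states are simulated sparse, below typical inclusion thresholds).
#' @param n_sc_genes genes in the single-cell counts.
#' @param panel_or planted odds ratio of the enriched cell-type panel.
#' @param n_regions_per_scenario genomic regions per colocalization scenario
#'   (shared / distinct / null).
#' @param n_variants_per_region variants per region.
#' @param seed integer seed; fully determines all generator output.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_cohorts = 3,
                       n_samples_per_cohort = 150,
                       n_controls = 75,
                       n_probes = 5000,
                       n_shared_subtypes = 2,
                       cohort_specific_cluster = TRUE,
                       cohort_specific_fraction = 0.3,
                       frac_subtype_cpgs = 0.05,
                       delta_beta = 0.1,
                       noise_sd = 0.3,
                       covariate_effects = list(age = 0.004, sex = 0.05,
                                                cell = 0.5, batch = 0.05),
                       platform_mask = 0.6,
                       n_genes = 2000,
                       n_causal_genes = 50,
                       fold_change = 2,
                       nb_dispersion = 0.2,
                       n_states = 12,
                       cells_per_state = 30,
                       n_sc_genes = 1000,
                       panel_or = 8,
                       n_regions_per_scenario = 4,
                       n_variants_per_region = 100,
                       seed = 1) {
  fracs <- c(cohort_specific_fraction, frac_subtype_cpgs, delta_beta,
             platform_mask)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_shared_subtypes < 1) stop("n_shared_subtypes must be >= 1",
                                  call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

subtype_names <- function(config) {
  shared <- paste0("S", seq_len(config$n_shared_subtypes))
  if (isTRUE(config$cohort_specific_cluster)) c(shared, "CS1") else shared
}

## Per-cohort disease-sample subtype labels. The cohort-specific cluster
## lives in cohort 1 only; shared subtypes split the remainder evenly.
assign_subtypes <- function(config, cohort) {
  n <- config$n_samples_per_cohort
  shared <- paste0("S", seq_len(config$n_shared_subtypes))
  if (isTRUE(config$cohort_specific_cluster) && cohort == 1L) {
    n_cs <- round(config$cohort_specific_fraction * n)
    lab <- c(rep("CS1", n_cs),
             rep(shared, length.out = n - n_cs))
  } else {
    lab <- rep(shared, length.out = n)
  }
  sample(lab)   # shuffle so subtype is not confounded with sample order
}

sim_sample_table <- function(config, cohort) {
  n_load <- config$n_samples_per_cohort
  n_hc <- config$n_controls
  n <- n_load + n_hc
  cp <- matrix(stats::rgamma(n * 5, shape = c(10, 6, 2, 3, 1)), ncol = 5,
               byrow = TRUE)
  cp <- cp / rowSums(cp)
  colnames(cp) <- paste0("prop_",
                         c("neuron", "oligo", "microglia", "astro", "other"))
  df <- data.frame(
    sample_id = sprintf("C%d_S%03d", cohort, seq_len(n)),
    diagnosis = c(rep("LOAD", n_load), rep("HC", n_hc)),
    age = round(stats::rnorm(n, 75, 8), 1),
    sex = stats::rbinom(n, 1, 0.5),
    postmortem_interval = round(stats::rnorm(n, 24, 6), 1),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    cohort = paste0("cohort", cohort),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(cp))
}

#' Generate synthetic multi-cohort methylation data
#'
#' Simulates beta matrices (probes x samples), sample sheets and a ground
#' truth object for \code{n_cohorts} cohorts sharing latent disease subtypes.
#' Subtype and covariate effects are applied on the logit scale and
#' inverse-logit transformed; the last cohort's matrix is restricted to the
#' 450K-like probe subset recorded in the probe annotation.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return list with elements \code{beta} (list of probes x samples
#'   matrices, with \code{cohort} and \code{platform} attributes),
#'   \code{samples} (list of sample-sheet data frames), \code{annotation}
#'   (probe annotation with \code{platform_450k} flag) and \code{truth}
#'   (subtype labels, causal CpG sets and effect signs).
#' @export
generate_methylation_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_probes
  probe_ids <- sprintf("cg%07d", seq_len(p))

  base_mu <- with_substream(config$seed, "probe_base",
                            stats::runif(p, 0.15, 0.85))
  platform_450k <- with_substream(config$seed, "platform",
                                  stats::rbinom(p, 1, config$platform_mask))

  sn <- subtype_names(config)
  n_causal <- round(config$frac_subtype_cpgs * p)
  causal <- with_substream(config$seed, "causal_cpgs", {
    pool <- sample(probe_ids)
    split_idx <- split(seq_len(n_causal * length(sn)),
                       rep(seq_along(sn), each = n_causal))
    stats::setNames(lapply(split_idx, function(i) sort(pool[i])), sn)
  })
  signs <- with_substream(config$seed, "causal_signs",
    stats::setNames(lapply(sn, function(s)
      stats::setNames(sample(c(-1, 1), n_causal, replace = TRUE),
                      causal[[s]])), sn))

  ## logit-scale effect sized so the beta-scale shift equals delta_beta
  logit_effect <- function(mu, sign) {
    tgt <- pmin(pmax(mu + sign * config$delta_beta, 0.02), 0.98)
    logit(tgt) - logit(mu)
  }

  ce <- config$covariate_effects
  cov_probes <- with_substream(config$seed, "cov_probes", {
    lapply(stats::setNames(nm = c("age", "sex", "cell", "batch")),
           function(nm) sample.int(p, round(0.3 * p)))
  })

  beta_list <- list()
  sample_list <- list()
  subtype_of_sample <- character(0)

  for (co in seq_len(config$n_cohorts)) {
    res <- with_substream(config$seed, paste0("cohort", co), {
      st <- sim_sample_table(config, co)
      lab <- rep("HC", nrow(st))
      lab[st$diagnosis == "LOAD"] <- assign_subtypes(config, co)
      n <- nrow(st)
      x <- matrix(logit(base_mu), nrow = p, ncol = n) +
        matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
      for (s in sn) {
        idx <- match(causal[[s]], probe_ids)
        in_s <- which(lab == s)
        if (length(in_s)) {
          x[idx, in_s] <- x[idx, in_s] +
            logit_effect(base_mu[idx], signs[[s]])
        }
      }
      age_c <- st$age - mean(st$age)
      cellv <- st$prop_neuron - mean(st$prop_neuron)
      batchv <- as.numeric(st$batch == "b2")
      x[cov_probes$age, ] <- x[cov_probes$age, ] +
        outer(rep(ce$age, length(cov_probes$age)), age_c)
      x[cov_probes$sex, ] <- x[cov_probes$sex, ] +
        outer(rep(ce$sex, length(cov_probes$sex)), st$sex)
      x[cov_probes$cell, ] <- x[cov_probes$cell, ] +
        outer(rep(ce$cell, length(cov_probes$cell)), cellv)
      x[cov_probes$batch, ] <- x[cov_probes$batch, ] +
        outer(rep(ce$batch, length(cov_probes$batch)), batchv)
      beta <- inv_logit(x)
      dimnames(beta) <- list(probe_ids, st$sample_id)
      list(beta = beta, samples = st, labels = stats::setNames(lab,
                                                               st$sample_id))
    })
    is_450k <- co == config$n_cohorts && config$n_cohorts > 1
    b <- res$beta
    if (is_450k) b <- b[platform_450k == 1, , drop = FALSE]
    attr(b, "cohort") <- paste0("cohort", co)
    attr(b, "platform") <- if (is_450k) "450K-like" else "EPIC-like"
    beta_list[[co]] <- b
    sample_list[[co]] <- res$samples
    subtype_of_sample <- c(subtype_of_sample, res$labels)
  }
  names(beta_list) <- names(sample_list) <-
    paste0("cohort", seq_len(config$n_cohorts))

  truth <- list(subtype_of_sample = subtype_of_sample,
                causal_cpgs = causal,
                causal_signs = signs,
                subtypes = sn)
  list(beta = beta_list, samples = sample_list,
       annotation = data.frame(probe_id = probe_ids,
                               platform_450k = platform_450k,
                               stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate synthetic bulk RNA counts per cohort
#'
#' Negative-binomial counts with per-subtype causal genes carrying the
#' configured fold change with a consistent direction across cohorts.
#'
#' @param config a \code{\link{sim_config}} object.
#' @param truth truth object from \code{\link{generate_methylation_cohorts}}
#'   (same seed lineage).
#' @return list with \code{counts} (list of genes x samples integer
#'   matrices) and \code{truth} gaining \code{causal_genes}.
#' @export
generate_expression_data <- function(config, truth) {
  g <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(g))
  base <- with_substream(config$seed, "gene_base",
                         exp(stats::rnorm(g, log(100), 1)))
  shared <- paste0("S", seq_len(config$n_shared_subtypes))
  causal_genes <- with_substream(config$seed, "causal_genes", {
    pool <- sample(gene_ids)
    idx <- split(seq_len(config$n_causal_genes * length(shared)),
                 rep(seq_along(shared), each = config$n_causal_genes))
    stats::setNames(lapply(idx, function(i) sort(pool[i])), shared)
  })
  gene_signs <- with_substream(config$seed, "gene_signs",
    stats::setNames(lapply(shared, function(s)
      stats::setNames(sample(c(-1, 1), config$n_causal_genes, TRUE),
                      causal_genes[[s]])), shared))

  counts <- list()
  for (co in seq_len(config$n_cohorts)) {
    cname <- paste0("cohort", co)
    ids <- names(truth$subtype_of_sample)
    ids <- ids[startsWith(ids, sprintf("C%d_", co))]
    lab <- truth$subtype_of_sample[ids]
    counts[[cname]] <- with_substream(config$seed, paste0("rna_", co), {
      n <- length(ids)
      libfac <- exp(stats::rnorm(n, 0, 0.3))
      mu <- matrix(base, g, n)
      for (s in shared) {
        gi <- match(causal_genes[[s]], gene_ids)
        si <- which(lab == s)
        if (length(si)) {
          fc <- config$fold_change ^ gene_signs[[s]]
          mu[gi, si] <- mu[gi, si] * fc
        }
      }
      mu <- sweep(mu, 2, libfac, "*")
      m <- matrix(stats::rnbinom(g * n, mu = mu,
                                 size = 1 / config$nb_dispersion), g, n)
      dimnames(m) <- list(gene_ids, ids)
      attr(m, "cohort") <- cname
      m
    })
  }
  truth$causal_genes <- causal_genes
  truth$gene_signs <- gene_signs
  list(counts = counts, truth = truth)
}

#' Generate synthetic single-cell counts with microglial-state labels
#'
#' Cell-level negative-binomial counts for one cohort, with per-state planted
#' differentially expressed genes specific to subtype S1 (up-regulated vs
#' both the other subtype and controls). The last two states are simulated
#' sparse, so they fall below typical pseudobulk inclusion thresholds.
#'
#' @param config a \code{\link{sim_config}} object.
#' @param truth truth object from the same seed lineage.
#' @param cohort cohort index whose samples receive cells (default last).
#' @return list with \code{counts} (genes x cells), \code{cells}
#'   (data frame with cell_id, sample_id, state) and augmented truth
#'   (\code{sc_causal_genes} per state).
#' @export
generate_sc_counts <- function(config, truth, cohort = config$n_cohorts) {
  g <- config$n_sc_genes
  gene_ids <- sprintf("gene%05d", seq_len(g))
  states <- paste0("MG", seq_len(config$n_states) - 1)
  ids <- names(truth$subtype_of_sample)
  ids <- ids[startsWith(ids, sprintf("C%d_", cohort))]
  lab <- truth$subtype_of_sample[ids]

  with_substream(config$seed, "sc", {
    base <- exp(stats::rnorm(g, log(2), 1))
    sc_causal <- stats::setNames(lapply(states, function(s)
      sort(sample(gene_ids, 25))), states)
    lam <- rep(config$cells_per_state, length(states))
    if (length(states) >= 2) lam[(length(states) - 1):length(states)] <- 2
    cells <- do.call(rbind, lapply(seq_along(ids), function(i) {
      nc <- stats::rpois(length(states), lam)
      data.frame(sample_id = ids[i],
                 state = rep(states, nc),
                 stringsAsFactors = FALSE)
    }))
    cells$cell_id <- sprintf("cell%06d", seq_len(nrow(cells)))
    mu <- matrix(base, g, nrow(cells))
    for (s in states) {
      gi <- match(sc_causal[[s]], gene_ids)
      ci <- which(cells$state == s &
                    lab[match(cells$sample_id, ids)] == "S1")
      if (length(ci)) mu[gi, ci] <- mu[gi, ci] * config$fold_change
    }
    m <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$nb_dispersion),
                g, nrow(cells))
    dimnames(m) <- list(gene_ids, cells$cell_id)
    truth$sc_causal_genes <- sc_causal
    list(counts = m, cells = cells[, c("cell_id", "sample_id", "state")],
         truth = truth)
  })
}

#' Generate synthetic cell-type CpG panels
#'
#' Builds panels for four brain cell types at three nested specificity
#' levels (level 1 most specific). The microglia level-1 panel is enriched
#' for the causal CpGs of the last shared subtype at the configured odds
#' ratio; higher levels add non-enriched probes, diluting the enrichment.
#'
#' @param config a \code{\link{sim_config}} object.
#' @param truth truth object carrying \code{causal_cpgs}.
#' @return list with \code{panels} (data frame: cell_type,
#'   specificity_level, probe_ids as list-column) and augmented truth
#'   (\code{enriched_panel}).
#' @export
generate_celltype_panels <- function(config, truth) {
  probe_ids <- sprintf("cg%07d", seq_len(config$n_probes))
  target_subtype <- paste0("S", config$n_shared_subtypes)
  causal <- truth$causal_cpgs[[target_subtype]]
  types <- c("neuron", "oligodendrocyte", "microglia", "astrocyte")

  with_substream(config$seed, "panels", {
    p0 <- 0.06                               # baseline inclusion rate
    odds0 <- p0 / (1 - p0)
    p1 <- config$panel_or * odds0 / (1 + config$panel_or * odds0)
    n_extra <- round(p0 * config$n_probes)
    rows <- list()
    for (ty in types) {
      enr <- ty == "microglia"
      take1 <- probe_ids[ifelse(probe_ids %in% causal & enr,
                                stats::runif(config$n_probes) < p1,
                                stats::runif(config$n_probes) < p0)]
      extra2 <- sample(setdiff(probe_ids, take1), n_extra)
      extra3 <- sample(setdiff(probe_ids, c(take1, extra2)), 2 * n_extra)
      lv <- list(sort(take1), sort(c(take1, extra2)),
                 sort(c(take1, extra2, extra3)))
      for (l in 1:3) {
        rows[[length(rows) + 1L]] <-
          list(cell_type = ty, specificity_level = l, probe_ids = lv[[l]])
      }
    }
    panels <- data.frame(
      cell_type = vapply(rows, `[[`, "", "cell_type"),
      specificity_level = vapply(rows, `[[`, 0L, "specificity_level"),
      stringsAsFactors = FALSE)
    panels$probe_ids <- lapply(rows, `[[`, "probe_ids")
    truth$enriched_panel <- list(cell_type = "microglia",
                                 specificity_level = 1L,
                                 subtype = target_subtype)
    list(panels = panels, truth = truth)
  })
}

#' Generate paired association summary statistics per genomic region
#'
#' For each region, simulates an mQTL track and a GWAS track over the same
#' variants under one of three scenarios: \code{shared} (one common causal
#' variant), \code{distinct} (different causal variants) or \code{null}
#' (no association). Effect sizes and standard errors are consistent with
#' the stated sample sizes and allele frequencies under a standardized-trait
#' regression model; linkage is a single-block exponential decay of the
#' marginal effect around the causal variant.
#'
#' @param config a \code{\link{sim_config}} object.
#' @param truth truth object (augmented with the scenario map).
#' @param n_mqtl,n_gwas sample sizes behind the two tracks.
#' @return list with \code{regions} (per region: two data frames
#'   \code{mqtl}, \code{gwas} with variant_id, beta, se, p, maf, n) and
#'   augmented truth (\code{coloc_scenario_of_region}).
#' @export
generate_summary_stats <- function(config, truth, n_mqtl = 500,
                                   n_gwas = 50000) {
  scen <- rep(c("shared", "distinct", "null"),
              each = config$n_regions_per_scenario)
  region_ids <- sprintf("region%02d", seq_along(scen))
  nv <- config$n_variants_per_region

  track <- function(maf, n, causal_idx, causal_beta) {
    se <- 1 / sqrt(2 * n * maf * (1 - maf))
    marg <- rep(0, nv)
    if (!is.na(causal_idx)) {
      ld <- exp(-abs(seq_len(nv) - causal_idx) / 2)
      marg <- causal_beta * ld
    }
    beta <- marg + stats::rnorm(nv, 0, se)
    data.frame(variant_id = sprintf("rs%04d", seq_len(nv)),
               beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(beta / se)),
               maf = maf, n = n, stringsAsFactors = FALSE)
  }

  regions <- with_substream(config$seed, "sumstats", {
    out <- list()
    for (i in seq_along(scen)) {
      maf <- stats::runif(nv, 0.1, 0.5)
      ci_m <- ci_g <- NA_integer_
      if (scen[i] == "shared") ci_m <- ci_g <- sample(20:(nv - 20), 1)
      if (scen[i] == "distinct") {
        ci_m <- sample(10:(nv %/% 2 - 10), 1)
        ci_g <- sample((nv %/% 2 + 10):(nv - 10), 1)
      }
      out[[region_ids[i]]] <- list(
        mqtl = track(maf, n_mqtl, ci_m, 0.6),
        gwas = track(maf, n_gwas, ci_g, 0.06))
    }
    out
  })
  truth$coloc_scenario_of_region <- stats::setNames(scen, region_ids)
  list(regions = regions, truth = truth)
}
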