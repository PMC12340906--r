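test_that("generators are seed-deterministic and substream-isolated", {
  cfg <- small_config(seed = 11)
  s1 <- generate_methylation_cohorts(cfg)
  s2 <- generate_methylation_cohorts(cfg)
  expect_identical(s1, s2)

  e1 <- generate_expression_data(cfg, s1$truth)
  e2 <- generate_expression_data(cfg, s2$truth)
  expect_identical(e1$counts, e2$counts)

  ## running another generator in between must not perturb outputs
  invisible(generate_summary_stats(cfg, s1$truth))
  expect_identical(generate_methylation_cohorts(cfg)$beta, s1$beta)

  cfg2 <- small_config(seed = 12)
  expect_false(identical(generate_methylation_cohorts(cfg2)$beta[[1]],
                         s1$beta[[1]]))
})

test_that("invalid configuration fractions are rejected", {
  expect_error(sim_config(frac_subtype_cpgs = 1.5), "fractions")
  expect_error(sim_config(delta_beta = -0.1), "fractions")
  expect_error(sim_config(n_shared_subtypes = 0), "n_shared_subtypes")
})

test_that("beta values are valid and the last cohort is 450K-masked", {
  cfg <- small_config(seed = 3)
  sim <- generate_methylation_cohorts(cfg)
  for (b in sim$beta) {
    expect_true(all(b > 0 & b < 1))
  }
  ann <- sim$annotation
  expect_setequal(rownames(sim$beta[[cfg$n_cohorts]]),
                  ann$probe_id[ann$platform_450k == 1])
  expect_identical(attr(sim$beta[[cfg$n_cohorts]], "platform"), "450K-like")
  expect_identical(attr(sim$beta[[1]], "platform"), "EPIC-like")
  ## every sample has exactly one truth label
  ids <- unlist(lapply(sim$samples, `[[`, "sample_id"))
  expect_setequal(names(sim$truth$subtype_of_sample), ids)
})

test_that("planted beta shift is recovered by group means on truth labels", {
  cfg <- sim_config(seed = 5)   # study-scale: n=150/cohort, delta 0.1
  sim <- generate_methylation_cohorts(cfg)
  truth <- sim$truth
  beta <- sim$beta[[1]]
  lab <- truth$subtype_of_sample[colnames(beta)]
  diffs <- unlist(lapply(c("S1", "S2"), function(s) {
    cg <- intersect(truth$causal_cpgs[[s]], rownames(beta))
    sgn <- truth$causal_signs[[s]][cg]
    in_s <- lab == s
    d <- rowMeans(beta[cg, in_s, drop = FALSE]) -
      rowMeans(beta[cg, !in_s, drop = FALSE])
    d * sgn
  }))
  expect_equal(mean(diffs), cfg$delta_beta, tolerance = 0.3)
  expect_gt(mean(diffs), cfg$delta_beta - 0.03)
  expect_lt(mean(diffs), cfg$delta_beta + 0.03)
})

test_that("no-signal configuration gives chance-level clustering", {
  cfg <- small_config(seed = 9, delta_beta = 0,
                      covariate_effects = list(age = 0, sex = 0, cell = 0,
                                               batch = 0))
  sim <- generate_methylation_cohorts(cfg)
  st <- sim$samples[[1]]
  load_ids <- st$sample_id[st$diagnosis == "LOAD"]
  lab <- cluster_hierarchical(sim$beta[[1]][, load_ids], 2)
  truth_lab <- sim$truth$subtype_of_sample[load_ids]
  expect_lt(nmi(lab, truth_lab), 0.15)
})

test_that("expression generator plants recoverable fold changes", {
  cfg <- small_config(seed = 13)
  sim <- generate_methylation_cohorts(cfg)
  ex <- generate_expression_data(cfg, sim$truth)
  cnt <- ex$counts[[1]]
  lab <- sim$truth$subtype_of_sample[colnames(cnt)]
  cg <- ex$truth$causal_genes$S1
  sgn <- ex$truth$gene_signs$S1[cg]
  up <- cg[sgn > 0]
  ratio <- rowMeans(cnt[up, lab == "S1", drop = FALSE]) /
    rowMeans(cnt[up, lab == "HC", drop = FALSE])
  expect_equal(mean(ratio), cfg$fold_change, tolerance = 0.25)
  expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
})

test_that("single-cell generator labels cells and plants sparse states", {
  cfg <- small_config(seed = 17)
  sim <- generate_methylation_cohorts(cfg)
  sc <- generate_sc_counts(cfg, sim$truth)
  expect_identical(colnames(sc$counts), sc$cells$cell_id)
  n_per_state <- table(sc$cells$state)
  states <- paste0("MG", seq_len(cfg$n_states) - 1)
  ## the two last states are simulated sparse
  expect_lt(n_per_state[states[cfg$n_states]],
            n_per_state[states[1]] / 3)
})

test_that("cell-type panels are nested and carry the planted enrichment", {
  cfg <- small_config(seed = 19)
  sim <- generate_methylation_cohorts(cfg)
  pn <- generate_celltype_panels(cfg, sim$truth)
  p <- pn$panels
  for (ty in unique(p$cell_type)) {
    l1 <- p$probe_ids[[which(p$cell_type == ty & p$specificity_level == 1)]]
    l2 <- p$probe_ids[[which(p$cell_type == ty & p$specificity_level == 2)]]
    l3 <- p$probe_ids[[which(p$cell_type == ty & p$specificity_level == 3)]]
    expect_true(all(l1 %in% l2) && all(l2 %in% l3))
  }
  expect_identical(pn$truth$enriched_panel$cell_type, "microglia")
})

test_that("summary-statistic scenarios place causal variants as declared", {
  cfg <- small_config(seed = 23)
  ss <- generate_summary_stats(cfg, list())
  scen <- ss$truth$coloc_scenario_of_region
  expect_setequal(unique(scen), c("shared", "distinct", "null"))
  ## null regions should rarely contain suggestive mQTLs
  for (rg in names(scen)[scen == "null"]) {
    expect_lt(sum(ss$regions[[rg]]$mqtl$p < 1e-5), 2)
  }
  ## shared regions must contain at least one strong signal in both tracks
  for (rg in names(scen)[scen == "shared"]) {
    expect_true(any(ss$regions[[rg]]$mqtl$p < 1e-5))
    expect_true(any(ss$regions[[rg]]$gwas$p < 1e-5))
  }
  expect_true(all(ss$regions[[1]]$mqtl$se > 0))
})
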