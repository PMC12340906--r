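test_that("low-expression filter applies the strict 'over 80%' rule", {
  counts <- rbind(
    all_high = rep(50L, 20),
    low_85 = c(rep(1L, 17), rep(50L, 3)),    # low in 85% -> dropped
    low_80 = c(rep(1L, 16), rep(50L, 4)),    # low in exactly 80% -> kept
    boundary = rep(10L, 20))                 # count == 10 is not low
  colnames(counts) <- paste0("s", 1:20)
  keep <- low_expression_filter(counts)
  expect_setequal(keep, c("all_high", "low_80", "boundary"))
})

test_that("TMM factors match composition invariants and the hand oracle", {
  set.seed(8)
  counts <- matrix(rpois(12, c(100, 200, 300, 50, 400, 80)), 6, 2)
  counts[, 2] <- counts[, 2] * 2 + rpois(6, 5)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("g", 1:6), c("s1", "s2"))

  ## hand-computed doubly-trimmed weighted mean of M values
  tmm_pair <- function(obs, ref, No, Nr) {
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    M <- log2((obs / No) / (ref / Nr))
    A <- 0.5 * log2((obs / No) * (ref / Nr))
    v <- (No - obs) / (No * obs) + (Nr - ref) / (Nr * ref)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    k2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k2] / v[k2]) / sum(1 / v[k2]))
  }
  lib <- colSums(counts)
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  refcol <- which.min(abs(f75 - mean(f75)))
  f_hand <- vapply(1:2, function(j)
    tmm_pair(counts[, j], counts[, refcol], lib[j], lib[refcol]), 0)
  f_hand <- f_hand / exp(mean(log(f_hand)))
  lc <- tmm_logcpm(counts)
  expect_equal(attr(lc, "norm_factors"), f_hand, tolerance = 1e-10)

  ## identical columns: all factors 1
  same <- cbind(s1 = counts[, 1], s2 = counts[, 1], s3 = counts[, 1])
  expect_equal(attr(tmm_logcpm(same), "norm_factors"), rep(1, 3),
               tolerance = 1e-10)
  ## pure depth scaling: factor stays 1, logCPM unchanged
  sc <- cbind(s1 = counts[, 1], s2 = counts[, 1] * 2L)
  lcs <- tmm_logcpm(sc)
  expect_equal(attr(lcs, "norm_factors"), rep(1, 2), tolerance = 1e-6)
  expect_equal(lcs[, 1], lcs[, 2], tolerance = 0.02)
  expect_error(tmm_logcpm(cbind(a = c(0L, 0L))), ">= 2 samples")
})

test_that("moderated DE matches its prior-df limits and the reference", {
  set.seed(21)
  g <- 300; n <- 30
  lc <- matrix(rnorm(g * n, 5, 1), g, n,
               dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  grp <- setNames(rep(c("A", "B"), each = n / 2), colnames(lc))
  st <- data.frame(sample_id = colnames(lc))

  ## d0 = 0: ordinary t (checked per gene against lm)
  de0 <- de_moderated(lc, st, grp, "A", "B", prior_df = 0)
  for (i in c(1, 50, 300)) {
    fit <- summary(lm(lc[i, ] ~ I(grp == "A")))
    expect_equal(de0$t[i], fit$coefficients[2, "t value"],
                 tolerance = 1e-10)
  }
  ## d0 = Inf: pooled-variance t
  deI <- de_moderated(lc, st, grp, "A", "B", prior_df = Inf)
  s2 <- vapply(seq_len(g), function(i)
    summary(lm(lc[i, ] ~ I(grp == "A")))$sigma^2, 0)
  expect_equal(deI$t, de0$t * sqrt(s2 / mean(s2)), tolerance = 1e-8)

  ## estimated shrinkage agrees with the reference empirical-Bayes fit
  de <- de_moderated(lc, st, grp, "A", "B")
  design <- cbind(1, as.numeric(grp == "A"))
  ref <- limma::eBayes(limma::lmFit(lc, design))
  expect_equal(attr(de, "d0"), ref$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s0_2"), ref$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(ref$t[, 2]), tolerance = 1e-10)
  expect_equal(de$p, unname(ref$p.value[, 2]), tolerance = 1e-10)

  ## null p-values are uniform
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("cross-cohort DEG filter reproduces the rule table exactly", {
  mk <- function(lfc, p) data.frame(gene_id = paste0("g", seq_along(lfc)),
                                    log2FC = lfc, p = p)
  tabs <- list(
    c1 = mk(c(0.7, 0.7, 0.2, 0.7, 0.7), c(0.01, 0.2, 0.01, 0.01, 0.01)),
    c2 = mk(c(0.2, 0.7, 0.3, -0.6, 0.2), c(0.02, 0.01, 0.02, 0.01, 0.02)),
    c3 = mk(c(0.1, 0.7, 0.4, 0.5, 0.1), c(0.03, 0.01, 0.03, 0.01, 0.03)))
  deg <- cross_cohort_deg_filter(tabs)
  ## g1: p ok everywhere, FC > 1.5 in cohort 1, consistent sign -> selected
  expect_true(deg$selected[deg$gene_id == "g1"])
  ## g2: p fails in cohort 1
  expect_false(deg$selected[deg$gene_id == "g2"])
  expect_false(deg$pass_p_all[deg$gene_id == "g2"])
  ## g3: no cohort reaches |log2FC| > log2(1.5)
  expect_false(deg$pass_fc_any[deg$gene_id == "g3"])
  ## g4: sign flip in cohort 2
  expect_false(deg$consistent_sign[deg$gene_id == "g4"])
  ## g5: same as g1 -> selected
  expect_true(deg$selected[deg$gene_id == "g5"])
  expect_error(cross_cohort_deg_filter(tabs[1]), ">= 2")

  ## monotonicity: relaxing thresholds never drops a selected gene
  relaxed <- cross_cohort_deg_filter(tabs, p_thresh = 0.1,
                                     fc_thresh = 1.2)
  expect_true(all(deg$gene_id[deg$selected] %in%
                    relaxed$gene_id[relaxed$selected]))
})

test_that("planted bulk DEGs are recovered across cohorts", {
  cfg <- sim_config(seed = 111, n_samples_per_cohort = 100,
                    n_controls = 50, n_probes = 200)
  sim <- generate_methylation_cohorts(cfg)
  ex <- generate_expression_data(cfg, sim$truth)
  tabs <- lapply(names(ex$counts), function(co) {
    cnt <- ex$counts[[co]]
    lc <- tmm_logcpm(cnt[low_expression_filter(cnt), ])
    grp <- sim$truth$subtype_of_sample[colnames(lc)]
    de_moderated(lc, sim$samples[[co]], grp, "S1", "HC")
  })
  names(tabs) <- names(ex$counts)
  deg <- cross_cohort_deg_filter(tabs)
  causal <- ex$truth$causal_genes$S1
  recovery <- mean(causal %in% deg$gene_id[deg$selected])
  expect_gte(recovery, 0.9)
  fp <- setdiff(deg$gene_id[deg$selected], causal)
  expect_lt(length(fp), 0.02 * nrow(deg))
})

test_that("pseudobulk sums are exact and inclusion rules apply", {
  counts <- matrix(c(1, 2, 0,
                     0, 1, 3,
                     5, 0, 1), 3, 3,
                   dimnames = list(paste0("g", 1:3),
                                   paste0("c", 1:3)))
  cells <- data.frame(cell_id = paste0("c", 1:3),
                      sample_id = c("sA", "sA", "sB"),
                      state = "MG0")
  pb <- pseudobulk(counts, cells, min_cells = 1, min_depth = 1)
  ## two cells (1,2,0) + (0,1,3) sum to (1,3,3)
  expect_equal(pb$MG0$counts[, "sA"], c(g1 = 1, g2 = 3, g3 = 3))
  expect_equal(pb$MG0$counts[, "sB"], c(g1 = 5, g2 = 0, g3 = 1))
  ## manual loop oracle
  manual <- sapply(c("sA", "sB"), function(s)
    rowSums(counts[, cells$cell_id[cells$sample_id == s], drop = FALSE]))
  expect_equal(pb$MG0$counts, manual)
  ## permutation invariance
  perm <- c(3, 1, 2)
  pb2 <- pseudobulk(counts[, perm], cells[perm, ], min_cells = 1,
                    min_depth = 1)
  expect_equal(pb2$MG0$counts, pb$MG0$counts)
  ## sparse state exclusion
  cells$state <- c("MG0", "MG0", "MG9")
  pb3 <- pseudobulk(counts, cells, min_cells = 2, min_depth = 1)
  expect_false(pb3$MG9$included)
  expect_false("MG9" %in% attr(pb3, "included_states"))
})

test_that("state-level gene selection applies the conjunction rule", {
  mk <- function(g, p) data.frame(gene_id = g, p = p)
  state_de <- list(MG0 = list(
    s1_vs_s2 = mk(c("g1", "g2", "g3"), c(0.01, 0.01, 0.5)),
    s1_vs_hc = mk(c("g1", "g2", "g3"), c(0.01, 0.5, 0.01)),
    s2_vs_hc = mk(c("g1", "g2", "g3"), c(0.5, 0.5, 0.01))))
  sel <- state_deg_selection(state_de)
  ## g1: subtype contrast + vs-control in S1 -> selected
  ## g2: subtype contrast only -> rejected
  ## g3: vs-control only -> rejected
  expect_identical(sel$per_state$MG0, "g1")
  expect_identical(sel$pooled, "g1")
  ## pooled list deduplicates across states
  state_de$MG1 <- state_de$MG0
  sel2 <- state_deg_selection(state_de)
  expect_identical(sel2$pooled, "g1")
})
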