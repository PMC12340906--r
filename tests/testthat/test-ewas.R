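test_that("EWAS recovers a planted shift and nulls are calibrated", {
  set.seed(91)
  n <- 200
  ids <- paste0("s", seq_len(n))
  grp <- setNames(rep(c("S1", "HC"), each = n / 2), ids)
  vals <- matrix(rnorm(500 * n, 0, 0.05), 500, n,
                 dimnames = list(sprintf("cg%03d", 1:500), ids))
  vals["cg001", grp == "S1"] <- vals["cg001", grp == "S1"] + 0.1
  st <- data.frame(sample_id = ids)
  ew <- ewas(vals, st, grp, "S1")
  hit <- ew[ew$probe_id == "cg001", ]
  expect_equal(hit$effect, 0.1, tolerance = 0.03)
  expect_lt(hit$p, 1e-6)
  lam <- attr(ew, "lambda_inflation")
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
  ## identical groups: effect exactly 0
  v2 <- vals; v2[] <- rep(rnorm(500), n)
  ew2 <- ewas(v2, st, grp, "S1")
  expect_equal(max(abs(ew2$effect)), 0, tolerance = 1e-12)
  expect_error(ewas(vals[, 1:4], st, grp[1:4], "S1"), ">= 3")
})

test_that("subtype EWAS excludes the other subtype under HC reference", {
  set.seed(92)
  ids <- paste0("s", 1:60)
  grp <- setNames(rep(c("S1", "S2", "HC"), each = 20), ids)
  vals <- matrix(rnorm(50 * 60), 50, 60,
                 dimnames = list(paste0("cg", 1:50), ids))
  ew <- ewas(vals, data.frame(sample_id = ids), grp, "S1")
  expect_equal(attr(ew, "n_case") + attr(ew, "n_ref"), 40)
  ew_rest <- ewas(vals, data.frame(sample_id = ids), grp, "S1",
                  reference = "rest")
  expect_equal(attr(ew_rest, "n_ref"), 40)
})

test_that("surrogate variables capture hidden structure and stay orthonormal", {
  set.seed(93)
  n <- 60
  vals <- matrix(rnorm(600 * n), 600, n,
                 dimnames = list(NULL, paste0("s", 1:n)))
  batch <- rep(0:1, n / 2)
  vals[1:120, ] <- vals[1:120, ] + 2 * matrix(batch, 120, n, byrow = TRUE)
  design <- cbind(1, rep(0:1, each = n / 2))
  sv <- estimate_svs(vals, design)
  expect_gte(ncol(sv), 1)
  expect_gt(abs(cor(sv[, 1], batch)), 0.9)
  expect_equal(crossprod(sv), diag(ncol(sv)), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## orthogonal to the design residual space by construction
  expect_lt(max(abs(crossprod(design, sv))), 1e-8)
  expect_error(estimate_svs(vals, design, n_sv = n), "degrees of freedom")
})

test_that("permutation rule selects zero SVs without hidden structure", {
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    vals <- matrix(rnorm(300 * 40), 300, 40,
                   dimnames = list(NULL, paste0("s", 1:40)))
    sv <- estimate_svs(vals, cbind(1, rep(0:1, each = 20)), seed = s,
                       n_perm = 40)
    hits <- hits + (ncol(sv) == 0)
  }
  expect_gte(hits, 18)
})

test_that("inflation lambda matches its definition", {
  set.seed(94)
  p <- runif(50000)
  expect_equal(as.numeric(inflation_lambda(p)), 1, tolerance = 0.02)
  z <- rnorm(50000, 0, 1.2)
  lam <- as.numeric(inflation_lambda(2 * pnorm(-abs(z))))
  expect_equal(lam, 1.44, tolerance = 0.05)
  single <- inflation_lambda(0.5)
  expect_true(attr(single, "low_n"))
  expect_true(is.finite(single))
})

test_that("empirical-null correction is the identity on calibrated input", {
  set.seed(95)
  z <- rnorm(50000)
  out <- empirical_null_correct(z, rep(1, length(z)))
  expect_lt(abs(attr(out, "bias_mu")), 0.02)
  expect_lt(abs(attr(out, "inflation_sigma") - 1), 0.02)
  expect_false(attr(out, "applied"))
  expect_equal(out$z, z)
})

test_that("empirical-null recovers bias and inflation under contamination", {
  set.seed(96)
  m <- 50000
  n_sig <- round(0.05 * m)
  z <- c(rnorm(m - n_sig, 0.3, 1.4),
         sample(c(-5, 5), n_sig, TRUE) + rnorm(n_sig, 0, 0.5))
  out <- empirical_null_correct(z, rep(1, m))
  expect_equal(attr(out, "bias_mu"), 0.3, tolerance = 0.07)
  expect_equal(attr(out, "inflation_sigma"), 1.4, tolerance = 0.07)
  expect_true(attr(out, "applied"))
  ## corrected z re-centred and re-scaled
  expect_equal(median(out$z), 0, tolerance = 0.05)
  expect_warning(empirical_null_correct(rnorm(100), rep(1, 100)),
                 "1000 probes")
  expect_error(empirical_null_correct(1, 0), "positive")
})

test_that("IVW meta closed forms hold exactly", {
  m1 <- ivw_meta(matrix(rep(0.5, 3), 1), matrix(rep(0.1, 3), 1))
  expect_equal(m1$meta_effect, 0.5, tolerance = 1e-10)
  expect_equal(m1$meta_se, 0.1 / sqrt(3), tolerance = 1e-10)
  expect_equal(m1$tau2, 0, tolerance = 1e-8)
  m2 <- ivw_meta(matrix(c(1, 3), 1), matrix(c(1, 1), 1), method = "fixed")
  expect_equal(m2$meta_effect, 2, tolerance = 1e-10)
  expect_equal(m2$meta_se, sqrt(0.5), tolerance = 1e-10)
  expect_equal(m2$Q, 2, tolerance = 1e-10)
  ## single study: passthrough with flag
  m3 <- ivw_meta(matrix(c(0.7, NA), 1), matrix(c(0.2, NA), 1))
  expect_true(m3$single_study)
  expect_equal(m3$meta_effect, 0.7)
  expect_error(ivw_meta(matrix(1, 1), matrix(0, 1)), "positive")
})

test_that("REML random-effects agree with the reference implementation", {
  set.seed(97)
  k <- 4
  eff <- matrix(rnorm(20 * k, 0.2, 0.3), 20, k)
  ses <- matrix(runif(20 * k, 0.05, 0.3), 20, k)
  mine <- ivw_meta(eff, ses, method = "random")
  for (i in seq_len(20)) {
    ref <- metafor::rma.uni(yi = eff[i, ], sei = ses[i, ], method = "REML")
    expect_equal(mine$meta_effect[i], as.numeric(ref$beta),
                 tolerance = 1e-4)
    expect_equal(mine$meta_se[i], ref$se, tolerance = 1e-4)
    expect_equal(mine$tau2[i], ref$tau2, tolerance = 1e-3)
  }
  ## fixed-effect se never exceeds the smallest study se
  fx <- ivw_meta(eff, ses, method = "fixed")
  expect_true(all(fx$meta_se <= apply(ses, 1, min) + 1e-12))
})

test_that("Bonferroni DMP calling applies the strict boundary", {
  m <- 100
  meta <- data.frame(probe_id = paste0("cg", 1:3),
                     meta_p = c(0.05 / m, 0.04 / m, 0.2))
  dmps <- call_dmps(meta, m = m)
  expect_identical(as.character(dmps), "cg2")
  bp <- attr(dmps, "bonferroni_p")
  expect_equal(unname(bp["cg1"]), 0.05)
  expect_equal(unname(bp["cg3"]), 1)   # capped at 1
})

test_that("family-wise error is controlled under the global null", {
  set.seed(98)
  reps <- 200; m <- 100; k <- 3
  fails <- 0
  for (r in seq_len(reps)) {
    eff <- matrix(rnorm(m * k, 0, 0.1), m, k)
    ses <- matrix(0.1, m, k)
    meta <- ivw_meta(eff, ses, method = "fixed")
    fails <- fails + (length(call_dmps(meta)) > 0)
  }
  ## binomial upper bound: reject if observed FWER clearly exceeds 5%
  expect_lte(fails, qbinom(0.999, reps, 0.05))
})
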