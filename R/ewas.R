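## Fast per-probe OLS: one design decomposition shared by all probes.
fit_ols_matrix <- function(y_mat, design, coef_idx) {
  n <- ncol(y_mat)
  p <- ncol(design)
  qx <- qr(design)
  if (qx$rank < p) stop("rank-deficient design", call. = FALSE)
  xtx_inv <- chol2inv(qr.R(qx))
  coefs <- y_mat %*% design %*% xtx_inv        # probes x p
  fitted <- coefs %*% t(design)
  resid <- y_mat - fitted
  df <- n - p
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 * xtx_inv[coef_idx, coef_idx])
  effect <- coefs[, coef_idx]
  tstat <- effect / se
  list(effect = effect, se = se, t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df), resid = resid, sigma2 = sigma2)
}

#' Per-probe subtype EWAS
#'
#' Ordinary least squares of each probe's (adjusted) methylation on a group
#' indicator plus covariates and optional surrogate variables. By default
#' each subtype is compared against healthy controls with the other disease
#' samples excluded; \code{reference = "rest"} switches to
#' subtype-vs-everyone-else.
#'
#' @param values probes x samples numeric matrix.
#' @param samples sample sheet with \code{sample_id} and \code{diagnosis}.
#' @param group named subtype labels per sample ("HC" for controls).
#' @param contrast the subtype tested (e.g. "S1"), or "LOAD" for the
#'   overall case-control contrast (all non-HC samples vs HC).
#' @param covariates covariate column names in \code{samples} (may be
#'   empty when \code{values} are already residualized).
#' @param surrogate_vars optional samples x k matrix of surrogate
#'   variables.
#' @param reference "HC" (default) or "rest".
#' @return data frame (class \code{ewas_result}) with probe_id, effect, se,
#'   z, p, plus attributes \code{lambda_inflation}, \code{contrast},
#'   \code{n_case}, \code{n_ref}.
#' @export
ewas <- function(values, samples, group, contrast, covariates = character(),
                 surrogate_vars = NULL, reference = c("HC", "rest")) {
  reference <- match.arg(reference)
  stop_if_not_matrix(values, "values")
  group <- group[colnames(values)]
  is_case <- if (contrast == "LOAD") group != "HC" else group == contrast
  is_ref <- if (reference == "HC") group == "HC" else !is_case
  keep <- which(is_case | is_ref)
  if (sum(is_case) < 3 || sum(is_ref) < 3) {
    stop("contrast groups must each have >= 3 samples", call. = FALSE)
  }
  v <- values[, keep, drop = FALSE]
  ind <- as.numeric(is_case[keep])
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
  out <- data.frame(probe_id = rownames(v), effect = fit$effect,
                    se = fit$se, z = fit$t, p = fit$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "lambda_inflation") <- inflation_lambda(out$p)
  attr(out, "contrast") <- contrast
  attr(out, "n_case") <- sum(is_case)
  attr(out, "n_ref") <- sum(is_ref)
  class(out) <- c("ewas_result", class(out))
  out
}

#' Surrogate-variable estimation by residual-space PCA
#'
#' Removes the modelled design from the data by OLS, then takes principal
#' components of the residual matrix as surrogate variables; they are
#' orthogonal to the design by construction of the residual space. The
#' number of components is chosen by parallel analysis: keep components
#' whose singular values exceed every leading singular value obtained from
#' per-probe permutations of the input (permuted matrices are residualized
#' the same way, so observed and permuted values are exchangeable under
#' the null).
#'
#' @param values probes x samples matrix.
#' @param design samples x q model matrix (the variation to protect).
#' @param n_sv fixed number of SVs, or "auto" for permutation selection.
#' @param n_perm permutations for the parallel analysis.
#' @param seed RNG seed for the permutations.
#' @return samples x k matrix of orthonormal surrogate variables (k may be
#'   0), with attribute \code{singular_values}.
#' @export
estimate_svs <- function(values, design, n_sv = "auto", n_perm = 20,
                         seed = 1) {
  stop_if_not_matrix(values, "values")
  n <- ncol(values)
  qx <- qr(design)
  resid <- t(qr.resid(qx, t(values)))   # probes x samples
  max_sv <- n - qx$rank - 1
  if (is.numeric(n_sv) && n_sv > max_sv) {
    stop("n_sv exceeds residual degrees of freedom", call. = FALSE)
  }
  sv <- svd(resid, nu = 0)
  k <- if (identical(n_sv, "auto")) {
    null_d1 <- with_substream(seed, "sva_perm", {
      vapply(seq_len(n_perm), function(b) {
        ## permute the raw values per probe, then residualize exactly as
        ## the observed matrix was: under the null the permuted and
        ## observed top singular values are exchangeable
        perm <- t(apply(values, 1, sample))
        perm <- t(qr.resid(qx, t(perm)))
        svd(perm, nu = 0, nv = 0)$d[1]
      }, 0)
    })
    ## conservative rule: a component is kept only when it exceeds every
    ## permuted leading singular value
    min(sum(sv$d > max(null_d1)), max_sv)
  } else min(n_sv, max_sv)
  out <- sv$v[, seq_len(k), drop = FALSE]
  rownames(out) <- colnames(values)
  if (k > 0) colnames(out) <- paste0("SV", seq_len(k))
  attr(out, "singular_values") <- sv$d
  out
}

#' Genomic inflation index of a p-value set
#'
#' Median observed chi-square(1) quantile divided by the null median
#' (0.4549...).
#'
#' @param p vector of p-values.
#' @return lambda; attribute \code{low_n} flags fewer than 100 tests.
#' @export
inflation_lambda <- function(p) {
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lam <- stats::median(chisq) / stats::qchisq(0.5, df = 1,
                                              lower.tail = FALSE)
  structure(lam, low_n = length(p) < 100)
}

## Three-component Gaussian mixture EM on z-scores. Component 1 is the
## null; the signal components are constrained to flank it (means on
## either side of the null mean) and to be at least as dispersed as the
## null, which stops them from eating the shoulders of a calibrated null.
fit_znull_mixture <- function(z, max_iter = 500, tol = 1e-8) {
  med <- stats::median(z); s <- stats::mad(z)
  mu <- c(med, med + 3 * s, med - 3 * s)
  sd_ <- c(s, 2 * s, 2 * s)
  w <- c(0.9, 0.05, 0.05)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(j) w[j] * stats::dnorm(z, mu[j], sd_[j]),
                   numeric(length(z)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    r <- dens / tot
    nk <- pmax(colSums(r), 1e-8)
    w <- nk / length(z)
    mu <- colSums(r * z) / nk
    sd_ <- sqrt(pmax(colSums(r * (z - rep(mu, each = length(z)))^2) / nk,
                     1e-6))
    ## signal components must flank the null beyond two null SDs, so they
    ## cannot eat the shoulders of a calibrated null
    mu[2] <- max(mu[2], mu[1] + 2 * sd_[1])
    mu[3] <- min(mu[3], mu[1] - 2 * sd_[1])
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) { converged <- TRUE
      break }
    ll_old <- ll
  }
  list(mu = mu[1], sigma = sd_[1], weights = w,
       mu_all = mu, sigma_all = sd_, converged = converged)
}

#' Empirical-null (bacon-style) correction of effect estimates
#'
#' Estimates the bias and inflation of the z-scores z = effect/se by
#' fitting a three-component normal mixture (null plus two signal
#' components) by EM with robust median/MAD initialization, then rescales:
#' corrected z = (z - mu)/sigma, corrected se = se * sigma, corrected
#' effect = effect - mu * se. Applied only when the estimated inflation or
#' bias exceeds \code{eps} (the "if needed" rule); otherwise inputs pass
#' through unchanged.
#'
#' @param effects,ses numeric vectors (one per probe).
#' @param eps tolerance below which no correction is applied.
#' @param force if TRUE, always rescale.
#' @return data frame with corrected effect, se, z, p; attributes
#'   \code{bias_mu}, \code{inflation_sigma}, \code{applied}.
#' @export
empirical_null_correct <- function(effects, ses, eps = 0.05, force = FALSE) {
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  z <- effects / ses
  if (length(z) < 1000) {
    warning("fewer than 1000 probes; empirical-null estimates are noisy")
  }
  fit <- fit_znull_mixture(z)
  mu <- fit$mu; sigma <- fit$sigma
  if (!fit$converged) {
    warning("EM did not converge; falling back to median/MAD null")
    mu <- stats::median(z); sigma <- stats::mad(z)
  }
  applied <- force || sigma > 1 + eps || abs(mu) > eps
  if (applied) {
    z_c <- (z - mu) / sigma
    out <- data.frame(effect = effects - mu * ses, se = ses * sigma,
                      z = z_c, p = 2 * stats::pnorm(-abs(z_c)))
  } else {
    out <- data.frame(effect = effects, se = ses, z = z,
                      p = 2 * stats::pnorm(-abs(z)))
  }
  attr(out, "bias_mu") <- mu
  attr(out, "inflation_sigma") <- sigma
  attr(out, "applied") <- applied
  out
}

## Restricted log-likelihood of a random-effects meta-analysis at tau2.
reml_ll <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' Inverse-variance-weighted meta-analysis per probe
#'
#' Fixed-effect: weights 1/se^2, closed form. Random-effects: tau^2 by REML
#' (restricted-likelihood maximization), weights 1/(se^2 + tau^2).
#' Cochran's Q and I^2 are reported for every probe. Probes observed in a
#' single study are passed through with a flag.
#'
#' @param effects,ses probes x studies matrices (NA where a probe is
#'   missing from a study), or vectors for a single probe.
#' @param method "random" (REML, default) or "fixed".
#' @return data frame (class \code{meta_ewas_result}): probe_id,
#'   meta_effect, meta_se, meta_z, meta_p, tau2, Q, I2, n_studies,
#'   single_study flag.
#' @export
ivw_meta <- function(effects, ses, method = c("random", "fixed")) {
  method <- match.arg(method)
  if (is.null(dim(effects))) effects <- matrix(effects, nrow = 1)
  if (is.null(dim(ses))) ses <- matrix(ses, nrow = 1)
  if (any(ses <= 0, na.rm = TRUE)) stop("non-positive standard error",
                                        call. = FALSE)
  m <- nrow(effects)
  ids <- rownames(effects) %||% as.character(seq_len(m))
  out <- data.frame(probe_id = ids, meta_effect = NA_real_,
                    meta_se = NA_real_, meta_z = NA_real_,
                    meta_p = NA_real_, tau2 = 0, Q = NA_real_,
                    I2 = NA_real_, n_studies = 0L, single_study = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(m)) {
    ok <- which(!is.na(effects[i, ]) & !is.na(ses[i, ]))
    k <- length(ok)
    out$n_studies[i] <- k
    if (k == 0) next
    y <- effects[i, ok]; v <- ses[i, ok]^2
    if (k == 1) {
      out[i, c("meta_effect", "meta_se")] <- c(y, sqrt(v))
      out$single_study[i] <- TRUE
    } else {
      wf <- 1 / v
      mu_f <- sum(wf * y) / sum(wf)
      Q <- sum(wf * (y - mu_f)^2)
      out$Q[i] <- Q
      out$I2[i] <- max(0, (Q - (k - 1)) / Q)
      if (method == "fixed") {
        out$meta_effect[i] <- mu_f
        out$meta_se[i] <- sqrt(1 / sum(wf))
      } else {
        upper <- max(stats::var(y) * 4, 4 * max(v), 1e-8)
        opt <- stats::optimize(reml_ll, c(0, upper), y = y, v = v,
                               maximum = TRUE, tol = 1e-10)
        tau2 <- if (reml_ll(0, y, v) >= opt$objective) 0 else opt$maximum
        w <- 1 / (v + tau2)
        out$tau2[i] <- tau2
        out$meta_effect[i] <- sum(w * y) / sum(w)
        out$meta_se[i] <- sqrt(1 / sum(w))
      }
    }
    out$meta_z[i] <- out$meta_effect[i] / out$meta_se[i]
    out$meta_p[i] <- 2 * stats::pnorm(-abs(out$meta_z[i]))
  }
  class(out) <- c("meta_ewas_result", class(out))
  out
}

#' Call differentially methylated positions by Bonferroni
#'
#' @param meta a \code{\link{ivw_meta}} result.
#' @param m number of tests (default: number of meta-analyzed probes).
#' @param alpha family-wise level.
#' @return character vector of DMP probe ids (strict inequality
#'   m * p < alpha); attribute \code{bonferroni_p} carries min(1, m*p) for
#'   all probes.
#' @export
call_dmps <- function(meta, m = NULL, alpha = 0.05) {
  m <- m %||% sum(!is.na(meta$meta_p))
  bp <- pmin(1, m * meta$meta_p)
  keep <- !is.na(meta$meta_p) & (m * meta$meta_p < alpha)
  structure(meta$probe_id[keep],
            bonferroni_p = stats::setNames(bp, meta$probe_id))
}
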