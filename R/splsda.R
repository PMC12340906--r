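## Soft-threshold at the (keep+1)-th largest magnitude: exactly `keep`
## entries stay nonzero (almost surely, for continuous data), then
## renormalize to unit length.
soft_keep <- function(u, keep) {
  if (keep < length(u)) {
    lam <- sort(abs(u), decreasing = TRUE)[keep + 1]
    u <- sign(u) * pmax(abs(u) - lam, 0)
  }
  u / sqrt(sum(u^2))
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Sparse PLS with per-component soft-thresholding of the X-weight vector to
#' its \code{keepX} largest absolute entries (the Le Cao formulation): per
#' component the weight is the dominant singular vector of the current
#' X'Y cross-covariance, thresholded and renormalized; X and Y are deflated
#' by regression on the component score. Class membership enters as a
#' centered dummy matrix.
#'
#' @param x probes x samples numeric matrix.
#' @param y class labels, one per sample (>= 2 classes).
#' @param ncomp number of components.
#' @param keepX retained features per component (scalar or length ncomp).
#' @param scale if TRUE (default) features are unit-variance scaled.
#' @return an object of class \code{splsda_model}: sparse \code{loadings}
#'   (probes x ncomp weight vectors, exactly keepX nonzeros each, unit
#'   norm), \code{scores} (samples x ncomp), \code{rotation} (projection
#'   matrix so that scores = standardized data \%*\% rotation),
#'   \code{center}/\code{scale} vectors, \code{selected} feature ids per
#'   component, \code{class_levels}, \code{y}.
#' @export
splsda_fit <- function(x, y, ncomp = 6, keepX = 2000, scale = TRUE) {
  stop_if_not_matrix(x, "x")
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("y must contain >= 2 classes", call. = FALSE)
  if (length(y) != ncol(x)) stop("length(y) must equal ncol(x)",
                                 call. = FALSE)
  p <- nrow(x)
  keepX <- rep(keepX, length.out = ncomp)
  if (any(keepX > p)) stop("keepX exceeds number of probes", call. = FALSE)

  X <- t(x)                                   # n x p, samples as rows
  ctr <- colMeans(X)
  scl <- if (scale) {
    s <- apply(X, 2, stats::sd); s[s == 0] <- 1; s
  } else rep(1, p)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Y <- stats::model.matrix(~ y - 1)
  Y <- sweep(Y, 2, colMeans(Y))

  n <- nrow(Xs)
  W <- P <- matrix(0, p, ncomp,
                   dimnames = list(rownames(x),
                                   paste0("comp", seq_len(ncomp))))
  Tm <- matrix(0, n, ncomp, dimnames = list(colnames(x),
                                            paste0("comp", seq_len(ncomp))))
  Xd <- Xs; Yd <- Y
  selected <- vector("list", ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xd, Yd)                    # p x g
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]
    v <- sv$v[, 1]
    for (it in 1:100) {
      u_new <- soft_keep(drop(M %*% v), keepX[h])
      v_new <- drop(crossprod(M, u_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (sum((u_new - u)^2) < 1e-12) { u <- u_new; v <- v_new; break }
      u <- u_new; v <- v_new
    }
    if (u[which.max(abs(u))] < 0) u <- -u     # deterministic sign
    t_h <- drop(Xd %*% u)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(Xd, t_h)) / tt
    q_h <- drop(crossprod(Yd, t_h)) / tt
    Xd <- Xd - tcrossprod(t_h, p_h)
    Yd <- Yd - tcrossprod(t_h, q_h)
    W[, h] <- u; P[, h] <- p_h; Tm[, h] <- t_h
    selected[[h]] <- rownames(x)[u != 0]
  }
  rotation <- W %*% solve(crossprod(P, W))
  structure(list(loadings = W, scores = Tm, rotation = rotation,
                 x_loadings = P, center = ctr, scale = scl,
                 keepX = keepX, ncomp = ncomp, selected = selected,
                 class_levels = levels(y), y = y),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat("Sparse PLS-DA model:", x$ncomp, "components,",
      length(x$class_levels), "classes\n")
  cat("  keepX:", paste(x$keepX, collapse = ", "), "\n")
  cat("  selected-feature union:", length(selected_features(x)), "probes\n")
  invisible(x)
}

#' Union of selected features across components
#' @param model a \code{splsda_model}.
#' @param dedupe if FALSE, per-component selections are concatenated.
#' @return character vector of probe ids.
#' @export
selected_features <- function(model, dedupe = TRUE) {
  all <- unlist(model$selected, use.names = FALSE)
  if (dedupe) unique(all) else all
}

#' Project samples onto a fitted sPLS-DA latent space
#'
#' Applies the stored centering/scaling and rotation, so projecting the
#' training data reproduces the training scores exactly.
#'
#' @param object a \code{splsda_model}.
#' @param newdata probes x samples matrix containing all model features.
#' @param min_feature_frac warn when fewer than this fraction of model
#'   features is available (features are then subset on both sides).
#' @param ... unused.
#' @return samples x ncomp score matrix.
#' @export
predict.splsda_model <- function(object, newdata,
                                 min_feature_frac = 0.9, ...) {
  stop_if_not_matrix(newdata, "newdata")
  feats <- rownames(object$loadings)
  have <- feats %in% rownames(newdata)
  if (!all(have)) {
    if (mean(have) < min_feature_frac) {
      stop("replication data lacks ", sum(!have), " of ", length(feats),
           " model features; first missing: ",
           paste(utils::head(feats[!have], 5), collapse = ", "),
           call. = FALSE)
    }
    warning(sum(!have), " model features absent; projecting on the ",
            sum(have), "-feature intersection")
  }
  idx <- which(have)
  Xn <- t(newdata[feats[idx], , drop = FALSE])
  Xn <- sweep(sweep(Xn, 2, object$center[idx]), 2, object$scale[idx], "/")
  Xn %*% object$rotation[idx, , drop = FALSE]
}

#' Label-randomization feature-stability validation
#'
#' Randomizes the class labels of a random fraction of samples, refits the
#' sparse PLS-DA model, and counts how many of the originally selected
#' features are re-selected. Repeated over a grid of randomized-population
#' proportions; the expected overlap of two random selections of size s
#' from m probes (s^2/m) is reported as the chance level.
#'
#' @inheritParams splsda_fit
#' @param proportions fractions of samples whose labels are shuffled.
#' @param reps randomization replicates per proportion.
#' @param seed RNG seed.
#' @param dedupe passed to \code{\link{selected_features}}.
#' @return data frame with columns proportion, rep, overlap_count,
#'   selected_size, chance_level; attribute \code{original_size}.
#' @export
feature_stability <- function(x, y, ncomp = 6, keepX = 2000,
                              proportions = c(0.01, 0.05, 0.1, 0.25,
                                              0.5, 0.75, 1),
                              reps = 10, seed = 1) {
  if (any(proportions < 0 | proportions > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  orig <- splsda_fit(x, y, ncomp = ncomp, keepX = keepX)
  sel0 <- selected_features(orig)
  m <- nrow(x)
  n <- ncol(x)
  rows <- list()
  with_substream(seed, "stability", {
    for (p in proportions) {
      for (r in seq_len(reps)) {
        y2 <- y
        n_rand <- ceiling(p * n)
        if (n_rand >= 2) {
          idx <- sample.int(n, n_rand)
          y2[idx] <- sample(y2[idx])  # shuffle preserves class frequencies
        }
        sel <- if (n_rand >= 2) {
          selected_features(splsda_fit(x, y2, ncomp = ncomp, keepX = keepX))
        } else sel0
        s <- length(sel)
        rows[[length(rows) + 1L]] <- data.frame(
          proportion = p, rep = r,
          overlap_count = length(intersect(sel, sel0)),
          selected_size = s,
          chance_level = length(sel0) * s / m)
      }
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "original_size") <- length(sel0)
  out
}
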