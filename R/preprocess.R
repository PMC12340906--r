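#' Residualize methylation on covariates
#'
#' Fits an ordinary-least-squares linear model per probe (intercept always
#' included) and returns the residual matrix. This is the pre-clustering
#' adjustment: clustering and EWAS operate on values orthogonal to age, sex,
#' cell composition, postmortem interval and batch.
#'
#' @param beta probes x samples numeric matrix (beta values or any
#'   per-probe measure); column names must match \code{samples$sample_id}.
#' @param samples sample sheet data frame with a \code{sample_id} column.
#' @param covariates character vector of column names in \code{samples};
#'   character/factor columns are dummy-expanded.
#' @param max_condition condition-number threshold above which the design
#'   is rejected as collinear.
#' @return an \code{adjusted_matrix}: probes x samples residual matrix with
#'   attribute \code{covariates_used}.
#' @export
residualize <- function(beta, samples, covariates,
                        max_condition = 1e8) {
  stop_if_not_matrix(beta, "beta")
  if (anyNA(beta)) stop("beta contains missing values; impute or drop first",
                        call. = FALSE)
  missing_cov <- setdiff(covariates, names(samples))
  if (length(missing_cov)) {
    stop("covariates not in sample table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  ord <- match(colnames(beta), samples$sample_id)
  if (anyNA(ord)) stop("beta columns not all present in sample table",
                       call. = FALSE)
  samples <- samples[ord, , drop = FALSE]

  x <- stats::model.matrix(
    stats::reformulate(covariates),
    data = samples)
  sds <- apply(x[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance covariate column(s): ",
         paste(colnames(x)[-1][sds == 0], collapse = ", "), call. = FALSE)
  }
  kap <- kappa(x, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    qrx <- qr(x)
    bad <- if (qrx$rank < ncol(x)) {
      colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    } else colnames(x)[-1]
    stop("collinear design (condition number ", format(kap, digits = 3),
         "); offending columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  qrx <- qr(x)
  res <- t(qr.resid(qrx, t(beta)))
  dimnames(res) <- dimnames(beta)
  attr(res, "covariates_used") <- covariates
  attr(res, "cohort") <- attr(beta, "cohort")
  class(res) <- c("adjusted_matrix", class(res))
  res
}

#' Select variable probes by a percentile-of-absolute-deviation score
#'
#' Scores each probe by the \code{quantile}-th percentile of the absolute
#' deviations from the probe median (a robust range statistic) and keeps
#' probes scoring at least \code{min_score}. Alternatively,
#' \code{top_fraction} keeps the most variable fraction of probes by the
#' same score; both readings of a percentile-deviation filter are offered
#' because an absolute cutoff cannot be transferred between datasets.
#'
#' @param adjusted probes x samples numeric matrix (typically residuals).
#' @param quantile percentile of absolute deviations used as the score.
#' @param min_score absolute score cutoff; probes with score >= min_score
#'   are kept. Ignored when \code{top_fraction} is given.
#' @param top_fraction optional fraction (0,1]; keep that fraction of
#'   probes with the highest scores instead of using an absolute cutoff.
#' @return character vector of retained probe ids, in decreasing score
#'   order (ties broken by probe id for determinism).
#' @export
variance_filter <- function(adjusted, quantile = 0.90, min_score = 0,
                            top_fraction = NULL) {
  stop_if_not_matrix(adjusted, "adjusted")
  if (ncol(adjusted) < 3) stop("need >= 3 samples", call. = FALSE)
  med <- apply(adjusted, 1, stats::median)
  dev <- abs(adjusted - med)
  score <- apply(dev, 1, stats::quantile, probs = quantile, names = FALSE)
  ids <- rownames(adjusted) %||% as.character(seq_len(nrow(adjusted)))
  ord <- order(-score, ids)
  if (!is.null(top_fraction)) {
    stopifnot(top_fraction > 0, top_fraction <= 1)
    keep <- ord[seq_len(max(1, round(top_fraction * length(ord))))]
  } else {
    keep <- ord[score[ord] >= min_score]
  }
  if (!length(keep)) warning("variance filter retained no probes")
  out <- ids[keep]
  attr(out, "score") <- stats::setNames(score[keep], out)
  out
}

#' Intersect probe sets across platforms/cohorts
#'
#' Returns the probes shared by every cohort matrix (e.g. the highly
#' variable CpGs present on both EPIC and 450K arrays), canonicalized to
#' lexicographic order so the result is invariant to cohort ordering.
#'
#' @param cohort_matrices list (length >= 2) of probes x samples matrices
#'   with probe ids as row names, or of character probe-id vectors.
#' @return sorted character vector of shared probe ids.
#' @export
harmonize_platforms <- function(cohort_matrices) {
  if (length(cohort_matrices) < 2) stop("need >= 2 cohorts", call. = FALSE)
  sets <- lapply(cohort_matrices, function(m)
    if (is.matrix(m)) rownames(m) else as.character(m))
  shared <- Reduce(intersect, sets)
  if (!length(shared)) stop("no probes shared across cohorts", call. = FALSE)
  sort(shared)
}

#' Read/write a beta matrix as TSV (probes as rows, header = sample ids)
#' @param path file path.
#' @param beta probes x samples matrix (for the writer).
#' @param impute if TRUE, missing values are replaced by the probe median;
#'   otherwise any NA is an error.
#' @return the reader returns a numeric matrix with probe-id row names.
#' @export
read_beta_tsv <- function(path, impute = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyNA(m)) {
    if (!impute) stop("missing beta values in ", path,
                      " (set impute=TRUE for per-probe median imputation)",
                      call. = FALSE)
    for (i in which(rowSums(is.na(m)) > 0)) {
      m[i, is.na(m[i, ])] <- stats::median(m[i, ], na.rm = TRUE)
    }
  }
  m
}

#' @rdname read_beta_tsv
#' @export
write_beta_tsv <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
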