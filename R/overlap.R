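## Noncentral hypergeometric machinery in log space. Support of the overlap
## count A given margins (m1 successes, n1 draws, universe N):
## k in [max(0, n1+m1-N), min(m1, n1)].
nchg_support <- function(m1, n1, N) {
  max(0L, n1 + m1 - N):min(m1, n1)
}

## E[A | psi] under Fisher's noncentral hypergeometric distribution,
## computed with log-space weights log C(m1,k) + log C(N-m1, n1-k) + k log psi.
nchg_mean <- function(log_psi, m1, n1, N) {
  k <- nchg_support(m1, n1, N)
  lw <- lchoose(m1, k) + lchoose(N - m1, n1 - k) + k * log_psi
  lw <- lw - max(lw)
  w <- exp(lw)
  sum(k * w) / sum(w)
}

#' Fisher-style overlap test with conditional-MLE odds ratio
#'
#' Builds the 2x2 table for the overlap of two feature lists drawn from a
#' common universe (a = overlap, b = list A only, c = list B only, d =
#' remainder) and reports the conditional maximum-likelihood odds ratio --
#' the root of E[A | psi] = a under Fisher's noncentral hypergeometric
#' model, the estimate printed by Fisher's exact test -- together with the
#' upper-tail hypergeometric enrichment p-value and the sample odds ratio
#' ad/bc.
#'
#' @param list_a_size,list_b_size sizes of the two lists.
#' @param overlap number of shared features.
#' @param universe size of the background set.
#' @param tol relative tolerance of the root search.
#' @return object of class \code{overlap_result}: a list with the table
#'   counts, \code{odds_ratio} (conditional MLE), \code{sample_or},
#'   \code{p}, \code{expected} overlap under independence, and
#'   \code{mle_deviates} flagging a >2\% disagreement between the two OR
#'   estimates.
#' @export
fisher_overlap <- function(list_a_size, list_b_size, overlap, universe,
                           tol = 1e-6) {
  a <- overlap; m1 <- list_a_size; n1 <- list_b_size; N <- universe
  if (a > min(m1, n1) || m1 > N || n1 > N || a < max(0, m1 + n1 - N)) {
    stop("impossible contingency table", call. = FALSE)
  }
  b <- m1 - a; c_ <- n1 - a; d <- N - m1 - n1 + a
  supp <- nchg_support(m1, n1, N)
  p <- stats::phyper(a - 1, m1, N - m1, n1, lower.tail = FALSE)
  expected <- as.numeric(m1) * n1 / N

  or <- if (a == min(supp)) 0 else if (a == max(supp)) Inf else {
    ## E[A|psi] is increasing in psi; bracket the root on log psi
    lo <- -1; hi <- 1
    while (nchg_mean(lo, m1, n1, N) > a) lo <- lo * 2
    while (nchg_mean(hi, m1, n1, N) < a) hi <- hi * 2
    exp(stats::uniroot(function(lp) nchg_mean(lp, m1, n1, N) - a,
                       c(lo, hi), tol = tol)$root)
  }
  sample_or <- if (b > 0 && c_ > 0) (as.numeric(a) * d) / (as.numeric(b) * c_)
    else Inf
  if (a == 0) sample_or <- 0
  structure(list(a = a, b = b, c = c_, d = d, universe = N,
                 odds_ratio = or, sample_or = sample_or, p = p,
                 expected = expected,
                 mle_deviates = is.finite(or) && is.finite(sample_or) &&
                   sample_or > 0 && abs(or / sample_or - 1) > 0.02),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap %d (expected %.2f) of lists %d and %d in universe %d\n",
              x$a, x$expected, x$a + x$b, x$a + x$c, x$universe))
  cat(sprintf("  conditional-MLE OR = %.4g (sample OR = %.4g), p = %.3g\n",
              x$odds_ratio, x$sample_or, x$p))
  invisible(x)
}

#' Cell-type CpG-panel enrichment of a DMP list
#'
#' Runs \code{\link{fisher_overlap}} of the DMP list against each cell-type
#' panel at each specificity level, restricted to the probe universe, with
#' Benjamini-Hochberg adjustment across panels.
#'
#' @param dmps character vector of DMP probe ids.
#' @param panels data frame with columns cell_type, specificity_level and a
#'   list-column probe_ids (as produced by
#'   \code{\link{generate_celltype_panels}}).
#' @param universe character vector of background probe ids.
#' @return data frame with one row per panel: cell_type,
#'   specificity_level, panel_size, overlap, odds_ratio, p, p_adj, flagged.
#' @export
celltype_enrichment <- function(dmps, panels, universe) {
  dmps <- intersect(dmps, universe)
  flagged_empty <- length(dmps) == 0
  rows <- lapply(seq_len(nrow(panels)), function(i) {
    pan <- intersect(panels$probe_ids[[i]], universe)
    degenerate <- flagged_empty || length(dmps) == length(universe) ||
      length(pan) == 0
    if (degenerate) {
      return(data.frame(cell_type = panels$cell_type[i],
                        specificity_level = panels$specificity_level[i],
                        panel_size = length(pan), overlap = NA_integer_,
                        odds_ratio = NA_real_, p = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    ov <- fisher_overlap(length(dmps), length(pan),
                         length(intersect(dmps, pan)), length(universe))
    data.frame(cell_type = panels$cell_type[i],
               specificity_level = panels$specificity_level[i],
               panel_size = length(pan), overlap = ov$a,
               odds_ratio = ov$odds_ratio, p = ov$p, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Generic over-representation analysis against user-supplied gene sets
#'
#' Upper-tail hypergeometric test of a query gene list against each set,
#' with BH adjustment; query genes absent from the universe are dropped
#' with a warning.
#'
#' @param genes query gene list.
#' @param gene_sets named list of gene-id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe background gene ids.
#' @param min_size,max_size set-size bounds applied after restriction to
#'   the universe.
#' @return data frame: set, set_size, overlap, fold_enrichment, p, p_adj,
#'   genes (comma-separated contributing genes), sorted by p.
#' @export
ora <- function(genes, gene_sets, universe, min_size = 10, max_size = 2000) {
  if (!length(gene_sets)) stop("gene_sets is empty", call. = FALSE)
  absent <- setdiff(genes, universe)
  if (length(absent)) {
    warning(length(absent), " query genes absent from universe; dropped")
    genes <- intersect(genes, universe)
  }
  if (!length(genes)) {
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), fold_enrichment = numeric(),
                      p = numeric(), p_adj = numeric(),
                      genes = character()))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    if (length(s) < min_size || length(s) > max_size) return(NULL)
    hit <- intersect(genes, s)
    p <- stats::phyper(length(hit) - 1, length(s),
                       length(universe) - length(s), length(genes),
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = length(hit),
               fold_enrichment = (length(hit) / length(genes)) /
                 (length(s) / length(universe)),
               p = p, genes = paste(hit, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), fold_enrichment = numeric(),
                      p = numeric(), p_adj = numeric(),
                      genes = character()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), c("set", "set_size", "overlap", "fold_enrichment",
                      "p", "p_adj", "genes")]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}
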