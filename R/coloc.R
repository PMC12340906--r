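#' Filter a summary-statistics track to suggestive cis-mQTLs
#'
#' Retains variants with p strictly below the suggestive threshold
#' (default 1e-5). An empty result means the region carries no usable
#' signal and should be dropped by the caller.
#'
#' @param stats data frame with at least variant_id, beta, se, p.
#' @param threshold nominal p-value cutoff (strict inequality).
#' @return the filtered data frame; attribute \code{dropped} = TRUE when
#'   nothing survives.
#' @export
filter_cis_mqtls <- function(stats, threshold = 1e-5) {
  keep <- !is.na(stats$p) & stats$p < threshold
  out <- stats[keep, , drop = FALSE]
  if (!nrow(out)) {
    message("no variants pass p < ", format(threshold), "; region dropped")
    attr(out, "dropped") <- TRUE
  } else {
    attr(out, "dropped") <- FALSE
  }
  out
}

#' Wakefield log approximate Bayes factor
#'
#' With V = se^2, Z = beta/se and r = W/(V+W):
#' log ABF = 0.5 log(1 - r) + 0.5 r Z^2, where W is the prior variance of
#' the effect (default 0.15^2, the quantitative-trait convention; supply
#' \code{sdY} to scale the prior to the phenotype SD).
#'
#' @param beta,se effect estimate and standard error (vectorized).
#' @param prior_w prior effect variance W.
#' @param sdY optional phenotype SD; when given, W = (0.15 * sdY)^2.
#' @return log approximate Bayes factor in favour of association.
#' @export
wakefield_abf <- function(beta, se, prior_w = 0.15^2, sdY = NULL) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (!is.null(sdY)) prior_w <- (0.15 * sdY)^2
  v <- se^2
  r <- prior_w / (v + prior_w)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * r * z^2
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a > b, stable.
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Approximate-Bayes-factor colocalization of two association tracks
#'
#' Standard five-hypothesis enumeration (H0 no association; H1/H2 one
#' trait only; H3 two distinct causal variants; H4 one shared causal
#' variant) from per-variant Wakefield log-ABFs and per-variant priors,
#' computed in log-sum-exp space. Significance follows the
#' PP.H3 + PP.H4 > 0.90 rule.
#'
#' @param track1,track2 data frames with variant_id, beta, se (track 1 is
#'   conventionally the mQTL track); joined on variant_id.
#' @param p1,p2,p12 per-variant prior probabilities of association with
#'   trait 1 only, trait 2 only, and both.
#' @param prior_w1,prior_w2 Wakefield prior variances per track.
#' @return object of class \code{coloc_result}: \code{pp} (named vector
#'   H0..H4 summing to 1), \code{n_variants}, \code{priors},
#'   \code{significant}.
#' @export
coloc_abf <- function(track1, track2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_w1 = 0.15^2, prior_w2 = 0.15^2) {
  shared <- intersect(track1$variant_id, track2$variant_id)
  if (!length(shared)) stop("no shared variants between tracks",
                            call. = FALSE)
  t1 <- track1[match(shared, track1$variant_id), ]
  t2 <- track2[match(shared, track2$variant_id), ]
  l1 <- wakefield_abf(t1$beta, t1$se, prior_w1)
  l2 <- wakefield_abf(t2$beta, t2$se, prior_w2)

  s1 <- logsumexp(l1)                 # sum_i ABF1_i
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)           # sum_i ABF1_i ABF2_i
  ## sum_{i != j} ABF1_i ABF2_j = (sum_i)(sum_j) - sum_i ABF1_i ABF2_i
  s_cross <- logdiff(s1 + s2, s12)

  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + s_cross,
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  structure(list(pp = pp, n_variants = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 significant = unname(pp["H3"] + pp["H4"] > 0.90)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("ABF colocalization over", x$n_variants, "variants\n")
  print(round(x$pp, 4))
  cat("  PP.H3 + PP.H4 =", round(x$pp["H3"] + x$pp["H4"], 4),
      if (x$significant) " (significant)" else " (not significant)", "\n")
  invisible(x)
}

#' Run colocalization over a region manifest
#'
#' A region enters the analysis only when its mQTL track carries at least
#' one suggestive cis-mQTL (\code{\link{filter_cis_mqtls}}); colocalization
#' then uses the region's full variant complement on both tracks, so a
#' distinct GWAS causal variant elsewhere in the region can still support
#' the two-independent-signals hypothesis.
#'
#' @param regions named list; each element a list with data frames
#'   \code{mqtl} and \code{gwas}.
#' @param mqtl_threshold suggestive p cutoff for region inclusion.
#' @param ... passed to \code{\link{coloc_abf}}.
#' @return data frame with one row per tested region: region, n_variants,
#'   PP.H0..PP.H4, significant.
#' @export
coloc_regions <- function(regions, mqtl_threshold = 1e-5, ...) {
  rows <- lapply(names(regions), function(rg) {
    mq <- filter_cis_mqtls(regions[[rg]]$mqtl, mqtl_threshold)
    if (isTRUE(attr(mq, "dropped"))) return(NULL)
    res <- coloc_abf(regions[[rg]]$mqtl, regions[[rg]]$gwas, ...)
    data.frame(region = rg, n_variants = res$n_variants,
               PP.H0 = res$pp["H0"], PP.H1 = res$pp["H1"],
               PP.H2 = res$pp["H2"], PP.H3 = res$pp["H3"],
               PP.H4 = res$pp["H4"], significant = res$significant,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(region = character(), n_variants = integer(),
                      PP.H0 = numeric(), PP.H1 = numeric(),
                      PP.H2 = numeric(), PP.H3 = numeric(),
                      PP.H4 = numeric(), significant = logical()))
  }
  do.call(rbind, rows)
}
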