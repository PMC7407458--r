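#' Fisher z-test for a difference of correlations
#'
#' `z_k = atanh(r_k)`; the statistic is
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided standard normal
#' P-value. Correlations at exactly +/-1 are clipped to `1 - 1e-12` (flagged
#' via the `clipped` attribute).
#'
#' @param r1,r2 correlation(s) in each dataset (vectorized).
#' @param n1,n2 sample sizes of the two datasets (each >= 4).
#' @return Data frame with `stat` and `pvalue`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) stop("need at least 4 samples per dataset", call. = FALSE)
  clip <- abs(r1) >= 1 | abs(r2) >= 1
  r1 <- pmin(pmax(r1, -1 + 1e-12), 1 - 1e-12)
  r2 <- pmin(pmax(r2, -1 + 1e-12), 1 - 1e-12)
  stat <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  out <- data.frame(stat = stat, pvalue = 2 * stats::pnorm(-abs(stat)))
  attr(out, "clipped") <- which(clip)
  out
}

#' Differential correlation over all gene pairs
#'
#' Computes the Pearson correlation of every unordered gene pair in each of
#' two datasets (e.g. wild and domesticated expression), tests each pair's
#' correlation change with [fisher_z_test()], and flags significance either
#' by local FDR (default, the threshold applying to the lfdr value) or by
#' BH-adjusted P-value. With fewer than 100 pairs the local FDR density
#' estimate is unstable and the method falls back to BH with a warning.
#'
#' @param expr_1,expr_2 genes x samples expression matrices over the same
#'   genes (>= 4 samples each).
#' @param threshold significance threshold (default 0.05).
#' @param method `"lfdr"` or `"bh"`.
#' @return An object of class `dc_pairs`: data frame with `gene_i`, `gene_j`,
#'   `r_1`, `r_2`, `stat`, `pvalue`, `padj`, `lfdr`, `sig`, plus attributes
#'   `n_1`, `n_2`, `method`, `threshold`.
#' @export
dc_pairs <- function(expr_1, expr_2, threshold = 0.05,
                     method = c("lfdr", "bh")) {
  method <- match.arg(method)
  if (!identical(rownames(expr_1), rownames(expr_2)))
    stop("the two datasets must cover the same genes in the same order",
         call. = FALSE)
  if (ncol(expr_1) < 4 || ncol(expr_2) < 4)
    stop("need at least 4 samples in each dataset", call. = FALSE)
  c1 <- correlation_matrix(expr_1)
  c2 <- correlation_matrix(expr_2)
  ut <- upper.tri(c1)
  idx <- which(ut, arr.ind = TRUE)
  genes <- rownames(c1)
  ft <- fisher_z_test(c1[ut], ncol(expr_1), c2[ut], ncol(expr_2))
  res <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                    r_1 = c1[ut], r_2 = c2[ut],
                    stat = ft$stat, pvalue = ft$pvalue,
                    stringsAsFactors = FALSE)
  res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  if (method == "lfdr" && nrow(res) < 100) {
    warning("fewer than 100 pairs; falling back to BH", call. = FALSE)
    method <- "bh"
  }
  if (method == "lfdr") {
    res$lfdr <- local_fdr(res$stat)
    res$sig <- res$lfdr < threshold
  } else {
    res$lfdr <- NA_real_
    res$sig <- res$padj < threshold
  }
  attr(res, "n_1") <- ncol(expr_1)
  attr(res, "n_2") <- ncol(expr_2)
  attr(res, "method") <- method
  attr(res, "threshold") <- threshold
  class(res) <- c("dc_pairs", "data.frame")
  res
}

#' Local false discovery rate from z-scores
#'
#' Two-component mixture with a theoretical N(0,1) null:
#' `lfdr(z) = pi0 * f0(z) / f(z)`, where `f` is a kernel density estimate of
#' the observed z-scores and `pi0` is estimated from the count of z-scores in
#' the central `[-1, 1]` region relative to the null expectation. The result
#' is made monotone non-increasing in `|z|` by isotonic regression and
#' clipped to `[0, 1]`.
#'
#' @param z numeric vector of z-scores (>= 100 for a stable density).
#' @return Numeric vector of per-test local FDR values.
#' @export
local_fdr <- function(z) {
  z <- as.numeric(z)
  if (length(z) < 100)
    stop("need >= 100 tests for local FDR estimation; use BH instead",
         call. = FALSE)
  pi0 <- min(1, mean(abs(z) <= 1) / (stats::pnorm(1) - stats::pnorm(-1)))
  dens <- stats::density(z, n = 2048, cut = 3)
  f <- stats::approx(dens$x, dens$y, xout = z, rule = 2)$y
  f <- pmax(f, 1e-12)
  lfdr <- pmin(1, pi0 * stats::dnorm(z) / f)
  ord <- order(abs(z))
  iso <- stats::isoreg(abs(z)[ord], -lfdr[ord])
  out <- numeric(length(z))
  out[ord] <- pmin(1, pmax(0, -iso$yf))
  out
}

#' Binomial test for differentially correlated genes
#'
#' A gene carrying `k` significant DC pairs among its `n` tested pairs is
#' scored against `Binomial(n, p0)` where `p0` is the global significant-pair
#' fraction; the P-value is the upper tail `Pr[X >= k]`. BH correction across
#' genes; DC genes are those with adjusted P below `alpha`.
#'
#' @param pairs a [dc_pairs()] result (or any data frame with `gene_i`,
#'   `gene_j`, `sig`).
#' @param alpha significance level on the adjusted P-value.
#' @return Data frame with `gene`, `k`, `n`, `p0`, `pvalue`, `padj`,
#'   `dc_gene`.
#' @export
dc_genes <- function(pairs, alpha = 0.05) {
  genes <- sort(unique(c(pairs$gene_i, pairs$gene_j)))
  n_tested <- table(factor(c(pairs$gene_i, pairs$gene_j), levels = genes))
  sigp <- pairs$sig
  k_sig <- table(factor(c(pairs$gene_i[sigp], pairs$gene_j[sigp]),
                        levels = genes))
  p0 <- sum(sigp) / nrow(pairs)
  k <- as.vector(k_sig); n <- as.vector(n_tested)
  if (p0 == 0) {
    pv <- rep(1, length(genes))
    if (any(k > 0)) warning("significant pairs but p0 = 0; inconsistent input",
                            call. = FALSE)
  } else {
    pv <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  }
  res <- data.frame(gene = genes, k = k, n = n, p0 = p0, pvalue = pv,
                    padj = stats::p.adjust(pv, method = "BH"),
                    stringsAsFactors = FALSE)
  res$dc_gene <- res$padj < alpha
  res
}
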