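#' Preranked gene-set enrichment on a kME ranking
#'
#' Classic weighted running-sum enrichment: genes are ranked by decreasing
#' score (ties broken by gene id); walking down the list, hitting a set
#' member increments the sum by `|score| / sum(|score| of members)` and a
#' miss decrements by `1 / (N - |S|)`. The enrichment score ES is the maximum
#' deviation from zero. The null is built from `n_perm` random gene sets of
#' the same size; `NES = ES / mean(|null ES| of the same sign)` and the
#' permutation P-value counts same-sign null ES at least as extreme
#' (with a +1 pseudocount). FDR q-values are BH over the tested sets.
#' Deterministic under `seed`.
#'
#' @param scores named numeric vector (e.g. one module's kME over the network
#'   gene universe).
#' @param gene_sets named list of character vectors; sets with fewer than
#'   `min_size` members in the universe are skipped with a warning.
#' @param n_perm number of random-set permutations (default 1000).
#' @param seed integer RNG seed.
#' @param min_size smallest testable set size (default 5).
#' @return Data frame with `set`, `size`, `es`, `nes`, `pvalue`, `fdr`.
#' @export
gsea_preranked <- function(scores, gene_sets, n_perm = 1000, seed = 1,
                           min_size = 5) {
  stopifnot(!is.null(names(scores)))
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  universe <- names(scores)
  N <- length(universe)

  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], universe)
    ns <- length(members)
    if (ns < min_size) {
      warning("set '", nm, "' has <", min_size,
              " genes in the universe; skipped", call. = FALSE)
      return(NULL)
    }
    hit <- universe %in% members
    es <- .running_es(scores, hit)
    null_es <- vapply(seq_len(n_perm), function(b) {
      h <- logical(N)
      h[sample.int(N, ns)] <- TRUE
      .running_es(scores, h)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    pv <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(set = nm, size = ns, es = es, nes = nes, pvalue = pv,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no testable gene sets", call. = FALSE)
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$pvalue, method = "BH")
  rownames(res) <- NULL
  res
}

## maximum-deviation running sum for an ordered score vector and hit mask
.running_es <- function(scores, hit) {
  w <- abs(scores)
  sum_hit <- sum(w[hit])
  if (sum_hit == 0) {                     # all-zero hit scores: uniform steps
    inc <- ifelse(hit, 1 / sum(hit), -1 / (length(hit) - sum(hit)))
  } else {
    inc <- ifelse(hit, w / sum_hit, -1 / (length(hit) - sum(hit)))
  }
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Hypergeometric term enrichment of a gene list
#'
#' Classic one-sided overrepresentation test: per term, the upper-tail
#' hypergeometric probability of observing at least the overlap between the
#' gene list and the term's annotated genes within the universe, BH-adjusted
#' across terms. The annotation is treated as flat term -> gene sets (no
#' ontology graph).
#'
#' @param gene_list character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector, the tested gene universe.
#' @param annotations two-column data frame (`gene`, `term`).
#' @return Data frame with `term`, `annotated`, `overlap`, `pvalue`, `padj`,
#'   sorted by P-value. Terms with no annotated gene in the universe are
#'   skipped.
#' @export
hypergeom_enrich <- function(gene_list, universe, annotations) {
  if (!all(gene_list %in% universe))
    stop("gene_list must be a subset of the universe", call. = FALSE)
  annotations <- annotations[annotations$gene %in% universe, , drop = FALSE]
  terms <- split(annotations$gene, annotations$term)
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(terms), function(tm) {
    ann <- unique(terms[[tm]])
    K <- length(ann)
    if (K == 0) return(NULL)
    k <- length(intersect(gene_list, ann))
    pv <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, annotated = K, overlap = k, pvalue = pv,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no annotated terms in the universe", call. = FALSE)
  res <- do.call(rbind, rows)
  res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  res <- res[order(res$pvalue, res$term), ]
  rownames(res) <- NULL
  res
}
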