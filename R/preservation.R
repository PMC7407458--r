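#' Observed module preservation statistics
#'
#' For every reference module, four statistics measured in the test dataset:
#' two density statistics — `meanCor` (mean off-diagonal intramodule
#' correlation) and `meanAdj` (mean intramodule unsigned adjacency at power
#' `beta`) — and two connectivity statistics — `cor_kIM` (correlation of the
#' members' intramodular connectivity between reference and test) and
#' `cor_cor` (correlation between the vectorized intramodule correlation
#' matrices of reference and test). Modules with fewer than 3 genes in the
#' test data get `NA` with a warning; label 0 is not a module and is skipped.
#'
#' @param ref_labels named integer module labels from the reference network.
#' @param ref_expr,test_expr genes x samples expression matrices covering the
#'   labelled genes.
#' @param beta soft-threshold power for the adjacency-based statistics.
#' @return Data frame with one row per module: `module`, `size`, `meanCor`,
#'   `meanAdj`, `cor_kIM`, `cor_cor`.
#' @export
preservation_stats <- function(ref_labels, ref_expr, test_expr, beta = 12) {
  if (inherits(ref_labels, "module_assignment")) ref_labels <- ref_labels$labels
  genes <- intersect(names(ref_labels), rownames(test_expr))
  genes <- intersect(genes, rownames(ref_expr))
  ref_cor <- correlation_matrix(ref_expr[genes, , drop = FALSE])
  test_cor <- correlation_matrix(test_expr[genes, , drop = FALSE])
  .pres_stats(ref_labels[genes], ref_cor, test_cor, beta, warn = TRUE)
}

## worker on precomputed correlation matrices (shared with the permutations)
.pres_stats <- function(labels, ref_cor, test_cor, beta, warn = FALSE) {
  mods <- sort(setdiff(unique(labels), 0L))
  out <- data.frame(module = mods, size = NA_integer_, meanCor = NA_real_,
                    meanAdj = NA_real_, cor_kIM = NA_real_, cor_cor = NA_real_)
  for (i in seq_along(mods)) {
    idx <- which(labels == mods[i])
    out$size[i] <- length(idx)
    if (length(idx) < 3) {
      if (warn) warning("module ", mods[i], " has <3 genes in test data",
                        call. = FALSE)
      next
    }
    ct <- test_cor[idx, idx]
    cr <- ref_cor[idx, idx]
    off <- upper.tri(ct)
    out$meanCor[i] <- mean(ct[off])
    at <- abs(ct)^beta
    ar <- abs(cr)^beta
    out$meanAdj[i] <- mean(at[off])
    kim_t <- colSums(at) - 1
    kim_r <- colSums(ar) - 1
    out$cor_kIM[i] <- stats::cor(kim_r, kim_t)
    out$cor_cor[i] <- stats::cor(cr[off], ct[off])
  }
  out
}

#' Permutation Zsummary module preservation
#'
#' Builds a permutation null by shuffling the module labels among all genes
#' (module sizes preserved) and recomputing the four [preservation_stats()]
#' per permutation. Each statistic's Z is `(observed - null mean) / null sd`;
#' `Zdensity` is the median of the two density Zs, `Zconnectivity` the median
#' of the two connectivity Zs, and `Zsummary` their mean. `medianRank` ranks
#' the observed statistics across modules ([median_rank()]). Deterministic
#' under `seed`. A statistic with zero null variance yields an infinite Z and
#' a `degenerate` flag.
#'
#' @inheritParams preservation_stats
#' @param n_perm number of label permutations (>= 20; default 100).
#' @param seed integer RNG seed.
#' @return An object of class `preservation_result`: the per-module data
#'   frame (observed statistics, Zs, `Zsummary`, `medianRank`, `class`) with
#'   attributes `n_perm` and `seed`.
#' @export
module_preservation <- function(ref_labels, ref_expr, test_expr,
                                n_perm = 100, seed = 1, beta = 12) {
  if (inherits(ref_labels, "module_assignment")) ref_labels <- ref_labels$labels
  if (n_perm < 20) stop("n_perm must be >= 20", call. = FALSE)
  genes <- intersect(names(ref_labels), rownames(test_expr))
  genes <- intersect(genes, rownames(ref_expr))
  labels <- ref_labels[genes]
  ref_cor <- correlation_matrix(ref_expr[genes, , drop = FALSE])
  test_cor <- correlation_matrix(test_expr[genes, , drop = FALSE])

  obs <- .pres_stats(labels, ref_cor, test_cor, beta, warn = TRUE)
  stat_cols <- c("meanCor", "meanAdj", "cor_kIM", "cor_cor")
  set.seed(seed)
  null <- array(NA_real_, c(nrow(obs), length(stat_cols), n_perm),
                dimnames = list(obs$module, stat_cols, NULL))
  for (b in seq_len(n_perm)) {
    pl <- sample(labels)
    names(pl) <- names(labels)
    ps <- .pres_stats(pl, ref_cor, test_cor, beta)
    null[, , b] <- as.matrix(ps[match(obs$module, ps$module), stat_cols])
  }
  mu <- apply(null, c(1, 2), mean)
  sdv <- apply(null, c(1, 2), stats::sd)
  Z <- (as.matrix(obs[, stat_cols]) - mu) / sdv
  colnames(Z) <- paste0("Z_", stat_cols)

  res <- cbind(obs, Z)
  res$degenerate <- apply(sdv == 0, 1, any)
  res$Zdensity <- apply(Z[, c("Z_meanCor", "Z_meanAdj"), drop = FALSE], 1,
                        stats::median)
  res$Zconnectivity <- apply(Z[, c("Z_cor_kIM", "Z_cor_cor"), drop = FALSE], 1,
                             stats::median)
  res$Zsummary <- (res$Zdensity + res$Zconnectivity) / 2
  res$medianRank <- if (nrow(obs) >= 2) median_rank(obs) else NA_real_
  res$class <- classify_preservation(res$Zsummary)
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("preservation_result", "data.frame")
  res
}

#' Median preservation rank across modules
#'
#' Each of the four observed statistics is ranked across modules with rank 1
#' for the most preserved (largest) value and average ranks for ties; the
#' module's medianRank is the median of its four ranks. Lower means
#' relatively better preserved.
#'
#' @param stats a [preservation_stats()] data frame (>= 2 modules).
#' @return Numeric vector of medianRank values, aligned with `stats` rows.
#' @export
median_rank <- function(stats) {
  stat_cols <- c("meanCor", "meanAdj", "cor_kIM", "cor_cor")
  if (nrow(stats) < 2) stop("need at least 2 modules", call. = FALSE)
  ranks <- vapply(stat_cols,
                  function(s) rank(-stats[[s]], ties.method = "average",
                                   na.last = "keep"),
                  numeric(nrow(stats)))
  apply(ranks, 1, stats::median, na.rm = TRUE)
}

#' Classify Zsummary preservation
#'
#' Strong preservation above 10, none below 2, weak-to-moderate in the
#' closed interval between them.
#'
#' @param zsummary numeric vector of Zsummary values.
#' @return Character vector with values `"strong"`, `"moderate"`, `"none"`.
#' @export
classify_preservation <- function(zsummary) {
  if (inherits(zsummary, "preservation_result")) zsummary <- zsummary$Zsummary
  ifelse(is.na(zsummary), NA_character_,
         ifelse(zsummary > 10, "strong",
                ifelse(zsummary >= 2, "moderate", "none")))
}
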