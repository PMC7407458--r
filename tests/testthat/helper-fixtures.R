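# Shared fixtures and independent brute-force oracles.

# plain count matrix with the standard 2 x 4 x n design
make_meta <- function(n_acc = 3, stages = c(5, 10, 15, 20)) {
  meta <- expand.grid(accession = seq_len(n_acc), stage = stages,
                      group = c("wild", "domesticated"),
                      stringsAsFactors = FALSE)
  meta$sample <- sprintf("s%02d", seq_len(nrow(meta)))
  meta[, c("sample", "accession", "group", "stage")]
}

# hub-structured module universe: per-module latent with heterogeneous
# loadings plus pure-noise background; mirrors what coexpression modules
# look like without going through the count layer
make_universe <- function(seed, n_mod = 4, msize = 100, n_bg = 200, ns = 24,
                          load_range = c(0.6, 1), loads = NULL,
                          target_loads = NULL) {
  set.seed(seed)
  lats <- matrix(rnorm(n_mod * ns), n_mod)
  if (is.null(loads)) {
    loads <- matrix(runif(n_mod * msize, load_range[1], load_range[2]), n_mod)
    if (!is.null(target_loads)) loads[1, ] <- target_loads
  }
  x <- NULL
  nm <- character(0)
  for (m in seq_len(n_mod)) {
    xm <- t(vapply(seq_len(msize), function(i) {
      l <- loads[m, i]
      l * lats[m, ] + sqrt(1 - l^2) * rnorm(ns)
    }, numeric(ns)))
    x <- rbind(x, xm)
    nm <- c(nm, sprintf("m%d_%03d", m, seq_len(msize)))
  }
  if (n_bg > 0) {
    x <- rbind(x, matrix(rnorm(n_bg * ns), n_bg))
    nm <- c(nm, sprintf("bg%03d", seq_len(n_bg)))
  }
  dimnames(x) <- list(nm, sprintf("s%02d", seq_len(ns)))
  list(x = x, loads = loads,
       labels = stats::setNames(c(rep(seq_len(n_mod), each = msize),
                                  rep(0L, n_bg)), nm))
}

# double-loop Pearson correlation
bf_cor <- function(x) {
  n <- nrow(x)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- stats::cor(x[i, ], x[j, ])
  }
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

# topological overlap by explicit triple loop
bf_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- colSums(a) - 1
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# classic GSEA running sum evaluated step by step
bf_gsea_es <- function(scores, members) {
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  hit <- names(scores) %in% members
  nh <- sum(hit)
  sum_w <- sum(abs(scores)[hit])
  rs <- 0
  best <- 0
  for (i in seq_along(scores)) {
    rs <- rs + if (hit[i]) abs(scores[i]) / sum_w else -1 / (length(scores) - nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# preservation statistics for one module via explicit loops
bf_pres_stats <- function(idx, ref_expr, test_expr, beta) {
  cr <- bf_cor(ref_expr[idx, , drop = FALSE])
  ct <- bf_cor(test_expr[idx, , drop = FALSE])
  n <- length(idx)
  offs <- which(upper.tri(ct))
  kim_r <- kim_t <- numeric(n)
  for (i in seq_len(n)) {
    kim_r[i] <- sum(abs(cr[i, -i])^beta)
    kim_t[i] <- sum(abs(ct[i, -i])^beta)
  }
  list(meanCor = mean(ct[offs]),
       meanAdj = mean((abs(ct)^beta)[offs]),
       cor_kIM = stats::cor(kim_r, kim_t),
       cor_cor = stats::cor(cr[offs], ct[offs]))
}
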