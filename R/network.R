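#' Network construction parameters
#'
#' @param beta soft-threshold power applied to |correlation| (default 12).
#' @param min_module_size smallest cluster retained as a module (default 30).
#' @param merge_height module-eigengene dissimilarity (1 - cor) below which
#'   modules are merged (default 0.15).
#' @param cut_height_frac static dendrogram cut height as a fraction of the
#'   maximum merge height (default 0.99).
#' @param scale_free_target scale-free topology fit index considered adequate
#'   (default 0.8).
#' @param kme_reassign kME membership-curation threshold (default 0.7): after
#'   merging, every gene is assigned to its best-kME module when that kME
#'   exceeds the threshold and is otherwise unassigned; set to `NA` to
#'   disable.
#' @return A `network_params` list.
#' @export
network_params <- function(beta = 12, min_module_size = 30,
                           merge_height = 0.15, cut_height_frac = 0.99,
                           scale_free_target = 0.8, kme_reassign = 0.7) {
  stopifnot(beta >= 1, min_module_size >= 1,
            merge_height > 0, merge_height <= 1,
            cut_height_frac > 0, cut_height_frac <= 1)
  structure(list(beta = beta, min_module_size = as.integer(min_module_size),
                 merge_height = merge_height,
                 cut_height_frac = cut_height_frac,
                 scale_free_target = scale_free_target,
                 kme_reassign = kme_reassign),
            class = "network_params")
}

#' Gene-gene Pearson correlation matrix
#'
#' @param expr numeric genes x samples expression matrix (at least 3
#'   samples); genes without variance across samples must be removed first.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  bad <- rownames(expr)[v == 0 | is.na(v)]
  if (length(bad))
    stop("zero-variance gene(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  r <- stats::cor(t(expr))
  diag(r) <- 1
  r
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor_ij|^beta`, with unit diagonal.
#'
#' @param cor correlation matrix (entries in `[-1, 1]`).
#' @param beta soft-threshold power.
#' @return Adjacency matrix in `[0, 1]`.
#' @export
soft_adjacency <- function(cor, beta = 12) {
  if (max(abs(cor)) > 1 + 1e-8) stop("|cor| must be <= 1", call. = FALSE)
  a <- abs(cor)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Bins the connectivities `k_i = sum_{j != i} a_ij` into `n_bins`, and
#' regresses `log10(frequency)` on `log10(mean k)` per bin. Returns the
#' signed R-squared: `R^2 * sign(-slope)`, so a near-1 value indicates a
#' power-law-like degree distribution.
#'
#' @param adj adjacency matrix with unit diagonal.
#' @param n_bins number of connectivity bins (default 10); reduced with a
#'   warning if too many bins are empty.
#' @return Signed fit index in `[-1, 1]`.
#' @export
scale_free_fit <- function(adj, n_bins = 10) {
  k <- colSums(adj) - 1
  if (length(unique(k)) < 2) stop("degenerate connectivity", call. = FALSE)
  repeat {
    cuts <- cut(k, breaks = n_bins)
    freq <- as.vector(table(cuts)) / length(k)
    mk <- tapply(k, cuts, mean)
    keep <- freq > 0 & !is.na(mk) & mk > 0
    if (sum(keep) >= 3 || n_bins <= 3) break
    n_bins <- n_bins - 1
    warning("reducing scale-free bins to ", n_bins, call. = FALSE)
  }
  x <- log10(mk[keep]); y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  unname(r2 * sign(-stats::coef(fit)[2]))
}

#' Topological overlap matrix
#'
#' For an unsigned adjacency with unit diagonal,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i` excludes the self-adjacency;
#' the diagonal is 1.
#'
#' @param adj symmetric adjacency matrix with unit diagonal.
#' @return Symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  a <- adj
  diag(a) <- 1
  L <- a %*% a - 2 * a          # removes the u = i and u = j terms (diag 1)
  k <- colSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, a static cut at
#' `cut_height_frac` of the maximum merge height, removal of clusters smaller
#' than `min_module_size` (label 0 = unassigned), then, when `expr` is
#' supplied, iterative merging of modules whose eigengene dissimilarity is
#' below `merge_height` and kME membership curation at the `kme_reassign`
#' threshold. Labels are renumbered by decreasing module size
#' (1 = largest).
#'
#' @param tom TOM from [tom_similarity()].
#' @param params a [network_params()] object.
#' @param expr optional genes x samples expression matrix (same genes as
#'   `tom`), enabling the eigengene-based merge and kME reassignment steps.
#' @return An object of class `module_assignment`: list with `labels` (named
#'   integer vector), `sizes`, `dendro` (the hclust tree) and `params`.
#' @export
detect_modules <- function(tom, params = network_params(), expr = NULL) {
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  cut_h <- params$cut_height_frac * max(tree$height)
  cl <- stats::cutree(tree, h = cut_h)
  labels <- .drop_small(cl, params$min_module_size)

  if (!is.null(expr) && any(labels > 0)) {
    labels <- .merge_by_me(labels, expr, params$merge_height)
    if (!is.na(params$kme_reassign) && any(labels > 0)) {
      ## membership curation: every gene lands in its best-|kME| module when
      ## that |kME| clears the threshold, otherwise it is unassigned; prunes
      ## genes chained onto a cluster by average linkage alone (unsigned
      ## network, so the magnitude is what counts)
      me <- module_eigengenes(expr, labels)
      kme <- abs(module_kme(expr, me))
      best <- max.col(kme, ties.method = "first")
      bestv <- kme[cbind(seq_len(nrow(kme)), best)]
      newlab <- ifelse(bestv > params$kme_reassign,
                       as.integer(sub("^ME", "", colnames(kme)[best])), 0L)
      labels <- stats::setNames(newlab, rownames(kme))[names(labels)]
      labels <- .drop_small(labels, params$min_module_size)
    }
  }
  labels <- .renumber(labels)
  if (all(labels == 0)) warning("all genes unassigned", call. = FALSE)
  names(labels) <- rownames(tom)
  structure(list(labels = labels, sizes = table(labels),
                 dendro = tree, params = params),
            class = "module_assignment")
}

.drop_small <- function(cl, min_size) {
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_size])
  cl[cl %in% small] <- 0L
  cl
}

.renumber <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) return(as.integer(labels))
  sizes <- table(factor(labels[labels != 0L], levels = mods))
  ord <- mods[order(-as.vector(sizes), mods)]
  new <- stats::setNames(seq_along(ord), ord)
  out <- ifelse(labels == 0L, 0L, new[as.character(labels)])
  as.integer(out)
}

.merge_by_me <- function(labels, expr, merge_height) {
  repeat {
    mods <- setdiff(unique(labels), 0L)
    if (length(mods) < 2) return(labels)
    me <- module_eigengenes(expr, labels)
    cc <- stats::cor(t(me))
    diss <- 1 - cc
    diag(diss) <- Inf
    ij <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[ij[1], ij[2]] >= merge_height) return(labels)
    m1 <- as.integer(sub("^ME", "", rownames(me)[ij[1]]))
    m2 <- as.integer(sub("^ME", "", rownames(me)[ij[2]]))
    labels[labels == m2] <- m1
  }
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector (unit norm,
#' over samples) of its members' standardized expression, oriented so that
#' the mean correlation with the member genes is positive.
#'
#' @param expr genes x samples expression matrix.
#' @param labels named integer module labels (0 = unassigned) or a
#'   `module_assignment`.
#' @return Numeric modules x samples matrix (rownames `ME<module>`), with the
#'   proportion of within-module variance explained in attribute
#'   `"var_explained"`. Constant genes are dropped; modules with fewer than 2
#'   usable genes are excluded with a warning.
#' @export
module_eigengenes <- function(expr, labels) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  labels <- labels[rownames(expr)]
  mods <- sort(setdiff(unique(labels), 0L))
  me <- list(); ve <- c()
  for (m in mods) {
    genes <- names(labels)[labels == m]
    x <- expr[genes, , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant gene(s) in module ", m, call. = FALSE)
      x <- x[sds > 0, , drop = FALSE]
    }
    if (nrow(x) < 2) {
      warning("module ", m, " has <2 usable genes; excluded", call. = FALSE)
      next
    }
    xs <- t(scale(t(x)))                     # standardize each gene
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (mean(stats::cor(t(xs), v)) < 0) v <- -v
    me[[paste0("ME", m)]] <- v
    ve[paste0("ME", m)] <- sv$d[1]^2 / sum(sv$d^2)
  }
  if (!length(me)) stop("no usable modules", call. = FALSE)
  out <- do.call(rbind, me)
  colnames(out) <- colnames(expr)
  attr(out, "var_explained") <- ve
  out
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene's expression profile with every module
#' eigengene.
#'
#' @param expr genes x samples expression matrix.
#' @param me eigengene matrix from [module_eigengenes()] (modules x samples,
#'   same sample order).
#' @return Genes x modules matrix of correlations in `[-1, 1]`.
#' @export
module_kme <- function(expr, me) {
  if (ncol(expr) != ncol(me))
    stop("expression and eigengenes must share the sample ordering",
         call. = FALSE)
  stats::cor(t(expr), t(me))
}

#' Module eigengene vs condition ANOVA
#'
#' Per module, fits `ME ~ group + stage` (both categorical) on the sample
#' metadata and reports the F-test P-value of each factor.
#'
#' @param me eigengene matrix (modules x samples).
#' @param samples sample metadata with `group` and `stage` matching the
#'   columns of `me`.
#' @param alpha significance threshold for the `significant` flag.
#' @return Data frame with `module`, `p_group`, `p_stage`, `significant`
#'   (either P < `alpha`). Constant eigengenes give `NA` P-values.
#' @export
me_condition_anova <- function(me, samples, alpha = 0.05) {
  samples <- .de_factors(samples)
  out <- data.frame(module = rownames(me), p_group = NA_real_,
                    p_stage = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(me))) {
    y <- me[i, ]
    if (stats::sd(y) == 0) next
    fit <- stats::lm(y ~ group + stage, data = samples)
    a <- stats::anova(fit)
    out$p_group[i] <- a["group", "Pr(>F)"]
    out$p_stage[i] <- a["stage", "Pr(>F)"]
  }
  out$significant <- !is.na(out$p_group) &
    (out$p_group < alpha | out$p_stage < alpha)
  out
}
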