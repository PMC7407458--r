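#' Fit per-gene negative-binomial GLMs
#'
#' Fits, for every gene, a log-link negative-binomial GLM of the counts on a
#' design built from the sample metadata, with `log(size factor)` offsets.
#' The per-gene dispersion phi (variance = mu + phi mu^2) is a
#' method-of-moments estimate pooled over the design cells of the normalized
#' counts, floored at 1e-8, and is held fixed during fitting (no shrinkage);
#' the same dispersions must be shared between a full and a reduced fit that
#' are compared by [nb_lrt()].
#'
#' Factors are treatment-coded with reference levels `wild` (group), the
#' earliest stage, and subgenome `A`, so coefficient signs read as
#' domesticated-vs-wild, later-vs-earliest, and A-vs-D is the negated
#' `subgenomeD` coefficient.
#'
#' @param cm a [count_matrix()] (genes should already pass
#'   [filter_expressed()]).
#' @param design model formula on columns of `cm$samples`, e.g.
#'   `~ group * stage`.
#' @param sf per-sample size factors; default [size_factors()] of `cm`.
#' @param dispersions optional fixed per-gene dispersions (named or in gene
#'   order), e.g. from a previous fit of the full model.
#' @return An object of class `nb_fit`: coefficients (natural-log scale),
#'   per-gene unscaled covariance array, dispersions, log-likelihoods,
#'   convergence flags, and the design information.
#' @export
fit_nb_glm <- function(cm, design, sf = size_factors(cm), dispersions = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  data <- .de_factors(cm$samples)
  X <- stats::model.matrix(design, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  counts <- cm$counts
  ng <- nrow(counts)
  genes <- rownames(counts)

  if (is.null(dispersions)) {
    dispersions <- .mom_dispersion(counts, sf, X)
  } else {
    if (!is.null(names(dispersions))) dispersions <- dispersions[genes]
    if (length(dispersions) != ng || anyNA(dispersions))
      stop("dispersions must cover every gene", call. = FALSE)
  }

  p <- ncol(X)
  coefs <- matrix(NA_real_, ng, p, dimnames = list(genes, colnames(X)))
  vcovs <- array(NA_real_, c(p, p, ng))
  ll <- rep(NA_real_, ng)
  conv <- logical(ng)
  off <- log(sf)
  for (g in seq_len(ng)) {
    y <- counts[g, ]
    theta <- 1 / dispersions[g]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, family = MASS::negative.binomial(theta = theta, link = "log"),
        offset = off, control = stats::glm.control(maxit = 100, epsilon = 1e-8)
      )),
      error = function(e) NULL)
    if (is.null(fit)) next
    coefs[g, ] <- fit$coefficients
    R <- qr.R(fit$qr)
    vc <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (!is.null(vc)) vcovs[, , g] <- vc
    mu <- fit$fitted.values
    ll[g] <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
    conv[g] <- isTRUE(fit$converged) && !is.null(vc)
  }
  structure(list(
    coefficients = coefs, vcov = vcovs, dispersion = stats::setNames(dispersions, genes),
    loglik = stats::setNames(ll, genes), converged = stats::setNames(conv, genes),
    design = design, X = X, data = data, sf = sf, n_params = p
  ), class = "nb_fit")
}

## canonical treatment coding: wild / earliest stage / subgenome A as references
.de_factors <- function(samples) {
  data <- as.data.frame(samples)
  if ("group" %in% names(data)) {
    lev <- intersect(c("wild", "domesticated"), unique(data$group))
    data$group <- factor(data$group, levels = lev)
  }
  if ("stage" %in% names(data)) {
    lev <- as.character(sort(unique(as.numeric(data$stage))))
    data$stage <- factor(as.character(data$stage), levels = lev)
  }
  if ("subgenome" %in% names(data)) {
    lev <- intersect(c("A", "D"), unique(data$subgenome))
    data$subgenome <- factor(data$subgenome, levels = lev)
  }
  data
}

## Pearson-moment dispersion on normalized counts: per gene, solve
## sum (y - mu)^2 / (mu + phi mu^2) = n - p at the design-cell means mu.
.mom_dispersion <- function(counts, sf, X, floor = 1e-8) {
  y <- sweep(counts, 2, sf, `/`)
  cell <- factor(apply(X, 1, paste, collapse = "\r"))
  p <- nlevels(cell)          # means are saturated cell means
  n <- ncol(y)
  if (n - p < 1) return(rep(floor, nrow(counts)))
  cellmeans <- t(rowsum(t(y), cell)) / rep(as.vector(table(cell)),
                                           each = nrow(y))
  vapply(seq_len(nrow(y)), function(g) {
    mu <- cellmeans[g, as.integer(cell)]
    if (all(mu == 0)) return(floor)
    mu <- pmax(mu, 1e-8)
    r2 <- (y[g, ] - mu)^2
    f <- function(ph) sum(r2 / (mu + ph * mu^2)) - (n - p)
    if (f(0) <= 0) return(floor)
    upper <- 1
    while (f(upper) > 0 && upper < 1e6) upper <- upper * 10
    if (f(upper) > 0) return(upper)
    stats::uniroot(f, c(0, upper), tol = 1e-10)$root
  }, numeric(1))
}

#' Likelihood-ratio test between nested negative-binomial fits
#'
#' Per gene, `2 * (loglik_full - loglik_reduced)` with degrees of freedom
#' equal to the difference in parameter count, referred by default to an F
#' distribution that accounts for the estimated dispersion (see
#' `reference`). Both
#' fits must share the same per-gene dispersions (fit the reduced model with
#' `dispersions = full_fit$dispersion`). Genes that failed convergence in
#' either fit get `NA` and are excluded from the Benjamini-Hochberg
#' denominator.
#'
#' @param full_fit,reduced_fit [fit_nb_glm()] objects with
#'   `reduced ⊂ full` design columns.
#' @param reference null reference for the statistic: `"f"` (default) refers
#'   `stat / df1` to `F(df1, n - p_full)`, a quasi-likelihood-style
#'   small-sample correction for the plug-in dispersion estimate; `"chisq"`
#'   uses the asymptotic chi-square with `df1` degrees of freedom.
#' @return Data frame with columns `gene`, `stat`, `df`, `pvalue`, `padj`,
#'   `test_kind = "LRT"`.
#' @export
nb_lrt <- function(full_fit, reduced_fit, reference = c("f", "chisq")) {
  reference <- match.arg(reference)
  stopifnot(inherits(full_fit, "nb_fit"), inherits(reduced_fit, "nb_fit"))
  if (!all(colnames(reduced_fit$X) %in% colnames(full_fit$X)))
    stop("reduced model is not nested in the full model", call. = FALSE)
  if (full_fit$n_params < reduced_fit$n_params)
    stop("full model must have at least as many parameters as the reduced ",
         "model", call. = FALSE)
  if (max(abs(full_fit$dispersion - reduced_fit$dispersion)) > 0)
    stop("full and reduced fits must share per-gene dispersions", call. = FALSE)
  ok <- full_fit$converged & reduced_fit$converged
  stat <- pmax(2 * (full_fit$loglik - reduced_fit$loglik), 0)
  stat[!ok] <- NA_real_
  df <- full_fit$n_params - reduced_fit$n_params
  p <- if (df == 0) {
    rep(1, length(stat))
  } else if (reference == "f") {
    df2 <- nrow(full_fit$X) - full_fit$n_params
    stats::pf(stat / df, df1 = df, df2 = df2, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  res <- data.frame(gene = names(full_fit$loglik), stat = unname(stat), df = df,
                    pvalue = unname(p), padj = NA_real_,
                    test_kind = "LRT", stringsAsFactors = FALSE)
  res$padj[ok] <- stats::p.adjust(res$pvalue[ok], method = "BH")
  rownames(res) <- NULL
  res
}

#' Wald test of a factor-level contrast
#'
#' Tests `level1 - level2` of one treatment-coded factor using the fitted
#' coefficients and observed-information standard errors. With interactions
#' in the design, the contrast is evaluated at the reference levels of the
#' other factors. Log2 fold changes are reported.
#'
#' @param fit a [fit_nb_glm()] object.
#' @param factor name of the factor, e.g. `"group"`.
#' @param level1,level2 the two levels to contrast (`lfc > 0` means higher in
#'   `level1`).
#' @param reference `"t"` (default) refers the statistic to a t distribution
#'   with `n - p` degrees of freedom, matching the plug-in dispersion
#'   estimate; `"normal"` uses the asymptotic standard normal.
#' @return Data frame with columns `gene`, `lfc`, `se`, `stat`, `pvalue`,
#'   `padj`, `contrast`, `test_kind = "Wald"`.
#' @export
wald_contrast <- function(fit, factor, level1, level2,
                          reference = c("t", "normal")) {
  reference <- match.arg(reference)
  stopifnot(inherits(fit, "nb_fit"))
  lev <- levels(fit$data[[factor]])
  if (is.null(lev) || !all(c(level1, level2) %in% lev))
    stop("unknown level(s) for factor '", factor, "': ",
         paste(setdiff(c(level1, level2), lev), collapse = ", "),
         call. = FALSE)
  cn <- colnames(fit$X)
  v <- stats::setNames(numeric(length(cn)), cn)
  for (s in list(c(level1, 1), c(level2, -1))) {
    nm <- paste0(factor, s[1])
    if (nm %in% cn) v[nm] <- v[nm] + as.numeric(s[2])
    # reference level contributes 0
  }
  est <- as.vector(fit$coefficients %*% v)
  se <- sqrt(vapply(seq_len(dim(fit$vcov)[3]), function(g) {
    as.vector(t(v) %*% fit$vcov[, , g] %*% v)
  }, numeric(1)))
  z <- est / se
  p <- if (reference == "t") {
    2 * stats::pt(-abs(z), df = nrow(fit$X) - fit$n_params)
  } else {
    2 * stats::pnorm(-abs(z))
  }
  ok <- fit$converged & is.finite(p)
  res <- data.frame(gene = rownames(fit$coefficients),
                    lfc = est / log(2), se = se / log(2),
                    stat = z, pvalue = p, padj = NA_real_,
                    contrast = paste0(factor, ":", level1, "-", level2),
                    test_kind = "Wald", stringsAsFactors = FALSE)
  res$pvalue[!ok] <- NA_real_
  res$padj[ok] <- stats::p.adjust(res$pvalue[ok], method = "BH")
  rownames(res) <- NULL
  res
}

#' Homoeolog expression bias per gene pair
#'
#' Builds the subgenome design: each pair becomes one row whose 2n columns
#' are the A-copy and D-copy counts of the n libraries, with `subgenome`
#' added to the sample metadata. An NB GLM of
#' `~ subgenome + group + stage` is fitted per pair and the A-vs-D Wald
#' contrast extracted.
#'
#' @param cm homoeolog-resolved [count_matrix()] (pass the homoeolog
#'   expression filter first).
#' @param pairing pairing table restricted to pairs present in `cm`.
#' @param design model formula; default `~ subgenome + group + stage`.
#' @return The [wald_contrast()] data frame for A-vs-D, with `gene` holding
#'   pair ids.
#' @export
homoeolog_bias <- function(cm, pairing, design = ~ subgenome + group + stage) {
  stopifnot(inherits(cm, "count_matrix"))
  miss <- setdiff(c(pairing$gene_A, pairing$gene_D), rownames(cm$counts))
  if (length(miss))
    stop("pair member(s) absent from counts: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  a <- cm$counts[pairing$gene_A, , drop = FALSE]
  d <- cm$counts[pairing$gene_D, , drop = FALSE]
  colnames(a) <- paste0(colnames(a), "_A")
  colnames(d) <- paste0(colnames(d), "_D")
  doubled <- cbind(a, d)
  rownames(doubled) <- pairing$pair_id
  meta <- rbind(
    transform(cm$samples, sample = paste0(sample, "_A"), subgenome = "A"),
    transform(cm$samples, sample = paste0(sample, "_D"), subgenome = "D")
  )
  dcm <- count_matrix(doubled, meta)
  fit <- fit_nb_glm(dcm, design)
  wald_contrast(fit, "subgenome", "A", "D")
}

#' Classify homoeolog bias from an A-vs-D contrast
#'
#' A pair is A-biased iff its BH-adjusted P-value is below `alpha` and the
#' log2 fold change favors the A copy; D-biased for the D copy; otherwise
#' unbiased.
#'
#' @param bias_result a [wald_contrast()] / [homoeolog_bias()] data frame for
#'   the A-vs-D contrast (`lfc > 0` = A higher).
#' @param alpha significance level on the adjusted P-value.
#' @return Named character vector over pairs with values `"A"`, `"D"`,
#'   `"none"`.
#' @export
classify_bias <- function(bias_result, alpha = 0.05) {
  sig <- !is.na(bias_result$padj) & bias_result$padj < alpha
  cls <- ifelse(sig & bias_result$lfc > 0, "A",
                ifelse(sig & bias_result$lfc < 0, "D", "none"))
  stats::setNames(cls, bias_result$gene)
}
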