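#' Construct a count matrix with sample metadata
#'
#' The basic container of the pipeline: an integer genes x samples matrix of
#' read counts plus a per-sample metadata table. Homoeolog-resolved datasets
#' tag genes with `_A`/`_D` suffixes; joint (pair-summed) datasets use the
#' unsuffixed pair id.
#'
#' @param counts integer matrix, genes in rows (unique rownames), samples in
#'   columns (colnames).
#' @param samples data frame with one row per sample and at least columns
#'   `sample`, `group` (`wild`/`domesticated`), `stage`; usually also
#'   `accession`. Rows are matched to `colnames(counts)` by `sample`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (gene ids)", call. = FALSE)
  if (is.null(colnames(counts)))
    stop("counts must have colnames (sample ids)", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  samples <- as.data.frame(samples)
  if (!"sample" %in% names(samples))
    stop("samples needs a 'sample' column", call. = FALSE)
  miss <- setdiff(colnames(counts), samples$sample)
  if (length(miss))
    stop("metadata missing for samples: ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if ("group" %in% names(x$samples))
    cat("groups:", paste(names(table(x$samples$group)),
                         table(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or sample
#'
#' @param x a [count_matrix()].
#' @param genes character or logical selector of genes (default: all).
#' @param samples character or logical selector of samples (default: all).
#' @return A [count_matrix()] restricted to the selection, order preserved as
#'   given.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  cm <- x$counts
  if (!is.null(genes)) cm <- cm[genes, , drop = FALSE]
  if (!is.null(samples)) cm <- cm[, samples, drop = FALSE]
  count_matrix(cm, x$samples[x$samples$sample %in% colnames(cm), , drop = FALSE])
}

#' Read / write tab-separated count and annotation tables
#'
#' `read_counts` expects a header of sample ids with gene ids in the first
#' column; `read_sample_meta` a table with columns `sample`, `accession`,
#' `group`, `stage`; `read_pairing` columns `gene_A`, `gene_D`, `pair_id`.
#'
#' @param path file path.
#' @param meta_path for `read_counts`, path to the sample metadata table.
#' @return `read_counts`: a [count_matrix()]; the others: data frames.
#' @export
read_counts <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  count_matrix(m, read_sample_meta(meta_path))
}

#' @rdname read_counts
#' @export
read_sample_meta <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_counts
#' @export
read_pairing <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_A", "gene_D", "pair_id")
  if (!all(need %in% names(p)))
    stop("pairing table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(c(p$gene_A, p$gene_D)))
    stop("a gene appears in more than one pair", call. = FALSE)
  p
}

#' @rdname read_counts
#' @param cm a [count_matrix()] to write.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(gene = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sum homoeolog pairs into a joint count matrix
#'
#' Collapses each A/D homoeolog pair to a single "gene" by adding the two
#' copies' counts per sample, producing the joint dataset that treats
#' homoeologs as alleles of one locus.
#'
#' @param cm homoeolog-resolved [count_matrix()].
#' @param pairing data frame with `gene_A`, `gene_D`, `pair_id`.
#' @return A [count_matrix()] with one row per pair (rownames = `pair_id`).
#' @export
sum_pairs <- function(cm, pairing) {
  stopifnot(inherits(cm, "count_matrix"))
  miss <- setdiff(c(pairing$gene_A, pairing$gene_D), rownames(cm$counts))
  if (length(miss))
    stop("pair member(s) absent from counts: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  joint <- cm$counts[pairing$gene_A, , drop = FALSE] +
    cm$counts[pairing$gene_D, , drop = FALSE]
  rownames(joint) <- pairing$pair_id
  count_matrix(joint, cm$samples)
}

#' Expression filter on raw counts
#'
#' `mode = "joint"` keeps genes whose mean raw count over all samples is
#' strictly greater than 1. `mode = "homoeolog"` keeps the genes of pairs in
#' which *both* members have a count of at least 1 in at least half
#' (`ceiling(n/2)`) of the libraries; it requires `pairing`.
#'
#' @param cm a [count_matrix()].
#' @param mode `"joint"` or `"homoeolog"`.
#' @param pairing pairing table, required for homoeolog mode.
#' @return Character vector of kept gene ids, in input order.
#' @export
filter_expressed <- function(cm, mode = c("joint", "homoeolog"),
                             pairing = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  mode <- match.arg(mode)
  if (nrow(cm$counts) == 0 || ncol(cm$counts) == 0)
    stop("empty count matrix", call. = FALSE)
  if (mode == "joint") {
    keep <- rowMeans(cm$counts) > 1
    return(rownames(cm$counts)[keep])
  }
  if (is.null(pairing))
    stop("homoeolog mode requires a pairing table", call. = FALSE)
  half <- ceiling(ncol(cm$counts) / 2)
  ok_gene <- rowSums(cm$counts >= 1) >= half
  ok_pair <- ok_gene[pairing$gene_A] & ok_gene[pairing$gene_D]
  ok_pair[is.na(ok_pair)] <- FALSE
  kept_pairs <- pairing[ok_pair, , drop = FALSE]
  keep <- rownames(cm$counts) %in% c(kept_pairs$gene_A, kept_pairs$gene_D)
  rownames(cm$counts)[keep]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio between the sample's count and the
#' gene's geometric mean across samples.
#'
#' @param cm a [count_matrix()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  allpos <- rowSums(m == 0) == 0
  if (!any(allpos))
    stop("no gene has nonzero counts in every sample; ",
         "consider adding a pseudocount before normalization", call. = FALSE)
  sub <- m[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub, 2, function(col) stats::median(col / geo))
  if (any(sf <= 0)) stop("non-positive size factor", call. = FALSE)
  sf
}

#' Variance-stabilizing log transform
#'
#' Normalizes counts by the size factors and maps them to
#' `log2(count / factor + 1)`, the log-like scale used for correlation and
#' network construction. Monotone in counts; finite for all inputs.
#'
#' @param cm a [count_matrix()].
#' @param factors per-sample size factors, e.g. from [size_factors()];
#'   defaults to computing them from `cm`.
#' @return Numeric genes x samples matrix with attribute
#'   `provenance = "normalized-log"` (or `"raw-log"` when all factors are 1).
#' @export
vst_counts <- function(cm, factors = size_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(factors <= 0)) stop("size factors must be positive", call. = FALSE)
  if (length(factors) != ncol(cm$counts))
    stop("one size factor per sample required", call. = FALSE)
  x <- log2(sweep(cm$counts, 2, factors, `/`) + 1)
  attr(x, "provenance") <-
    if (all(factors == 1)) "raw-log" else "normalized-log"
  x
}
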