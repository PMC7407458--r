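#' Simulation parameters for homoeolog-pair count data
#'
#' Bundles and validates the parameters of the negative-binomial homoeolog-pair
#' simulator. The default design mirrors a wild-vs-domesticated allopolyploid
#' fiber study: 2 domestication groups x 4 developmental stages (5, 10, 15,
#' 20 dpa) x 3 accessions = 24 libraries, with an A- and a D-subgenome copy
#' per gene pair.
#'
#' @param n_pairs number of homoeolog gene pairs.
#' @param n_modules number of planted coexpression modules.
#' @param module_sizes integer vector of planted module sizes (in pairs);
#'   must sum to at most `n_pairs`. Pairs beyond the planted modules are
#'   background (module 0).
#' @param n_accessions biological replicates (accessions) per group.
#' @param timepoints ordered developmental stage labels in days post-anthesis.
#' @param bias_fraction fraction of pairs with homoeolog expression bias
#'   (split evenly between A- and D-bias).
#' @param bias_lfc log2 magnitude of the planted bias. Applied symmetrically
#'   (+/- `bias_lfc`/2 per subgenome) so the summed pair signal is unchanged.
#' @param split_fraction fraction of pairs whose A and D copies belong to
#'   different planted modules (co-module divergence).
#' @param rewire_fraction fraction of module-member genes whose coexpression
#'   is rewired between the wild and domesticated groups (by sign-flipping
#'   their module loading in the domesticated samples).
#' @param dispersion negative-binomial dispersion phi >= 0 (variance =
#'   mu + phi * mu^2). `dispersion = 0` yields deterministic rounded means.
#' @param lib_size_range range of multiplicative library-size factors.
#' @param noise_sd residual standard deviation on the latent log2 scale.
#' @param seed integer RNG seed; identical parameters (including seed) give
#'   bit-identical output.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [generate_truth()], [simulate_counts()]
#' @export
sim_params <- function(n_pairs = 1000,
                       n_modules = 4,
                       module_sizes = rep(150L, 4),
                       n_accessions = 3,
                       timepoints = c(5, 10, 15, 20),
                       bias_fraction = 0.4,
                       bias_lfc = 1,
                       split_fraction = 0.8,
                       rewire_fraction = 0.3,
                       dispersion = 0.05,
                       lib_size_range = c(0.7, 1.3),
                       noise_sd = 0.1,
                       seed = 1L) {
  p <- list(
    n_pairs = as.integer(n_pairs), n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    n_accessions = as.integer(n_accessions), timepoints = timepoints,
    bias_fraction = bias_fraction, bias_lfc = bias_lfc,
    split_fraction = split_fraction, rewire_fraction = rewire_fraction,
    dispersion = dispersion, lib_size_range = as.numeric(lib_size_range),
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (length(p$module_sizes) != p$n_modules)
    stop("module_sizes must have length n_modules", call. = FALSE)
  if (sum(p$module_sizes) > p$n_pairs)
    stop("sum(module_sizes) exceeds n_pairs", call. = FALSE)
  for (f in c("bias_fraction", "split_fraction", "rewire_fraction")) {
    v <- p[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  }
  if (p$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(p$lib_size_range) != 2 || any(p$lib_size_range <= 0) ||
      diff(p$lib_size_range) < 0)
    stop("lib_size_range must be an increasing positive pair", call. = FALSE)
  if (p$n_accessions < 1) stop("n_accessions must be >= 1", call. = FALSE)
  invisible(p)
}

#' Generate the ground truth of a simulated homoeolog-pair dataset
#'
#' Draws, deterministically under the seed in `params`, the latent structure
#' that [simulate_counts()] turns into read counts: planted module labels for
#' the A and D copy of every pair, per-pair homoeolog-bias classes, per-module
#' latent activity profiles over the 2 x 4 condition grid, per-pair module
#' loadings, and the set of genes rewired between wild and domesticated
#' groups.
#'
#' Module labels are assigned to pairs in contiguous blocks (pairs beyond the
#' planted modules get label 0 = background). Exactly
#' `floor(split_fraction * n_pairs)` randomly chosen pairs have their D copy
#' reassigned to a different module. Rewired genes are drawn per module
#' (`floor(rewire_fraction * module member count)` members each); their
#' domesticated-group label is recorded as 0 since the sign-flipped copy is no
#' longer a positively co-regulated member, and every same-module pair with
#' exactly one rewired member enters `dc_pair_set`.
#'
#' @param params a [sim_params()] object.
#' @return An object of class `sim_truth`: a list with per-gene label vectors
#'   `module_label_A`, `module_label_D` (and wild/domesticated variants
#'   `module_wild`, `module_dom` over all 2 * n_pairs genes), `bias_class`,
#'   `latent_profiles` (module x condition matrix), `loadings`, `split_pairs`,
#'   `rewired` gene ids and `dc_pair_set`.
#' @export
generate_truth <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  np <- params$n_pairs
  K <- params$n_modules

  pair_id <- sprintf("p%04d", seq_len(np))
  gene_A <- paste0(pair_id, "_A")
  gene_D <- paste0(pair_id, "_D")

  ## contiguous block assignment of pairs to planted modules
  label_A <- integer(np)
  at <- 1L
  for (m in seq_len(K)) {
    sz <- params$module_sizes[m]
    if (sz > 0) label_A[at:(at + sz - 1L)] <- m
    at <- at + sz
  }
  label_D <- label_A

  ## co-module divergence: D copy moves to a different module
  n_split <- floor(params$split_fraction * np)
  split_pairs <- integer(0)
  if (n_split > 0) {
    split_pairs <- sort(sample.int(np, n_split))
    for (i in split_pairs) {
      choices <- if (label_A[i] == 0L) seq_len(K) else setdiff(seq_len(K), label_A[i])
      if (length(choices) == 0L) choices <- 0L  # single-module edge case
      label_D[i] <- if (length(choices) == 1L) choices else sample(choices, 1L)
    }
  }

  ## homoeolog bias classes, split evenly A/D
  bias_class <- rep("none", np)
  n_bias <- floor(params$bias_fraction * np)
  if (n_bias > 0) {
    idx <- sample.int(np, n_bias)
    n_a <- ceiling(n_bias / 2)
    bias_class[idx[seq_len(n_a)]] <- "A"
    if (n_bias > n_a) bias_class[idx[(n_a + 1L):n_bias]] <- "D"
  }

  ## latent module activity over the 2 x 4 condition grid (log2 units):
  ## a developmental shape shared by both groups plus a per-group offset, so
  ## domestication shifts expression level without altering correlations —
  ## rewiring (below) is then the only source of correlation change
  groups <- c("wild", "domesticated")
  conds <- as.vector(outer(params$timepoints, groups,
                           function(t, g) paste(g, t, sep = "_")))
  cond_stage <- rep(seq_along(params$timepoints), times = length(groups))
  cond_group <- rep(seq_along(groups), each = length(params$timepoints))
  nt <- length(params$timepoints)
  ## planted modules must be mutually identifiable and carry real signal:
  ## each profile is redrawn until it is distinct from the accepted ones
  ## (|cor| <= 0.4 — an unsigned network cannot tell strongly (anti-)
  ## correlated profiles apart) and has amplitude sd >= 0.9 log2 units;
  ## amplitudes are kept moderate so that median-of-ratios normalization
  ## is not distorted by the planted structure
  mod_names <- if (K > 0) paste0("M", seq_len(K)) else character(0)
  latent <- matrix(0, K, length(conds), dimnames = list(mod_names, conds))
  for (m in seq_len(K)) {
    for (try in 1:200) {
      prof <- stats::rnorm(nt, 0, 1.2)[cond_stage] +
        stats::rnorm(2, 0, 0.6)[cond_group]
      if (stats::sd(prof) < 0.9) next
      if (m > 1 &&
          max(abs(stats::cor(prof, t(latent[seq_len(m - 1), , drop = FALSE])))) > 0.4)
        next
      break
    }
    latent[m, ] <- prof
  }
  ## weak developmental profiles for background pairs: with few distinct
  ## stages, high-amplitude independent profiles would still correlate by
  ## chance, so non-modular genes must sit near the noise floor;
  ## no group offset — a shared domestication step across many independent
  ## genes would itself constitute a (spurious) module
  shape_bg <- matrix(stats::rnorm(np * nt, 0, 0.2), nrow = np)
  latent_bg <- shape_bg[, cond_stage, drop = FALSE]
  dimnames(latent_bg) <- list(pair_id, conds)

  ## loading magnitudes 0.6-1.0 with random signs: planted modules contain
  ## both positively and negatively co-regulated members (as unsigned-network
  ## modules do), which keeps the per-sample count distribution balanced so
  ## median-of-ratios normalization is not distorted by module activity
  loadings <- stats::runif(np, 0.6, 1.0) *
    sample(c(-1, 1), np, replace = TRUE)
  names(loadings) <- pair_id
  base_log2 <- stats::runif(np, 5, 9)
  names(base_log2) <- pair_id

  ## per-gene labels; rewiring flips loadings in the domesticated group,
  ## drawn stratified within each planted module
  genes <- c(gene_A, gene_D)
  gene_label <- c(label_A, label_D)
  names(gene_label) <- genes
  rewired <- character(0)
  if (params$rewire_fraction > 0) {
    for (m in seq_len(K)) {
      members <- genes[gene_label == m]
      n_rw <- floor(params$rewire_fraction * length(members))
      if (n_rw > 0) rewired <- c(rewired, sample(members, n_rw))
    }
  }

  module_wild <- gene_label
  module_dom <- gene_label
  module_dom[rewired] <- 0L

  ## pairs whose wild/domesticated correlation differs by construction:
  ## same planted module, exactly one member rewired
  dc_pair_set <- NULL
  if (length(rewired) > 0) {
    rw <- names(gene_label) %in% rewired
    out <- vector("list", K)
    for (m in seq_len(K)) {
      flip <- genes[gene_label == m & rw]
      keep <- genes[gene_label == m & !rw]
      if (length(flip) && length(keep))
        out[[m]] <- expand.grid(gene_i = flip, gene_j = keep,
                                stringsAsFactors = FALSE)
    }
    dc_pair_set <- do.call(rbind, out)
  }
  if (is.null(dc_pair_set))
    dc_pair_set <- data.frame(gene_i = character(0), gene_j = character(0))

  structure(list(
    pair_id = pair_id, gene_A = gene_A, gene_D = gene_D,
    module_label_A = stats::setNames(label_A, pair_id),
    module_label_D = stats::setNames(label_D, pair_id),
    module_wild = module_wild, module_dom = module_dom,
    bias_class = stats::setNames(bias_class, pair_id),
    latent_profiles = latent, latent_background = latent_bg,
    loadings = loadings, base_log2 = base_log2,
    split_pairs = pair_id[split_pairs], rewired = sort(rewired),
    dc_pair_set = dc_pair_set, params = params
  ), class = "sim_truth")
}

#' Simulate homoeolog-specific read counts from a ground truth
#'
#' Expression of gene g in sample s is generated on the log2 scale as
#' `base + loading * latent(module, condition) + bias/2 + noise`, exponentiated
#' to a negative-binomial mean, multiplied by a per-library size factor, and
#' drawn from NB(mean, phi). With `dispersion = 0` the counts are the rounded
#' deterministic means. A-biased pairs shift the A copy up and the D copy down
#' by `bias_lfc/2` each (and vice versa), so the pair sum is bias-invariant.
#' Rewired genes have the sign of their loading flipped in domesticated
#' samples.
#'
#' The RNG draw order is fixed (library factors, then noise, then counts), so
#' identical truth and params give bit-identical matrices.
#'
#' @param truth a [generate_truth()] result.
#' @param params the same [sim_params()] object used to generate `truth`.
#' @return A [count_matrix()] of 2 * n_pairs genes (suffixes `_A`/`_D`) by
#'   `2 * length(timepoints) * n_accessions` samples, with sample metadata.
#' @export
simulate_counts <- function(truth, params) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_sim_params(params)
  if (!identical(truth$params$seed, params$seed) ||
      !identical(truth$params$n_pairs, params$n_pairs))
    stop("truth was generated from different parameters", call. = FALSE)
  set.seed(params$seed + 1L)

  np <- params$n_pairs
  groups <- c("wild", "domesticated")
  meta <- expand.grid(accession = seq_len(params$n_accessions),
                      stage = params$timepoints, group = groups,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("group", "stage", "accession")]
  meta$accession <- paste0(substr(meta$group, 1, 1), "acc", meta$accession)
  meta$sample <- sprintf("%s_%sdpa_%s", meta$group, meta$stage, meta$accession)
  ns <- nrow(meta)
  cond <- paste(meta$group, meta$stage, sep = "_")

  lib <- stats::runif(ns, params$lib_size_range[1], params$lib_size_range[2])

  genes <- c(truth$gene_A, truth$gene_D)
  ng <- length(genes)
  copy <- rep(c("A", "D"), each = np)
  pair <- rep(truth$pair_id, 2)
  label <- c(unname(truth$module_label_A), unname(truth$module_label_D))

  ## latent signal per gene x sample
  sig <- matrix(0, ng, ns)
  for (g in seq_len(ng)) {
    p <- pair[g]
    if (label[g] > 0) {
      prof <- truth$latent_profiles[label[g], cond]
      sgn <- if (genes[g] %in% truth$rewired)
        ifelse(meta$group == "domesticated", -1, 1) else rep(1, ns)
      sig[g, ] <- sgn * truth$loadings[p] * prof
    } else {
      sig[g, ] <- truth$loadings[p] * truth$latent_background[p, cond]
    }
  }

  bias_term <- ifelse(truth$bias_class[pair] == "A", params$bias_lfc / 2,
               ifelse(truth$bias_class[pair] == "D", -params$bias_lfc / 2, 0))
  bias_term <- bias_term * ifelse(copy == "A", 1, -1)

  log2mu <- sweep(sig, 1, truth$base_log2[pair] + bias_term, `+`)
  if (params$noise_sd > 0)
    log2mu <- log2mu + matrix(stats::rnorm(ng * ns, 0, params$noise_sd), ng, ns)
  mu <- sweep(2^log2mu, 2, lib, `*`)

  if (params$dispersion == 0) {
    counts <- round(mu)
  } else {
    counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = 1 / params$dispersion),
                     ng, ns)
  }
  dimnames(counts) <- list(genes, meta$sample)
  storage.mode(counts) <- "integer"

  count_matrix(counts, meta[, c("sample", "accession", "group", "stage")])
}

#' Homoeolog pairing table of a simulated dataset
#'
#' @param truth a [generate_truth()] result.
#' @return A data frame with columns `gene_A`, `gene_D`, `pair_id`.
#' @export
sim_pairing <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  data.frame(gene_A = truth$gene_A, gene_D = truth$gene_D,
             pair_id = truth$pair_id, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to tab-separated files
#'
#' Emits the same formats consumed by the I/O layer: `counts.tsv`,
#' `samples.tsv`, `pairs.tsv`, and the truth tables `truth_modules.tsv`
#' (per-gene wild/domesticated labels) and `truth_bias.tsv`.
#'
#' @param truth a [generate_truth()] result.
#' @param counts the matching [simulate_counts()] result.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
write_sim <- function(truth, counts, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("counts.tsv", "samples.tsv", "pairs.tsv",
                               "truth_modules.tsv", "truth_bias.tsv"))
  write_counts(counts, paths[1])
  utils::write.table(counts$samples, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim_pairing(truth), paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tm <- data.frame(gene = names(truth$module_wild),
                   module_wild = unname(truth$module_wild),
                   module_dom = unname(truth$module_dom),
                   rewired = names(truth$module_wild) %in% truth$rewired)
  utils::write.table(tm, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- data.frame(pair_id = truth$pair_id,
                   bias_class = unname(truth$bias_class))
  utils::write.table(tb, paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
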