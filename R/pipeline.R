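#' Pipeline configuration
#'
#' Collects the per-stage parameters of the full analysis. Either supply a
#' [sim_params()] object (`sim`) to run on simulated data, or the three input
#' paths (`counts`, `samples`, `pairs`).
#'
#' @param sim optional [sim_params()]; when given, input paths are ignored.
#' @param counts,samples,pairs paths to tab-separated inputs (see
#'   [read_counts()]).
#' @param network a [network_params()] object.
#' @param alpha significance level used for DE, bias and DC calls.
#' @param preservation_n_perm permutations for [module_preservation()].
#' @param dc_method `"lfdr"` or `"bh"` for [dc_pairs()].
#' @param dc_max_genes cap on the number of genes entering the all-pairs DC
#'   stage (the most variable genes are kept beyond it).
#' @param gsea_modules number of largest homoeologous-network modules whose
#'   kME rankings are tested for DE-category enrichment.
#' @param gsea_n_perm permutations for [gsea_preranked()].
#' @param annotations optional path to a two-column gene/term table for
#'   hypergeometric enrichment of DC genes.
#' @param seed global seed propagated to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, counts = NULL, samples = NULL,
                            pairs = NULL, network = network_params(),
                            alpha = 0.05, preservation_n_perm = 100,
                            dc_method = c("lfdr", "bh"), dc_max_genes = 1000,
                            gsea_modules = 3, gsea_n_perm = 200,
                            annotations = NULL, seed = 1L) {
  dc_method <- match.arg(dc_method)
  if (is.null(sim)) {
    for (p in c(counts, samples, pairs))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    if (is.null(counts) || is.null(samples) || is.null(pairs))
      stop("either 'sim' or all of counts/samples/pairs must be given",
           call. = FALSE)
  } else {
    stopifnot(inherits(sim, "sim_params"))
  }
  structure(list(sim = sim, counts = counts, samples = samples, pairs = pairs,
                 network = network, alpha = alpha,
                 preservation_n_perm = preservation_n_perm,
                 dc_method = dc_method, dc_max_genes = dc_max_genes,
                 gsea_modules = gsea_modules, gsea_n_perm = gsea_n_perm,
                 annotations = annotations, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full duplicated-network analysis
#'
#' Orchestrates: data (simulation or files) -> expression filters and
#' normalization -> differential expression (development / domestication /
#' interaction, homoeolog bias) -> four networks (joint, homoeologous, wild,
#' domesticated) -> module preservation (joint vs A, joint vs D, wild vs
#' domesticated) -> per-module bias table and co-module fraction ->
#' differential correlation and DC genes -> kME-ranked enrichment of DE
#' categories. Result tables are written to `outdir` together with a
#' `manifest.txt` recording parameters, seeds and per-stage gene counts; the
#' same objects are returned invisibly. A stage failure raises an error named
#' after the stage, with earlier outputs retained on disk.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, a named list of all result objects.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(outdir, "manifest.txt")
  cat(sprintf("polynet %s seed=%d started=%s\n",
              as.character(utils::packageVersion("polynet")),
              config$seed, format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file = manifest)
  log_stage <- function(stage, ...) {
    line <- paste(stage, paste(..., sep = " "), sep = ": ")
    cat(line, "\n", sep = "", file = manifest, append = TRUE)
    message(line)
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[3]
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    log_stage(stage, sprintf("elapsed=%.1fs", proc.time()[3] - t0))
    out
  }
  res <- list(config = config)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## -- data ------------------------------------------------------------
  dat <- run_stage("data", function() {
    if (!is.null(config$sim)) {
      truth <- generate_truth(config$sim)
      cm <- simulate_counts(truth, config$sim)
      list(cm = cm, pairing = sim_pairing(truth), truth = truth)
    } else {
      list(cm = read_counts(config$counts, config$samples),
           pairing = read_pairing(config$pairs), truth = NULL)
    }
  })
  res$truth <- dat$truth
  log_stage("data", sprintf("genes=%d samples=%d pairs=%d",
                            nrow(dat$cm$counts), ncol(dat$cm$counts),
                            nrow(dat$pairing)))

  ## -- filters + normalization ----------------------------------------
  prep <- run_stage("prepare", function() {
    joint_all <- sum_pairs(dat$cm, dat$pairing)
    keep_joint <- filter_expressed(joint_all, "joint")
    joint_cm <- subset_counts(joint_all, keep_joint)
    keep_hom <- filter_expressed(dat$cm, "homoeolog", dat$pairing)
    hom_cm <- subset_counts(dat$cm, keep_hom)
    pairing_hom <- dat$pairing[dat$pairing$gene_A %in% keep_hom &
                                 dat$pairing$gene_D %in% keep_hom, ]
    wild <- dat$cm$samples$sample[dat$cm$samples$group == "wild"]
    dom <- dat$cm$samples$sample[dat$cm$samples$group == "domesticated"]
    list(joint_cm = joint_cm, hom_cm = hom_cm, pairing_hom = pairing_hom,
         joint_expr = vst_counts(joint_cm), hom_expr = vst_counts(hom_cm),
         wild_expr = vst_counts(subset_counts(hom_cm, samples = wild)),
         dom_expr = vst_counts(subset_counts(hom_cm, samples = dom)))
  })
  res$prep <- prep
  log_stage("prepare", sprintf("joint=%d homoeolog=%d pairs=%d",
                               nrow(prep$joint_cm$counts),
                               nrow(prep$hom_cm$counts),
                               nrow(prep$pairing_hom)))

  ## -- differential expression ----------------------------------------
  de <- run_stage("de", function() {
    cm <- prep$hom_cm
    full <- fit_nb_glm(cm, ~ group * stage)
    red_int <- fit_nb_glm(cm, ~ group + stage, dispersions = full$dispersion)
    red_dev <- fit_nb_glm(cm, ~ group, dispersions = full$dispersion)
    red_dom <- fit_nb_glm(cm, ~ stage, dispersions = full$dispersion)
    list(interaction = nb_lrt(full, red_int),
         development = nb_lrt(red_int, red_dev),
         domestication = nb_lrt(red_int, red_dom),
         fit_additive = red_int)
  })
  n_sig <- function(x) sum(!is.na(x$padj) & x$padj < config$alpha)
  de_summary <- data.frame(
    effect = c("development", "domestication", "interaction"),
    n_significant = c(n_sig(de$development), n_sig(de$domestication),
                      n_sig(de$interaction)),
    n_tested = nrow(prep$hom_cm$counts))
  res$de <- de; res$de_summary <- de_summary
  tsv(de_summary, "de_summary.tsv")
  for (nm in c("development", "domestication", "interaction"))
    tsv(de[[nm]], paste0("de_", nm, ".tsv"))

  ## -- homoeolog bias ---------------------------------------------------
  bias <- run_stage("bias", function() {
    br <- homoeolog_bias(prep$hom_cm, prep$pairing_hom)
    list(result = br, classes = classify_bias(br, config$alpha))
  })
  res$bias <- bias
  tsv(data.frame(pair_id = names(bias$classes), bias = unname(bias$classes)),
      "bias_classes.tsv")

  ## -- networks ---------------------------------------------------------
  nets <- run_stage("network", function() {
    list(joint = .build_network(prep$joint_expr, config$network,
                                prep$joint_cm$samples),
         homoeologous = .build_network(prep$hom_expr, config$network,
                                       prep$hom_cm$samples),
         wild = .build_network(prep$wild_expr, config$network),
         domesticated = .build_network(prep$dom_expr, config$network))
  })
  res$networks <- nets
  for (nm in names(nets)) {
    tsv(data.frame(gene = names(nets[[nm]]$modules$labels),
                   module = unname(nets[[nm]]$modules$labels)),
        paste0("modules_", nm, ".tsv"))
    if (!is.null(nets[[nm]]$anova))
      tsv(nets[[nm]]$anova, paste0("me_anova_", nm, ".tsv"))
  }
  log_stage("network", paste(vapply(names(nets), function(nm)
    sprintf("%s=%d", nm, length(setdiff(unique(nets[[nm]]$modules$labels), 0L))),
    character(1)), collapse = " "))

  ## -- preservation -----------------------------------------------------
  pres <- run_stage("preserve", function() {
    jl <- nets$joint$modules$labels
    a_expr <- .pair_view(prep$hom_expr, prep$pairing_hom, "gene_A")
    d_expr <- .pair_view(prep$hom_expr, prep$pairing_hom, "gene_D")
    list(
      joint_vs_A = module_preservation(jl, nets$joint$expr, a_expr,
                                       config$preservation_n_perm,
                                       seed = config$seed,
                                       beta = config$network$beta),
      joint_vs_D = module_preservation(jl, nets$joint$expr, d_expr,
                                       config$preservation_n_perm,
                                       seed = config$seed + 1L,
                                       beta = config$network$beta),
      wild_vs_dom = module_preservation(nets$wild$modules$labels,
                                        nets$wild$expr, prep$dom_expr,
                                        config$preservation_n_perm,
                                        seed = config$seed + 2L,
                                        beta = config$network$beta))
  })
  res$preservation <- pres
  for (nm in names(pres)) tsv(as.data.frame(pres[[nm]]),
                              paste0("preservation_", nm, ".tsv"))

  ## -- homoeolog comparison --------------------------------------------
  comp <- run_stage("bias-table", function() {
    hl <- nets$homoeologous$modules$labels
    cmf <- co_module_fraction(hl, hl, prep$pairing_hom)
    bt <- module_bias_table(.joint_pair_labels(nets$joint$modules$labels),
                            bias$classes, config$alpha)
    list(co_module = cmf, bias_table = bt)
  })
  res$comparison <- comp
  tsv(comp$bias_table, "bias_table.tsv")
  tsv(data.frame(comp$co_module[c("fraction", "n_matched", "n_assigned",
                                  "n_expressed", "n_pairs", "denominator")]),
      "co_module.tsv")

  ## -- differential correlation ----------------------------------------
  dc <- run_stage("diffcorr", function() {
    genes <- intersect(rownames(prep$wild_expr), rownames(prep$dom_expr))
    if (length(genes) > config$dc_max_genes) {
      v <- apply(prep$hom_expr[genes, ], 1, stats::var)
      genes <- names(sort(v, decreasing = TRUE))[seq_len(config$dc_max_genes)]
    }
    genes <- genes[apply(prep$wild_expr[genes, ], 1, stats::var) > 0 &
                     apply(prep$dom_expr[genes, ], 1, stats::var) > 0]
    pairs <- dc_pairs(prep$wild_expr[genes, ], prep$dom_expr[genes, ],
                      threshold = config$alpha, method = config$dc_method)
    list(pairs = pairs, genes = dc_genes(pairs, config$alpha))
  })
  res$dc <- dc
  tsv(dc$genes, "dc_genes.tsv")
  log_stage("diffcorr", sprintf("pairs=%d sig=%d dc_genes=%d",
                                nrow(dc$pairs), sum(dc$pairs$sig),
                                sum(dc$genes$dc_gene)))

  ## -- enrichment -------------------------------------------------------
  enr <- run_stage("enrich", function() {
    sets <- list(
      development_de = de$development$gene[!is.na(de$development$padj) &
                                             de$development$padj < config$alpha],
      domestication_de = de$domestication$gene[!is.na(de$domestication$padj) &
                                                 de$domestication$padj < config$alpha])
    sets <- sets[vapply(sets, length, integer(1)) >= 5]
    kme <- nets$homoeologous$kme
    sz <- sort(table(nets$homoeologous$modules$labels[
      nets$homoeologous$modules$labels > 0]), decreasing = TRUE)
    mods <- utils::head(names(sz), config$gsea_modules)
    gsea <- NULL
    if (length(sets) && length(mods)) {
      gs <- lapply(mods, function(m) {
        cn <- paste0("ME", m)
        if (!cn %in% colnames(kme)) return(NULL)
        r <- gsea_preranked(kme[, cn], sets, n_perm = config$gsea_n_perm,
                            seed = config$seed + as.integer(m))
        cbind(module = m, r)
      })
      gsea <- do.call(rbind, gs[!vapply(gs, is.null, logical(1))])
    }
    hyper <- NULL
    if (!is.null(config$annotations)) {
      ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE)
      dcg <- dc$genes$gene[dc$genes$dc_gene]
      if (length(dcg))
        hyper <- hypergeom_enrich(dcg, dc$genes$gene, ann)
    }
    list(gsea = gsea, hypergeom = hyper)
  })
  res$enrichment <- enr
  if (!is.null(enr$gsea)) tsv(enr$gsea, "enrichment_gsea.tsv")
  if (!is.null(enr$hypergeom)) tsv(enr$hypergeom, "enrichment_hypergeom.tsv")

  log_stage("done", sprintf("outdir=%s", normalizePath(outdir)))
  invisible(res)
}

## drop zero-variance genes, then cor -> adjacency -> TOM -> modules -> ME/kME
.build_network <- function(expr, params, samples = NULL) {
  v <- apply(expr, 1, stats::var)
  expr <- expr[v > 0, , drop = FALSE]
  cc <- correlation_matrix(expr)
  adj <- soft_adjacency(cc, params$beta)
  sft <- tryCatch(scale_free_fit(adj), error = function(e) NA_real_)
  tom <- tom_similarity(adj)
  mods <- detect_modules(tom, params, expr = expr)
  me <- kme <- anova <- NULL
  if (any(mods$labels > 0)) {
    me <- module_eigengenes(expr, mods$labels)
    kme <- module_kme(expr, me)
    if (!is.null(samples)) me_anova <- me_condition_anova(me, samples)
    anova <- if (!is.null(samples)) me_anova else NULL
  }
  list(expr = expr, modules = mods, eigengenes = me, kme = kme,
       scale_free_fit = sft, anova = anova)
}

## re-index a homoeolog expression matrix by pair id for one subgenome
.pair_view <- function(expr, pairing, col) {
  x <- expr[pairing[[col]], , drop = FALSE]
  rownames(x) <- pairing$pair_id
  x
}

## joint network labels are already indexed by pair id
.joint_pair_labels <- function(labels) labels
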