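sim_two_group <- function(ngene, lfc = 0, mu0 = 100, phi = 0.1, n = 12,
                          seed = 1) {
  set.seed(seed)
  meta <- data.frame(sample = sprintf("s%02d", 1:(2 * n)),
                     accession = 1:(2 * n),
                     group = rep(c("wild", "domesticated"), each = n),
                     stage = 5)
  mu <- cbind(matrix(mu0, ngene, n), matrix(mu0 * 2^lfc, ngene, n))
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), ngene)
  dimnames(cnt) <- list(sprintf("g%04d", seq_len(ngene)), meta$sample)
  count_matrix(cnt, meta)
}

test_that("one-factor NB fit reproduces group means (closed-form MLE)", {
  cm <- sim_two_group(40, lfc = 1, seed = 2)
  fit <- fit_nb_glm(cm, ~ group, sf = rep(1, 24))
  wild_mean <- rowMeans(cm$counts[, 1:12])
  dom_mean <- rowMeans(cm$counts[, 13:24])
  expect_equal(unname(exp(fit$coefficients[, "(Intercept)"])),
               unname(wild_mean), tolerance = 1e-8)
  expect_equal(unname(exp(rowSums(fit$coefficients))),
               unname(dom_mean), tolerance = 1e-8)
  expect_true(all(fit$converged))
})

test_that("symmetric counts give a zero group coefficient", {
  meta <- data.frame(sample = paste0("s", 1:8), accession = 1:8,
                     group = rep(c("wild", "domesticated"), each = 4),
                     stage = 5)
  cnt <- matrix(rep(c(10L, 20L, 30L, 40L), 2), 2, 8, byrow = TRUE,
                dimnames = list(c("g1", "g2"), meta$sample))
  fit <- fit_nb_glm(count_matrix(cnt, meta), ~ group, sf = rep(1, 8),
                    dispersions = c(0.1, 0.1))
  expect_equal(unname(fit$coefficients[, "groupdomesticated"]), c(0, 0),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the aliased term named", {
  cm <- sim_two_group(5, seed = 3)
  cm$samples$dup <- cm$samples$group
  expect_error(fit_nb_glm(cm, ~ group + dup, sf = rep(1, 24)),
               "rank deficient")
})

test_that("the LRT of identical models is exactly null", {
  cm <- sim_two_group(10, seed = 4)
  fit <- fit_nb_glm(cm, ~ group, sf = rep(1, 24))
  res <- nb_lrt(fit, fit)
  expect_equal(res$stat, rep(0, 10))
  expect_equal(res$pvalue, rep(1, 10))
})

test_that("the LRT is invariant to design reparameterization", {
  p <- sim_params(n_pairs = 40, n_modules = 1, module_sizes = 20L, seed = 6,
                  split_fraction = 0)
  tr <- generate_truth(p)
  cm <- simulate_counts(tr, p)
  full <- fit_nb_glm(cm, ~ group * stage)
  red <- fit_nb_glm(cm, ~ group + stage, dispersions = full$dispersion)
  res1 <- nb_lrt(full, red)

  # permuting the samples must not change the per-gene statistics
  set.seed(99)
  perm <- sample(ncol(cm$counts))
  cm2 <- count_matrix(cm$counts[, perm], cm$samples[perm, ])
  full2 <- fit_nb_glm(cm2, ~ group * stage, dispersions = full$dispersion)
  red2 <- fit_nb_glm(cm2, ~ group + stage, dispersions = full$dispersion)
  res2 <- nb_lrt(full2, red2)
  expect_equal(res1$stat, res2$stat, tolerance = 1e-6)
  expect_true(all(res1$stat >= 0))
})

test_that("Wald contrasts are antisymmetric and match the null at equality", {
  cm <- sim_two_group(30, lfc = 1.5, phi = 0.05, seed = 7)
  fit <- fit_nb_glm(cm, ~ group, sf = rep(1, 24))
  fw <- wald_contrast(fit, "group", "domesticated", "wild")
  bw <- wald_contrast(fit, "group", "wild", "domesticated")
  expect_equal(fw$lfc, -bw$lfc)
  expect_equal(fw$pvalue, bw$pvalue)
  expect_error(wald_contrast(fit, "group", "feral", "wild"), "unknown level")

  # planted lfc recovered without systematic bias
  expect_equal(mean(fw$lfc), 1.5, tolerance = 0.2)
})

test_that("Wald and LRT agree on which genes carry a planted effect", {
  cm <- sim_two_group(120, lfc = 0, phi = 0.05, seed = 8)
  half <- 1:60
  cm$counts[half, 13:24] <- matrix(
    rnbinom(60 * 12, mu = 100 * 2^1.5, size = 20), 60)
  fit_full <- fit_nb_glm(cm, ~ group, sf = rep(1, 24))
  fit_null <- fit_nb_glm(cm, ~ 1, sf = rep(1, 24),
                         dispersions = fit_full$dispersion)
  lr <- nb_lrt(fit_full, fit_null)
  wd <- wald_contrast(fit_full, "group", "domesticated", "wild")
  sig_l <- lr$gene[!is.na(lr$padj) & lr$padj < 0.05]
  sig_w <- wd$gene[!is.na(wd$padj) & wd$padj < 0.05]
  expect_gte(length(intersect(sig_l, sig_w)) /
               max(1, length(union(sig_l, sig_w))), 0.9)
})

test_that("BH rejections nest across significance levels", {
  cm <- sim_two_group(200, lfc = 0.6, phi = 0.1, seed = 9)
  fit <- fit_nb_glm(cm, ~ group, sf = rep(1, 24))
  res <- wald_contrast(fit, "group", "domesticated", "wild")
  r01 <- res$gene[!is.na(res$padj) & res$padj < 0.01]
  r05 <- res$gene[!is.na(res$padj) & res$padj < 0.05]
  expect_true(all(r01 %in% r05))
  expect_true(all(res$padj >= res$pvalue, na.rm = TRUE))
})

test_that("homoeolog bias classification recovers planted bias classes", {
  p <- sim_params(n_pairs = 300, n_modules = 2, module_sizes = c(60L, 60L),
                  split_fraction = 0, rewire_fraction = 0,
                  bias_fraction = 0.2, bias_lfc = 2, seed = 13)
  tr <- generate_truth(p)
  cm <- simulate_counts(tr, p)
  pairing <- sim_pairing(tr)
  keep <- filter_expressed(cm, "homoeolog", pairing)
  hom <- subset_counts(cm, keep)
  ph <- pairing[pairing$gene_A %in% keep & pairing$gene_D %in% keep, ]
  cls <- classify_bias(homoeolog_bias(hom, ph))
  expect_lt(abs(mean(cls == "A") - 0.1), 0.03)
  expect_lt(abs(mean(cls == "D") - 0.1), 0.03)
  truthy <- tr$bias_class[names(cls)]
  expect_gte(mean(cls[truthy == "A"] == "A"), 0.9)
  expect_gte(mean(cls[truthy == "D"] == "D"), 0.9)
})

test_that("classify_bias follows the sign and significance rule", {
  res <- data.frame(gene = c("p1", "p2", "p3"),
                    lfc = c(2, -2, 3),
                    padj = c(0.01, 0.01, 0.2))
  expect_identical(unname(classify_bias(res)), c("A", "D", "none"))
})
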