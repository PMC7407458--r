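test_that("correlation matrix matches the pairwise formula exactly", {
  set.seed(1)
  x <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("g", 1:5),
                                               paste0("s", 1:8)))
  cc <- correlation_matrix(x)
  expect_equal(cc, bf_cor(x), tolerance = 1e-12)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))

  dup <- rbind(x, g6 = x["g1", ])
  cd <- correlation_matrix(dup)
  expect_equal(cd["g1", "g6"], 1)
  neg <- rbind(x, g6 = -x["g1", ])
  expect_equal(correlation_matrix(neg)["g1", "g6"], -1)

  flat <- rbind(x, g6 = rep(2, 8))
  expect_error(correlation_matrix(flat), "g6")
  expect_error(correlation_matrix(x[, 1:2]), "3 samples")
})

test_that("soft adjacency is the unsigned beta power", {
  cc <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0, -0.9, 0, 1), 3)
  a <- soft_adjacency(cc, beta = 12)
  expect_equal(a[1, 2], 0.9^12)
  expect_equal(a[1, 3], 0.9^12)   # unsigned
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_equal(soft_adjacency(matrix(1, 1, 1), 7)[1, 1], 1)
})

test_that("scale-free fit index matches an independent binned regression", {
  set.seed(2)
  # approximate power-law connectivity
  u <- make_universe(3, n_mod = 5, msize = 40, n_bg = 100)
  adj <- soft_adjacency(correlation_matrix(u$x), 6)
  sfi <- scale_free_fit(adj, n_bins = 10)

  k <- colSums(adj) - 1
  cuts <- cut(k, breaks = 10)
  freq <- as.vector(table(cuts)) / length(k)
  mk <- tapply(k, cuts, mean)
  keep <- freq > 0 & !is.na(mk) & mk > 0
  fit <- lm(log10(freq[keep]) ~ log10(mk[keep]))
  oracle <- summary(fit)$r.squared * sign(-coef(fit)[2])
  expect_equal(sfi, unname(oracle), tolerance = 1e-10)

  # uniform connectivity scores poorly
  n <- 40
  flat <- matrix(0.5, n, n); diag(flat) <- 1
  flat <- flat + matrix(runif(n * n, 0, 1e-3), n); flat <- (flat + t(flat)) / 2
  diag(flat) <- 1
  expect_lt(suppressWarnings(scale_free_fit(flat)), 0.5)
})

test_that("TOM equals its definition on hand and brute-force cases", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- tom_similarity(a)
  expect_equal(unname(diag(tom)), rep(1, 3))
  expect_equal(tom[1, 2], 0.75 / 1.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)

  disc <- diag(2)
  expect_equal(tom_similarity(disc)[1, 2], 0)

  set.seed(4)
  x <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  adj <- soft_adjacency(correlation_matrix(x), 4)
  expect_equal(tom_similarity(adj), bf_tom(adj), tolerance = 1e-12)
  expect_true(all(tom_similarity(adj) >= 0 & tom_similarity(adj) <= 1))
})

test_that("two clean blocks give exactly two perfectly labelled modules", {
  u <- make_universe(5, n_mod = 2, msize = 60, n_bg = 0,
                     load_range = c(0.93, 0.97))
  cc <- correlation_matrix(u$x)
  tom <- tom_similarity(soft_adjacency(cc, 12))
  mods <- detect_modules(tom, network_params(min_module_size = 30), expr = u$x)
  expect_equal(length(setdiff(unique(mods$labels), 0L)), 2L)
  tab <- table(mods$labels, u$labels)
  expect_equal(sort(diag(tab[c("1", "2"), ])), c(60, 60),
               ignore_attr = TRUE)
})

test_that("module labels are stable under gene permutation", {
  u <- make_universe(6, n_mod = 2, msize = 40, n_bg = 30,
                     load_range = c(0.85, 0.95))
  cc <- correlation_matrix(u$x)
  tom <- tom_similarity(soft_adjacency(cc, 12))
  m1 <- detect_modules(tom, network_params(min_module_size = 20), expr = u$x)
  set.seed(7)
  perm <- sample(nrow(u$x))
  xp <- u$x[perm, ]
  tomp <- tom_similarity(soft_adjacency(correlation_matrix(xp), 12))
  m2 <- detect_modules(tomp, network_params(min_module_size = 20), expr = xp)
  expect_identical(unname(m1$labels[rownames(xp)]), unname(m2$labels))
})

test_that("modules tracking one latent profile are merged", {
  # two blocks driven by the same latent: eigengene dissimilarity ~ 0
  set.seed(8)
  ns <- 24
  lat <- rnorm(ns)
  x <- t(sapply(1:80, function(i) 0.95 * lat + sqrt(1 - 0.95^2) * rnorm(ns)))
  dimnames(x) <- list(sprintf("g%02d", 1:80), paste0("s", 1:ns))
  labels <- stats::setNames(rep(c(1L, 2L), each = 40), rownames(x))
  me <- module_eigengenes(x, labels)
  expect_gt(stats::cor(me[1, ], me[2, ]), 0.85)
  tom <- tom_similarity(soft_adjacency(correlation_matrix(x), 12))
  mods <- detect_modules(tom, network_params(min_module_size = 30), expr = x)
  expect_equal(length(setdiff(unique(mods$labels), 0L)), 1L)
})

test_that("eigengenes are oriented unit first principal components", {
  u <- make_universe(9, n_mod = 1, msize = 50, n_bg = 0)
  me <- module_eigengenes(u$x, u$labels)
  expect_equal(sum(me[1, ]^2), 1)
  kme <- module_kme(u$x, me)
  expect_gt(mean(kme[, 1]), 0)   # orientation convention

  # variance explained equals the leading eigenvalue share
  xs <- t(scale(t(u$x)))
  ev <- eigen(tcrossprod(xs), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(attr(me, "var_explained")[1]), ev[1] / sum(ev),
               tolerance = 1e-10)

  # flipping all members flips the eigengene back via orientation
  me2 <- module_eigengenes(-u$x, u$labels)
  kme2 <- module_kme(-u$x, me2)
  expect_gt(mean(kme2[, 1]), 0)

  # identical genes: kME is exactly 1
  ident <- matrix(rep(rnorm(10), each = 4), 4, byrow = FALSE)
  dimnames(ident) <- list(paste0("g", 1:4), paste0("s", 1:10))
  mei <- module_eigengenes(ident, stats::setNames(rep(1L, 4), rownames(ident)))
  kmei <- module_kme(ident, mei)
  expect_equal(unname(kmei[, 1]), rep(1, 4), tolerance = 1e-10)
})

test_that("kME is the gene-eigengene correlation, all entries bounded", {
  u <- make_universe(10, n_mod = 2, msize = 30, n_bg = 20)
  me <- module_eigengenes(u$x, u$labels)
  kme <- module_kme(u$x, me)
  for (g in sample(rownames(u$x), 10))
    for (m in rownames(me))
      expect_equal(kme[g, m], stats::cor(u$x[g, ], me[m, ]), tolerance = 1e-12)
  expect_true(all(abs(kme) <= 1))
  # member genes' own-module kME dominates non-member kME
  own <- vapply(seq_len(60), function(i) kme[i, paste0("ME", u$labels[i])],
                numeric(1))
  expect_gt(median(own), median(abs(kme[61:80, ])))
})

test_that("eigengene ANOVA matches hand-computed sums of squares", {
  meta <- make_meta()
  set.seed(11)
  me <- rbind(ME1 = as.numeric(factor(meta$stage)) + rnorm(24, 0, 0.3),
              ME2 = rnorm(24))
  colnames(me) <- meta$sample
  res <- me_condition_anova(me, meta)

  y <- me[1, ]
  g <- factor(meta$group, levels = c("wild", "domesticated"))
  s <- factor(meta$stage)
  # balanced design: sequential SS equal partial SS
  ss_g <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  ss_s <- sum(tapply(y, s, function(v) length(v) * (mean(v) - mean(y))^2))
  fitted <- tapply(y, g, mean)[g] + tapply(y, s, mean)[s] - mean(y)
  ss_e <- sum((y - fitted)^2)
  df_e <- 24 - 1 - 1 - 3
  f_g <- (ss_g / 1) / (ss_e / df_e)
  f_s <- (ss_s / 3) / (ss_e / df_e)
  expect_equal(res$p_group[1], pf(f_g, 1, df_e, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$p_stage[1], pf(f_s, 3, df_e, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(res$significant[1])

  # a perfect stage effect is detected at essentially zero P
  me3 <- rbind(ME1 = as.numeric(factor(meta$stage)))
  colnames(me3) <- meta$sample
  expect_lt(suppressWarnings(me_condition_anova(me3, meta))$p_stage[1], 1e-12)

  # constant eigengene: undefined, flagged NA
  me4 <- rbind(ME1 = rep(1, 24)); colnames(me4) <- meta$sample
  r4 <- me_condition_anova(me4, meta)
  expect_true(is.na(r4$p_group[1]))
  expect_false(r4$significant[1])
})
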