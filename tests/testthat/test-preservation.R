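test_that("observed statistics match the brute-force oracle on a small module", {
  set.seed(1)
  ref <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  test <- matrix(rnorm(8 * 12), 8, 12, dimnames = dimnames(ref))
  labels <- stats::setNames(rep(1L, 8), rownames(ref))
  st <- preservation_stats(labels, ref, test, beta = 6)
  bf <- bf_pres_stats(1:8, ref, test, beta = 6)
  expect_equal(st$meanCor, bf$meanCor, tolerance = 1e-12)
  expect_equal(st$meanAdj, bf$meanAdj, tolerance = 1e-12)
  expect_equal(st$cor_kIM, bf$cor_kIM, tolerance = 1e-12)
  expect_equal(st$cor_cor, bf$cor_cor, tolerance = 1e-12)
})

test_that("self-comparison gives perfect connectivity statistics", {
  u <- make_universe(2, n_mod = 2, msize = 30, n_bg = 20)
  st <- preservation_stats(u$labels, u$x, u$x, beta = 12)
  expect_equal(st$cor_kIM, c(1, 1), tolerance = 1e-12)
  expect_equal(st$cor_cor, c(1, 1), tolerance = 1e-12)

  # a module of mutually independent genes has near-zero density
  set.seed(3)
  noise <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
  stn <- preservation_stats(stats::setNames(rep(1L, 40), rownames(noise)),
                            noise, noise, beta = 12)
  expect_lt(abs(stn$meanCor), 0.1)
})

test_that("tiny test-side modules yield NA with a warning", {
  set.seed(4)
  x <- matrix(rnorm(5 * 10), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  labels <- stats::setNames(c(1L, 1L, 2L, 2L, 2L), rownames(x))
  expect_warning(st <- preservation_stats(labels, x, x), "<3 genes")
  expect_true(is.na(st$meanCor[st$module == 1]))
  expect_false(is.na(st$meanCor[st$module == 2]))
})

test_that("Zsummary separates preserved, destroyed and random modules", {
  mk <- function(seed, loads = NULL) make_universe(seed, n_mod = 3,
                                                   msize = 60, n_bg = 180,
                                                   load_range = c(0.75, 0.95),
                                                   loads = loads)
  u1 <- mk(10)
  u2 <- mk(11, loads = u1$loads)
  pres <- module_preservation(u1$labels, u1$x, u2$x, n_perm = 40, seed = 5)
  expect_true(all(pres$Zsummary > 10))
  expect_true(all(pres$class == "strong"))

  # destroy module 1 in the test data by shuffling its samples
  x2 <- u2$x
  set.seed(6)
  for (g in which(u1$labels == 1)) x2[g, ] <- x2[g, sample(ncol(x2))]
  pres2 <- module_preservation(u1$labels, u1$x, x2, n_perm = 40, seed = 5)
  expect_lt(pres2$Zsummary[pres2$module == 1], 2)
  expect_identical(pres2$class[pres2$module == 1], "none")
  expect_gt(pres2$Zsummary[pres2$module == 2], 10)

  # determinism under the seed
  pres3 <- module_preservation(u1$labels, u1$x, x2, n_perm = 40, seed = 5)
  expect_identical(as.data.frame(pres2), as.data.frame(pres3))
})

test_that("a random gene set scores near zero", {
  set.seed(20)
  ref <- matrix(rnorm(150 * 24), 150, 24,
                dimnames = list(sprintf("g%03d", 1:150), paste0("s", 1:24)))
  test <- matrix(rnorm(150 * 24), 150, 24, dimnames = dimnames(ref))
  labels <- stats::setNames(rep(0L, 150), rownames(ref))
  labels[sample(150, 60)] <- 1L
  pres <- module_preservation(labels, ref, test, n_perm = 40, seed = 21)
  expect_lt(abs(pres$Zsummary), 2)
})

test_that("medianRank ranks modules with average ties, best stat = rank 1", {
  st <- data.frame(module = 1:5, size = 10,
                   meanCor = c(0.9, 0.5, 0.3, 0.2, 0.1),
                   meanAdj = c(0.8, 0.5, 0.3, 0.2, 0.1),
                   cor_kIM = c(0.9, 0.6, 0.4, 0.3, 0.2),
                   cor_cor = c(0.9, 0.7, 0.5, 0.3, 0.2))
  mr <- median_rank(st)
  expect_equal(mr, 1:5)

  tie <- st[c(1, 1, 3), ]
  mr2 <- median_rank(tie)
  expect_equal(mr2, c(1.5, 1.5, 3))

  # sorting oracle: medianRank is the median of the per-statistic ranks
  set.seed(8)
  st5 <- data.frame(module = 1:5, size = 10,
                    meanCor = runif(5), meanAdj = runif(5),
                    cor_kIM = runif(5), cor_cor = runif(5))
  ranks <- sapply(c("meanCor", "meanAdj", "cor_kIM", "cor_cor"),
                  function(cn) rank(-st5[[cn]]))
  expect_equal(median_rank(st5), apply(ranks, 1, median))
  expect_error(median_rank(st5[1, ]), "2 modules")
})

test_that("Zsummary grows with module size on identical per-gene signal", {
  sizes <- c(30, 100)
  ns <- 24
  mk <- function(seed, loads) {
    set.seed(seed)
    lats <- list(rnorm(ns), rnorm(ns))
    x <- NULL; labs <- integer(0)
    for (m in 1:2) {
      xm <- t(vapply(loads[[m]],
                     function(l) l * lats[[m]] + sqrt(1 - l^2) * rnorm(ns),
                     numeric(ns)))
      x <- rbind(x, xm); labs <- c(labs, rep(m, sizes[m]))
    }
    x <- rbind(x, matrix(rnorm(130 * ns), 130)); labs <- c(labs, rep(0L, 130))
    dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))), paste0("s", 1:ns))
    list(x = x, labs = stats::setNames(labs, rownames(x)))
  }
  set.seed(29)
  loads <- lapply(sizes, function(s) runif(s, 0.8, 0.95))
  u1 <- mk(30, loads)
  u2 <- mk(31, loads)   # independent redraw, same structure
  pres <- module_preservation(u1$labs, u1$x, u2$x, n_perm = 40, seed = 32)
  expect_gt(pres$Zsummary[pres$module == 2],
            pres$Zsummary[pres$module == 1])
})

test_that("preservation classes follow the published thresholds", {
  expect_identical(classify_preservation(c(10.5, 10, 2, 1.9, -3)),
                   c("strong", "moderate", "moderate", "none", "none"))
})
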