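make_cm <- function(mat, genotype = rep(c("WT", "M1"), each = ncol(mat) / 2)) {
  colnames(mat) <- paste0(genotype, "_", ave(seq_along(genotype),
                                             genotype, FUN = seq_along))
  rownames(mat) <- sprintf("gene%03d", seq_len(nrow(mat)))
  count_matrix(mat, data.frame(sample = colnames(mat), genotype = genotype,
                               replicate = ave(seq_along(genotype), genotype,
                                               FUN = seq_along)))
}

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(2L, 4L, 8L, 16L), nrow = 2)
  dimnames(m) <- list(c("g1", "g2"), c("s1", "s2"))
  expect_equal(unname(estimate_size_factors(m)), c(0.5, 2))

  same <- matrix(rep(c(3L, 7L, 11L), 4), nrow = 3)
  dimnames(same) <- list(paste0("g", 1:3), paste0("s", 1:4))
  expect_equal(unname(estimate_size_factors(same)), rep(1, 4))

  # scaling one sample's counts by c scales its size factor by c (and the
  # ratio structure of the others stays fixed)
  set.seed(1)
  m2 <- matrix(rnbinom(300, mu = 50, size = 10), ncol = 3,
               dimnames = list(sprintf("g%d", 1:100), c("a", "b", "c")))
  sf <- estimate_size_factors(m2)
  m3 <- m2
  m3[, 2] <- m3[, 2] * 4L
  sf3 <- estimate_size_factors(m3)
  # geometric means shift by 4^(1/3) for every gene, so all factors rescale
  expect_equal(unname(sf3[2] / sf[2] / (sf3[1] / sf[1])), 4,
               tolerance = 1e-12)

  # gene order is irrelevant
  expect_equal(estimate_size_factors(m2[sample(100), ]), sf)

  zeros <- matrix(c(0L, 1L, 1L, 0L), nrow = 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(zeros), "pseudo-reference")
})

test_that("BH adjustment matches hand-computed examples and the reference", {
  expect_equal(adjust_bh(1), 1)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"))
  }
  # monotone over sorted inputs, idempotent-ordered, capped at 1
  p <- sort(runif(100))
  a <- adjust_bh(p)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a <= 1))
  expect_true(all(a >= p))
})

test_that("dispersion estimates recover simulated truth", {
  set.seed(21)
  n <- 2000
  # NB genes at alpha = 0.05
  mu <- 2^runif(n, 6, 9)
  y <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 1 / 0.05), ncol = 6)
  dimnames(y) <- list(sprintf("g%04d", 1:n), sprintf("s%d", 1:6))
  sf <- rep(1, 6)
  cond <- rep(c("WT", "M1"), each = 3)
  a <- estimate_dispersion(y, sf, cond)
  expect_lt(abs(median(a) - 0.05), 0.2 * 0.05)

  # Poisson genes: estimates collapse to (near) the floor via the trend
  yp <- matrix(rpois(n * 6, rep(mu, 6)), ncol = 6, dimnames = dimnames(y))
  ap <- estimate_dispersion(yp, sf, cond)
  expect_lt(median(ap), 0.005)

  # constant gene with equal size factors sits at the floor
  yc <- matrix(50L, nrow = 12, ncol = 6, dimnames =
                 list(sprintf("g%d", 1:12), sprintf("s%d", 1:6)))
  ac <- estimate_dispersion(yc, sf, cond, floor = 1e-8)
  expect_equal(unname(ac[1]), 1e-8)
})

test_that("Wald test is exact-zero on mirrored data and well-behaved on shifts", {
  base <- matrix(rep(c(30L, 300L, 70L), each = 6), nrow = 3, byrow = TRUE)
  cm <- make_cm(base)
  sf <- estimate_size_factors(cm$counts)
  disp <- setNames(rep(0.05, 3), rownames(cm$counts))
  de <- wald_test(cm, sf, disp, line = "M1")
  expect_equal(de$log2fc, rep(0, 3), tolerance = 1e-9)
  expect_equal(de$fc, rep(1, 3), tolerance = 1e-9)

  # 10-fold shift at mu = 256, alpha = 0.01, n = 3: essentially always
  # detected (power > 0.99); simulate many such genes at once
  set.seed(31)
  n <- 400
  y <- cbind(matrix(rnbinom(3 * n, mu = 256, size = 100), ncol = 3),
             matrix(rnbinom(3 * n, mu = 2560, size = 100), ncol = 3))
  dimnames(y) <- list(sprintf("g%d", 1:n),
                      c(paste0("WT_", 1:3), paste0("M1_", 1:3)))
  cm2 <- count_matrix(y, data.frame(sample = colnames(y),
                                    genotype = rep(c("WT", "M1"), each = 3),
                                    replicate = rep(1:3, 2)))
  de2 <- wald_test(cm2, setNames(rep(1, 6), colnames(y)),
                   setNames(rep(0.01, n), rownames(y)), line = "M1")
  expect_gt(mean(de2$pvalue < 0.05), 0.99)
  expect_equal(median(de2$log2fc), log2(10), tolerance = 0.1)

  # all-zero genes: NA fold change, p = 1, excluded from BH
  y0 <- rbind(y[1:5, ], gene_zero = 0L)
  cm0 <- count_matrix(y0, cm2$samples)
  de0 <- wald_test(cm0, setNames(rep(1, 6), colnames(y0)),
                   setNames(rep(0.01, 6), rownames(y0)), line = "M1")
  z <- de0[de0$gene_id == "gene_zero", ]
  expect_true(is.na(z$fc))
  expect_equal(z$pvalue, 1)
  expect_true(is.na(z$padj))
})

test_that("DE results are invariant to sample order", {
  set.seed(5)
  cfg <- simulation_config(n_groups = 40, seed = 17)
  sim <- simulate_experiment(cfg)
  cm <- sim$counts
  de1 <- run_de(cm, line = "M1")
  perm <- sample(ncol(cm$counts))
  cm2 <- count_matrix(cm$counts[, perm], cm$samples[perm, ])
  de2 <- run_de(cm2, line = "M1")
  expect_equal(de1$pvalue, de2$pvalue, tolerance = 1e-9)
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-9)
  expect_identical(de1$status, de2$status)
})

test_that("classify_de applies the padj and fold-change direction rule", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   fc = c(0.18, 1.5, 2.0, NA),
                   padj = c(7.8e-19, 0.2, 0.01, 0.001))
  out <- classify_de(de, alpha = 0.05)
  expect_equal(out$status, c("down", "no_change", "up", "no_change"))
})
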