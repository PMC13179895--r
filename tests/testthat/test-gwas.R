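test_that("Bonferroni threshold follows -log10(alpha/n) and is monotone", {
  expect_equal(bonferroni_threshold(293783, 0.05), -log10(0.05 / 293783))
  expect_equal(round(bonferroni_threshold(293783, 0.05), 3), 6.769)
  expect_equal(round(bonferroni_threshold(1), 4), 1.301)
  n <- c(10, 100, 1000, 10000)
  expect_true(all(diff(bonferroni_threshold(n)) > 0))
  expect_error(bonferroni_threshold(0), ">= 1")
  expect_error(bonferroni_threshold(10, 1.2), "0, 1")
})

test_that("a planted near-noiseless signal attains the scan minimum p", {
  sim <- shared_sim()
  gm <- filter_maf(sim$genotypes, 0.1)
  set.seed(41)
  j <- which.max(apply(gm$dosages, 2, var))
  y <- setNames(2 * gm$dosages[, j] + rnorm(nrow(gm$dosages), 0, 1e-4),
                gm$line_ids)
  scan <- run_gwas(gm, y, n_pcs = 3)
  expect_equal(scan$marker[which.min(scan$p)], gm$map$marker[j])
  expect_gte(max(scan$neglog10p, na.rm = TRUE), attr(scan, "threshold"))
})

test_that("with zero PCs the scan equals per-marker simple regression", {
  gm <- tiny_gm()
  set.seed(2)
  y <- setNames(rnorm(6), gm$line_ids)
  scan <- run_gwas(gm, y, n_pcs = 0)
  for (j in c(1, 4, 7)) {
    lmf <- summary(lm(y ~ gm$dosages[, j]))
    expect_equal(scan$beta[j], lmf$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(scan$p[j], lmf$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("scan p-values are invariant to affine phenotype rescaling", {
  sim <- shared_sim()
  gm <- filter_maf(subset_genotypes(sim$genotypes,
                                    markers = 1:150), 0.05)
  set.seed(3)
  y <- setNames(rnorm(length(gm$line_ids)), gm$line_ids)
  s1 <- run_gwas(gm, y, n_pcs = 2)
  s2 <- run_gwas(gm, 100 + 7 * y, n_pcs = 2)
  expect_equal(s1$p, s2$p, tolerance = 1e-9)
  expect_equal(s2$beta, 7 * s1$beta, tolerance = 1e-9)
})

test_that("type-I error rate under the null is nominal", {
  sim <- shared_sim()
  gm <- filter_maf(sim$genotypes, 0.04)
  set.seed(99)
  y <- setNames(sample(rnorm(length(gm$line_ids))), gm$line_ids)
  scan <- run_gwas(gm, y, n_pcs = 3)
  frac <- mean(scan$p < 0.05, na.rm = TRUE)
  # binomial CI is inflated by marker LD; allow a generous band around 0.05
  expect_lt(frac, 0.15)
})

test_that("LD r^2 matches the brute-force correlation formula", {
  gm <- tiny_gm()
  expect_equal(ld_r2(gm, "m1", "m1"), 1)
  # perfect negative correlation still gives r^2 = 1
  dos <- cbind(c(0, 1, 2, 0), c(2, 1, 0, 2), c(0, 0, 2, 2))
  g2 <- genotype_matrix(dos, data.frame(marker = c("a", "b", "c"),
                                        chrom = "1", pos = 1:3))
  expect_equal(ld_r2(g2, "a", "b"), 1)
  expect_equal(ld_r2(g2, "a", "c"), cor(dos[, 1], dos[, 3])^2)
  g3 <- genotype_matrix(cbind(dos[, 1], 2), data.frame(
    marker = c("a", "mono"), chrom = "1", pos = 1:2))
  expect_error(ld_r2(g3, "a", "mono"), "monomorphic")
})

test_that("region delimitation applies the window, LD and support rules", {
  # constructed scan: peak at 10 Mb on chr1, candidates at varying distance,
  # LD and support; dosages built so r^2 with the peak is high or ~0
  set.seed(8)
  n <- 40
  peak <- rbinom(n, 2, 0.5)
  linked <- peak; flip <- sample(n, 2); linked[flip] <- 2 - linked[flip]
  unlinked <- sample(peak)
  dos <- cbind(p0 = peak, near = linked, far = linked, beyond = linked,
               nold = unlinked)
  map <- data.frame(marker = colnames(dos), chrom = "chr1",
                    pos = c(10e6, 10.5e6, 11.9e6, 12.5e6, 9.2e6))
  ord <- order(map$pos)
  gm <- genotype_matrix(dos[, ord], map[ord, ], line_ids = paste0("L", 1:n))
  scan <- structure(
    data.frame(marker = map$marker[ord], chrom = "chr1", pos = map$pos[ord],
               beta = 1, se = 0.1, t = 10,
               p = 10^-c(p0 = 8, near = 5.5, far = 5.5, beyond = 6,
                         nold = 6)[map$marker[ord]],
               neglog10p = c(p0 = 8, near = 5.5, far = 5.5, beyond = 6,
                             nold = 6)[map$marker[ord]],
               r2 = 0.3, maf = 0.4, stringsAsFactors = FALSE),
    class = c("gwas_scan", "data.frame"), threshold = 6, n_pcs = 0,
    n_snps = 5, n_lines = n)
  reg <- define_region(scan, gm, "p0", window_bp = 4e6, r2_min = 0.4,
                       support_logp = 5)
  # near (0.5 Mb, r2 high, logp 5.5 > 5): in; far (1.9 Mb, in half-window): in
  # beyond (2.5 Mb > half-window): out; nold (r2 ~ 0): out
  expect_setequal(reg$members, c("p0", "near", "far"))
  expect_equal(reg$start, 10e6)
  expect_equal(reg$end, 11.9e6)
  expect_lte(reg$end - reg$start, 4e6)
  expect_true(reg$start <= reg$peak_pos && reg$peak_pos <= reg$end)
  # with the full +/- 4 Mb window, 'beyond' joins
  reg2 <- define_region(scan, gm, "p0", window_bp = 4e6, full_window = TRUE)
  expect_true("beyond" %in% reg2$members)
  # non-significant peak is rejected
  expect_error(define_region(scan, gm, "near"), "not significant")
})

test_that("an isolated significant SNP collapses to a zero-length region", {
  set.seed(12)
  n <- 30
  dos <- cbind(a = rbinom(n, 2, 0.5), b = rbinom(n, 2, 0.5))
  gm <- genotype_matrix(dos, data.frame(marker = c("a", "b"), chrom = "chr2",
                                        pos = c(5e6, 6e6)),
                        line_ids = paste0("L", 1:n))
  scan <- structure(
    data.frame(marker = c("a", "b"), chrom = "chr2", pos = c(5e6, 6e6),
               beta = 1, se = 0.1, t = 10, p = c(1e-8, 0.5),
               neglog10p = c(8, 0.3), r2 = 0.3, maf = 0.4,
               stringsAsFactors = FALSE),
    class = c("gwas_scan", "data.frame"), threshold = 6, n_pcs = 0,
    n_snps = 2, n_lines = n)
  reg <- define_region(scan, gm, "a")
  expect_equal(reg$start, reg$end)
  expect_equal(reg$n_members, 1L)
})

test_that("a QTL in a simulated LD block yields a region covering the block", {
  cfg <- sim_config(seed = 404, n_magic_lines = 150, n_phenotyped = 150,
                    snps_per_chrom = 250, n_chromosomes = 2)
  f <- simulate_founders(cfg)
  mg <- simulate_magic(f, cfg)
  gm <- filter_maf(mg$gm, 0.1)
  set.seed(405)
  j <- 60
  g <- gm$dosages[, j]
  y <- setNames(g * sqrt(0.35 / var(g)) + rnorm(length(g), 0, sqrt(0.65)),
                gm$line_ids)
  scan <- run_gwas(gm, y, n_pcs = 3)
  pk <- scan$marker[which.min(scan$p)]
  reg <- define_region(scan, gm, pk, check_significant = FALSE)
  # the region contains the causal marker's LD block neighbourhood and does
  # not extend beyond the physical window
  expect_true(reg$chrom == gm$map$chrom[j])
  expect_lte(reg$end - reg$start, 4e6)
  expect_gte(ld_r2(gm, pk, gm$map$marker[j]), 0.4)
  for (mmb in reg$members) {
    expect_gte(ld_r2(gm, pk, mmb), 0.4)
  }
})
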