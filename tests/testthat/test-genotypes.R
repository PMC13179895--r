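test_that("VCF import converts GT fields to dosages and honours flags", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnp2\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2",
    "chr1\t300\tsnp3\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1",
    "chr2\t150\tsnp4\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1\t1/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)

  expect_error(read_vcf(path, skip_multiallelic = FALSE), "multi-allelic")
  expect_error(read_vcf(path), "missing GT")

  gm <- read_vcf(path, impute_mean = TRUE)
  expect_false("snp2" %in% gm$map$marker)   # multiallelic skipped
  expect_equal(unname(gm$dosages[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(gm$dosages[, "snp3"]), c(2, 0, 1))
  # missing S1 call imputed at the mean of the observed dosages (1, 2)
  expect_equal(unname(gm$dosages[, "snp4"]), c(1.5, 1, 2))
  expect_equal(gm$line_ids, c("S1", "S2", "S3"))
})

test_that("dosage CSV round-trip reproduces the genotype matrix exactly", {
  gm <- tiny_gm()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dosage_csv(gm, path)
  gm2 <- read_dosage_csv(path)
  expect_identical(gm2$dosages, gm$dosages)
  expect_equal(gm2$map, gm$map)
})

test_that("constructor rejects invalid dosages and unsorted maps", {
  map <- data.frame(marker = c("a", "b"), chrom = "1", pos = c(10, 5))
  expect_error(genotype_matrix(matrix(0, 2, 2), map), "strictly increasing")
  map$pos <- c(5, 10)
  expect_error(genotype_matrix(matrix(c(0, 3, 1, 2), 2), map), "0, 2")
  expect_error(genotype_matrix(matrix(c(0, NA, 1, 2), 2), map), "missing")
})

test_that("MAF filter is strict and matches a brute-force frequency check", {
  # a marker at exactly the cutoff frequency is removed
  dos <- cbind(c(rep(0, 24), 2), matrix(rbinom(25 * 5, 2, 0.5), 25, 5))
  map <- data.frame(marker = paste0("m", 1:6), chrom = "1", pos = 1:6 * 100)
  gm <- genotype_matrix(dos, map)
  p1 <- mean(dos[, 1]) / 2
  expect_equal(p1, 0.04)
  expect_false("m1" %in% filter_maf(gm, 0.04)$map$marker)

  # monomorphic markers always removed
  dos2 <- cbind(0, matrix(rbinom(40, 2, 0.5), 10, 4))
  gm2 <- genotype_matrix(dos2, data.frame(marker = paste0("x", 1:5),
                                          chrom = "1", pos = 1:5))
  expect_false("x1" %in% filter_maf(gm2, 0)$map$marker)

  # 1000 simulated markers: retained set equals the brute-force list
  set.seed(42)
  freqs <- runif(1000, 0, 0.5)
  dos3 <- sapply(freqs, function(p) rbinom(50, 2, p))
  gm3 <- genotype_matrix(dos3, data.frame(marker = paste0("s", 1:1000),
                                          chrom = "1", pos = seq_len(1000)))
  got <- filter_maf(gm3, 0.1)$map$marker
  p <- colMeans(dos3) / 2
  want <- paste0("s", which(pmin(p, 1 - p) > 0.1))
  expect_identical(got, want)
})

test_that("distance thinning is greedy keep-first within chromosomes", {
  gm <- tiny_gm()  # chr1 pos 100,1500,3500,9000; chr2 pos 50,2050,2100,8000
  th <- thin_markers(gm, 2000)
  expect_identical(th$map$pos, c(100, 3500, 9000, 50, 2050, 8000))
  # min_bp = 0 is the identity
  expect_identical(thin_markers(gm, 0)$map, gm$map)
  # single marker per chromosome unchanged
  gm1 <- subset_genotypes(gm, markers = c("m1", "m5"))
  expect_identical(thin_markers(gm1, 1e9)$map$marker, c("m1", "m5"))
  # retained markers pairwise >= min_bp apart
  for (ch in unique(th$map$chrom)) {
    expect_true(all(diff(th$map$pos[th$map$chrom == ch]) >= 2000))
  }
})

test_that("VanRaden GRM equals the element-wise hand computation", {
  dos <- matrix(c(0, 1, 2, 1,
                  2, 1, 0, 0,
                  1, 2, 1, 2), nrow = 3, byrow = TRUE)
  gm <- genotype_matrix(dos, data.frame(marker = paste0("m", 1:4),
                                        chrom = "1", pos = 1:4 * 1000),
                        line_ids = c("a", "b", "c"))
  p <- colMeans(dos) / 2
  W <- sweep(dos, 2, 2 * p)
  G_hand <- (W %*% t(W)) / (2 * sum(p * (1 - p)))
  G <- vanraden_grm(gm)
  expect_equal(unclass(G), G_hand, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(G), t(unclass(G)))
})

test_that("GRM invariances: duplicate lines, marker order, monomorphics", {
  gm <- tiny_gm()
  G <- unclass(vanraden_grm(gm))
  # identical genotypes give identical rows/diagonal entries
  dup <- genotype_matrix(gm$dosages[c(1, 1, 2, 3), ], gm$map,
                         line_ids = paste0("D", 1:4))
  Gd <- unclass(vanraden_grm(dup))
  expect_equal(Gd[1, 1], Gd[2, 2])
  expect_equal(Gd[1, 1], Gd[1, 2])
  # permuting markers leaves the GRM unchanged
  perm <- sample(8)
  mp <- gm$map[perm, ]
  ord <- order(match(mp$chrom, unique(gm$map$chrom)), mp$pos)
  gmp <- genotype_matrix(gm$dosages[, perm][, ord], mp[ord, ],
                         line_ids = gm$line_ids)
  expect_equal(unclass(vanraden_grm(gmp)), G, tolerance = 1e-12)
  # adding a monomorphic marker changes nothing
  dos2 <- cbind(gm$dosages, mono = 2)
  map2 <- rbind(gm$map, data.frame(marker = "mono", chrom = "chr2", pos = 99000))
  gmm <- genotype_matrix(dos2, map2, line_ids = gm$line_ids)
  expect_equal(unclass(vanraden_grm(gmm)), G, tolerance = 1e-12)
  # all-monomorphic input is rejected
  gm0 <- genotype_matrix(matrix(2, 3, 2),
                         data.frame(marker = c("z1", "z2"), chrom = "1",
                                    pos = c(1, 2)))
  expect_error(vanraden_grm(gm0), "monomorphic")
})

test_that("GRM of an inbred population is PSD with diagonal near 1 + F", {
  sim <- shared_sim()
  G <- shared_grm()
  ev <- eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # fully inbred lines: mean diagonal approaches 2 under the HWE scaling
  expect_gt(mean(diag(unclass(G))), 1.8)
  expect_lt(mean(diag(unclass(G))), 2.1)
  expect_equal(attr(G, "bend_epsilon"), 0)
})

test_that("genotype PCA separates subpopulations and orders variance", {
  set.seed(9)
  blockA <- matrix(rbinom(20 * 40, 2, 0.8), 20, 40)
  blockB <- matrix(rbinom(20 * 40, 2, 0.2), 20, 40)
  gm <- genotype_matrix(rbind(blockA, blockB),
                        data.frame(marker = paste0("m", 1:40), chrom = "1",
                                   pos = 1:40 * 100),
                        line_ids = paste0("L", 1:40))
  pc <- genotype_pca(gm, 3)
  s1 <- pc$scores[, 1]
  expect_true(all(s1[1:20] > 0) && all(s1[21:40] < 0) ||
                all(s1[1:20] < 0) && all(s1[21:40] > 0))
  expect_true(all(diff(pc$varexp) <= 1e-12))
  expect_true(all(pc$varexp >= 0 & pc$varexp <= 1))
  # duplicated line gets identical scores
  gm2 <- genotype_matrix(rbind(blockA[1, ], blockA[1, ], blockB[1:4, ]),
                         gm$map, line_ids = paste0("d", 1:6))
  pc2 <- genotype_pca(gm2, 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
  expect_error(genotype_pca(gm2, 6), "rank")
})
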