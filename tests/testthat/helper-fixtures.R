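# Shared fixtures, built in code. The heavier simulated study is created
# once per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# tiny deterministic genotype set: 6 lines x 8 markers on 2 chromosomes
tiny_gm <- function() {
  dos <- matrix(c(0, 1, 2, 0, 1, 2, 2, 0,
                  1, 1, 0, 2, 0, 1, 2, 0,
                  2, 0, 1, 1, 2, 0, 0, 1,
                  0, 2, 2, 0, 1, 1, 1, 2,
                  1, 0, 1, 2, 2, 0, 1, 1,
                  2, 2, 0, 1, 0, 2, 0, 2),
                nrow = 6, byrow = TRUE)
  map <- data.frame(marker = paste0("m", 1:8),
                    chrom = rep(c("chr1", "chr2"), each = 4),
                    pos = c(100, 1500, 3500, 9000, 50, 2050, 2100, 8000))
  genotype_matrix(dos, map, line_ids = paste0("L", 1:6))
}

# moderate simulated study reused across test files
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 77, n_magic_lines = 150, n_phenotyped = 100,
                      snps_per_chrom = 250, n_chromosomes = 4)
    .fixture_env$sim <- simulate_magic_study(cfg)
  }
  .fixture_env$sim
}

shared_grm <- function() {
  if (is.null(.fixture_env$grm)) {
    sim <- shared_sim()
    .fixture_env$grm <- vanraden_grm(filter_maf(sim$genotypes, 0.04))
  }
  .fixture_env$grm
}

# random plant table exercising the phenotype derivations
random_plant_table <- function(n_lines = 4, seed = 5) {
  set.seed(seed)
  df <- expand.grid(line = paste0("L", seq_len(n_lines)), experiment = 1:3,
                    stage = c("final", "baseline"), stringsAsFactors = FALSE)
  df$role <- "magic"
  dw <- matrix(runif(nrow(df) * 3, 0.5, 3), ncol = 3)
  df$dw_leaf <- dw[, 1]; df$dw_stem <- dw[, 2]; df$dw_root <- dw[, 3]
  df$fw_leaf <- df$dw_leaf / runif(nrow(df), 0.12, 0.3)
  df$fw_stem <- df$dw_stem / runif(nrow(df), 0.12, 0.3)
  df$fw_root <- df$dw_root / runif(nrow(df), 0.12, 0.3)
  df$leaf_number <- rpois(nrow(df), 5) + 1
  df$stem_length <- runif(nrow(df), 5, 25)
  df
}

# dense restricted log-likelihood oracle, independent of the package's
# Woodbury/eigen implementation (same constant-dropping convention)
dense_reml_logl <- function(y, X, Z, G, sa, sn, se) {
  V <- sa * Z %*% G %*% t(Z) + sn * tcrossprod(Z) + se * diag(length(y))
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(B) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(B)$modulus +
                       t(y) %*% P %*% y))
}
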