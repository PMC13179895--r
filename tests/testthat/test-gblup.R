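test_that("adjusted means reduce to raw means and undo experiment shifts", {
  # balanced data, no experiment effect: adjusted = raw line mean
  df <- expand.grid(line = c("A", "B", "C"), experiment = 1:2,
                    stringsAsFactors = FALSE)
  df$y <- c(1, 2, 3, 1.4, 2.2, 2.4)
  am <- adjusted_means(df, "y")
  expect_equal(am$value, as.numeric(tapply(df$y, df$line, mean)))

  # additive +1 shift in experiment 2: adjusted means equal the line means
  # of the de-shifted data (hand OLS on 6 observations)
  df2 <- df
  df2$y <- c(1, 2, 3, 2, 3, 4)   # experiment 2 = experiment 1 + 1
  am2 <- adjusted_means(df2, "y")
  expect_equal(am2$value, c(1.5, 2.5, 3.5))

  # single experiment: raw means
  df3 <- df[df$experiment == 1, ]
  expect_equal(adjusted_means(df3, "y")$value, c(1, 2, 3))

  # baseline-stage records are excluded
  df4 <- rbind(cbind(df, stage = "final"),
               data.frame(line = "A", experiment = 1, y = 99, stage = "baseline"))
  expect_equal(adjusted_means(df4, "y")$value, am$value)
})

test_that("REML solution dominates a dense grid and matches the dense oracle", {
  set.seed(301)
  q <- 10
  dos <- matrix(rbinom(q * 50, 2, runif(50, 0.2, 0.8)), q, 50, byrow = FALSE)
  gm <- genotype_matrix(dos, data.frame(marker = paste0("m", 1:50),
                                        chrom = "1", pos = 1:50 * 1e4),
                        line_ids = paste0("L", 1:q))
  G <- vanraden_grm(gm)
  df <- expand.grid(line = gm$line_ids, experiment = 1:3,
                    stringsAsFactors = FALSE)
  idx <- match(df$line, gm$line_ids)
  ua <- drop(t(chol(unclass(G) + diag(1e-6, q))) %*% rnorm(q))
  df$y <- 3 + c(0, 0.8, -0.4)[df$experiment] + ua[idx] +
    rnorm(q)[idx] * 0.5 + rnorm(nrow(df), 0, 0.6)
  fit <- gblup(df, G, trait = "y")

  ids <- sort(unique(df$line))
  Z <- stats::model.matrix(~ 0 + factor(df$line, levels = ids))
  X <- stats::model.matrix(~ factor(df$experiment))
  Gt <- unclass(G)[ids, ids]
  # the package's restricted log-likelihood agrees with the dense formula
  th <- pmax(fit$varcomp, 1e-8)
  expect_equal(fit$logLik,
               dense_reml_logl(df$y, X, Z, Gt, th[["sa"]], fit$varcomp[["sn"]],
                               th[["se"]]),
               tolerance = 1e-6)
  # and dominates every point of a coarse grid over the variance box
  vy <- var(df$y)
  grid <- expand.grid(sa = seq(0.05, 2, length = 8) * vy,
                      sn = seq(0.01, 1, length = 8) * vy,
                      se = seq(0.05, 1.5, length = 8) * vy)
  gl <- apply(grid, 1, function(g)
    dense_reml_logl(df$y, X, Z, Gt, g[1], g[2], g[3]))
  expect_gte(fit$logLik, max(gl) - 1e-4)
})

test_that("identity-GRM fit reduces to the lme4 repeatability model", {
  skip_if_not_installed("lme4")
  set.seed(17)
  q <- 25
  df <- expand.grid(line = paste0("L", 1:q), experiment = 1:3,
                    stringsAsFactors = FALSE)
  idx <- match(df$line, paste0("L", 1:q))
  df$y <- 10 + c(0, 1, 2)[df$experiment] + rnorm(q, 0, 1.2)[idx] +
    rnorm(nrow(df), 0, 0.8)
  I_grm <- structure(diag(q), dimnames = list(paste0("L", 1:q), paste0("L", 1:q)))
  fit <- gblup(df, I_grm, trait = "y", partition = FALSE)
  lf <- lme4::lmer(y ~ factor(experiment) + (1 | line), df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$varcomp[["sa"]], vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$varcomp[["se"]], vc$vcov[2], tolerance = 1e-5)
  # with partitioning on, sa + sn matches the single-component genetic fit
  fit2 <- gblup(df, I_grm, trait = "y", partition = TRUE)
  expect_equal(fit2$varcomp[["sa"]] + fit2$varcomp[["sn"]],
               fit$varcomp[["sa"]], tolerance = 1e-4)
})

test_that("pure-noise data drives the additive component to the boundary", {
  set.seed(23)
  G <- shared_grm()
  ids <- rownames(unclass(G))[1:60]
  y <- setNames(rnorm(60), ids)
  fit <- gblup(y, G)
  expect_lt(fit$varcomp[["sa"]], 0.05 * var(y))
  expect_lt(max(abs(fit$gebv)), 0.2 * sd(y))
})

test_that("GEBVs sum to zero when the GRM is centred on the fitted lines", {
  sim <- shared_sim()
  ph <- derive_all_traits(sim$phenotypes)
  magic <- ph[ph$role == "magic", ]
  # centring must be on the very line set entering the fit: G 1 = 0 then
  # forces 1' u_hat = sa 1'G Z'Py = 0
  gm_ph <- subset_genotypes(sim$genotypes, lines = unique(magic$line))
  Gp <- vanraden_grm(filter_maf(gm_ph, 0.04))
  fit <- gblup(magic, Gp, trait = "total_dw")
  expect_lt(abs(sum(fit$gebv)), 1e-6 * sd(fit$y) * fit$q)
})

test_that("Cullis heritabilities follow the PEV definitions and edge cases", {
  sim <- shared_sim()
  G <- shared_grm()
  ph <- derive_all_traits(sim$phenotypes)
  fit <- gblup(ph[ph$role == "magic", ], G, trait = "total_dw",
               cullis_vd = TRUE)
  vc <- fit$varcomp
  expect_equal(fit$H2, 1 - fit$pev_g / (vc[["sa"]] + vc[["sn"]]))
  expect_equal(fit$h2, 1 - fit$pev_a / vc[["sa"]])
  expect_true(all(heritability(fit) >= 0 & heritability(fit) <= 1))
  expect_true(all(heritability(fit, vd = TRUE) >= 0 &
                    heritability(fit, vd = TRUE) <= 1))
  # when sigma_n^2 is estimated at zero, h2 equals H2 exactly
  if (vc[["sn"]] == 0) expect_identical(fit$h2, fit$H2)

  # scale invariance: multiplying the phenotype by a constant leaves both
  # heritabilities unchanged
  ph2 <- ph
  ph2$total_dw <- ph2$total_dw * 3.7
  fit2 <- gblup(ph2[ph2$role == "magic", ], G, trait = "total_dw")
  expect_equal(fit2$H2, fit$H2, tolerance = 1e-5)
  expect_equal(fit2$h2, fit$h2, tolerance = 1e-5)
  # and the components scale by the square of the constant
  expect_equal(fit2$varcomp, fit$varcomp * 3.7^2, tolerance = 1e-4)
})

test_that("genetic coefficient of variation has SD and literal modes", {
  fit <- list(sigma_g2 = 4, trait_mean = 10)
  class(fit) <- "gblup"
  expect_equal(genetic_cv(fit), 20)
  expect_equal(genetic_cv(fit, mode = "literal"), 0.4)
  fit$sigma_g2 <- 0
  expect_equal(genetic_cv(fit), 0)
  expect_equal(genetic_cv(fit, mode = "literal"), 0)
  expect_error(genetic_cv(fit, trait_mean = 0), "positive")
})

test_that("prediction of unphenotyped lines is consistent across routes", {
  sim <- shared_sim()
  G <- shared_grm()
  ph <- derive_all_traits(sim$phenotypes)
  am <- adjusted_means(ph[ph$role == "magic", ], "total_dw")
  train <- am$line[1:70]
  y <- setNames(am$value, am$line)[train]
  fit <- gblup(y, G)
  new_lines <- setdiff(rownames(unclass(G)), train)[1:20]
  p1 <- predict(fit, G, lines = new_lines)
  p2 <- predict(fit, G, lines = new_lines, method = "joint")
  expect_lt(max(abs(p1 - p2)), 1e-8)

  # a new line genetically identical to a training line gets its GEBV
  Gx <- unclass(G)[c(train, train[1]), c(train, train[1])]
  rownames(Gx)[71] <- colnames(Gx)[71] <- "copy"
  fitx <- gblup(y, structure(Gx[train, train], dimnames = list(train, train)))
  px <- drop(Gx["copy", train] %*% solve(Gx[train, train] +
                                           diag(1e-8, 70), fitx$gebv))
  expect_equal(px, unname(fitx$gebv[train[1]]), tolerance = 1e-4)

  # a line with zero genomic covariance to training is predicted at 0
  Gz <- rbind(cbind(unclass(G)[train, train], 0), 0)
  diag(Gz)[71] <- 1
  rownames(Gz) <- colnames(Gz) <- c(train, "orthogonal")
  fitz <- gblup(y, structure(Gz[train, train], dimnames = list(train, train)))
  expect_equal(unname(predict(fitz, Gz, lines = "orthogonal",
                              method = "joint")), 0)

  # held-out predictions correlate positively with the true breeding values
  tbv <- sim$truth$tbv[new_lines, "total_dw"]
  expect_gt(cor(p1, tbv), 0)
})

test_that("gblup fit methods expose coefficients, fitted values, residuals", {
  sim <- shared_sim()
  G <- shared_grm()
  ph <- derive_all_traits(sim$phenotypes)
  fit <- gblup(ph[ph$role == "magic", ], G, trait = "total_dw")
  expect_named(coef(fit), c("(Intercept)", "experiment2", "experiment3"))
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(length(gebv(fit)), fit$q)
  expect_equal(gebv(fit, total = TRUE), fit$gebv + fit$u_n)
  expect_s3_class(fit, "gblup")
  expect_output(print(fit), "sigma_a")
  expect_output(print(summary(fit)), "Fixed effects")
})
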