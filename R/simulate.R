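#' Default simulated trait panel
#'
#' The six drought-index traits with means, line-mean phenotypic SDs,
#' narrow-sense heritabilities, residual-genetic shares and experiment-effect
#' SDs chosen to emulate a water-stressed MAGIC trial: total and root dry
#' weight, total dry-weight growth during stress, flavonol index, total
#' water content and proline.
#'
#' @return data.frame with columns \code{name}, \code{mean}, \code{sd},
#'   \code{h2} (line-mean additive heritability), \code{n_share}
#'   (sigma_n^2 / (sigma_a^2 + sigma_n^2)) and \code{exp_sd}.
#' @export
default_sim_traits <- function() {
  data.frame(
    name = c("total_dw", "total_dw_growth", "root_dw", "flav", "total_wc", "pro"),
    mean = c(4.75, 2.91, 1.08, 1.37, 83.74, 108.16),
    sd = c(0.914, 0.693, 0.264, 0.108, 1.273, 27.91),
    h2 = c(0.44, 0.21, 0.42, 0.46, 0.43, 0.31),
    n_share = c(0, 0, 0, 0.35, 0.30, 0),
    exp_sd = c(0.30, 0.25, 0.08, 0.03, 0.40, 5.0),
    stringsAsFactors = FALSE)
}

#' Default genetic correlation matrix of the simulated trait panel
#'
#' Biomass traits correlate positively with each other and with proline,
#' root biomass with flavonols, and water content negatively with biomass —
#' the broad structure observed in drought trials.
#'
#' @return 6 x 6 positive-definite correlation matrix.
#' @export
default_trait_cor <- function() {
  nm <- c("total_dw", "total_dw_growth", "root_dw", "flav", "total_wc", "pro")
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set_r("total_dw", "total_dw_growth", 0.80)
  set_r("total_dw", "root_dw", 0.50)
  set_r("total_dw", "flav", 0.30)
  set_r("total_dw", "total_wc", -0.45)
  set_r("total_dw", "pro", 0.40)
  set_r("total_dw_growth", "root_dw", 0.40)
  set_r("total_dw_growth", "flav", 0.20)
  set_r("total_dw_growth", "total_wc", -0.30)
  set_r("total_dw_growth", "pro", 0.35)
  set_r("root_dw", "flav", 0.35)
  set_r("root_dw", "total_wc", -0.20)
  set_r("root_dw", "pro", 0.20)
  set_r("flav", "total_wc", -0.30)
  set_r("flav", "pro", 0.10)
  R
}

#' Configuration of a synthetic MAGIC water-stress study
#'
#' Defaults describe the emulated study design: 8 founders (7 cultivated and
#' one divergent wild-relative), 325 recombinant inbred lines from a balanced
#' 8-way funnel followed by 5 selfing generations, 184 phenotyped lines,
#' three sequential experiments with one stressed and one destructive
#' baseline plant per MAGIC line and three of each per parent, and the
#' correlated trait panel of \code{\link{default_sim_traits}}. The desk-scale
#' genome is 4 chromosomes x 500 SNPs.
#'
#' @param seed mandatory integer seed; every downstream draw derives from it.
#' @param n_founders number of founders, must be a power of two.
#' @param n_chromosomes,chrom_length_bp,snps_per_chrom genome dimensions.
#' @param cm_per_mb genetic map density (uniform; Haldane recombination).
#' @param n_magic_lines,n_phenotyped population and phenotyped subset sizes.
#' @param selfing_generations selfings after the final funnel cross.
#' @param n_experiments sequential experiments.
#' @param parent_reps,magic_reps stressed replicates per experiment (an
#'   equal number of baseline plants is added for each).
#' @param traits trait panel data.frame (see \code{\link{default_sim_traits}}).
#' @param trait_cor genetic correlation matrix among the traits; must be
#'   symmetric positive semi-definite.
#' @param n_qtl number of causal markers (shared across traits).
#' @param wild_divergence probability per marker that the wild founder's
#'   allele frequency spectrum is flipped relative to the cultivated pool.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed, n_founders = 8, n_chromosomes = 4,
                       chrom_length_bp = 5e7, snps_per_chrom = 500,
                       cm_per_mb = 1, n_magic_lines = 325,
                       n_phenotyped = min(184, n_magic_lines),
                       selfing_generations = 5,
                       n_experiments = 3, parent_reps = 3, magic_reps = 1,
                       traits = default_sim_traits(),
                       trait_cor = default_trait_cor(), n_qtl = 50,
                       wild_divergence = 0.5) {
  if (missing(seed)) stop("a seed is mandatory")
  if (bitwAnd(n_founders, n_founders - 1L) != 0 || n_founders < 2) {
    stop("n_founders must be a power of two")
  }
  traits <- as.data.frame(traits)
  need <- c("name", "mean", "sd", "h2", "n_share", "exp_sd")
  if (!all(need %in% names(traits))) {
    stop("traits needs columns ", paste(need, collapse = ", "))
  }
  if (any(traits$h2 < 0 | traits$h2 > 1)) stop("h2 must lie in [0, 1]")
  if (any(traits$n_share < 0 | traits$n_share >= 1)) {
    stop("n_share must lie in [0, 1)")
  }
  bad <- traits$h2 * (1 + traits$n_share / (1 - traits$n_share)) >= 1
  if (any(bad)) stop("infeasible h2/n_share for trait(s): ",
                     paste(traits$name[bad], collapse = ", "))
  trait_cor <- as.matrix(trait_cor)
  if (!isTRUE(all.equal(trait_cor, t(trait_cor))) ||
      min(eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("trait_cor must be a symmetric positive semi-definite matrix")
  }
  if (nrow(trait_cor) != nrow(traits)) {
    stop("trait_cor dimension must match the number of traits")
  }
  if (n_phenotyped > n_magic_lines) stop("n_phenotyped exceeds n_magic_lines")
  structure(list(seed = as.integer(seed), n_founders = n_founders,
                 n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 snps_per_chrom = snps_per_chrom, cm_per_mb = cm_per_mb,
                 n_magic_lines = n_magic_lines, n_phenotyped = n_phenotyped,
                 selfing_generations = selfing_generations,
                 n_experiments = n_experiments, parent_reps = parent_reps,
                 magic_reps = magic_reps, traits = traits,
                 trait_cor = trait_cor, n_qtl = n_qtl,
                 wild_divergence = wild_divergence),
            class = "sim_config")
}

#' Simulate the founder haplotype panel
#'
#' Fully homozygous inbred founders drawn from a common allele-frequency
#' spectrum, except the last founder, which is drawn from a diverged
#' spectrum to mimic a wild relative.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{sim_founders} list: \code{map} (marker, chrom, pos, cm),
#'   \code{haplo} (founders x markers 0/1 matrix), \code{founder_ids},
#'   \code{wild} (ID of the divergent founder), \code{base_freq}.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  maps <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$snps_per_chrom))
    data.frame(marker = sprintf("S%d_%d", ch, pos), chrom = paste0("chr", ch),
               pos = pos, cm = pos / 1e6 * cfg$cm_per_mb,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  m <- nrow(map)
  p <- stats::runif(m, 0.05, 0.95)
  nf <- cfg$n_founders
  haplo <- matrix(0L, nf, m)
  for (f in seq_len(nf - 1)) haplo[f, ] <- stats::rbinom(m, 1, p)
  flip <- stats::rbinom(m, 1, cfg$wild_divergence) == 1
  q <- ifelse(flip, 1 - p, p)
  haplo[nf, ] <- stats::rbinom(m, 1, q)
  ids <- paste0("P", seq_len(nf))
  rownames(haplo) <- ids
  structure(list(map = map, haplo = haplo, founder_ids = ids,
                 wild = ids[nf], base_freq = p),
            class = "sim_founders")
}

## Per-gap recombination fractions (Haldane, no interference) across the
## concatenated genome; 0.5 at chromosome boundaries makes chromosomes
## independent.
recomb_fractions <- function(map) {
  m <- nrow(map)
  r <- numeric(m - 1)
  d <- diff(map$cm) / 100                 # Morgans
  r[] <- 0.5 * (1 - exp(-2 * d))
  r[map$chrom[-m] != map$chrom[-1]] <- 0.5
  r
}

## One meiosis: a gamete from a pair of founder-origin haplotypes.
meiosis <- function(h1, h2, r) {
  m <- length(h1)
  sw <- stats::rbinom(m - 1, 1, r)
  phase <- (stats::rbinom(1, 1, 0.5) + cumsum(c(0L, sw))) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate a MAGIC population from the founder panel
#'
#' Balanced power-of-two funnel (pairs, then four-ways, then the final
#' cross), with the founder order permuted independently per line, followed
#' by single-seed-descent selfing. Recombination uses the Haldane map
#' function per meiosis. Lines are near-homozygous: residual per-locus
#' heterozygosity is the final-cross heterozygosity scaled by
#' 2^-selfing_generations in expectation.
#'
#' @param founders a \code{\link{simulate_founders}} panel.
#' @param cfg the \code{\link{sim_config}}.
#' @return list with \code{gm} (the MAGIC \code{genotype_matrix}),
#'   \code{mosaic} (two lines x markers integer matrices of founder origin),
#'   \code{f1_het} (per-line heterozygosity of the final funnel cross),
#'   \code{het} (per-line residual heterozygosity after selfing).
#' @export
simulate_magic <- function(founders, cfg) {
  stopifnot(inherits(founders, "sim_founders"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  map <- founders$map
  m <- nrow(map)
  r <- recomb_fractions(map)
  nf <- cfg$n_founders
  nl <- cfg$n_magic_lines
  dos <- matrix(0L, nl, m)
  mos1 <- matrix(0L, nl, m)
  mos2 <- matrix(0L, nl, m)
  f1_het <- numeric(nl)
  het <- numeric(nl)
  for (i in seq_len(nl)) {
    ord <- sample.int(nf)
    ## funnel: constant-origin haplotypes crossed pairwise until one
    ## individual remains
    gen <- lapply(ord, function(f) list(rep(f, m), rep(f, m)))
    while (length(gen) > 1) {
      nxt <- vector("list", length(gen) / 2)
      for (k in seq_along(nxt)) {
        a <- gen[[2 * k - 1]]; b <- gen[[2 * k]]
        nxt[[k]] <- list(meiosis(a[[1]], a[[2]], r), meiosis(b[[1]], b[[2]], r))
      }
      gen <- nxt
    }
    ind <- gen[[1]]
    a1 <- founders$haplo[cbind(ind[[1]], seq_len(m))]
    a2 <- founders$haplo[cbind(ind[[2]], seq_len(m))]
    f1_het[i] <- mean(a1 != a2)
    for (s in seq_len(cfg$selfing_generations)) {
      ind <- list(meiosis(ind[[1]], ind[[2]], r), meiosis(ind[[1]], ind[[2]], r))
    }
    mos1[i, ] <- ind[[1]]
    mos2[i, ] <- ind[[2]]
    a1 <- founders$haplo[cbind(ind[[1]], seq_len(m))]
    a2 <- founders$haplo[cbind(ind[[2]], seq_len(m))]
    het[i] <- mean(a1 != a2)
    dos[i, ] <- a1 + a2
  }
  ids <- sprintf("L%d", seq_len(nl))
  rownames(mos1) <- rownames(mos2) <- ids
  gm <- genotype_matrix(dos, map[c("marker", "chrom", "pos")], line_ids = ids)
  list(gm = gm, mosaic = list(mos1, mos2), f1_het = f1_het, het = het)
}

#' Founder genome shares of a simulated MAGIC population
#' @param magic result of \code{\link{simulate_magic}}.
#' @param n_founders number of founders.
#' @return numeric vector: mean genome share per founder across lines.
#' @export
founder_shares <- function(magic, n_founders = 8) {
  counts <- tabulate(c(magic$mosaic[[1]], magic$mosaic[[2]]), n_founders)
  counts / sum(counts)
}

#' Simulate the water-stress trial layout
#'
#' Per experiment, each phenotyped MAGIC line contributes
#' \code{magic_reps} stressed plant(s) and the same number of destructive
#' baseline plants; each parent contributes \code{parent_reps} of each. Rows
#' are completely randomised within experiment.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param magic_ids IDs of the phenotyped MAGIC lines.
#' @param parent_ids IDs of the parents.
#' @return data.frame with columns \code{plant_id}, \code{line},
#'   \code{role}, \code{experiment}, \code{stage}.
#' @export
simulate_trial_design <- function(cfg, magic_ids, parent_ids) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- list()
  for (e in seq_len(cfg$n_experiments)) {
    blk <- rbind(
      expand.grid(line = magic_ids, rep = seq_len(cfg$magic_reps),
                  stage = c("final", "baseline"), stringsAsFactors = FALSE),
      expand.grid(line = parent_ids, rep = seq_len(cfg$parent_reps),
                  stage = c("final", "baseline"), stringsAsFactors = FALSE))
    blk$role <- ifelse(blk$line %in% parent_ids, "parent", "magic")
    blk$experiment <- e
    blk <- blk[sample.int(nrow(blk)), ]
    rows[[e]] <- blk
  }
  out <- do.call(rbind, rows)
  out$plant_id <- sprintf("plant_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("plant_id", "line", "role", "experiment", "stage")]
}

#' Simulate correlated traits and raw plant records
#'
#' Draws causal-marker effects from a multivariate normal across traits,
#' computes true breeding values, adds line-level residual genetic effects,
#' experiment shifts and plant residual noise, and back-constructs raw organ
#' fresh/dry weights so that the phenotype-derivation pipeline reproduces
#' the simulated targets: total dry weight is partitioned into leaf, stem
#' and root, water content converts dry to fresh weight, and destructive
#' baseline plants are placed at final value minus the simulated growth.
#' Additive variances are rescaled so the realised variance of the true
#' breeding values matches the target exactly.
#'
#' @param magic result of \code{\link{simulate_magic}}.
#' @param founders the founder panel (parents enter the trial as lines).
#' @param cfg the \code{\link{sim_config}}.
#' @return list with \code{phenotypes} (raw plant table ready for
#'   \code{\link{derive_all_traits}}), \code{trait_values} (per-plant
#'   simulated trait targets), \code{truth} (QTL table, effects, true
#'   breeding values, variance components, phenotyped line IDs).
#' @export
simulate_traits <- function(magic, founders, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  gm <- magic$gm
  tr <- cfg$traits
  Tn <- nrow(tr)
  m <- nrow(gm$map)
  pheno_ids <- sort(sample(gm$line_ids, cfg$n_phenotyped))
  parent_ids <- founders$founder_ids
  ## causal markers shared across traits; effects correlated across traits
  qtl_idx <- sort(sample.int(m, min(cfg$n_qtl, m)))
  effects <- matrix(stats::rnorm(length(qtl_idx) * Tn), length(qtl_idx), Tn) %*%
    chol(cfg$trait_cor + diag(1e-10, Tn))
  colnames(effects) <- tr$name
  ## genotypes of MAGIC lines and parents at all markers
  par_dos <- 2 * founders$haplo
  rownames(par_dos) <- parent_ids
  all_dos <- rbind(gm$dosages, par_dos)
  pfreq <- colMeans(gm$dosages) / 2        # centring on the MAGIC population
  Wq <- sweep(all_dos[, qtl_idx, drop = FALSE], 2, 2 * pfreq[qtl_idx], "-")
  tbv <- Wq %*% effects
  magic_rows <- rownames(tbv) %in% gm$line_ids
  varcomp <- data.frame(trait = tr$name, sa = NA_real_, sn = NA_real_,
                        se = NA_real_, mu = tr$mean, exp_sd = tr$exp_sd)
  un <- matrix(0, nrow(tbv), Tn, dimnames = list(rownames(tbv), tr$name))
  for (k in seq_len(Tn)) {
    sd2 <- tr$sd[k]^2
    sa <- tr$h2[k] * sd2
    v0 <- stats::var(tbv[magic_rows, k])
    scl <- if (v0 > 0) sqrt(sa / v0) else 0
    tbv[, k] <- tbv[, k] * scl
    effects[, k] <- effects[, k] * scl
    sn <- sa * tr$n_share[k] / (1 - tr$n_share[k])
    se <- cfg$n_experiments * (sd2 - sa - sn)
    if (se <= 0) stop("infeasible variance partition for trait ", tr$name[k])
    varcomp$sa[k] <- sa; varcomp$sn[k] <- sn; varcomp$se[k] <- se
    un[, k] <- stats::rnorm(nrow(tbv), 0, sqrt(sn))
  }
  design <- simulate_trial_design(cfg, pheno_ids, parent_ids)
  np <- nrow(design)
  exp_eff <- sapply(seq_len(Tn), function(k)
    stats::rnorm(cfg$n_experiments, 0, tr$exp_sd[k]))
  colnames(exp_eff) <- tr$name
  ## per-plant trait targets on final plants
  vals <- matrix(NA_real_, np, Tn, dimnames = list(design$plant_id, tr$name))
  fin <- design$stage == "final"
  li <- match(design$line, rownames(tbv))
  for (k in seq_len(Tn)) {
    vals[fin, k] <- tr$mean[k] + exp_eff[design$experiment[fin], k] +
      tbv[li[fin], k] + un[li[fin], k] +
      stats::rnorm(sum(fin), 0, sqrt(varcomp$se[k]))
  }
  ## --- back-construct raw organ weights -------------------------------
  gv <- function(nm, default) if (nm %in% tr$name) vals[, nm] else default
  total_dw <- pmax(gv("total_dw", 4.75 + stats::rnorm(np, 0, 0.9)), 0.3)
  root_dw <- gv("root_dw", 0.23 * total_dw)
  root_dw <- pmin(pmax(root_dw, 0.05 * total_dw), 0.6 * total_dw)
  aerial_dw <- total_dw - root_dw
  leaf_share <- stats::rbeta(np, 30 * 0.76, 30 * 0.24)
  leaf_dw <- aerial_dw * leaf_share
  stem_dw <- aerial_dw - leaf_dw
  wc <- pmin(pmax(gv("total_wc", 83.7 + stats::rnorm(np, 0, 1.5)), 55), 95)
  growth <- gv("total_dw_growth", 0.6 * total_dw)
  df <- design
  df$dw_leaf <- leaf_dw; df$dw_stem <- stem_dw; df$dw_root <- root_dw
  ## baseline plants sit at final minus simulated growth, same organ split
  ## and water content; each baseline row is matched to a final row of the
  ## same line and experiment (cycled over replicates for parents)
  key <- paste(df$line, df$experiment)
  for (kk in unique(key)) {
    bidx <- which(!fin & key == kk)
    fidx <- which(fin & key == kk)
    for (jj in seq_along(bidx)) {
      b <- bidx[jj]
      src <- fidx[1 + (jj - 1) %% length(fidx)]
      shrink <- max(0.05, 1 - growth[src] / total_dw[src])
      df$dw_leaf[b] <- leaf_dw[src] * shrink
      df$dw_stem[b] <- stem_dw[src] * shrink
      df$dw_root[b] <- root_dw[src] * shrink
      wc[b] <- wc[src]
    }
  }
  df$fw_leaf <- df$dw_leaf / (1 - wc / 100)
  df$fw_stem <- df$dw_stem / (1 - wc / 100)
  df$fw_root <- df$dw_root / (1 - wc / 100)
  ## non-genetic nuisance measurements so the full derivation pipeline runs
  df$leaf_number <- pmax(1, round(5.2 + stats::rnorm(np, 0, 1.4)))
  df$stem_length <- pmax(2, 13.8 + stats::rnorm(np, 0, 3.1))
  df$leaf_number[!fin] <- pmax(1, df$leaf_number[!fin] + 1)
  df$stem_length[!fin] <- pmax(1, df$stem_length[!fin] - 3.6)
  df$chl <- ifelse(fin, 42.9 + stats::rnorm(np, 0, 4), NA)
  df$anth <- ifelse(fin, 0.34 + stats::rnorm(np, 0, 0.03), NA)
  df$nbi <- ifelse(fin, 31.6 + stats::rnorm(np, 0, 3), NA)
  df$flav <- ifelse(fin, gv("flav", 1.37 + stats::rnorm(np, 0, 0.1)), NA)
  df$pro <- ifelse(fin, pmax(gv("pro", 108 + stats::rnorm(np, 0, 27)), 1), NA)
  truth <- list(qtl = data.frame(gm$map[qtl_idx, c("marker", "chrom", "pos")],
                                 row.names = NULL),
                effects = effects, tbv = tbv, varcomp = varcomp,
                exp_eff = exp_eff, phenotyped = pheno_ids,
                residual_genetic = un)
  list(phenotypes = df, trait_values = vals, truth = truth)
}

#' Simulate a complete synthetic MAGIC water-stress study
#'
#' Founder panel, MAGIC population, trial design, correlated traits and raw
#' plant records in one call; the truth set (causal markers, effects, true
#' breeding values, variance components) is returned alongside.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{magic_sim} list: \code{config}, \code{founders},
#'   \code{genotypes} (MAGIC \code{genotype_matrix}), \code{magic} (mosaics
#'   and heterozygosity bookkeeping), \code{phenotypes}, \code{trait_values},
#'   \code{truth}.
#' @export
simulate_magic_study <- function(cfg) {
  founders <- simulate_founders(cfg)
  magic <- simulate_magic(founders, cfg)
  tv <- simulate_traits(magic, founders, cfg)
  structure(list(config = cfg, founders = founders, genotypes = magic$gm,
                 magic = magic, phenotypes = tv$phenotypes,
                 trait_values = tv$trait_values, truth = tv$truth),
            class = "magic_sim")
}

#' @method print magic_sim
#' @export
print.magic_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic MAGIC study (seed %d): %d founders, %d lines (%d phenotyped)\n",
              cfg$seed, cfg$n_founders, cfg$n_magic_lines, cfg$n_phenotyped))
  cat(sprintf("  genome: %d chromosomes x %d SNPs; %d experiments; traits: %s\n",
              cfg$n_chromosomes, cfg$snps_per_chrom, cfg$n_experiments,
              paste(cfg$traits$name, collapse = ", ")))
  invisible(x)
}

#' Serialise the simulation truth set to JSON
#' @param sim a \code{magic_sim}.
#' @param path output path.
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "magic_sim"))
  tr <- sim$truth
  jsonlite::write_json(
    list(qtl = tr$qtl, effects = as.data.frame(tr$effects),
         tbv = data.frame(line = rownames(tr$tbv), tr$tbv),
         varcomp = tr$varcomp, phenotyped = tr$phenotyped),
    path, dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(path)
}
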