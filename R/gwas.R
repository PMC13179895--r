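#' Bonferroni significance threshold on the -log10 scale
#'
#' @param n_snps number of markers tested (>= 1).
#' @param alpha family-wise error rate in (0, 1); default 0.05.
#' @return -log10(alpha / n_snps).
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.05) {
  if (any(n_snps < 1)) stop("n_snps must be >= 1")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)")
  -log10(alpha / n_snps)
}

#' Single-marker GWAS with principal-component covariates
#'
#' For each SNP, an ordinary least squares fit of the adjusted line mean on
#' an intercept, the first \code{n_pcs} genotype principal components and the
#' SNP dosage; a two-sided t test on the dosage coefficient gives the
#' p-value, and the partial R^2 of the SNP term given the covariates is
#' reported. SNPs collinear with the covariates get a missing p-value.
#'
#' @param gm a \code{genotype_matrix}.
#' @param means an \code{\link{adjusted_means}} object or named numeric
#'   vector of line values; the scan runs on the line intersection.
#' @param n_pcs number of principal-component covariates (default 3; 0 gives
#'   simple marker regression).
#' @param alpha family-wise rate for the Bonferroni threshold recorded in
#'   the scan metadata.
#' @return a \code{gwas_scan}: data.frame with one row per tested SNP
#'   (marker, chrom, pos, beta, se, t, p, neglog10p, r2, maf) and attributes
#'   \code{n_pcs}, \code{n_snps}, \code{n_lines}, \code{threshold},
#'   \code{trait}.
#' @export
run_gwas <- function(gm, means, n_pcs = 3, alpha = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (inherits(means, "adjusted_means")) {
    trait <- attr(means, "trait")
    means <- stats::setNames(means$value, means$line)
  } else trait <- NULL
  means <- means[!is.na(means)]
  ids <- intersect(gm$line_ids, names(means))
  if (length(ids) < 3) stop("too few lines shared between genotypes and means")
  gms <- subset_genotypes(gm, lines = ids)
  y <- means[ids]
  n <- length(y)
  Q <- matrix(1, n, 1)
  if (n_pcs > 0) {
    pc <- genotype_pca(gms, n_components = n_pcs)
    Q <- cbind(Q, pc$scores)
  }
  ## Frisch-Waugh-Lovell: residualise y and every dosage column on Q, then
  ## the per-SNP slope/t from simple regression of the residuals
  qrQ <- qr(Q)
  ry <- stats::setNames(qr.resid(qrQ, y), NULL)
  S <- gms$dosages
  RS <- qr.resid(qrQ, S)
  ss <- colSums(RS^2)
  df <- n - ncol(Q) - 1
  if (df < 1) stop("not enough lines for the covariate set")
  sxy <- drop(crossprod(RS, ry))
  beta <- sxy / ss
  syy <- sum(ry^2)
  rss <- syy - beta * sxy
  sigma2 <- rss / df
  se <- sqrt(sigma2 / ss)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  r2 <- tval^2 / (tval^2 + df)
  ## collinear (or monomorphic) SNPs: no testable dosage contrast
  bad <- ss <= n * .Machine$double.eps * max(ss, 1)
  beta[bad] <- se[bad] <- tval[bad] <- p[bad] <- r2[bad] <- NA_real_
  pfreq <- allele_freq(gms)
  out <- data.frame(marker = gms$map$marker, chrom = gms$map$chrom,
                    pos = gms$map$pos, beta = beta, se = se, t = tval,
                    p = p, neglog10p = -log10(p), r2 = r2,
                    maf = pmin(pfreq, 1 - pfreq),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("gwas_scan", "data.frame"),
            n_pcs = n_pcs, n_snps = sum(!bad), n_lines = n,
            threshold = bonferroni_threshold(max(sum(!bad), 1), alpha),
            alpha = alpha, trait = trait,
            reason = ifelse(bad, "collinear with covariates", NA_character_))
}

#' Linkage disequilibrium r^2 between two markers
#'
#' Squared Pearson correlation of the dosage vectors, invariant to allele
#' coding sign.
#'
#' @param gm a \code{genotype_matrix}.
#' @param snp_i,snp_j marker names or column indices; both must be
#'   polymorphic.
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(gm, snp_i, snp_j) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- function(s) if (is.character(s)) match(s, gm$map$marker) else s
  i <- idx(snp_i); j <- idx(snp_j)
  if (is.na(i) || is.na(j)) stop("unknown marker")
  xi <- gm$dosages[, i]; xj <- gm$dosages[, j]
  if (stats::var(xi) == 0 || stats::var(xj) == 0) {
    stop("monomorphic marker: LD r^2 undefined")
  }
  stats::cor(xi, xj)^2
}

#' Delimit the genomic region supported by a GWAS peak
#'
#' The region spans the outermost markers within half the physical window of
#' the peak that are both in LD with the peak (r^2 >= \code{r2_min}) and
#' supported by the scan (-log10 p above \code{support_logp}, or themselves
#' significant at the scan threshold). A peak with no supporting neighbours
#' collapses to a zero-length region at its own position.
#'
#' @param scan a \code{gwas_scan}.
#' @param gm the \code{genotype_matrix} the scan was run on.
#' @param peak_snp marker name of the peak (must be significant at the scan
#'   threshold unless \code{check_significant = FALSE}).
#' @param window_bp physical window surrounding the peak (default 4 Mb,
#'   i.e. +/- 2 Mb); set \code{full_window = TRUE} to use +/- window_bp.
#' @param r2_min LD r^2 membership bound (default 0.4).
#' @param support_logp -log10(p) support bound for non-significant members
#'   (default 5).
#' @param full_window interpret \code{window_bp} as the half-width.
#' @param check_significant require the peak to pass the scan threshold.
#' @return a \code{genomic_region}: list with chrom, start, end, peak
#'   marker/position/-log10 p/R2/MAF, and the rule parameters applied.
#' @export
define_region <- function(scan, gm, peak_snp, window_bp = 4e6, r2_min = 0.4,
                          support_logp = 5, full_window = FALSE,
                          check_significant = TRUE) {
  stopifnot(inherits(scan, "gwas_scan"))
  k <- match(peak_snp, scan$marker)
  if (is.na(k)) stop("peak marker not in scan")
  thr <- attr(scan, "threshold")
  if (check_significant && !(scan$neglog10p[k] >= thr)) {
    stop("peak marker is not significant at the scan threshold (",
         round(thr, 3), ")")
  }
  half <- if (full_window) window_bp else window_bp / 2
  cand <- which(scan$chrom == scan$chrom[k] &
                  abs(scan$pos - scan$pos[k]) <= half &
                  !is.na(scan$p))
  ok <- logical(length(cand))
  for (ii in seq_along(cand)) {
    j <- cand[ii]
    if (j == k) { ok[ii] <- TRUE; next }
    poly <- stats::var(gm$dosages[, match(scan$marker[j], gm$map$marker)]) > 0
    if (!poly) next
    r2 <- ld_r2(gm, scan$marker[k], scan$marker[j])
    supported <- scan$neglog10p[j] > support_logp || scan$neglog10p[j] >= thr
    ok[ii] <- r2 >= r2_min && supported
  }
  members <- cand[ok]
  structure(list(chrom = scan$chrom[k],
                 start = min(scan$pos[members]),
                 end = max(scan$pos[members]),
                 peak_marker = scan$marker[k], peak_pos = scan$pos[k],
                 peak_neglog10p = scan$neglog10p[k], peak_r2 = scan$r2[k],
                 peak_maf = scan$maf[k], n_members = length(members),
                 members = scan$marker[members],
                 window_bp = window_bp, r2_min = r2_min,
                 support_logp = support_logp),
            class = "genomic_region")
}

#' @method print genomic_region
#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("genomic region %s:%s-%s (%d marker(s))\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$n_members))
  cat(sprintf("  peak %s at %s: -log10(p) = %.2f, R2 = %.3f, MAF = %.3f\n",
              x$peak_marker, format(x$peak_pos, big.mark = ","),
              x$peak_neglog10p, x$peak_r2, x$peak_maf))
  invisible(x)
}

#' Significant markers of a scan
#' @param scan a \code{gwas_scan}.
#' @return the scan rows at or above the Bonferroni threshold.
#' @export
significant_snps <- function(scan) {
  stopifnot(inherits(scan, "gwas_scan"))
  scan[!is.na(scan$neglog10p) & scan$neglog10p >= attr(scan, "threshold"), ]
}

#' Manhattan plot of a GWAS scan
#'
#' Base-graphics Manhattan plot with alternating chromosome colours and the
#' scan's Bonferroni threshold as a dashed line.
#'
#' @param x a \code{gwas_scan}.
#' @param ... passed to \code{plot}.
#' @method plot gwas_scan
#' @export
plot.gwas_scan <- function(x, ...) {
  chroms <- unique(x$chrom)
  span <- tapply(x$pos, factor(x$chrom, levels = chroms), max)
  offs <- cumsum(c(0, as.numeric(span)))[seq_along(chroms)]
  gx <- x$pos + offs[match(x$chrom, chroms)]
  col <- c("grey35", "steelblue")[1 + match(x$chrom, chroms) %% 2]
  graphics::plot(gx, x$neglog10p, pch = 20, col = col,
                 xlab = "cumulative position (bp)",
                 ylab = expression(-log[10](italic(p))), ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2, col = "firebrick")
  invisible(x)
}
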