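#' Phenotypic and genetic covariance matrices over lines
#'
#' Sample covariance matrices of the adjusted phenotypic means (P) and of
#' the genetic values (Gc) across traits, computed over the common line set.
#'
#' @param pheno lines x traits matrix of phenotypic values (adjusted means).
#' @param genetic lines x traits matrix of genetic values (GEBVs), same
#'   lines and traits.
#' @return list with \code{P}, \code{Gc} (t x t) and \code{condition}, the
#'   condition number of P; a warning is issued when P is numerically
#'   rank deficient.
#' @export
trait_cov_matrices <- function(pheno, genetic) {
  pheno <- as.matrix(pheno); genetic <- as.matrix(genetic)
  if (!identical(dim(pheno), dim(genetic))) stop("matrices must match in shape")
  if (!is.null(rownames(pheno)) && !is.null(rownames(genetic)) &&
      !identical(rownames(pheno), rownames(genetic))) {
    stop("line sets (rownames) of the two matrices differ")
  }
  if (nrow(pheno) < ncol(pheno) + 1) stop("need at least t + 1 lines")
  P <- stats::cov(pheno)
  Gc <- stats::cov(genetic)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  if (!is.finite(cond) || cond > 1e12) {
    warning("phenotypic covariance matrix P is numerically rank deficient ",
            "(condition number ", format(cond), ")")
  }
  list(P = P, Gc = Gc, condition = cond)
}

#' Smith-Hazel index coefficients
#'
#' Solves b = P^-1 Gc a, the weights of the linear index I = b'x that
#' maximises the correlation between the index and the aggregate genotypic
#' merit a'g.
#'
#' @param P phenotypic covariance matrix (t x t, symmetric).
#' @param Gc genetic covariance matrix (t x t).
#' @param a economic weights; default 1 for every trait.
#' @param ridge optional ridge added to diag(P) as a fraction of its mean
#'   diagonal (e.g. 1e-6) when P is near singular; recorded as an attribute.
#' @return numeric vector b (named after the traits when P has dimnames),
#'   with attribute \code{ridge} giving the absolute ridge applied (0 if
#'   none).
#' @export
smith_hazel <- function(P, Gc, a = rep(1, ncol(P)), ridge = NULL) {
  P <- as.matrix(P); Gc <- as.matrix(Gc)
  if (nrow(P) != ncol(P) || !isTRUE(all.equal(P, t(P), tolerance = 1e-8))) {
    stop("P must be a symmetric square matrix")
  }
  if (!identical(dim(P), dim(Gc))) stop("P and Gc must have the same dimension")
  if (length(a) != ncol(P)) stop("a must have one weight per trait")
  rhs <- drop(Gc %*% a)
  applied <- 0
  Pw <- P
  if (!is.null(ridge)) {
    applied <- ridge * mean(diag(P))
    diag(Pw) <- diag(Pw) + applied
  }
  b <- tryCatch(solve(Pw, rhs), error = function(e) {
    stop("P is singular; supply a ridge (e.g. ridge = 1e-6): ",
         conditionMessage(e))
  })
  if (max(abs(Pw %*% b - rhs)) > 1e-10 * max(1, max(abs(rhs)))) {
    warning("linear solve residual exceeds 1e-10; P is ill conditioned")
  }
  names(b) <- colnames(P)
  attr(b, "ridge") <- applied
  b
}

#' Per-line Smith-Hazel index values
#'
#' I = sum_t b_t x_t per line; lines with any missing genetic value are
#' excluded with a warning. Ranking is descending: the highest index is the
#' most drought tolerant.
#'
#' @param genetic lines x traits matrix of additive genetic values.
#' @param b index coefficients from \code{\link{smith_hazel}}.
#' @return a \code{selection_index}: data.frame with \code{line},
#'   \code{index} and \code{rank} (1 = highest index), sorted by rank.
#' @export
index_values <- function(genetic, b) {
  genetic <- as.matrix(genetic)
  if (ncol(genetic) != length(b)) stop("b must have one weight per trait")
  keep <- stats::complete.cases(genetic)
  if (!all(keep)) {
    warning(sum(!keep), " line(s) with missing genetic values excluded")
    genetic <- genetic[keep, , drop = FALSE]
  }
  I <- drop(genetic %*% b)
  ids <- rownames(genetic)
  if (is.null(ids)) ids <- paste0("L", seq_along(I))
  ord <- order(-I, ids)
  out <- data.frame(line = ids[ord], index = I[ord],
                    rank = seq_along(I), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, class = c("selection_index", "data.frame"), b = b)
}

#' Classify the most tolerant and most susceptible lines
#'
#' Top-k and bottom-k lines by index value; ties at a boundary are broken
#' by lexicographic line ID, and any boundary tie is recorded in the
#' \code{ties} attribute.
#'
#' @param index a \code{selection_index} (or data.frame with \code{line} and
#'   \code{index}).
#' @param k number of lines per class (default 3); needs >= 2k lines.
#' @return list with \code{tolerant} and \code{susceptible} character
#'   vectors (tolerant in decreasing, susceptible in increasing index
#'   order).
#' @export
classify_lines <- function(index, k = 3) {
  if (nrow(index) < 2 * k) stop("need at least 2k lines")
  ord <- order(-index$index, index$line)
  asc <- order(index$index, index$line)
  tol <- index$line[ord][seq_len(k)]
  sus <- index$line[asc][seq_len(k)]
  ties <- character(0)
  bnd <- index$index[ord][k]
  if (sum(index$index == bnd) > 1) {
    ties <- index$line[index$index == bnd]
  }
  structure(list(tolerant = tol, susceptible = sus), ties = ties)
}

#' Genetic correlation matrix between traits
#'
#' Pearson correlations between the per-line genetic values of trait pairs,
#' with two-sided p-values; a display mask hides non-significant entries.
#'
#' @param genetic lines x traits matrix of genetic values (>= 4 lines).
#' @param alpha significance level for the display mask (default 0.05).
#' @return list with \code{r} (correlations), \code{p} (p-values, NA on the
#'   diagonal), and \code{masked} (r with entries at p >= alpha set to NA).
#'   Constant traits give NA correlations.
#' @export
genetic_correlations <- function(genetic, alpha = 0.05) {
  genetic <- as.matrix(genetic)
  n <- nrow(genetic)
  if (n < 4) warning("fewer than 4 lines: correlations are very imprecise")
  t_ <- ncol(genetic)
  sds <- apply(genetic, 2, stats::sd)
  r <- suppressWarnings(stats::cor(genetic))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  diag(p) <- NA
  masked <- r
  masked[!is.na(p) & p >= alpha] <- NA
  list(r = r, p = p, masked = masked)
}

#' PCA of standardised genetic values
#'
#' Each trait's genetic values are standardised to zero mean and unit
#' variance over lines, then the correlation matrix is eigen-decomposed.
#' Zero-variance traits are dropped with a warning. The sign of each
#' component is fixed by making its largest-magnitude loading positive.
#'
#' @param genetic lines x traits matrix (>= 3 lines, >= 2 traits).
#' @return list with \code{scores} (lines x components), \code{loadings}
#'   (traits x components), \code{varexp} (fraction of variance per
#'   component).
#' @export
pca_genetic_values <- function(genetic) {
  genetic <- as.matrix(genetic)
  if (nrow(genetic) < 3 || ncol(genetic) < 2) {
    stop("need at least 3 lines and 2 traits")
  }
  sds <- apply(genetic, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance trait(s): ",
            paste(colnames(genetic)[sds == 0], collapse = ", "))
    genetic <- genetic[, sds > 0, drop = FALSE]
  }
  Xs <- scale(genetic)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, varexp = varexp)
}
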