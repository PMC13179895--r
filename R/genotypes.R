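#' Construct a genotype matrix
#'
#' Bundles a lines x markers dosage matrix with its marker map. Dosages are
#' alternate-allele counts in \{0, 1, 2\} (fractional values only arise from
#' opt-in mean imputation at load time). The map uses 1-based physical
#' positions, as in VCF, and chromosome labels are treated as opaque strings.
#'
#' @param dosages numeric matrix, lines x markers, values in [0, 2], no
#'   missing values. Row names are line identifiers, column names marker
#'   identifiers (generated when absent).
#' @param map data.frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   (bp, 1-based), one row per column of \code{dosages}, positions strictly
#'   increasing within each chromosome.
#' @param line_ids character vector of unique line identifiers; defaults to
#'   \code{rownames(dosages)}.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{dosages}, \code{map}, \code{line_ids}.
#' @export
genotype_matrix <- function(dosages, map, line_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(dosages)))
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stop("line identifiers must be unique")
  if (length(line_ids) != nrow(dosages)) {
    stop("length(line_ids) must equal nrow(dosages)")
  }
  if (anyNA(dosages)) {
    stop("dosage matrix contains missing values; load with impute_mean = TRUE ",
         "or complete the data before constructing a genotype_matrix")
  }
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map))) {
    stop("map must have columns 'marker', 'chrom', 'pos'")
  }
  map <- map[need]
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (nrow(map) != ncol(dosages)) {
    stop("map must have one row per marker column")
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("map positions must be strictly increasing within chromosome ", ch)
    }
  }
  rownames(dosages) <- line_ids
  colnames(dosages) <- map$marker
  structure(list(dosages = dosages, map = map, line_ids = line_ids),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  p <- allele_freq(x)
  cat("genotype_matrix:", length(x$line_ids), "lines x", nrow(x$map),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  cat(sprintf("  alt allele frequency: min %.3f, median %.3f, max %.3f\n",
              min(p), stats::median(p), max(p)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Alternate-allele frequencies
#'
#' @param gm a \code{genotype_matrix}.
#' @return numeric vector, one frequency per marker (column mean dosage / 2).
#' @export
allele_freq <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  colMeans(gm$dosages) / 2
}

#' Subset a genotype matrix
#'
#' @param gm a \code{genotype_matrix}.
#' @param lines line identifiers or indices to keep (default all).
#' @param markers marker identifiers or indices to keep (default all).
#' @return a \code{genotype_matrix}.
#' @export
subset_genotypes <- function(gm, lines = NULL, markers = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  map <- gm$map
  if (!is.null(markers)) {
    j <- if (is.character(markers)) match(markers, map$marker) else markers
    if (anyNA(j)) stop("unknown marker identifiers")
    d <- d[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  if (!is.null(lines)) {
    i <- if (is.character(lines)) match(lines, gm$line_ids) else lines
    if (anyNA(i)) stop("unknown line identifiers")
    d <- d[i, , drop = FALSE]
  }
  genotype_matrix(d, map)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Converts GT fields to alternate-allele dosages. Multi-allelic records are
#' skipped (default) or rejected. Missing genotypes are an error unless
#' per-marker mean imputation is requested.
#'
#' @param path path to a VCF file (v4.x, GT format field).
#' @param skip_multiallelic logical; drop records with more than one ALT
#'   allele (\code{TRUE}, default) or fail on them.
#' @param impute_mean logical; replace missing GT calls by the marker mean
#'   dosage computed over observed calls.
#' @return a \code{genotype_matrix} with samples as lines.
#' @export
read_vcf <- function(path, skip_multiallelic = TRUE, impute_mean = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi) && !skip_multiallelic) {
    stop("multi-allelic record(s) at line(s): ",
         paste(which(multi), collapse = ", "),
         " (set skip_multiallelic = TRUE to drop them)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(gt) == 0L) stop("no biallelic SNP records in ", path)
  # count ALT alleles in a diploid GT string such as 0/1 or 1|1
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    a <- strsplit(gsub("\\|", "/", g[ok]), "/", fixed = FALSE)
    out[ok] <- vapply(a, function(x) sum(as.integer(x) > 0L), numeric(1))
    out
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  dos <- t(dos)  # lines x markers
  if (anyNA(dos)) {
    if (!impute_mean) {
      stop("missing GT calls present; set impute_mean = TRUE to mean-impute")
    }
    for (j in which(colSums(is.na(dos)) > 0)) {
      m <- mean(dos[, j], na.rm = TRUE)
      if (is.nan(m)) m <- 0
      dos[is.na(dos[, j]), j] <- m
    }
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  genotype_matrix(dos[, ord, drop = FALSE], map[ord, ],
                  line_ids = colnames(gt))
}

#' Write genotypes as a dosage CSV plus sidecar map CSV
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output CSV (header row = marker IDs, first column = line ID).
#' @param map_path output map CSV (columns marker, chrom, pos); defaults to
#'   \code{path} with a \code{.map.csv} suffix.
#' @return invisibly, the two paths.
#' @export
write_dosage_csv <- function(gm, path, map_path = sub("\\.csv$", ".map.csv", path)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(line = gm$line_ids, gm$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(gm$map, map_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, map_path))
}

#' Read genotypes from a dosage CSV plus sidecar map CSV
#'
#' @inheritParams write_dosage_csv
#' @return a \code{genotype_matrix}.
#' @export
read_dosage_csv <- function(path, map_path = sub("\\.csv$", ".map.csv", path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  genotype_matrix(d, map, line_ids = df[[1]])
}

#' Filter markers by minor allele frequency
#'
#' Keeps markers whose minor allele frequency strictly exceeds
#' \code{min_maf}; a marker with MAF exactly at the cutoff is removed, and
#' monomorphic markers are always removed. Marker order is preserved.
#'
#' @param gm a \code{genotype_matrix}.
#' @param min_maf MAF cutoff in [0, 0.5).
#' @return a \code{genotype_matrix} with the retained markers.
#' @export
filter_maf <- function(gm, min_maf = 0.04) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must lie in [0, 0.5)")
  p <- allele_freq(gm)
  keep <- pmin(p, 1 - p) > min_maf
  subset_genotypes(gm, markers = which(keep))
}

#' Thin markers to a minimum pairwise distance
#'
#' Greedy left-to-right keep-first thinning within each chromosome: the first
#' marker is kept and each subsequent marker is kept only if it lies at least
#' \code{min_bp} beyond the last kept marker, so retained markers are pairwise
#' at least \code{min_bp} apart.
#'
#' @param gm a \code{genotype_matrix} (map sorted within chromosomes, as the
#'   constructor enforces).
#' @param min_bp minimum distance in bp between retained markers.
#' @return a \code{genotype_matrix}.
#' @export
thin_markers <- function(gm, min_bp = 2000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (min_bp < 0) stop("min_bp must be non-negative")
  if (min_bp == 0) return(gm)
  keep <- logical(nrow(gm$map))
  for (ch in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == ch)
    pos <- gm$map$pos[idx]
    if (is.unsorted(pos, strictly = TRUE)) stop("map unsorted on chromosome ", ch)
    last <- -Inf
    for (k in seq_along(idx)) {
      if (pos[k] - last >= min_bp) {
        keep[idx[k]] <- TRUE
        last <- pos[k]
      }
    }
  }
  subset_genotypes(gm, markers = which(keep))
}

#' VanRaden genomic relationship matrix
#'
#' Computes G = W W' / (2 * sum_j p_j (1 - p_j)) where W is the dosage matrix
#' with columns centred at twice the alternate-allele frequency. Monomorphic
#' markers contribute nothing to either numerator or denominator. If G is not
#' positive semi-definite to tolerance, the smallest epsilon from
#' \code{c(1e-8, 1e-6, 1e-4)} achieving a minimum eigenvalue >= -1e-8 is added
#' to the diagonal and recorded.
#'
#' @param gm a \code{genotype_matrix} with at least 2 lines and one
#'   polymorphic marker.
#' @return an object of class \code{grm}: the n x n matrix with attributes
#'   \code{bend_epsilon} (0 when no bending was needed) and \code{denom}.
#' @export
vanraden_grm <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$dosages) < 2) stop("need at least 2 lines")
  p <- allele_freq(gm)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic: GRM denominator is zero")
  W <- sweep(gm$dosages, 2, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  eps <- 0
  if (ev_min < -1e-8) {
    for (cand in c(1e-8, 1e-6, 1e-4)) {
      if (ev_min + cand >= -1e-8) { eps <- cand; break }
    }
    if (eps == 0) eps <- 1e-4  # largest candidate; eigenvalue deficit beyond it is pathological
    diag(G) <- diag(G) + eps
  }
  structure(G, class = c("grm", class(G)), bend_epsilon = eps, denom = denom)
}

#' @method print grm
#' @export
print.grm <- function(x, ...) {
  cat("VanRaden genomic relationship matrix:", nrow(x), "x", ncol(x), "lines\n")
  cat(sprintf("  mean diagonal %.4f, bend epsilon %g\n",
              mean(diag(x)), attr(x, "bend_epsilon")))
  invisible(x)
}

#' Write a GRM as a square CSV with line IDs
#' @param grm a \code{grm} (or plain square matrix with dimnames).
#' @param path output CSV path.
#' @export
write_grm_csv <- function(grm, path) {
  utils::write.csv(as.data.frame(unclass(grm)), path, row.names = TRUE)
  invisible(path)
}

#' Principal components of the genotype matrix
#'
#' Eigen-decomposition (via SVD) of the column-centred dosage matrix; used as
#' population-structure covariates in the GWAS scan. Columns may optionally be
#' scaled to unit variance.
#'
#' @param gm a \code{genotype_matrix}.
#' @param n_components number of components, at most the matrix rank.
#' @param scale. logical; scale columns to unit variance (zero-variance
#'   markers are dropped before scaling). Default \code{FALSE}.
#' @return list with \code{scores} (lines x n_components), \code{varexp}
#'   (fraction of variance per component, non-increasing), \code{sdev}.
#' @export
genotype_pca <- function(gm, n_components = 3, scale. = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  X <- gm$dosages
  if (scale.) {
    v <- apply(X, 2, stats::var)
    X <- X[, v > 0, drop = FALSE]
  }
  if (n_components > min(dim(X))) {
    stop("n_components exceeds min(n_lines, n_markers)")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  r <- sum(pc$sdev > max(dim(X)) * .Machine$double.eps * pc$sdev[1])
  if (n_components > r) stop("n_components (", n_components,
                             ") exceeds matrix rank (", r, ")")
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- gm$line_ids
  list(scores = scores, varexp = varexp[seq_len(n_components)],
       sdev = pc$sdev[seq_len(n_components)])
}
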