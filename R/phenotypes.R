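#' The derived drought-trait dictionary
#'
#' Names of the 25 traits the phenotype pipeline derives for a water-stress
#' trial: organ and aggregate dry weights, water contents, growth during the
#' stress period against destructive baselines, plant architecture, optical
#' pigment indices and proline.
#'
#' @return character vector of trait column names.
#' @export
magic_traits <- function() {
  c("stem_length", "stem_dw", "anth", "flav", "total_wc", "leaf_wc",
    "stem_wc", "leaf_number", "aerial_wc", "aerial_root_ratio", "chl",
    "leaf_number_growth", "stem_length_growth", "nbi", "stem_dw_growth",
    "root_wc", "aerial_dw", "leaf_dw", "total_dw", "root_dw",
    "root_dw_growth", "pro", "aerial_dw_growth", "total_dw_growth",
    "leaf_dw_growth")
}

#' Plant water content
#'
#' Water content on a fresh-weight basis: 100 * (FW - DW) / FW, in percent.
#' This is the only formulation bounded by [0, 100] and consistent with
#' typical plant tissue values of 70-90\%.
#'
#' @param fw fresh weight (g), > 0.
#' @param dw dry weight (g), with 0 <= dw <= fw.
#' @return water content in percent; vectorised.
#' @export
water_content <- function(fw, dw) {
  if (any(!is.finite(fw)) || any(!is.finite(dw))) stop("weights must be finite")
  if (any(fw <= 0)) stop("fresh weight must be positive")
  if (any(dw < 0) || any(dw > fw)) stop("dry weight must satisfy 0 <= dw <= fw")
  100 * (fw - dw) / fw
}

#' Gravimetric watering target
#'
#' Mass of water corresponding to a fraction of field capacity (FC), given
#' the water mass held at 100\% FC (pot and dry substrate weight already
#' subtracted). E.g. a substrate holding 780 g at 100\% FC is watered with
#' 234 g to impose 30\% FC stress.
#'
#' @param mass_at_100fc water mass at 100\% FC (g), > 0.
#' @param fc_fraction target fraction of field capacity in (0, 1].
#' @return target water mass in g.
#' @export
watering_target <- function(mass_at_100fc, fc_fraction) {
  if (any(mass_at_100fc <= 0)) stop("mass_at_100fc must be positive")
  if (any(fc_fraction <= 0) || any(fc_fraction > 1)) {
    stop("fc_fraction must lie in (0, 1]")
  }
  fc_fraction * mass_at_100fc
}

raw_organ_cols <- c("fw_leaf", "fw_stem", "fw_root",
                    "dw_leaf", "dw_stem", "dw_root")

check_phenotype_table <- function(df) {
  need <- c("line", "experiment", "role", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$role %in% c("magic", "parent"))) {
    stop("role must be 'magic' or 'parent'")
  }
  if (!all(df$stage %in% c("baseline", "final"))) {
    stop("stage must be 'baseline' or 'final'")
  }
  invisible(df)
}

#' Derive organ aggregates and water contents
#'
#' Adds the per-plant derived columns to a long-format plant table: organ dry
#' weights under their trait names, aerial DW (leaf + stem), total DW
#' (aerial + root), aerial/root ratio, and water contents. Aggregate water
#' contents are computed from summed fresh and dry weights (mass
#' conservation), not from averaged organ percentages. Re-derivation on an
#' already-derived table is idempotent.
#'
#' @param df data.frame with columns \code{line}, \code{experiment},
#'   \code{role} (magic/parent), \code{stage} (baseline/final) and the raw
#'   organ weights \code{fw_leaf}, \code{fw_stem}, \code{fw_root},
#'   \code{dw_leaf}, \code{dw_stem}, \code{dw_root} (g); optical indices and
#'   proline columns pass through untouched.
#' @return the input with derived trait columns added/replaced. A zero root
#'   dry weight flags the aerial/root ratio as missing.
#' @export
derive_traits <- function(df) {
  check_phenotype_table(df)
  miss <- setdiff(raw_organ_cols, names(df))
  if (length(miss)) stop("missing raw organ weight column(s): ",
                         paste(miss, collapse = ", "))
  with_w <- stats::complete.cases(df[raw_organ_cols])
  bad <- with_w &
    (df$fw_leaf < df$dw_leaf | df$fw_stem < df$dw_stem | df$fw_root < df$dw_root |
       df$dw_leaf < 0 | df$dw_stem < 0 | df$dw_root < 0)
  if (any(bad)) stop("fresh weight below dry weight (or negative dry weight) ",
                     "in row(s): ", paste(utils::head(which(bad)), collapse = ", "))
  nav <- rep(NA_real_, nrow(df))
  df$leaf_dw <- ifelse(with_w, df$dw_leaf, nav)
  df$stem_dw <- ifelse(with_w, df$dw_stem, nav)
  df$root_dw <- ifelse(with_w, df$dw_root, nav)
  df$aerial_dw <- df$leaf_dw + df$stem_dw
  df$total_dw <- df$aerial_dw + df$root_dw
  df$aerial_root_ratio <- ifelse(with_w & df$root_dw > 0,
                                 df$aerial_dw / df$root_dw, nav)
  wc_or_na <- function(fw, dw, ok) {
    out <- nav
    use <- ok & fw > 0
    out[use] <- 100 * (fw[use] - dw[use]) / fw[use]
    out
  }
  df$leaf_wc <- wc_or_na(df$fw_leaf, df$dw_leaf, with_w)
  df$stem_wc <- wc_or_na(df$fw_stem, df$dw_stem, with_w)
  df$root_wc <- wc_or_na(df$fw_root, df$dw_root, with_w)
  df$aerial_wc <- wc_or_na(df$fw_leaf + df$fw_stem,
                           df$dw_leaf + df$dw_stem, with_w)
  df$total_wc <- wc_or_na(df$fw_leaf + df$fw_stem + df$fw_root,
                          df$dw_leaf + df$dw_stem + df$dw_root, with_w)
  df
}

growth_base_traits <- c("total_dw", "aerial_dw", "leaf_dw", "stem_dw",
                        "root_dw", "leaf_number", "stem_length")

#' Growth during the stress period against destructive baselines
#'
#' Adds \code{<trait>_growth} columns to the final-stage records. For a MAGIC
#' line, growth is the final value minus the value of the single baseline
#' plant of the same line in the same experiment; for a parental line, the
#' experiment-specific mean of that parent's baseline plants is subtracted
#' from each final replicate. Final plants lacking a matched baseline get a
#' missing growth value and are listed in the \code{unmatched} attribute.
#'
#' @param df a derived plant table (see \code{\link{derive_traits}}).
#' @param traits traits to difference; default dry weights, leaf number and
#'   stem length where present.
#' @return \code{df} with growth columns added on final records (NA on
#'   baseline records).
#' @export
growth_traits <- function(df, traits = intersect(growth_base_traits, names(df))) {
  check_phenotype_table(df)
  fin <- df$stage == "final"
  base <- df$stage == "baseline"
  key <- paste(df$line, df$experiment, sep = "\r")
  unmatched <- character(0)
  for (tr in traits) {
    g <- rep(NA_real_, nrow(df))
    bvals <- df[[tr]][base]
    bkey <- key[base]
    # per (line, experiment) baseline mean: one plant for MAGIC lines,
    # several replicates for parents
    bmean <- tapply(bvals, bkey, mean, na.rm = TRUE)
    idx <- match(key[fin], names(bmean))
    g[fin] <- df[[tr]][fin] - as.numeric(bmean)[idx]
    unmatched <- union(unmatched, unique(df$line[fin][is.na(idx)]))
    df[[paste0(tr, "_growth")]] <- g
  }
  attr(df, "unmatched") <- unmatched
  df
}

#' Derive the full trait set for a raw plant table
#'
#' Convenience wrapper: organ aggregates and water contents, then growth
#' columns. The result carries one row per plant with all derivable columns
#' of \code{\link{magic_traits}} populated on final-stage records.
#'
#' @param df raw long-format plant table.
#' @return derived plant table.
#' @export
derive_all_traits <- function(df) {
  growth_traits(derive_traits(df))
}
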