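# trapezoidal integral of y over x
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Global translation efficiency from an absorbance trace
#'
#' The global translation efficiency of a lysate is the ratio between the
#' area under the polysomal portion of the A254 sucrose-gradient trace and
#' the area under the non-translating 80S monosome peak, both obtained by
#' trapezoidal integration over labelled boundary intervals.
#'
#' @param trace Data.frame with columns `position` (monotone increasing)
#'   and `a254` (baseline-corrected absorbance).
#' @param boundaries Named list of `c(lo, hi)` position intervals; must
#'   include `"80S"` and `"polysomes"`.
#' @return The polysome/80S area ratio.
#' @export
global_te <- function(trace, boundaries) {
  if (!all(c("80S", "polysomes") %in% names(boundaries)))
    stop("boundaries must include '80S' and 'polysomes'")
  if (is.unsorted(trace$position, strictly = TRUE))
    stop("trace positions must be strictly increasing")
  area <- function(b) {
    sel <- trace$position >= b[1] & trace$position <= b[2]
    if (sum(sel) < 2) stop("boundary interval covers < 2 samples")
    trapz(trace$position[sel], trace$a254[sel])
  }
  a80 <- area(boundaries[["80S"]])
  if (a80 <= 0) stop("zero 80S area")
  area(boundaries[["polysomes"]]) / a80
}

#' Gene-level translation efficiency from qPCR fold changes
#'
#' The TE ratio of a gene is the fold change measured at the polysomal
#' level divided by the fold change at the total RNA level.
#'
#' @param pol_fc,tot_fc Positive fold changes.
#' @return `pol_fc / tot_fc`.
#' @export
gene_te_qpcr <- function(pol_fc, tot_fc) {
  if (any(pol_fc <= 0) || any(tot_fc <= 0))
    stop("fold changes must be positive")
  pol_fc / tot_fc
}

#' Transcriptome-wide delta-TE table
#'
#' Counts are CPM-normalized per library (plain counts-per-million; see the
#' methods vignette for why TMM is not used here). Translation efficiency
#' per gene and condition is polysomal CPM over total CPM; `delta_te` is
#' its log2 change from control to case. Genes below `min_cpm` in any of
#' the four libraries are excluded. Classification: `up` when
#' `delta_te >= class_threshold`, `down` when `<= -class_threshold`,
#' `unchanged` otherwise.
#'
#' @param pol_counts,tot_counts Gene x condition integer matrices with
#'   columns `ctrl` and `case` and identical rownames (gene ids).
#' @param min_cpm CPM floor applied to every library (default 1).
#' @param class_threshold Absolute log2 delta-TE for the up/down classes
#'   (default 1).
#' @return Data.frame with `gene_id`, `pol_cpm_ctrl`, `pol_cpm_case`,
#'   `tot_cpm_ctrl`, `tot_cpm_case`, `te_ctrl`, `te_case`, `delta_te`,
#'   `class`.
#' @export
delta_te_table <- function(pol_counts, tot_counts, min_cpm = 1,
                           class_threshold = 1) {
  if (!identical(rownames(pol_counts), rownames(tot_counts)))
    stop("polysomal and total matrices must share the same genes")
  need <- c("ctrl", "case")
  if (!all(need %in% colnames(pol_counts)) ||
      !all(need %in% colnames(tot_counts)))
    stop("count matrices need 'ctrl' and 'case' columns")
  cpm <- function(x) {
    ls <- colSums(x)
    if (any(ls <= 0)) stop("library size must be positive")
    sweep(x, 2, ls, "/") * 1e6
  }
  pc <- cpm(pol_counts[, need, drop = FALSE])
  tc <- cpm(tot_counts[, need, drop = FALSE])
  keep <- apply(cbind(pc, tc) >= min_cpm, 1, all)
  pc <- pc[keep, , drop = FALSE]; tc <- tc[keep, , drop = FALSE]
  te_ctrl <- pc[, "ctrl"] / tc[, "ctrl"]
  te_case <- pc[, "case"] / tc[, "case"]
  delta <- log2(te_case / te_ctrl)
  cls <- ifelse(delta >= class_threshold, "up",
                ifelse(delta <= -class_threshold, "down", "unchanged"))
  data.frame(gene_id = rownames(pc),
             pol_cpm_ctrl = pc[, "ctrl"], pol_cpm_case = pc[, "case"],
             tot_cpm_ctrl = tc[, "ctrl"], tot_cpm_case = tc[, "case"],
             te_ctrl = te_ctrl, te_case = te_case,
             delta_te = delta, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Target-set over-representation in a gene class
#'
#' Fold enrichment of a target set among a gene class, with a one-sided
#' hypergeometric p-value for over-representation
#' (`P(X >= overlap)` drawing `|class|` genes from the universe).
#'
#' @param target_set,class_set Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector of all tested genes.
#' @return List with `overlap`, `fold_enrichment` and `p_value`.
#' @export
target_enrichment <- function(target_set, class_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  class_set <- unique(intersect(class_set, universe))
  target_set <- unique(intersect(target_set, universe))
  if (length(class_set) == 0) stop("empty class set")
  ov <- length(intersect(target_set, class_set))
  fold <- (ov / length(class_set)) / (length(target_set) / length(universe))
  p <- stats::phyper(ov - 1, length(target_set),
                     length(universe) - length(target_set),
                     length(class_set), lower.tail = FALSE)
  list(overlap = ov, fold_enrichment = fold, p_value = p)
}

#' Molecule counts from a western-blot calibration curve
#'
#' A least-squares line is fitted through (amount in ng, optical density)
#' standards; the sample optical density is inverted through the line to an
#' amount, converted to molecules via the molecular mass, and divided by
#' the number of cells.
#'
#' @param standards Data.frame with columns `ng` and `od` (>= 2 rows).
#' @param sample_od Optical density of the lysate band.
#' @param mw_kda Molecular mass of the species in kDa.
#' @param cells Number of cells in the lysate.
#' @return List with `slope`, `intercept`, `sample_ng` and
#'   `molecules_per_cell`.
#' @export
stoichiometry <- function(standards, sample_od, mw_kda, cells) {
  if (nrow(standards) < 2) stop("need at least 2 standards")
  if (cells <= 0) stop("cells must be positive")
  fit <- stats::lm(od ~ ng, data = standards)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive")
  ng <- (sample_od - intercept) / slope
  grams <- ng * 1e-9
  molecules <- grams / (mw_kda * 1000 * 1.66053906660e-24)
  list(slope = slope, intercept = intercept, sample_ng = ng,
       molecules_per_cell = molecules / cells)
}

#' Stoichiometric ratio of two species
#'
#' Per-cell molecule count of species A over species B, rounded to two
#' decimals for reporting.
#'
#' @param molecules_a,molecules_b Per-cell molecule counts.
#' @return The ratio rounded to 2 decimals.
#' @export
molecule_ratio <- function(molecules_a, molecules_b) {
  if (molecules_b <= 0) stop("denominator must be positive")
  round(molecules_a / molecules_b, 2)
}
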