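#' Merge cross-linked replicate pileups
#'
#' Stacks the per-replicate coverage and deletion tracks into per-contig
#' matrices (replicates x positions) and computes element-wise totals.
#' Per-replicate vectors are preserved because the downstream
#' high-confidence filters impose per-replicate minima.
#'
#' @param pileups A `pileup_set` from [build_pileup()] containing the
#'   cross-linked samples.
#' @param samples Character vector naming the cross-linked replicate samples
#'   in replicate order; at least two.
#' @return An object of class `merged_pileup`: per contig, integer matrices
#'   `cov` and `del` with one row per replicate, plus `samples` and
#'   `contig_lengths`.
#' @export
merge_replicates <- function(pileups, samples) {
  if (length(samples) < 2) stop("need at least 2 cross-linked replicates")
  miss <- setdiff(samples, names(pileups$tracks))
  if (length(miss) > 0) stop("sample(s) missing from pileup: ",
                             paste(miss, collapse = ", "))
  contigs <- names(pileups$contig_lengths)
  out <- list(contigs = list(), samples = samples,
              contig_lengths = pileups$contig_lengths)
  for (ctg in contigs) {
    len <- pileups$contig_lengths[[ctg]]
    cov <- matrix(0L, nrow = length(samples), ncol = len)
    del <- matrix(0L, nrow = length(samples), ncol = len)
    for (i in seq_along(samples)) {
      tr <- pileups$tracks[[samples[i]]][[ctg]]
      if (length(tr$coverage) != len) stop("mismatched contig lengths for ", ctg)
      cov[i, ] <- tr$coverage
      del[i, ] <- tr$deletions
    }
    out$contigs[[ctg]] <- list(cov = cov, del = del)
  }
  class(out) <- "merged_pileup"
  out
}

#' Enumerate candidate deletion sites
#'
#' A candidate is any position with at least `min_del` deletions summed
#' over the cross-linked replicates. Deletions are the localizing signal:
#' reverse transcription stalls at the cross-linked nucleotide and skips
#' it, leaving a micro-deletion in the read.
#'
#' @param merged A `merged_pileup` from [merge_replicates()].
#' @param min_del Minimum summed deletion count (default 1).
#' @param strand Strand label recorded for the candidates (the annotated
#'   transcript strand; default `+`).
#' @return A data.frame with columns `contig`, `pos` (0-based), `strand`,
#'   one `del.<i>`/`cov.<i>` pair per replicate, `del_total`, `cov_total`.
#' @export
candidate_sites <- function(merged, min_del = 1L, strand = "+") {
  nrep <- length(merged$samples)
  rows <- list()
  for (ctg in names(merged$contigs)) {
    m <- merged$contigs[[ctg]]
    dtot <- colSums(m$del)
    idx <- which(dtot >= min_del)
    if (length(idx) == 0) next
    df <- data.frame(contig = ctg, pos = idx - 1L, strand = strand,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrep)) {
      df[[paste0("del.", i)]] <- m$del[i, idx]
      df[[paste0("cov.", i)]] <- m$cov[i, idx] + m$del[i, idx]
    }
    df$del_total <- dtot[idx]
    df$cov_total <- colSums(m$cov[, idx, drop = FALSE]) + dtot[idx]
    rows[[length(rows) + 1]] <- df
  }
  if (length(rows) == 0) {
    df <- data.frame(contig = character(), pos = integer(),
                     strand = character(), stringsAsFactors = FALSE)
    for (i in seq_len(nrep)) {
      df[[paste0("del.", i)]] <- integer()
      df[[paste0("cov.", i)]] <- integer()
    }
    df$del_total <- integer(); df$cov_total <- integer()
    return(df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Penalize candidates by control signal
#'
#' Positions with deletions in the control (non-cross-linked) library are
#' penalized two ways: the summed deletion count is reduced by the
#' library-size-scaled control deletion count (floored at zero), and
#' candidates whose raw control deletions reach the case deletions are
#' removed outright. Candidates whose adjusted deletion total drops below
#' one are also removed.
#'
#' @param candidates Candidate table from [candidate_sites()].
#' @param ctrl_pileup A `pileup_set` holding the control sample.
#' @param ctrl_sample Name of the control sample within `ctrl_pileup`.
#' @param scale Case/control library-size ratio (total mapped case reads
#'   divided by total mapped control reads); must be positive.
#' @param subtract,remove_dominated Switches for the two penalization
#'   effects (both on by default).
#' @return The filtered candidate table with added columns `ctrl_del`,
#'   `ctrl_cov` (scaled control counts) and `del_total` adjusted.
#' @export
subtract_control <- function(candidates, ctrl_pileup, ctrl_sample, scale,
                             subtract = TRUE, remove_dominated = TRUE) {
  if (scale <= 0) stop("scale must be positive")
  if (nrow(candidates) == 0) {
    candidates$ctrl_del <- numeric(0)
    candidates$ctrl_cov <- numeric(0)
    return(candidates)
  }
  tr <- ctrl_pileup$tracks[[ctrl_sample]]
  if (is.null(tr)) stop("control sample not in pileup: ", ctrl_sample)
  raw_del <- numeric(nrow(candidates))
  raw_cov <- numeric(nrow(candidates))
  for (ctg in unique(candidates$contig)) {
    i <- which(candidates$contig == ctg)
    t <- tr[[ctg]]
    if (is.null(t)) next
    p <- candidates$pos[i] + 1L
    raw_del[i] <- t$deletions[p]
    raw_cov[i] <- t$coverage[p] + t$deletions[p]
  }
  candidates$ctrl_del <- scale * raw_del
  candidates$ctrl_cov <- scale * raw_cov
  if (subtract)
    candidates$del_total <- pmax(candidates$del_total - candidates$ctrl_del, 0)
  keep <- candidates$del_total >= 1
  if (remove_dominated)
    keep <- keep & (raw_del < candidates$del_total + if (subtract)
      candidates$ctrl_del else 0)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical right-tail p-value
#'
#' `p = #\{v in values : v >= observed\} / N`. The observed value is drawn
#' from the same universe and therefore counts itself, so the minimum
#' attainable p-value is `1/N` and log transforms are always valid.
#'
#' @param values Non-negative integers: the genome-wide experimental
#'   distribution (e.g. deletion counts at all coverage-positive positions).
#' @param observed Integer vector of observed values to score.
#' @return p-values in `(0, 1]`, one per observation.
#' @export
empirical_pvalue <- function(values, observed) {
  if (length(values) == 0) stop("empty value distribution")
  sv <- sort(values)
  n <- length(sv)
  # number >= x via binary search on the sorted vector; the tiny epsilon
  # makes the count inclusive also for non-integer observations (which
  # arise after scaled control subtraction)
  lt <- findInterval(observed - 1e-9, sv)
  (n - lt) / n
}

#' Combine two p-values with Fisher's method
#'
#' `X = -2 (ln p1 + ln p2)` is chi-square distributed with 4 degrees of
#' freedom under the null; the combined p-value is its survival function,
#' which for two p-values has the closed form `exp(-X/2) (1 + X/2)`.
#'
#' @param p1,p2 p-values in `(0, 1]` (vectorized).
#' @return Combined p-values in `(0, 1]`.
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0) || any(p2 <= 0)) stop("p-values must be > 0")
  if (any(p1 > 1) || any(p2 > 1)) stop("p-values must be <= 1")
  x <- -2 * (log(p1) + log(p2))
  stats::pchisq(x, df = 4, lower.tail = FALSE)
}

#' Attach empirical and combined p-values to candidates
#'
#' The empirical null universes are the coverage-positive positions of the
#' merged case pileup (coverage counted as spanning reads, i.e. M plus D):
#' one distribution of summed coverage and one of summed deletions. Each
#' candidate's `cov_total` and `del_total` are converted to right-tail
#' empirical p-values and combined with Fisher's method.
#'
#' @param candidates Candidate table ([candidate_sites()], optionally after
#'   [subtract_control()]).
#' @param merged The `merged_pileup` the candidates came from.
#' @return The candidate table with columns `p_cov`, `p_del`, `p_comb`.
#' @export
site_pvalues <- function(candidates, merged) {
  cov_univ <- integer(0)
  del_univ <- integer(0)
  for (ctg in names(merged$contigs)) {
    m <- merged$contigs[[ctg]]
    tot_cov <- colSums(m$cov) + colSums(m$del)
    pos <- which(tot_cov > 0)
    cov_univ <- c(cov_univ, tot_cov[pos])
    del_univ <- c(del_univ, colSums(m$del)[pos])
  }
  if (length(cov_univ) == 0) stop("no coverage-positive positions")
  candidates$p_cov <- empirical_pvalue(cov_univ, candidates$cov_total)
  # del_total may be non-integer after scaled control subtraction; the
  # right-tail count is still well defined
  candidates$p_del <- empirical_pvalue(del_univ, candidates$del_total)
  candidates$p_comb <- fisher_combine(candidates$p_cov, candidates$p_del)
  candidates
}

#' Select seed sites for PWM construction
#'
#' Unique genomic locations with a Fisher-combined p-value strictly below
#' `alpha` seed the positional weight matrix. Uniqueness key is
#' (contig, pos, strand).
#'
#' @param candidates Candidate table with `p_comb`.
#' @param alpha Significance threshold, strict inequality (default 0.05).
#' @return The seed subset of the candidate table.
#' @export
select_seed_sites <- function(candidates, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  sel <- candidates[candidates$p_comb < alpha, , drop = FALSE]
  key <- paste(sel$contig, sel$pos, sel$strand)
  sel <- sel[!duplicated(key), , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no seed sites at alpha = ", alpha,
         "; review depth, control scaling or alpha (seed PWM cannot be built)")
  rownames(sel) <- NULL
  sel
}
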