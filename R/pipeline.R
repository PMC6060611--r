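#' Run the full deletion-and-PWM binding-site pipeline
#'
#' Orchestrates both stages end to end: load and deduplicate alignments,
#' build per-sample pileups, merge cross-linked replicates, enumerate
#' candidate deletion sites, penalize control signal, compute empirical
#' coverage/deletion p-values and Fisher-combine them, build the seed PWM
#' from significant sites, derive the exhaustive-heptamer score threshold,
#' score every candidate and apply the high-confidence filters. When an
#' annotation and expression table are supplied, sites are additionally
#' annotated and affinity-weighted.
#'
#' @param sam_paths Character vector of SAM/BAM files (replicates and
#'   control together or split across files).
#' @param sample_sheet Data.frame (`sample`, `replicate`, `is_control`) as
#'   from [read_sample_sheet()].
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param models Optional segment table ([read_transcript_models()]).
#' @param expression Optional named FPKM vector or data.frame
#'   (`transcript_id`, `fpkm`).
#' @param alpha Seed-site significance threshold (default 0.05).
#' @param percentile Null-score percentile for the PWM threshold
#'   (default 95).
#' @param pseudocount,background PWM construction parameters.
#' @param collapse Collapse PCR duplicates by position+barcode
#'   (default TRUE).
#' @return List with `sites` (scored, filtered candidate table), `pwm`
#'   (seed PWM with threshold set), `seed_sites`, `pileups`, `merged`,
#'   `scale` (case/control library ratio) and `n_candidates`.
#' @export
run_mapas <- function(sam_paths, sample_sheet, genome, models = NULL,
                      expression = NULL, alpha = 0.05, percentile = 95,
                      pseudocount = 1, background = rep(0.25, 4),
                      collapse = TRUE) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  contig_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

  records <- do.call(rbind, lapply(sam_paths, load_alignments,
                                   sample_sheet = sample_sheet))
  if (collapse) records <- collapse_duplicates(records)

  case_samples <- sample_sheet$sample[!sample_sheet$is_control]
  case_samples <- case_samples[order(
    sample_sheet$replicate[!sample_sheet$is_control])]
  ctrl_samples <- sample_sheet$sample[sample_sheet$is_control]
  if (length(ctrl_samples) < 1) stop("need a control sample")

  pileups <- build_pileup(records, contig_lengths)
  merged <- merge_replicates(pileups, case_samples)

  n_case <- sum(records$sample %in% case_samples)
  n_ctrl <- sum(records$sample %in% ctrl_samples)
  scale <- n_case / max(n_ctrl, 1)

  cands <- candidate_sites(merged)
  cands <- subtract_control(cands, pileups, ctrl_samples[1], scale)
  cands <- site_pvalues(cands, merged)

  seeds <- select_seed_sites(cands, alpha)
  seed_win <- extract_windows(seeds, genome)
  seed_win <- seed_win[!grepl("N", seed_win, fixed = TRUE)]
  pwm <- build_seed_pwm(seed_win, pseudocount = pseudocount,
                        background = background)
  pwm <- set_null_threshold(pwm, percentile)

  win <- extract_windows(cands, genome)
  kept <- attr(win, "kept")
  cands <- cands[kept, , drop = FALSE]
  ok <- !grepl("N", win, fixed = TRUE)
  cands <- cands[ok, , drop = FALSE]
  cands$window_seq <- win[ok]
  cands$score <- score_windows(pwm, cands$window_seq)
  cands <- high_confidence_filter(cands, pwm$threshold)

  if (!is.null(models)) {
    cands <- annotate_sites(cands, models, expression)
    if (!is.null(expression)) cands <- affinity_weights(cands, expression)
  }
  rownames(cands) <- NULL
  list(sites = cands, pwm = pwm, seed_sites = seeds, pileups = pileups,
       merged = merged, scale = scale, n_candidates = nrow(cands))
}

#' High-confidence calls
#'
#' @param result A [run_mapas()] result.
#' @return The subset of `result$sites` passing all filters.
#' @export
high_confidence_sites <- function(result) {
  result$sites[result$sites$passes_filters, , drop = FALSE]
}

#' Compare calls against planted truth
#'
#' Recovery is the fraction of truth positions present among the calls;
#' the false-discovery proportion (FDP) is the fraction of calls not in
#' the truth set. Positions match on (contig, pos, strand).
#'
#' @param calls Site table (e.g. [high_confidence_sites()] output).
#' @param truth Truth table with `contig`, `pos`, `strand`.
#' @return List with `recovery`, `fdp`, `n_calls`, `n_truth`,
#'   `n_recovered`.
#' @export
evaluate_calls <- function(calls, truth) {
  key <- function(d) paste(d$contig, d$pos, d$strand)
  ck <- key(calls); tk <- key(truth)
  n_rec <- length(intersect(ck, tk))
  list(recovery = if (length(tk)) n_rec / length(unique(tk)) else NA_real_,
       fdp = if (length(ck)) 1 - length(intersect(unique(ck), tk)) /
         length(unique(ck)) else NA_real_,
       n_calls = length(unique(ck)), n_truth = length(unique(tk)),
       n_recovered = n_rec)
}
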