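RNA_ALPHABET <- c("A", "C", "G", "U")

#' Extract 7-nt sequence windows around deletion sites
#'
#' The window spans three nucleotides on each side of the cross-link
#' position (crystallography of tandem RRM domains bound to AU-rich
#' elements motivates the 7-nt footprint). Minus-strand windows are
#' reverse-complemented; DNA `T` is transliterated to `U`. Sites whose
#' window would run off the contig are dropped with a count recorded in
#' the `dropped` attribute.
#'
#' @param sites Data.frame with columns `contig`, `pos` (0-based), `strand`.
#' @param genome A [Biostrings::DNAStringSet], or the path of a FASTA file.
#' @param flank Nucleotides on each side of the site (default 3).
#' @return Character vector of RNA windows (length `2*flank + 1`), one per
#'   retained site, with attributes `kept` (row indices into `sites`) and
#'   `dropped` (number of out-of-bounds sites).
#' @export
extract_windows <- function(sites, genome, flank = 3L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(unique(sites$contig), names(genome))
  if (length(miss) > 0)
    stop("contig(s) missing from genome: ", paste(miss, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  lo <- sites$pos - flank
  hi <- sites$pos + flank
  ok <- unname(lo >= 0 & hi < lens[sites$contig])
  kept <- which(ok)
  if (length(kept) == 0) {
    out <- character(0)
    attr(out, "kept") <- integer(0)
    attr(out, "dropped") <- nrow(sites)
    return(out)
  }
  s <- sites[kept, , drop = FALSE]
  seqs <- as.character(Biostrings::subseq(
    genome[s$contig], start = s$pos - flank + 1L, width = 2L * flank + 1L))
  minus <- s$strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  seqs <- chartr("Tt", "Uu", toupper(seqs))
  attr(seqs, "kept") <- kept
  attr(seqs, "dropped") <- sum(!ok)
  names(seqs) <- NULL
  seqs
}

#' Build the seed positional weight matrix
#'
#' Column frequencies are `(count + pseudocount) / (n + 4 * pseudocount)`;
#' log-odds are `log2(freq / background)`. Windows containing `N` must be
#' excluded beforehand.
#'
#' @param windows Character vector of equal-length RNA windows over
#'   `A,C,G,U`.
#' @param pseudocount Added per letter per column (default 1).
#' @param background Background letter probabilities, alphabet order
#'   A,C,G,U (default uniform).
#' @return An object of class `seed_pwm`: list with `freq` and `logodds`
#'   (4 x width matrices, rows A,C,G,U), `background`, `pseudocount`,
#'   `n_seed`, and `threshold` (`NA` until [null_threshold()] is applied).
#' @export
build_seed_pwm <- function(windows, pseudocount = 1, background = rep(0.25, 4)) {
  if (length(windows) == 0) stop("no windows to build a PWM from")
  if (any(grepl("N", windows, fixed = TRUE)))
    stop("windows containing N must be excluded")
  w <- unique(nchar(windows))
  if (length(w) != 1) stop("windows must share one length")
  mat <- do.call(rbind, strsplit(windows, ""))
  bad <- setdiff(unique(as.vector(mat)), RNA_ALPHABET)
  if (length(bad) > 0) stop("invalid letters in windows: ",
                            paste(bad, collapse = ", "))
  counts <- apply(mat, 2, function(col)
    table(factor(col, levels = RNA_ALPHABET)))
  freq <- (counts + pseudocount) / (length(windows) + 4 * pseudocount)
  background <- background / sum(background)
  lo <- log2(sweep(freq, 1, background, "/"))
  dimnames(freq) <- dimnames(lo) <- list(RNA_ALPHABET, NULL)
  structure(list(freq = freq, logodds = lo, background = background,
                 pseudocount = pseudocount, n_seed = length(windows),
                 threshold = NA_real_),
            class = "seed_pwm")
}

#' @export
print.seed_pwm <- function(x, ...) {
  cat("seed PWM:", ncol(x$freq), "nt,", x$n_seed, "seed sequences\n")
  cat("consensus:", paste(RNA_ALPHABET[apply(x$freq, 2, which.max)],
                          collapse = ""), "\n")
  if (!is.na(x$threshold))
    cat(sprintf("score threshold (null percentile): %.4f\n", x$threshold))
  invisible(x)
}

#' Score sequence windows against a seed PWM
#'
#' The score of a window is the sum over columns of
#' `log2(freq[letter, j] / background[letter])`. A uniform PWM scores every
#' sequence exactly 0.
#'
#' @param pwm A `seed_pwm`.
#' @param seqs Character vector of windows, same width as the PWM, letters
#'   in `A,C,G,U` (no `N`).
#' @return Numeric score vector.
#' @export
score_windows <- function(pwm, seqs) {
  if (length(seqs) == 0) return(numeric(0))
  w <- ncol(pwm$logodds)
  if (any(nchar(seqs) != w)) stop("windows must be ", w, " nt")
  mat <- do.call(rbind, strsplit(seqs, ""))
  idx <- match(mat, RNA_ALPHABET)
  if (anyNA(idx)) stop("invalid letters in windows (N not scoreable)")
  dim(idx) <- dim(mat)
  sc <- numeric(length(seqs))
  for (j in seq_len(w)) sc <- sc + pwm$logodds[cbind(idx[, j], j)]
  sc
}

#' @rdname score_windows
#' @param seq A single window.
#' @export
score_window <- function(pwm, seq) score_windows(pwm, seq)

# all 4^w k-mer index matrix (rows = kmers, cols = positions), plus the
# background probability of each k-mer
all_kmer_index <- function(w) {
  as.matrix(expand.grid(rep(list(1:4), w), KEEP.OUT.ATTRS = FALSE))
}

#' Exhaustive random-heptamer score threshold
#'
#' Scores all `4^w` possible windows (16,384 heptamers for `w = 7`), each
#' weighted by its background probability, and returns the requested
#' percentile of that null distribution (lower nearest-rank convention on
#' the weighted, sorted score multiset). The enumeration is exhaustive, so
#' the threshold is deterministic: no sampling, no RNG.
#'
#' @param pwm A `seed_pwm`.
#' @param percentile Percentile of the null score distribution (default 95).
#' @return The threshold tau. `set_null_threshold()` returns the PWM with
#'   its `threshold` field set.
#' @export
null_threshold <- function(pwm, percentile = 95) {
  w <- ncol(pwm$logodds)
  idx <- all_kmer_index(w)
  sc <- numeric(nrow(idx))
  lp <- numeric(nrow(idx))
  logbg <- log(pwm$background)
  for (j in seq_len(w)) {
    sc <- sc + pwm$logodds[cbind(idx[, j], j)]
    lp <- lp + logbg[idx[, j]]
  }
  o <- order(sc)
  cw <- cumsum(exp(lp[o]))
  cw <- cw / cw[length(cw)]
  # lower nearest-rank: smallest score whose cumulative weight reaches p
  sc[o][which(cw >= percentile / 100)[1]]
}

#' @rdname null_threshold
#' @export
set_null_threshold <- function(pwm, percentile = 95) {
  pwm$threshold <- null_threshold(pwm, percentile)
  pwm
}

#' High-confidence binding-site filter
#'
#' A scored candidate passes when all of: PWM score strictly above the
#' null threshold; summed deletions at least `min_del_total` with at least
#' `min_del_rep` in every replicate; summed spanning-read coverage at least
#' `min_cov_total` with at least `min_cov_rep` in every replicate.
#'
#' @param sites Candidate table with a `score` column and per-replicate
#'   `del.<i>` / `cov.<i>` columns.
#' @param tau Score threshold from [null_threshold()].
#' @param min_del_total,min_del_rep,min_cov_total,min_cov_rep Evidence
#'   minima (defaults 3, 1, 6, 2).
#' @return The table with a logical `passes_filters` column.
#' @export
high_confidence_filter <- function(sites, tau, min_del_total = 3,
                                   min_del_rep = 1, min_cov_total = 6,
                                   min_cov_rep = 2) {
  del_cols <- grep("^del\\.", names(sites), value = TRUE)
  cov_cols <- grep("^cov\\.", names(sites), value = TRUE)
  if (length(del_cols) == 0 || length(cov_cols) == 0)
    stop("per-replicate del./cov. columns required")
  del_m <- as.matrix(sites[del_cols])
  cov_m <- as.matrix(sites[cov_cols])
  pass <- sites$score > tau &
    sites$del_total >= min_del_total &
    apply(del_m >= min_del_rep, 1, all) &
    sites$cov_total >= min_cov_total &
    apply(cov_m >= min_cov_rep, 1, all)
  sites$passes_filters <- as.logical(pass)
  sites
}

#' Expression-normalized binding affinity
#'
#' Site intensity (control-adjusted deletion total) divided by the
#' expression of the host transcript, so that strongly expressed
#' transcripts do not dominate the motif logo. Transcripts below the FPKM
#' floor are floored; sites on transcripts absent from the expression table
#' get `NA` affinity and are excluded from the weighted logo (the count of
#' exclusions is recorded in the `excluded` attribute).
#'
#' @param sites Site table with `transcript_id` and `del_total` columns
#'   (intensity = `del_total`).
#' @param expression Named numeric vector of FPKM per transcript, or a
#'   data.frame with columns `transcript_id`, `fpkm`.
#' @param floor Minimum FPKM used in the denominator (default 0.1).
#' @return The table with `fpkm` and `affinity` columns.
#' @export
affinity_weights <- function(sites, expression, floor = 0.1) {
  if (floor <= 0) stop("floor must be positive")
  if (is.data.frame(expression))
    expression <- stats::setNames(expression$fpkm, expression$transcript_id)
  fpkm <- expression[sites$transcript_id]
  sites$fpkm <- as.numeric(fpkm)
  sites$affinity <- sites$del_total / pmax(sites$fpkm, floor)
  out <- sites
  attr(out, "excluded") <- sum(is.na(out$affinity))
  out
}

#' Affinity-weighted sequence logo matrix
#'
#' Each site contributes its window letters weighted by its binding
#' affinity. Weights are normalized by the total affinity and then rescaled
#' so the largest entry of the matrix equals 1 (the convention in which the
#' dominant letters carry weight 1).
#'
#' @param sites Site table with `window_seq` and `affinity` columns; rows
#'   with `NA` affinity are dropped.
#' @return A 4 x width matrix (rows A,C,G,U), maximum entry 1.
#' @export
weighted_logo <- function(sites) {
  sites <- sites[!is.na(sites$affinity), , drop = FALSE]
  if (nrow(sites) == 0) stop("no sites with defined affinity")
  w <- unique(nchar(sites$window_seq))
  if (length(w) != 1) stop("windows must share one length")
  mat <- do.call(rbind, strsplit(sites$window_seq, ""))
  W <- matrix(0, nrow = 4, ncol = w, dimnames = list(RNA_ALPHABET, NULL))
  for (j in seq_len(w)) {
    s <- tapply(sites$affinity, factor(mat[, j], levels = RNA_ALPHABET), sum)
    s[is.na(s)] <- 0
    W[, j] <- s
  }
  W <- W / sum(sites$affinity)
  W / max(W)
}

#' Write a PWM or logo matrix as TSV
#'
#' @param mat A 4 x width matrix with rows A,C,G,U (e.g. `pwm$freq` or a
#'   [weighted_logo()] result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_tsv <- function(mat, path) {
  df <- data.frame(letter = rownames(mat), mat, check.names = FALSE)
  names(df)[-1] <- paste0("pos", seq_len(ncol(mat)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write binding sites as BED6+
#'
#' Standard BED columns (0-based half-open single-nucleotide intervals,
#' score = PWM score x 100 rounded) followed by `del_total`, `cov_total`,
#' `p_comb`, `affinity`, `passes_filters`.
#'
#' @param sites Annotated site table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  name <- if ("transcript_id" %in% names(sites)) sites$transcript_id else "."
  name[is.na(name)] <- "."
  df <- data.frame(
    chrom = sites$contig, start = sites$pos, end = sites$pos + 1L,
    name = name, score = round(sites$score * 100), strand = sites$strand,
    del_total = sites$del_total, cov_total = sites$cov_total,
    p_comb = signif(sites$p_comb, 6),
    affinity = if ("affinity" %in% names(sites)) sites$affinity else NA,
    passes_filters = sites$passes_filters)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
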