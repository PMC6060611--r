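#' Read a sample sheet
#'
#' A sample sheet is a tab-separated file with columns `sample`, `replicate`
#' and `is_control` mapping each library (SAM read group) to its role in the
#' experiment. Cross-linked replicates carry `is_control = FALSE` and
#' `replicate >= 1`; control libraries carry `is_control = TRUE`.
#'
#' @param path Path to a TSV file with columns `sample`, `replicate`,
#'   `is_control`.
#' @return A data.frame with columns `sample` (character), `replicate`
#'   (integer) and `is_control` (logical).
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "replicate", "is_control")
  if (!all(need %in% names(ss)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  ss$replicate <- as.integer(ss$replicate)
  ss$is_control <- as.logical(ss$is_control)
  if (anyDuplicated(ss$sample)) stop("duplicated sample names in sample sheet")
  ss
}

#' Load primary alignments from a SAM/BAM file
#'
#' Reads primary alignments and returns one record per aligned read, with
#' 0-based leftmost coordinates and the CIGAR string retained for pileup
#' construction. Secondary, supplementary and unmapped records are skipped
#' and counted. The sample label is taken from the read group (`RG` tag);
#' the optional random barcode from the `BC` tag (empty when absent).
#'
#' @param path SAM or BAM file. Plain-text SAM is converted on the fly.
#' @param sample_sheet Data.frame as returned by [read_sample_sheet()]. Every
#'   read group present in the file must appear in the sheet.
#' @param sample Fallback sample label for files without `RG` tags.
#' @return A data.frame of alignment records with columns `read_id`,
#'   `barcode`, `contig`, `start` (0-based), `strand`, `cigar`, `sample`,
#'   `replicate`, `is_control`, and attribute `skipped` holding the number
#'   of non-primary/unmapped records dropped.
#' @export
load_alignments <- function(path, sample_sheet, sample = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    bam <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = NA,
                                 isSupplementaryAlignment = NA,
                                 isUnmappedQuery = NA)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar"),
    tag = c("RG", "BC"), flag = flag)
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_all <- length(res$qname)
  fl <- res$flag
  drop <- is.na(res$pos) | bitwAnd(fl, 4L) > 0L |   # unmapped
    bitwAnd(fl, 256L) > 0L | bitwAnd(fl, 2048L) > 0L # secondary/supplementary
  keep <- !drop
  rg <- res$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, n_all)
  bc <- res$tag$BC
  if (is.null(bc)) bc <- rep("", n_all)
  bc[is.na(bc)] <- ""
  smp <- rg
  if (anyNA(smp)) {
    if (is.null(sample) && all(is.na(smp)))
      stop("file has no RG tags; supply `sample`")
    smp[is.na(smp)] <- if (is.null(sample)) NA_character_ else sample
  }
  rec <- data.frame(
    read_id = res$qname[keep],
    barcode = bc[keep],
    contig = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L,           # SAM is 1-based
    strand = as.character(res$strand[keep]),
    cigar = res$cigar[keep],
    sample = smp[keep],
    stringsAsFactors = FALSE)
  bad_op <- grepl("[^0-9MIDSN]", rec$cigar)
  if (any(bad_op)) {
    op <- regmatches(rec$cigar[bad_op][1],
                     regexpr("[^0-9MIDSN]", rec$cigar[bad_op][1]))
    stop("unsupported CIGAR op '", op, "' in read ", rec$read_id[bad_op][1])
  }
  miss <- setdiff(unique(rec$sample), sample_sheet$sample)
  if (length(miss) > 0)
    stop("read group(s) absent from sample sheet: ", paste(miss, collapse = ", "))
  i <- match(rec$sample, sample_sheet$sample)
  rec$replicate <- sample_sheet$replicate[i]
  rec$is_control <- sample_sheet$is_control[i]
  attr(rec, "skipped") <- sum(drop)
  rec
}

#' Collapse PCR duplicates by position and random barcode
#'
#' Alignments sharing (contig, start, strand, barcode, sample) are treated
#' as PCR duplicates of one molecule; a single record is kept per key, the
#' one with the lexicographically smallest read id, so the operation is
#' deterministic and idempotent.
#'
#' @param records Alignment records from [load_alignments()].
#' @return The deduplicated records, same columns.
#' @export
collapse_duplicates <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$contig, records$start, records$strand,
               records$barcode, records$sample, sep = "\r")
  o <- order(key, records$read_id, method = "radix")
  records <- records[o, , drop = FALSE]
  keep <- !duplicated(key[o])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Reference span of a CIGAR string: sum of M, D, N lengths.
cigar_ref_span <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Build per-position coverage, deletion and read-start tracks
#'
#' For each sample and contig three integer tracks are produced: `coverage`
#' counts reads whose alignment places an aligned (M) base at the position;
#' `deletions` counts reads whose alignment places a deletion (D) op across
#' the position (deleted bases are *not* counted in coverage); `read_starts`
#' counts alignments whose 5'-most reference base is the position (leftmost
#' base on `+`, rightmost on `-`). Insertions and soft clips consume no
#' reference; N skips advance neither coverage nor deletions.
#'
#' Reads antisense to the annotated contig strand are ignored with a count
#' kept in the `antisense_skipped` attribute.
#'
#' @param records Alignment records (one sample or several; tracks are kept
#'   per sample).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param contig_strand Named character vector giving the annotated strand
#'   of each contig (default `+` for all).
#' @return An object of class `pileup_set`: a nested list
#'   `tracks[[sample]][[contig]]` with integer vectors `coverage`,
#'   `deletions`, `read_starts`, plus `contig_lengths`.
#' @export
build_pileup <- function(records, contig_lengths, contig_strand = NULL) {
  if (is.null(names(contig_lengths)) || anyNA(names(contig_lengths)))
    stop("contig_lengths must be a named vector")
  if (is.null(contig_strand))
    contig_strand <- stats::setNames(rep("+", length(contig_lengths)),
                                     names(contig_lengths))
  miss <- setdiff(unique(records$contig), names(contig_lengths))
  if (length(miss) > 0)
    stop("contig(s) absent from contig_lengths: ", paste(miss, collapse = ", "))

  antisense <- records$strand != contig_strand[records$contig]
  n_anti <- sum(antisense)
  records <- records[!antisense, , drop = FALSE]

  span <- if (nrow(records)) cigar_ref_span(records$cigar) else integer(0)
  ends <- records$start + span           # half-open end
  oob <- records$start < 0L | ends > contig_lengths[records$contig]
  if (any(oob))
    stop("alignment out of contig bounds: read ", records$read_id[oob][1])

  empty_tracks <- function(len) list(
    coverage = integer(len), deletions = integer(len), read_starts = integer(len))
  out <- list(tracks = list(), contig_lengths = contig_lengths)
  class(out) <- "pileup_set"

  for (smp in unique(records$sample)) {
    rs <- records[records$sample == smp, , drop = FALSE]
    tr <- lapply(contig_lengths, empty_tracks)
    pos1 <- rs$start + 1L                 # 1-based for IRanges
    mr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      rs$cigar, ops = "M", pos = pos1)
    dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      rs$cigar, ops = "D", pos = pos1)
    fac <- factor(rs$contig, levels = names(contig_lengths))
    for (ctg in levels(fac)) {
      idx <- which(fac == ctg)
      if (length(idx) == 0) next
      len <- contig_lengths[[ctg]]
      covr <- IRanges::coverage(unlist(mr[idx]), width = len)
      delr <- IRanges::coverage(unlist(dr[idx]), width = len)
      tr[[ctg]]$coverage <- as.integer(covr)
      tr[[ctg]]$deletions <- as.integer(delr)
      five <- ifelse(rs$strand[idx] == "+", rs$start[idx],
                     rs$start[idx] + span[idx] - 1L)
      tb <- tabulate(five + 1L, nbins = len)
      tr[[ctg]]$read_starts <- as.integer(tb)
    }
    out$tracks[[smp]] <- tr
  }
  attr(out, "antisense_skipped") <- n_anti
  out
}

#' Read or write the pileup TSV dialect
#'
#' A desk-scale plain-text exchange format for pileup tracks: columns
#' `contig`, `pos0`, `sample`, `coverage`, `deletions`, `read_starts`, with
#' all-zero positions omitted.
#'
#' @param pileups A `pileup_set`.
#' @param path Output (or input) TSV path.
#' @return `write_pileup_tsv` returns `path` invisibly; `read_pileup_tsv`
#'   returns a `pileup_set` (contig lengths must be supplied because
#'   trailing zero positions are not stored).
#' @export
write_pileup_tsv <- function(pileups, path) {
  rows <- list()
  for (smp in names(pileups$tracks)) {
    for (ctg in names(pileups$tracks[[smp]])) {
      tr <- pileups$tracks[[smp]][[ctg]]
      nz <- which(tr$coverage > 0 | tr$deletions > 0 | tr$read_starts > 0)
      if (length(nz) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        contig = ctg, pos0 = nz - 1L, sample = smp,
        coverage = tr$coverage[nz], deletions = tr$deletions[nz],
        read_starts = tr$read_starts[nz], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), pos0 = integer(), sample = character(),
               coverage = integer(), deletions = integer(),
               read_starts = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @param contig_lengths Named integer vector of contig lengths.
#' @export
read_pileup_tsv <- function(path, contig_lengths) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list(tracks = list(), contig_lengths = contig_lengths)
  class(out) <- "pileup_set"
  for (smp in unique(df$sample)) {
    tr <- lapply(contig_lengths, function(len) list(
      coverage = integer(len), deletions = integer(len),
      read_starts = integer(len)))
    sub <- df[df$sample == smp, , drop = FALSE]
    for (ctg in unique(sub$contig)) {
      s <- sub[sub$contig == ctg, , drop = FALSE]
      i <- s$pos0 + 1L
      tr[[ctg]]$coverage[i] <- s$coverage
      tr[[ctg]]$deletions[i] <- s$deletions
      tr[[ctg]]$read_starts[i] <- s$read_starts
    }
    out$tracks[[smp]] <- tr
  }
  out
}
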