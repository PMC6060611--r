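# in-code fixtures shared across test files

# minimal SAM writer: records is a data.frame with qname, flag, rname,
# pos1, cigar, seq, and optional rg / bc
write_mini_sam <- function(records, contig_lengths,
                           path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(contig_lengths),
                     "\tLN:", contig_lengths))
  rgs <- unique(records$rg)
  header <- c(header, paste0("@RG\tID:", rgs, "\tSM:", rgs))
  tags <- paste0("RG:Z:", records$rg)
  if (!is.null(records$bc)) tags <- paste(tags, paste0("BC:Z:", records$bc),
                                          sep = "\t")
  lines <- paste(records$qname, records$flag, records$rname, records$pos1,
                 255L, records$cigar, "*", 0L, 0L, records$seq,
                 strrep("I", nchar(records$seq)), tags, sep = "\t")
  writeLines(c(header, lines), path)
  path
}

simple_sheet <- function(samples = "s1", replicate = 1L, is_control = FALSE) {
  data.frame(sample = samples, replicate = replicate,
             is_control = is_control, stringsAsFactors = FALSE)
}

# pileup_set built directly from per-replicate count vectors
make_pileup_set <- function(tracks, contig_lengths) {
  out <- list(tracks = tracks, contig_lengths = contig_lengths)
  class(out) <- "pileup_set"
  out
}

# alignment-record data.frame in the load_alignments() layout
make_records <- function(contig, start, cigar, sample = "s1", strand = "+",
                         barcode = "", replicate = 1L, is_control = FALSE,
                         read_id = NULL) {
  n <- max(length(contig), length(start), length(cigar))
  data.frame(
    read_id = if (is.null(read_id)) sprintf("r%03d", seq_len(n)) else read_id,
    barcode = rep_len(barcode, n), contig = rep_len(contig, n),
    start = rep_len(start, n), strand = rep_len(strand, n),
    cigar = rep_len(cigar, n), sample = rep_len(sample, n),
    replicate = rep_len(replicate, n), is_control = rep_len(is_control, n),
    stringsAsFactors = FALSE)
}

# random column-stochastic 4 x w matrix
random_pwm_matrix <- function(w = 7) {
  m <- matrix(stats::rgamma(4 * w, shape = 1), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(c("A", "C", "G", "U"), NULL)
  m
}

all_heptamers <- function(w = 7) {
  letters4 <- c("A", "C", "G", "U")
  g <- expand.grid(rep(list(letters4), w), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  do.call(paste0, g)
}
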