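#' Build transcript models from a GTF/GFF annotation
#'
#' Parses `exon`, `CDS`, `five_prime_utr`/`three_prime_utr` (or `UTR`)
#' features into a per-segment table. When explicit UTR features are absent
#' for a protein-coding transcript, UTRs are derived by subtracting the CDS
#' span from the exons (5' vs 3' resolved by strand). Exons of non-coding
#' transcripts become `ncRNA_exon` segments.
#'
#' @param gtf Path to a GTF/GFF file, or a `GRanges` as returned by
#'   [rtracklayer::import()].
#' @return A data.frame of segments with columns `transcript_id`,
#'   `gene_id`, `biotype`, `contig`, `strand`, `region`
#'   (`5UTR`/`CDS`/`3UTR`/`ncRNA_exon`), `start` (0-based), `end`
#'   (half-open).
#' @export
read_transcript_models <- function(gtf) {
  gr <- if (is.character(gtf)) rtracklayer::import(gtf) else gtf
  md <- S4Vectors::mcols(gr)
  biotype <- if ("transcript_biotype" %in% names(md)) md$transcript_biotype
             else if ("gene_biotype" %in% names(md)) md$gene_biotype
             else rep("protein_coding", length(gr))
  df <- data.frame(
    type = as.character(md$type),
    transcript_id = md$transcript_id,
    gene_id = if ("gene_id" %in% names(md)) md$gene_id else md$transcript_id,
    biotype = biotype,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$transcript_id), , drop = FALSE]
  region_of <- c(five_prime_utr = "5UTR", CDS = "CDS",
                 three_prime_utr = "3UTR")
  segs <- list()
  for (tx in unique(df$transcript_id)) {
    d <- df[df$transcript_id == tx, , drop = FALSE]
    coding <- d$biotype[1] == "protein_coding"
    if (!coding) {
      e <- d[d$type == "exon", , drop = FALSE]
      if (nrow(e)) e$region <- "ncRNA_exon"
      segs[[tx]] <- e
      next
    }
    named <- d[d$type %in% names(region_of), , drop = FALSE]
    has_utr <- any(d$type %in% c("five_prime_utr", "three_prime_utr"))
    if (has_utr && any(d$type == "CDS")) {
      named$region <- region_of[named$type]
      segs[[tx]] <- named
      next
    }
    # derive UTRs: exon minus CDS span, sided by strand
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(cds) == 0) { ex$region <- "ncRNA_exon"; segs[[tx]] <- ex; next }
    cds_lo <- min(cds$start); cds_hi <- max(cds$end)
    pieces <- list()
    for (i in seq_len(nrow(ex))) {
      s <- ex$start[i]; e <- ex$end[i]
      if (s < cds_lo) {
        p <- ex[i, , drop = FALSE]; p$end <- min(e, cds_lo)
        p$region <- if (ex$strand[i] == "+") "5UTR" else "3UTR"
        pieces[[length(pieces) + 1]] <- p
      }
      if (e > cds_hi) {
        p <- ex[i, , drop = FALSE]; p$start <- max(s, cds_hi)
        p$region <- if (ex$strand[i] == "+") "3UTR" else "5UTR"
        pieces[[length(pieces) + 1]] <- p
      }
    }
    cds$region <- "CDS"
    segs[[tx]] <- do.call(rbind, c(pieces, list(cds)))
  }
  out <- do.call(rbind, segs)
  out$type <- NULL
  rownames(out) <- NULL
  out[out$end > out$start, , drop = FALSE]
}

#' Assign binding sites to transcripts and regions
#'
#' Each site is matched to the transcript segments containing its position
#' (same contig and strand, 0-based half-open containment). A site covered
#' by several transcripts is assigned to the one with the highest
#' expression (ties broken by lexicographic transcript id); sites outside
#' every model are labelled `unassigned`.
#'
#' @param sites Site table with `contig`, `pos`, `strand`.
#' @param models Segment table from [read_transcript_models()].
#' @param expression Named FPKM vector (or data.frame with `transcript_id`,
#'   `fpkm`) used only to resolve multi-transcript overlaps; optional.
#' @return The site table with `transcript_id`, `gene_id`, `biotype` and
#'   `region` columns.
#' @export
annotate_sites <- function(sites, models, expression = NULL) {
  if (is.data.frame(expression))
    expression <- stats::setNames(expression$fpkm, expression$transcript_id)
  site_gr <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$pos + 1L, sites$pos + 1L),
    strand = sites$strand)
  seg_gr <- GenomicRanges::GRanges(
    models$contig, IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand)
  hits <- GenomicRanges::findOverlaps(site_gr, seg_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n <- nrow(sites)
  sites$transcript_id <- NA_character_
  sites$gene_id <- NA_character_
  sites$biotype <- NA_character_
  sites$region <- "unassigned"
  if (length(qh) > 0) {
    fp <- if (is.null(expression)) rep(0, length(sh)) else {
      v <- expression[models$transcript_id[sh]]
      v[is.na(v)] <- 0
      as.numeric(v)
    }
    # per site: highest FPKM, then lexicographic transcript id
    o <- order(qh, -fp, models$transcript_id[sh], method = "radix")
    first <- !duplicated(qh[o])
    qi <- qh[o][first]; si <- sh[o][first]
    sites$transcript_id[qi] <- models$transcript_id[si]
    sites$gene_id[qi] <- models$gene_id[si]
    sites$biotype[qi] <- models$biotype[si]
    sites$region[qi] <- models$region[si]
  }
  sites
}

#' Interaction weights per RNA or RNA species
#'
#' The interaction weight of a group is the percentage of total site
#' intensity (summed deletion counts) carried by that group; weights over
#' any partition sum to 100.
#'
#' @param sites Site table with `del_total` and the grouping columns.
#' @param group_by `"rna"` (per `transcript_id`) or `"species"` (per
#'   `biotype`), or the name of any column of `sites`.
#' @return Data.frame with columns `key`, `intensity`, `weight_pct`,
#'   ordered by decreasing weight.
#' @export
interaction_weights <- function(sites, group_by = c("rna", "species")) {
  group_by <- group_by[1]
  col <- switch(group_by, rna = "transcript_id", species = "biotype", group_by)
  if (!col %in% names(sites)) stop("no such grouping column: ", col)
  total <- sum(sites$del_total)
  if (!is.finite(total) || total <= 0) stop("zero total site intensity")
  s <- tapply(sites$del_total, sites[[col]], sum)
  out <- data.frame(key = names(s), intensity = as.numeric(s),
                    weight_pct = 100 * as.numeric(s) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight_pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# region lengths and 5'->3' offset of a genomic position in region space
region_offset <- function(pos, segs) {
  segs <- segs[order(segs$start), , drop = FALSE]
  minus <- segs$strand[1] == "-"
  if (minus) segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  widths <- segs$end - segs$start
  cum <- cumsum(c(0, widths))[seq_len(nrow(segs))]
  for (i in seq_len(nrow(segs))) {
    if (pos >= segs$start[i] && pos < segs$end[i]) {
      off <- if (minus) segs$end[i] - 1L - pos else pos - segs$start[i]
      return(list(offset = cum[i] + off, len = sum(widths)))
    }
  }
  NULL
}

#' Metaprofile of sites along scaled transcript regions
#'
#' Each protein-coding site is mapped to a bin of its region (5'UTR, CDS or
#' 3'UTR scaled to fixed bin counts); densities are normalized to sum to 1.
#' Transcripts lacking a region simply contribute nothing to it.
#'
#' @param sites Annotated site table (needs `transcript_id` and `region`).
#' @param models Segment table from [read_transcript_models()].
#' @param bins Named integer vector of bins per region
#'   (default `c("5UTR" = 10, CDS = 30, "3UTR" = 10)`).
#' @return Data.frame with `region`, `bin` (0-based within region) and
#'   `density`, ordered 5'UTR, CDS, 3'UTR.
#' @export
metaprofile <- function(sites, models,
                        bins = c("5UTR" = 10L, "CDS" = 30L, "3UTR" = 10L)) {
  use <- sites$region %in% names(bins) & !is.na(sites$transcript_id)
  s <- sites[use, , drop = FALSE]
  if (nrow(s) == 0) stop("no sites in profiled regions")
  counts <- lapply(bins, function(b) numeric(b))
  for (i in seq_len(nrow(s))) {
    segs <- models[models$transcript_id == s$transcript_id[i] &
                     models$region == s$region[i], , drop = FALSE]
    ro <- region_offset(s$pos[i], segs)
    if (is.null(ro)) next
    b <- bins[[s$region[i]]]
    k <- min(floor(ro$offset / ro$len * b), b - 1)
    counts[[s$region[i]]][k + 1] <- counts[[s$region[i]]][k + 1] + 1
  }
  tot <- sum(unlist(counts))
  out <- do.call(rbind, lapply(c("5UTR", "CDS", "3UTR"), function(r) {
    data.frame(region = r, bin = seq_len(bins[[r]]) - 1L,
               density = counts[[r]] / tot, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Polyadenylation-site usage from read starts
#'
#' Counts, for each annotated polyadenylation site, the alignments whose
#' 5'-most base falls within `window` nucleotides of the site (closed on
#' both ends, direction-agnostic). A read start within range of two pA
#' sites is credited to the nearer one; exact ties go to the 5'-most
#' (smaller coordinate) site.
#'
#' @param pileups A `pileup_set` (read starts are taken from its tracks).
#' @param sample Sample whose read starts to use.
#' @param pa_sites Data.frame with columns `contig`, `pos` (0-based) and
#'   optionally `name`.
#' @param window Maximum distance in nt (default 10).
#' @return `pa_sites` with a `count` column.
#' @export
apa_pau <- function(pileups, sample, pa_sites, window = 10L) {
  tr <- pileups$tracks[[sample]]
  if (is.null(tr)) stop("sample not in pileup: ", sample)
  pa_sites$count <- 0L
  for (ctg in unique(pa_sites$contig)) {
    pi <- which(pa_sites$contig == ctg)
    t <- tr[[ctg]]
    if (is.null(t)) next
    starts <- which(t$read_starts > 0) - 1L
    if (length(starts) == 0) next
    n <- t$read_starts[starts + 1L]
    pa <- pa_sites$pos[pi]
    for (k in seq_along(starts)) {
      d <- abs(starts[k] - pa)
      j <- which(d <= window)
      if (length(j) == 0) next
      j <- j[order(d[j], pa[j])][1]
      pa_sites$count[pi[j]] <- pa_sites$count[pi[j]] + n[k]
    }
  }
  pa_sites
}
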