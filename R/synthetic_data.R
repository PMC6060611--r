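#' Default planted binding-motif PWM
#'
#' A 4 x 7 column-stochastic matrix describing the planted cross-link
#' window: a U-triplet core (the deletion falls on its middle base) with a
#' C-biased preceding position and a downstream U bias, mimicking CU-rich
#' elements of the CUUU type bound by ELAV-family proteins.
#'
#' @return 4 x 7 matrix, rows A,C,G,U, columns summing to 1.
#' @export
default_planted_pwm <- function() {
  m <- cbind(c(.25, .25, .25, .25),
             c(.31, .40, .27, .02),
             c(.02, .02, .01, .95),
             c(.02, .02, .01, .95),
             c(.02, .02, .01, .95),
             c(.10, .10, .10, .70),
             c(.20, .20, .15, .45))
  dimnames(m) <- list(c("A", "C", "G", "U"), NULL)
  m
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic world in one validated list. All
#' generators are deterministic functions of this configuration (including
#' its mandatory `seed`).
#'
#' @param seed Mandatory RNG seed (integer).
#' @param n_transcripts Number of protein-coding transcripts (default 60).
#' @param utr5_range,cds_range,utr3_range Length ranges (nt) of the three
#'   regions of each coding transcript.
#' @param ncrna_length Length of the single designated small ncRNA sponge.
#' @param planted_pwm 4 x 7 letter-probability matrix for planted windows.
#' @param n_planted_sites Planted mRNA binding sites (default 500).
#' @param utr3_fraction Fraction of planted mRNA sites placed in 3'UTRs
#'   (default 0.9).
#' @param ncrna_sites Binding sites planted on the sponge ncRNA (default 2).
#' @param crosslink_deletion_rate Probability that a read covering a
#'   planted site carries a deletion at it (default 0.3).
#' @param background_deletion_rate Per covered internal base probability of
#'   a spurious deletion (default 0.001).
#' @param deletion_length Deletion length in nt (default 1; larger values
#'   exercise the 5'-most-base centering convention).
#' @param reads_per_replicate,n_replicates,control_reads Library sizes
#'   (defaults 50000, 2, 50000).
#' @param read_length Read length after trimming (default 40).
#' @param pcr_duplicate_rate Fraction of records that are PCR copies of an
#'   earlier molecule (default 0.1).
#' @param barcode_length Random-barcode length (default 5).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal expression parameters for the
#'   coding transcripts (defaults 1 and 0.4).
#' @param sponge_fraction Target fraction of planted deletion intensity on
#'   the ncRNA sponge (default 0.7); its expression is solved from this.
#' @param min_end_distance Minimum distance of a planted site from the
#'   transcript ends (default `read_length + 10`), so every truth site can
#'   be covered by the full window of read starts and recovery measures the
#'   caller rather than end geometry.
#' @param te_n_genes,te_n_targets Genes and targets in the TE simulation
#'   (defaults 500, 50).
#' @param te_effect Planted log2 delta-TE of the targets (default 1).
#' @param te_depth Expected reads per TE library (default 1e6).
#' @param te_dispersion Negative-binomial dispersion of the TE counts
#'   (default 0.002, technical-replicate scale).
#' @param te_expr_sdlog Log-normal spread of gene expression in the TE
#'   simulation (default 0.4).
#' @param trace_ratio True polysome/80S area ratio of the simulated
#'   absorbance trace (default 2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_transcripts = 60L,
                       utr5_range = c(50L, 150L),
                       cds_range = c(300L, 600L),
                       utr3_range = c(200L, 450L),
                       ncrna_length = 100L,
                       planted_pwm = default_planted_pwm(),
                       n_planted_sites = 500L,
                       utr3_fraction = 0.9,
                       ncrna_sites = 2L,
                       crosslink_deletion_rate = 0.3,
                       background_deletion_rate = 0.001,
                       deletion_length = 1L,
                       reads_per_replicate = 50000L,
                       n_replicates = 2L,
                       control_reads = 50000L,
                       read_length = 40L,
                       pcr_duplicate_rate = 0.1,
                       barcode_length = 5L,
                       fpkm_meanlog = 1,
                       fpkm_sdlog = 0.4,
                       sponge_fraction = 0.7,
                       min_end_distance = read_length + 10L,
                       te_n_genes = 500L,
                       te_n_targets = 50L,
                       te_effect = 1,
                       te_depth = 1e6,
                       te_dispersion = 0.002,
                       te_expr_sdlog = 0.4,
                       trace_ratio = 2) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(crosslink_deletion_rate >= 0, crosslink_deletion_rate <= 1,
            background_deletion_rate >= 0, background_deletion_rate <= 1,
            pcr_duplicate_rate >= 0, pcr_duplicate_rate < 1,
            sponge_fraction >= 0, sponge_fraction < 1,
            utr3_fraction >= 0, utr3_fraction <= 1,
            deletion_length >= 1, trace_ratio >= 0)
  if (!isTRUE(all.equal(colSums(planted_pwm), rep(1, ncol(planted_pwm)),
                        tolerance = 1e-6)))
    stop("planted_pwm columns must sum to 1")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# draw n sequences of given width from a column-probability matrix (DNA)
draw_from_pwm <- function(pwm, n) {
  dna <- c("A", "C", "G", "T")
  w <- ncol(pwm)
  m <- vapply(seq_len(w), function(j)
    sample(dna, n, replace = TRUE, prob = pwm[, j]), character(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  apply(m, 1, paste, collapse = "")
}

#' Generate the synthetic transcriptome
#'
#' Builds a toy transcriptome in which every transcript is its own contig
#' (splicing is out of scope): `n_transcripts` protein-coding transcripts
#' with 5'UTR/CDS/3'UTR structure plus one small non-coding sponge RNA.
#' Windows drawn from the planted PWM are embedded at the truth positions,
#' predominantly in 3'UTRs; the sponge carries its own sites and its
#' expression is solved so that the expected share of planted deletion
#' intensity on it equals `sponge_fraction`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `models`
#'   (segment table as from [read_transcript_models()]), `truth`
#'   (data.frame `contig`, `pos`, `strand`, `transcript_id`, `region`),
#'   `fpkm` (named vector), `contig_lengths`, `ncrna_id`, `pa_sites`
#'   (annotated 3' end of each transcript).
#' @export
make_transcriptome <- function(config) {
  set.seed(config$seed + 11L)
  dna <- c("A", "C", "G", "T")
  n <- config$n_transcripts
  u5 <- sample(config$utr5_range[1]:config$utr5_range[2], n, replace = TRUE)
  cds <- sample(config$cds_range[1]:config$cds_range[2], n, replace = TRUE)
  u3 <- sample(config$utr3_range[1]:config$utr3_range[2], n, replace = TRUE)
  lens <- u5 + cds + u3
  tx_ids <- sprintf("TX%04d", seq_len(n))
  nc_id <- "ncY1"
  ids <- c(tx_ids, nc_id)
  lens_all <- c(lens, config$ncrna_length)
  names(lens_all) <- ids

  seqs <- vapply(lens_all, function(L)
    paste(sample(dna, L, replace = TRUE), collapse = ""), character(1))

  models <- do.call(rbind, c(lapply(seq_len(n), function(i) data.frame(
    transcript_id = tx_ids[i], gene_id = sub("TX", "G", tx_ids[i]),
    biotype = "protein_coding", contig = tx_ids[i], strand = "+",
    region = c("5UTR", "CDS", "3UTR"),
    start = c(0L, u5[i], u5[i] + cds[i]),
    end = c(u5[i], u5[i] + cds[i], lens[i]),
    stringsAsFactors = FALSE)), list(data.frame(
      transcript_id = nc_id, gene_id = nc_id, biotype = "misc_RNA",
      contig = nc_id, strand = "+", region = "ncRNA_exon",
      start = 0L, end = config$ncrna_length, stringsAsFactors = FALSE))))

  # place planted sites: utr3_fraction in 3'UTR, the rest in CDS
  flank <- (ncol(config$planted_pwm) - 1L) %/% 2L
  margin <- max(config$min_end_distance, flank + 1L)
  place <- function(region_tbl, n_sites, margin) {
    pos <- integer(0); tx <- character(0); reg <- character(0)
    occupied <- lapply(stats::setNames(vector("list", length(ids)), ids),
                       identity)
    tries <- 0L
    while (length(pos) < n_sites && tries < n_sites * 50L) {
      tries <- tries + 1L
      i <- sample(nrow(region_tbl), 1L)
      r <- region_tbl[i, ]
      len <- lens_all[[r$contig]]
      lo <- max(r$start, margin)
      hi <- min(r$end, len - margin) - 1L
      if (hi - lo < 1L) next
      p <- sample(lo:hi, 1L)
      occ <- occupied[[r$contig]]
      if (!is.null(occ) && length(occ) && any(abs(occ - p) < 2L * flank + 2L))
        next
      occupied[[r$contig]] <- c(occ, p)
      pos <- c(pos, p); tx <- c(tx, r$transcript_id); reg <- c(reg, r$region)
    }
    if (length(pos) < n_sites)
      warning("placed ", length(pos), " of ", n_sites,
              " sites; regions too short for more")
    data.frame(contig = tx, pos = pos, strand = rep("+", length(pos)),
               transcript_id = tx, region = reg, stringsAsFactors = FALSE)
  }
  n_u3 <- round(config$n_planted_sites * config$utr3_fraction)
  # the short, saturated sponge keeps its sites central so every site sees
  # a near-full window of read starts
  nc_margin <- max(flank + 1L, as.integer(config$ncrna_length * 0.4))
  truth <- rbind(
    if (n_u3 > 0) place(models[models$region == "3UTR", ], n_u3, margin),
    if (config$n_planted_sites - n_u3 > 0)
      place(models[models$region == "CDS", ],
            config$n_planted_sites - n_u3, margin),
    if (config$ncrna_sites > 0)
      place(models[models$region == "ncRNA_exon", ], config$ncrna_sites,
            nc_margin))
  if (is.null(truth))
    truth <- data.frame(contig = character(), pos = integer(),
                        strand = character(), transcript_id = character(),
                        region = character(), stringsAsFactors = FALSE)

  # embed PWM draws (DNA alphabet) centred on the truth positions
  if (nrow(truth) > 0) {
    wins <- draw_from_pwm(config$planted_pwm, nrow(truth))
    for (k in seq_len(nrow(truth))) {
      ctg <- truth$contig[k]
      s <- seqs[[ctg]]
      a <- truth$pos[k] - flank + 1L
      substr(s, a, a + 2L * flank) <- wins[k]
      seqs[[ctg]] <- s
    }
  }

  fpkm <- stats::setNames(
    stats::rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog), tx_ids)
  # Solve the sponge expression so that the expected share of planted
  # deletion intensity on the ncRNA, AFTER duplicate collapse, equals
  # sponge_fraction. The sponge is short and extremely abundant, so the
  # finite (start, barcode) key space saturates: with B barcode variants
  # and m molecules per start position, the expected surviving molecules
  # per start are B * (1 - (1 - 1/B)^m).
  nc_sites <- truth$transcript_id == nc_id
  f <- config$sponge_fraction
  if (any(nc_sites) && f > 0 && sum(!nc_sites) > 0) {
    L <- config$read_length
    B <- 4^config$barcode_length
    n_mol <- config$reads_per_replicate * (1 - config$pcr_duplicate_rate)
    S <- pmax(lens_all - L - 6, 1)            # usable start positions
    mrna_tx <- truth$transcript_id[!nc_sites]
    n_nc <- sum(nc_sites)
    share_gap <- function(log_fnc) {
      fnc <- exp(log_fnc)
      u <- c(fpkm[tx_ids], stats::setNames(fnc, nc_id)) * lens_all
      w <- u / sum(u)
      i_m <- sum(n_mol * w[mrna_tx] / S[mrna_tx]) * (L - 2)
      m <- n_mol * w[[nc_id]] / S[[nc_id]]
      i_nc <- (L - 2) * B * (1 - (1 - 1 / B)^m) * n_nc
      i_nc / (i_nc + i_m) - f
    }
    hi <- log(1e9)
    if (share_gap(hi) < 0) {
      warning("sponge_fraction unattainable at this depth/barcode length; ",
              "using maximal sponge expression")
      fpkm_nc <- exp(hi)
    } else {
      fpkm_nc <- exp(stats::uniroot(share_gap, c(log(1e-3), hi),
                                    tol = 1e-4)$root)
    }
  } else fpkm_nc <- if (any(nc_sites)) stats::rlnorm(1, config$fpkm_meanlog,
                                                     config$fpkm_sdlog) else 0
  fpkm <- c(fpkm, stats::setNames(fpkm_nc, nc_id))

  pa <- data.frame(contig = ids, pos = lens_all - 1L, name = ids,
                   stringsAsFactors = FALSE)
  list(genome = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
       models = models, truth = truth, fpkm = fpkm,
       contig_lengths = lens_all, ncrna_id = nc_id, pa_sites = pa)
}

# CIGAR for a read of n_m aligned bases with deletions at the given sorted
# ref offsets (relative to the alignment start); adjacent offsets merge
# into longer D runs
build_cigar <- function(n_m, del_offsets) {
  if (length(del_offsets) == 0) return(paste0(n_m, "M"))
  del_offsets <- sort(del_offsets)
  runs <- split(del_offsets, cumsum(c(1L, diff(del_offsets) != 1L)))
  parts <- character(0)
  consumed_ref <- 0L; consumed_m <- 0L
  for (r in runs) {
    m <- r[1] - consumed_ref
    parts <- c(parts, paste0(m, "M"), paste0(length(r), "D"))
    consumed_m <- consumed_m + m
    consumed_ref <- r[length(r)] + 1L
  }
  paste0(paste(parts, collapse = ""), n_m - consumed_m, "M")
}

# read sequence given transcript sequence, start, M count and deletion
# offsets (ref-relative)
read_seq <- function(txseq, start0, n_m, del_offsets) {
  span <- n_m + length(del_offsets)
  s <- substr(txseq, start0 + 1L, start0 + span)
  if (length(del_offsets) == 0) return(s)
  keep <- setdiff(seq_len(span), del_offsets + 1L)
  paste(strsplit(s, "")[[1]][keep], collapse = "")
}

#' Simulate CRAC libraries as SAM files
#'
#' For each cross-linked replicate and for the control, reads are sampled
#' proportionally to expression, PCR duplicates are injected at the
#' configured rate (identical coordinates and barcode), reads covering a
#' truth site acquire a deletion there with probability
#' `crosslink_deletion_rate` (case libraries only), and every covered
#' internal base can acquire a background deletion. Each SAM file contains
#' exactly the configured number of primary records, with `RG` (sample)
#' and `BC` (random barcode) tags.
#'
#' @param config A [sim_config()].
#' @param tx Transcriptome from [make_transcriptome()].
#' @param dir Output directory for the SAM files.
#' @return List with `sam_paths` (named character vector), `sample_sheet`
#'   (data.frame `sample`, `replicate`, `is_control`) and `case_reads` /
#'   `control_reads` totals.
#' @export
simulate_crac_reads <- function(config, tx, dir = tempfile("crac")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 23L)
  L <- config$read_length
  dl <- config$deletion_length
  ids <- names(tx$contig_lengths)
  lens <- tx$contig_lengths
  seqs <- stats::setNames(as.character(tx$genome), ids)
  w <- tx$fpkm[ids] * lens
  w <- w / sum(w)
  truth_by_tx <- split(tx$truth$pos, tx$truth$contig)

  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", ids, "\tLN:", lens))

  samples <- c(paste0("crac_rep", seq_len(config$n_replicates)), "control")
  sheet <- data.frame(
    sample = samples,
    replicate = c(seq_len(config$n_replicates), 1L),
    is_control = c(rep(FALSE, config$n_replicates), TRUE),
    stringsAsFactors = FALSE)
  paths <- stats::setNames(file.path(dir, paste0(samples, ".sam")), samples)

  for (si in seq_along(samples)) {
    smp <- samples[si]
    is_ctrl <- sheet$is_control[si]
    n <- if (is_ctrl) config$control_reads else config$reads_per_replicate
    n_dup <- round(n * config$pcr_duplicate_rate)
    n_mol <- n - n_dup

    ti <- sample.int(length(ids), n_mol, replace = TRUE, prob = w)
    max_start <- lens[ti] - L - 6L - dl
    start <- floor(stats::runif(n_mol) * pmax(max_start + 1L, 1L))
    start <- pmin(start, pmax(max_start, 0L))
    bc <- draw_from_pwm(matrix(0.25, 4, config$barcode_length), n_mol)

    # planted deletions: per truth site, find covering molecules
    dels <- vector("list", n_mol)
    if (!is_ctrl && config$crosslink_deletion_rate > 0 &&
        length(truth_by_tx) > 0) {
      for (ctg in names(truth_by_tx)) {
        ci <- match(ctg, ids)
        ridx <- which(ti == ci)
        if (length(ridx) == 0) next
        st <- start[ridx]
        for (p in truth_by_tx[[ctg]]) {
          cover <- ridx[st > p - L + 1L & st < p]  # site internal to read
          if (length(cover) == 0) next
          hit <- cover[stats::runif(length(cover)) <
                         config$crosslink_deletion_rate]
          for (r in hit)
            dels[[r]] <- c(dels[[r]], (p - start[r]) + seq_len(dl) - 1L)
        }
      }
    }
    # background deletions at internal aligned offsets
    if (config$background_deletion_rate > 0) {
      k <- stats::rbinom(n_mol, L - 2L, config$background_deletion_rate)
      for (r in which(k > 0))
        dels[[r]] <- unique(c(dels[[r]], sample(seq_len(L - 2L), k[r])))
    }

    ndel <- lengths(dels)
    cig <- character(n_mol)
    sq <- character(n_mol)
    plain <- ndel == 0L
    cig[plain] <- paste0(L, "M")
    sq[plain] <- substring(seqs[ti[plain]], start[plain] + 1L,
                           start[plain] + L)
    for (r in which(!plain)) {
      offs <- sort(unique(dels[[r]]))
      cig[r] <- build_cigar(L, offs)
      sq[r] <- read_seq(seqs[[ti[r]]], start[r], L, offs)
    }

    # PCR duplicates: exact copies of earlier molecules, new read ids
    src <- if (n_dup > 0) sample.int(n_mol, n_dup, replace = TRUE) else integer(0)
    all_ti <- c(ti, ti[src]); all_start <- c(start, start[src])
    all_cig <- c(cig, cig[src]); all_sq <- c(sq, sq[src])
    all_bc <- c(bc, bc[src])
    qname <- sprintf("%s.%07d", smp, seq_len(n))

    lines <- paste(qname, 0L, ids[all_ti], all_start + 1L, 255L, all_cig,
                   "*", 0L, 0L, all_sq, strrep("I", nchar(all_sq)),
                   paste0("RG:Z:", smp), paste0("BC:Z:", all_bc),
                   sep = "\t")
    writeLines(c(header, paste0("@RG\tID:", smp, "\tSM:", smp), lines),
               paths[[smp]])
  }
  list(sam_paths = paths, sample_sheet = sheet,
       case_reads = config$reads_per_replicate * config$n_replicates,
       control_reads = config$control_reads)
}

#' Simulate polysomal and total count matrices
#'
#' Negative-binomial counts for `te_n_genes` genes in four libraries
#' (polysomal/total x control/case). The polysomal case means of the
#' target genes are multiplied by `2^te_effect`; all other means are
#' shared, so total RNA is unchanged in expectation.
#'
#' @param config A [sim_config()].
#' @return List with `pol` and `tot` (gene x `ctrl`/`case` matrices),
#'   `gene_ids`, `target_set`.
#' @export
simulate_te_counts <- function(config) {
  set.seed(config$seed + 37L)
  n <- config$te_n_genes
  genes <- sprintf("G%04d", seq_len(n))
  targets <- sample(genes, config$te_n_targets)
  expr <- stats::rlnorm(n, 0, config$te_expr_sdlog)
  mu <- expr / sum(expr) * config$te_depth
  boost <- ifelse(genes %in% targets, 2^config$te_effect, 1)
  rnb <- function(m) {
    if (config$te_dispersion > 0)
      stats::rnbinom(length(m), mu = m, size = 1 / config$te_dispersion)
    else stats::rpois(length(m), m)
  }
  pol <- cbind(ctrl = rnb(mu), case = rnb(mu * boost))
  tot <- cbind(ctrl = rnb(mu), case = rnb(mu))
  rownames(pol) <- rownames(tot) <- genes
  list(pol = pol, tot = tot, gene_ids = genes, target_set = targets)
}

#' Simulate a sucrose-gradient absorbance trace
#'
#' Gaussian peaks for the RNP, 40S, 60S and 80S components and a train of
#' polysomal peaks on a zero baseline, with the polysomal amplitudes
#' scaled so that the integrated polysome/80S area ratio equals
#' `config$trace_ratio` (within well under 1% at the default sampling
#' density).
#'
#' @param config A [sim_config()].
#' @param step Sampling step along the gradient coordinate (default 0.1).
#' @return List with `trace` (data.frame `position`, `a254`), `boundaries`
#'   (named list of intervals incl. `"80S"` and `"polysomes"`) and
#'   `true_ratio`.
#' @export
simulate_trace <- function(config, step = 0.1) {
  x <- seq(0, 100, by = step)
  g <- function(mu, sd, mass) mass / (sd * sqrt(2 * pi)) *
    exp(-(x - mu)^2 / (2 * sd^2))
  mass80 <- 1
  y <- g(8, 2, 0.9) + g(18, 1.2, 0.35) + g(26, 1.2, 0.4) +
    g(36, 1.8, mass80)
  poly_mu <- c(58, 66, 74, 82)
  poly_share <- c(0.35, 0.28, 0.22, 0.15)
  for (i in seq_along(poly_mu))
    y <- y + g(poly_mu[i], 2.2, config$trace_ratio * mass80 * poly_share[i])
  list(trace = data.frame(position = x, a254 = y),
       boundaries = list(RNP = c(0, 14), "40S" = c(14, 22),
                         "60S" = c(22, 30.5), "80S" = c(30.5, 41.5),
                         polysomes = c(50, 92)),
       true_ratio = config$trace_ratio)
}

#' Write the synthetic transcriptome to standard files
#'
#' Emits `genome.fa` (FASTA), `annotation.gtf` (gene/transcript/exon plus
#' UTR and CDS features), `truth_sites.bed` (0-based BED6 of planted
#' sites), `expression.tsv` (`transcript_id`, `fpkm`) and `pa_sites.tsv`.
#'
#' @param tx Transcriptome from [make_transcriptome()].
#' @param dir Output directory.
#' @return Named vector of the file paths, invisibly.
#' @export
write_transcriptome <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(tx$genome, fa)

  gtf <- file.path(dir, "annotation.gtf")
  feat <- c("5UTR" = "five_prime_utr", CDS = "CDS",
            "3UTR" = "three_prime_utr", ncRNA_exon = "exon")
  m <- tx$models
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
    m$gene_id, m$transcript_id, m$biotype, m$biotype)
  body <- paste(m$contig, "sim", feat[m$region], m$start + 1L, m$end, ".",
                m$strand, ".", attrs, sep = "\t")
  exons <- paste(m$contig, "sim", "exon", m$start + 1L, m$end, ".",
                 m$strand, ".", attrs, sep = "\t")[m$biotype == "protein_coding"]
  writeLines(c(body, exons), gtf)

  bed <- file.path(dir, "truth_sites.bed")
  if (nrow(tx$truth) > 0) {
    writeLines(paste(tx$truth$contig, tx$truth$pos, tx$truth$pos + 1L,
                     tx$truth$transcript_id, 0L, tx$truth$strand,
                     sep = "\t"), bed)
  } else writeLines(character(0), bed)

  expr <- file.path(dir, "expression.tsv")
  utils::write.table(
    data.frame(transcript_id = names(tx$fpkm), fpkm = unname(tx$fpkm)),
    expr, sep = "\t", quote = FALSE, row.names = FALSE)

  pa <- file.path(dir, "pa_sites.tsv")
  utils::write.table(tx$pa_sites, pa, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, gtf = gtf, truth = bed, expression = expr,
              pa_sites = pa))
}
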