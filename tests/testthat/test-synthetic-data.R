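small_cfg <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_transcripts = 12, n_planted_sites = 40,
         reads_per_replicate = 2000, control_reads = 2000),
    list(...))
  do.call(sim_config, args)
}

test_that("generators are pure functions of (config, seed)", {
  a <- make_transcriptome(small_cfg())
  b <- make_transcriptome(small_cfg())
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$fpkm, b$fpkm)
  c <- make_transcriptome(small_cfg(seed = 4))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
  ta <- simulate_te_counts(small_cfg())
  tb <- simulate_te_counts(small_cfg())
  expect_identical(ta$pol, tb$pol)
  expect_identical(ta$tot, tb$tot)
})

test_that("make_transcriptome honours site-placement constraints", {
  tx <- make_transcriptome(small_cfg())
  expect_equal(nrow(tx$truth), 40 + 2)      # mRNA sites + sponge sites
  # truth regions respect the 3'UTR fraction setting
  all_u3 <- make_transcriptome(small_cfg(utr3_fraction = 1))
  mrna <- all_u3$truth[all_u3$truth$transcript_id != all_u3$ncrna_id, ]
  expect_true(all(mrna$region == "3UTR"))
  none <- make_transcriptome(small_cfg(n_planted_sites = 0, ncrna_sites = 0))
  expect_equal(nrow(none$truth), 0L)
  # planted windows actually sit in the sequences: the centre base is the
  # PWM consensus most of the time (U core -> T in DNA)
  wins <- extract_windows(tx$truth, tx$genome)
  centre <- substr(wins, 4, 4)
  expect_gt(mean(centre == "U"), 0.75)
})

test_that("simulate_crac_reads writes the configured number of records", {
  cfg <- small_cfg()
  tx <- make_transcriptome(cfg)
  sim <- simulate_crac_reads(cfg, tx)
  for (smp in names(sim$sam_paths)) {
    n_rec <- sum(!startsWith(readLines(sim$sam_paths[[smp]]), "@"))
    expect_equal(n_rec, 2000L)
  }
  expect_setequal(sim$sample_sheet$sample[!sim$sample_sheet$is_control],
                  c("crac_rep1", "crac_rep2"))
})

test_that("forced cross-linking puts deletions exactly at truth sites", {
  cfg <- small_cfg(crosslink_deletion_rate = 1, background_deletion_rate = 0,
                   pcr_duplicate_rate = 0)
  tx <- make_transcriptome(cfg)
  sim <- simulate_crac_reads(cfg, tx)
  ss <- sim$sample_sheet
  recs <- do.call(rbind, lapply(sim$sam_paths[!ss$is_control],
                                load_alignments, sample_sheet = ss))
  pl <- build_pileup(recs, tx$contig_lengths)
  del_pos <- unlist(lapply(pl$tracks, function(trk)
    lapply(names(trk), function(ctg)
      paste(ctg, which(trk[[ctg]]$deletions > 0) - 1L))))
  truth_keys <- paste(tx$truth$contig, tx$truth$pos)
  expect_true(all(del_pos %in% truth_keys))
  # every covered truth site carries deletions (rate 1)
  covered <- vapply(seq_len(nrow(tx$truth)), function(i) {
    t1 <- pl$tracks$crac_rep1[[tx$truth$contig[i]]]
    t1$deletions[tx$truth$pos[i] + 1L] +
      t1$coverage[tx$truth$pos[i] + 1L] > 0
  }, logical(1))
  hit <- vapply(seq_len(nrow(tx$truth)), function(i) {
    t1 <- pl$tracks$crac_rep1[[tx$truth$contig[i]]]
    t1$deletions[tx$truth$pos[i] + 1L] > 0
  }, logical(1))
  expect_true(all(hit[covered]))
})

test_that("control libraries carry only background deletions", {
  cfg <- small_cfg(background_deletion_rate = 0.002)
  tx <- make_transcriptome(cfg)
  sim <- simulate_crac_reads(cfg, tx)
  ss <- sim$sample_sheet
  ctrl <- load_alignments(sim$sam_paths[["control"]], ss)
  pl <- build_pileup(ctrl, tx$contig_lengths)
  ndel <- sum(vapply(pl$tracks$control, function(t) sum(t$deletions),
                     numeric(1)))
  # expected: reads * (L - 2) * rate; allow wide Poisson slack
  expected <- 2000 * (cfg$read_length - 2) * 0.002
  expect_lt(ndel, expected * 2)
  expect_gt(ndel, expected / 2)
  # truth positions are not enriched in the control
  at_truth <- sum(vapply(seq_len(nrow(tx$truth)), function(i)
    pl$tracks$control[[tx$truth$contig[i]]]$deletions[tx$truth$pos[i] + 1L],
    numeric(1)))
  expect_lt(at_truth, 0.2 * ndel)
})

test_that("PCR duplicates collapse back to unique molecules", {
  cfg <- small_cfg(pcr_duplicate_rate = 0.3)
  tx <- make_transcriptome(cfg)
  sim <- simulate_crac_reads(cfg, tx)
  recs <- load_alignments(sim$sam_paths[["crac_rep1"]], sim$sample_sheet)
  kept <- collapse_duplicates(recs)
  expect_lt(nrow(kept), nrow(recs))
  # at least the injected duplicate fraction disappears
  expect_lte(nrow(kept), nrow(recs) * 0.72)
})

test_that("multi-nucleotide deletions span from the 5'-most truth base", {
  cfg <- small_cfg(deletion_length = 2L, crosslink_deletion_rate = 1,
                   background_deletion_rate = 0, pcr_duplicate_rate = 0)
  tx <- make_transcriptome(cfg)
  sim <- simulate_crac_reads(cfg, tx)
  recs <- load_alignments(sim$sam_paths[["crac_rep1"]], sim$sample_sheet)
  expect_true(any(grepl("2D", recs$cigar)))
  pl <- build_pileup(recs, tx$contig_lengths)
  del_pos <- unlist(lapply(names(pl$tracks$crac_rep1), function(ctg)
    paste(ctg, which(pl$tracks$crac_rep1[[ctg]]$deletions > 0) - 1L)))
  keys <- c(paste(tx$truth$contig, tx$truth$pos),
            paste(tx$truth$contig, tx$truth$pos + 1L))
  expect_true(all(del_pos %in% keys))
})

test_that("simulate_te_counts plants the effect only in polysomal case", {
  cfg <- sim_config(seed = 5, te_effect = 0)
  te0 <- simulate_te_counts(cfg)
  tbl <- delta_te_table(te0$pol, te0$tot)
  expect_lt(abs(mean(tbl$delta_te)), 0.05)  # null world is centred
  cfg1 <- sim_config(seed = 5, te_effect = 1)
  te1 <- simulate_te_counts(cfg1)
  tbl1 <- delta_te_table(te1$pol, te1$tot, class_threshold = 0.5)
  tmean <- mean(tbl1$delta_te[tbl1$gene_id %in% te1$target_set])
  omean <- mean(tbl1$delta_te[!tbl1$gene_id %in% te1$target_set])
  expect_gt(tmean - omean, 0.8)
})

test_that("simulate_trace hits the configured area ratio stably", {
  cfg <- sim_config(seed = 6, trace_ratio = 2)
  tr <- simulate_trace(cfg)
  expect_equal(global_te(tr$trace, tr$boundaries), 2, tolerance = 0.01)
  # refinement stability
  fine <- simulate_trace(cfg, step = 0.05)
  expect_equal(global_te(fine$trace, fine$boundaries),
               global_te(tr$trace, tr$boundaries), tolerance = 1e-3)
  zero <- simulate_trace(sim_config(seed = 6, trace_ratio = 0))
  expect_equal(global_te(zero$trace, zero$boundaries), 0, tolerance = 1e-6)
})

test_that("write_transcriptome emits parseable standard files", {
  tx <- make_transcriptome(small_cfg())
  dir <- tempfile("txout")
  paths <- write_transcriptome(tx, dir)
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(sort(names(fa)), sort(names(tx$genome)))
  models <- read_transcript_models(paths[["gtf"]])
  expect_setequal(unique(models$region),
                  c("5UTR", "CDS", "3UTR", "ncRNA_exon"))
  bed <- utils::read.delim(paths[["truth"]], header = FALSE)
  expect_equal(nrow(bed), nrow(tx$truth))
  expect_equal(bed$V2, tx$truth$pos)
})

test_that("cigar construction merges adjacent deletions", {
  expect_equal(mapas:::build_cigar(10, integer(0)), "10M")
  expect_equal(mapas:::build_cigar(10, 4L), "4M1D6M")
  expect_equal(mapas:::build_cigar(10, c(4L, 5L)), "4M2D6M")
  expect_equal(mapas:::build_cigar(10, c(3L, 7L)), "3M1D3M1D4M")
  # start 2, span 7 -> ref chars GTACGTA; dropping offset 2 removes the A
  expect_equal(mapas:::read_seq("ACGTACGTACGTACGT", 2L, 6L, 2L), "GTCGTA")
})
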