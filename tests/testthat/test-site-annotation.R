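toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(contig, type, start1, end, tx, gene = tx,
                     biotype = "protein_coding", strand = "+") {
  paste(contig, "test", type, start1, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
                gene, tx, biotype, biotype), sep = "\t")
}

test_that("read_transcript_models parses explicit UTR features", {
  path <- toy_gtf(c(
    gtf_line("c1", "five_prime_utr", 1, 100, "tx1"),
    gtf_line("c1", "CDS", 101, 400, "tx1"),
    gtf_line("c1", "three_prime_utr", 401, 500, "tx1"),
    gtf_line("c2", "exon", 1, 90, "nc1", biotype = "misc_RNA")))
  m <- read_transcript_models(path)
  expect_setequal(m$region[m$transcript_id == "tx1"], c("5UTR", "CDS", "3UTR"))
  expect_equal(m$start[m$region == "CDS"], 100L)   # 0-based
  expect_equal(m$end[m$region == "CDS"], 400L)
  expect_equal(m$region[m$transcript_id == "nc1"], "ncRNA_exon")
})

test_that("read_transcript_models derives UTRs from exon minus CDS", {
  path <- toy_gtf(c(
    gtf_line("c1", "exon", 1, 500, "tx1"),
    gtf_line("c1", "CDS", 101, 400, "tx1"),
    gtf_line("c2", "exon", 1, 500, "tx2", strand = "-"),
    gtf_line("c2", "CDS", 101, 400, "tx2", strand = "-")))
  m <- read_transcript_models(path)
  p <- m[m$transcript_id == "tx1", ]
  expect_equal(p$region[p$start == 0L], "5UTR")
  expect_equal(p$region[p$start == 400L], "3UTR")
  # minus strand: genomic-left piece is the 3'UTR
  q <- m[m$transcript_id == "tx2", ]
  expect_equal(q$region[q$start == 0L], "3UTR")
  expect_equal(q$region[q$start == 400L], "5UTR")
})

simple_models <- function() {
  data.frame(transcript_id = "tx1", gene_id = "g1",
             biotype = "protein_coding", contig = "c1", strand = "+",
             region = c("5UTR", "CDS", "3UTR"),
             start = c(0L, 100L, 400L), end = c(100L, 400L, 500L),
             stringsAsFactors = FALSE)
}

test_that("annotate_sites assigns regions with half-open containment", {
  sites <- data.frame(contig = "c1", pos = c(450L, 100L, 99L, 700L),
                      strand = "+", stringsAsFactors = FALSE)
  out <- annotate_sites(sites, simple_models())
  expect_equal(out$region, c("3UTR", "CDS", "5UTR", "unassigned"))
  expect_equal(out$transcript_id[1], "tx1")
  expect_true(is.na(out$transcript_id[4]))
})

test_that("multi-transcript overlap resolves by expression then id", {
  m <- rbind(simple_models(),
             within(simple_models(), transcript_id <- "tx0"))
  sites <- data.frame(contig = "c1", pos = 450L, strand = "+",
                      stringsAsFactors = FALSE)
  hi <- annotate_sites(sites, m, c(tx1 = 10, tx0 = 1))
  expect_equal(hi$transcript_id, "tx1")
  tie <- annotate_sites(sites, m, c(tx1 = 5, tx0 = 5))
  expect_equal(tie$transcript_id, "tx0")    # lexicographic on ties
})

test_that("region assignment agrees with a brute-force scan", {
  set.seed(33)
  for (trial in 1:40) {
    n_tx <- sample(2:4, 1)
    models <- do.call(rbind, lapply(seq_len(n_tx), function(i) {
      u5 <- sample(10:50, 1); cds <- sample(30:100, 1); u3 <- sample(10:80, 1)
      off <- sample(0:40, 1)
      data.frame(transcript_id = paste0("t", i), gene_id = paste0("g", i),
                 biotype = "protein_coding", contig = "c1", strand = "+",
                 region = c("5UTR", "CDS", "3UTR"),
                 start = off + c(0L, u5, u5 + cds),
                 end = off + c(u5, u5 + cds, u5 + cds + u3),
                 stringsAsFactors = FALSE)
    }))
    expr <- stats::setNames(runif(n_tx, 1, 10), paste0("t", seq_len(n_tx)))
    sites <- data.frame(contig = "c1", pos = sample(0:250, 25), strand = "+",
                        stringsAsFactors = FALSE)
    got <- annotate_sites(sites, models, expr)
    for (k in seq_len(nrow(sites))) {
      hit <- models[models$start <= sites$pos[k] & sites$pos[k] < models$end, ]
      if (nrow(hit) == 0) {
        expect_equal(got$region[k], "unassigned")
      } else {
        hit <- hit[order(-expr[hit$transcript_id], hit$transcript_id), ]
        expect_equal(got$transcript_id[k], hit$transcript_id[1])
        expect_equal(got$region[k], hit$region[1])
      }
    }
  }
})

test_that("interaction_weights partitions intensity into percentages", {
  s <- data.frame(transcript_id = c("a", "a", "b"), del_total = c(30, 40, 30),
                  stringsAsFactors = FALSE)
  w <- interaction_weights(s, "rna")
  expect_equal(w$weight_pct[w$key == "a"], 70)
  expect_equal(w$weight_pct[w$key == "b"], 30)
  expect_equal(sum(w$weight_pct), 100)
  one <- interaction_weights(data.frame(transcript_id = "x", del_total = 5),
                             "rna")
  expect_equal(one$weight_pct, 100)
  thirds <- interaction_weights(
    data.frame(transcript_id = c("a", "b", "c"), del_total = rep(7, 3)), "rna")
  expect_equal(thirds$weight_pct, rep(100 / 3, 3))
  expect_equal(sum(thirds$weight_pct), 100)
  expect_error(interaction_weights(
    data.frame(transcript_id = "x", del_total = 0), "rna"), "zero")
})

test_that("metaprofile bins by relative region position and normalizes", {
  m <- simple_models()
  # 3'UTR is 400..500; relative position 0.05 -> 3UTR bin 0
  sites <- annotate_sites(data.frame(contig = "c1", pos = c(405L, 495L, 450L),
                                     strand = "+"), m)
  prof <- metaprofile(sites, m)
  expect_equal(sum(prof$density), 1)
  u3 <- prof[prof$region == "3UTR", ]
  expect_equal(u3$density[u3$bin == 0], 1 / 3)
  expect_equal(sum(u3$density), 1)          # all sites in the 3'UTR
  expect_error(metaprofile(sites[0, ], m), "no sites")
})

test_that("metaprofile is invariant under transcript-length rescaling", {
  scale_models <- function(f) {
    m <- simple_models()
    m$start <- m$start * f; m$end <- m$end * f
    m
  }
  for (f in c(1L, 3L)) {
    m <- scale_models(f)
    sites <- annotate_sites(
      data.frame(contig = "c1", pos = as.integer(c(410, 430, 470) * f),
                 strand = "+"), m)
    prof <- metaprofile(sites, m)
    if (f == 1L) ref <- prof else expect_equal(prof, ref)
  }
})

test_that("apa_pau counts read starts near pA sites with nearest assignment", {
  n <- 200L
  rs <- integer(n)
  rs[c(95, 105, 111, 100) + 1L] <- 1L       # starts at 95, 100, 105, 111
  pl <- make_pileup_set(list(s1 = list(c1 = list(
    coverage = integer(n), deletions = integer(n), read_starts = rs))),
    c(c1 = n))
  pa <- data.frame(contig = "c1", pos = 100L, stringsAsFactors = FALSE)
  out <- apa_pau(pl, "s1", pa)
  expect_equal(out$count, 3L)               # 111 is 11 nt away, excluded
  # two pA sites: start goes to the nearer; exact tie to the 5'-most
  pa2 <- data.frame(contig = "c1", pos = c(90L, 100L), stringsAsFactors = FALSE)
  rs2 <- integer(n); rs2[c(92, 95, 99) + 1L] <- 1L
  pl2 <- make_pileup_set(list(s1 = list(c1 = list(
    coverage = integer(n), deletions = integer(n), read_starts = rs2))),
    c(c1 = n))
  out2 <- apa_pau(pl2, "s1", pa2)
  expect_equal(out2$count, c(2L, 1L))       # 92 -> 90, 95 tie -> 90, 99 -> 100
  # no reads at all
  pl0 <- make_pileup_set(list(s1 = list(c1 = list(
    coverage = integer(n), deletions = integer(n),
    read_starts = integer(n)))), c(c1 = n))
  expect_equal(apa_pau(pl0, "s1", pa)$count, 0L)
})
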