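test_that("polyA hexamer scan finds canonical signals in the 3' window", {
  seq <- paste0(strrep("C", 80), "AATAAA", strrep("G", 10))
  expect_equal(find_polya_signals(seq, 100L), nchar(seq) - 16L)
  expect_identical(find_polya_signals(strrep("C", 300), 100L), integer(0))
  v <- paste0(strrep("C", 200), "ATTAAA", strrep("C", 20))
  expect_equal(find_polya_signals(v, 100L), 200L)
  # signal upstream of the window is not reported
  u <- paste0("AATAAA", strrep("C", 300))
  expect_identical(find_polya_signals(u, 100L), integer(0))
  expect_error(find_polya_signals("ACGTX"), "ACGTN")
})

test_that("hallmark report recovers the planted large-terminal-exon geometry", {
  sim <- simulate_isoform_annotation(list(n_swap = 2L, n_null = 2L),
                                     seed = 11)
  cand <- screen_genes(sim$genes, sim$hits)
  me <- cand[cand$mutually_exclusive, , drop = FALSE]
  expect_equal(nrow(me), 2L)
  for (i in seq_len(nrow(me))) {
    rep <- hallmark_report(me[i, ], sim$genes, sim$genome, sim$hits)
    tr <- sim$truth$planted_swap_genes[[me$gene_id[i]]]
    expect_equal(rep$a$terminal_exon_length_bp,
                 tr$terminal_exon$length_bp)
    expect_equal(rep$a$coding_aa_in_terminal_exon,
                 tr$terminal_exon$coding_aa)
    expect_true(rep$a$single_large_exon)
    expect_true(rep$a$has_polyA_signal)
    expect_true(tr$terminal_exon$polya_offset %in%
                  rep$a$polyA_signal_positions)
    expect_true(rep$a$shares_acceptor_with_backbone)
    # partner isoform: domain spans an exon junction, so not single-exon
    expect_false(rep$b$single_large_exon)
  }
})

test_that("terminal-exon coding count agrees with the per-base CDS walk", {
  sim <- simulate_isoform_annotation(list(n_swap = 3L, n_null = 0L),
                                     seed = 13)
  cand <- screen_genes(sim$genes, sim$hits)
  for (i in seq_len(nrow(cand))) {
    rep <- hallmark_report(cand[i, ], sim$genes, sim$genome, sim$hits)
    for (side in c("a", "b")) {
      tid <- if (side == "a") cand$transcript_a[i] else cand$transcript_b[i]
      t <- sim$genes[[cand$gene_id[i]]]$transcripts[[tid]]
      term <- nrow(t$exons)
      ts <- t$exons$start[term]; te <- t$exons$end[term]
      walk <- oracle_cds_walk(t)
      n_aa <- length(walk) %/% 3L
      full_in <- sum(vapply(seq_len(n_aa), function(k) {
        pos <- walk[(3L * (k - 1L) + 1L):(3L * k)]
        all(pos >= ts & pos < te)
      }, logical(1)))
      expect_equal(rep[[side]]$coding_aa_in_terminal_exon, full_in)
    }
  }
})

test_that("hallmark reports are strand-symmetric", {
  # one gene laid out on +, then mirrored onto the minus strand of the
  # reverse-complemented contig: every report field must match
  L <- 4000L
  e1 <- c(100L, 220L); e2 <- c(300L, 420L); e3a <- c(500L, 2400L)
  e3b <- c(2500L, 2800L); e4 <- c(2900L, 3200L)
  mk <- function(iv, strand) {
    if (strand == "+") data.frame(start = iv[1], end = iv[2])
    else data.frame(start = L - iv[2], end = L - iv[1])
  }
  build <- function(strand) {
    cds_sh <- rbind(mk(c(130L, 220L), strand), mk(e2, strand))  # 210 nt
    ta <- transcript("ta", "g", "chr", strand,
                     exons = rbind(mk(e1, strand), mk(e2, strand),
                                   mk(e3a, strand)),
                     cds = rbind(cds_sh, mk(c(500L, 1703L), strand)))
    tb <- transcript("tb", "g", "chr", strand,
                     exons = rbind(mk(e1, strand), mk(e2, strand),
                                   mk(e3b, strand), mk(e4, strand)),
                     cds = rbind(cds_sh, mk(e3b, strand),
                                 mk(c(2900L, 3101L), strand)))
    gene("g", list(ta, tb))
  }
  set.seed(5)
  fwd <- random_dna_str(L)
  substr(fwd, 2371, 2376) <- "AATAAA"   # near end of e3a
  genomes <- list(
    "+" = Biostrings::DNAStringSet(c(chr = fwd)),
    "-" = Biostrings::DNAStringSet(c(chr = as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(fwd))))))
  hits <- data.frame(transcript_id = c("ta", "tb"),
                     accession = c("PF1.1", "PF2.1"),
                     name = c("A", "B"),
                     aa_start = c(80L, 75L), aa_end = c(300L, 160L),
                     evalue = c(1e-9, 1e-9), stringsAsFactors = FALSE)
  cand <- data.frame(gene_id = "g", transcript_a = "ta",
                     transcript_b = "tb", domains_only_in_a = "PF1",
                     domains_only_in_b = "PF2", shared_backbone_exons = 2L,
                     mutually_exclusive = TRUE, stringsAsFactors = FALSE)
  reps <- lapply(c("+", "-"), function(s)
    hallmark_report(cand, list(g = build(s)), genomes[[s]], hits))
  for (side in c("a", "b"))
    expect_equal(reps[[1]][[side]], reps[[2]][[side]])
})
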