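test_that("generators are byte-reproducible given the same seed", {
  d1 <- tempfile(); d2 <- tempfile()
  a <- simulate_isoform_annotation(list(n_swap = 2L, n_null = 4L),
                                   seed = 5, out_dir = d1)
  b <- simulate_isoform_annotation(list(n_swap = 2L, n_null = 4L),
                                   seed = 5, out_dir = d2)
  for (f in names(a$files))
    expect_identical(readLines(a$files[[f]]), readLines(b$files[[f]]))
  c1 <- simulate_isoform_annotation(list(n_swap = 2L, n_null = 4L),
                                    seed = 6)
  expect_false(identical(as.character(a$genome), as.character(c1$genome)))

  e1 <- simulate_element_genome(list(n_elements = 3L, n_decoys = 1L,
                                     n_contigs = 2L), seed = 5,
                                out_dir = tempfile())
  e2 <- simulate_element_genome(list(n_elements = 3L, n_decoys = 1L,
                                     n_contigs = 2L), seed = 5,
                                out_dir = tempfile())
  expect_identical(readLines(e1$files$genome), readLines(e2$files$genome))
  expect_identical(readLines(e1$files$hits), readLines(e2$files$hits))

  tree <- default_sim_tree(0.1)
  s1 <- simulate_codon_alignment(tree, 0.5, 2, 40, seed = 5)
  s2 <- simulate_codon_alignment(tree, 0.5, 2, 40, seed = 5)
  expect_identical(s1$alignment$sequences, s2$alignment$sequences)
})

test_that("isoform truth coordinates validate against the emitted files", {
  sim <- simulate_isoform_annotation(list(n_swap = 3L, n_null = 5L),
                                     seed = 12, out_dir = tempfile())
  genes <- read_gtf(sim$files$gtf)
  expect_setequal(names(genes), names(sim$genes))
  genome <- Biostrings::readDNAStringSet(sim$files$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  for (tr in sim$truth$planted_swap_genes) {
    g <- genes[[tr$gene_id]]
    clen <- Biostrings::width(genome[names(genome) == g$interval$contig])
    expect_true(g$interval$end <= clen)
    for (dom in list(tr$domain_a, tr$domain_b))
      expect_true(all(dom$blocks$end <= clen & dom$blocks$start >= 0))
    # planted hexamer really is AATAAA in the terminal exon sense sequence
    ta <- g$transcripts[[tr$transcript_a]]
    term <- nrow(ta$exons)
    seq <- substr(as.character(genome[[ta$contig]]),
                  ta$exons$start[term] + 1L, ta$exons$end[term])
    if (ta$strand == "-")
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    off <- tr$terminal_exon$polya_offset
    expect_equal(substr(seq, off + 1L, off + 6L), "AATAAA")
  }
  # proteins have no stop characters (CDS excludes the stop codon)
  prot <- Biostrings::readAAStringSet(sim$files$proteins)
  expect_false(any(grepl("\\*", as.character(prot))))
})

test_that("zero planted swaps yield an empty screen", {
  sim <- simulate_isoform_annotation(list(n_swap = 0L, n_null = 10L),
                                     seed = 3)
  out <- screen_genes(sim$genes, sim$hits)
  expect_false(any(out$mutually_exclusive))
})

test_that("element truth validates and zero-noise elements classify cleanly", {
  sim <- simulate_element_genome(list(n_elements = 4L, n_decoys = 2L,
                                      n_contigs = 3L, mutation_rate = 0),
                                 seed = 7, out_dir = tempfile())
  hits <- read_similarity_hits(sim$files$hits)
  expect_equal(nrow(hits), 4L * 4L + 2L)
  genome <- Biostrings::readDNAStringSet(sim$files$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  for (el in sim$truth$planted_elements) {
    expect_true(el$end <= Biostrings::width(
      genome[names(genome) == el$contig]))
    expect_equal(el$itr_identity, 100)
  }
  loci <- cluster_hits(hits)
  archs <- lapply(loci, classify_locus, genome = genome)
  cls <- vapply(archs, `[[`, "", "classification")
  kind <- vapply(archs, function(a) a$terminal_repeat$kind, "")
  expect_equal(sum(cls == "DIRS1-like" & kind == "ITR"), 4L)
  # direct-repeat decoys are LTR, never ITR
  expect_equal(sum(cls == "partial"), 2L)
  expect_true(all(kind[cls == "partial"] == "LTR"))
})

test_that("codon simulation respects branch lengths and stays stop-free", {
  zero <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulate_codon_alignment(zero, omega = 1, kappa = 1, n_codons = 50,
                                  seed = 2)
  expect_equal(length(unique(sim$alignment$sequences)), 1L)
  expect_equal(unname(sim$alignment$sequences[1]),
               sim$truth$root_sequence)

  busy <- simulate_codon_alignment(default_sim_tree(0.3), omega = 2,
                                   kappa = 3, n_codons = 120, seed = 8)
  # constructor enforces the invariants (length, whole-codon gaps, stops)
  expect_s3_class(codon_alignment(busy$alignment$sequences),
                  "codon_alignment")
  expect_equal(busy$alignment$length_nt %% 3L, 0L)
})

test_that("infeasible generator parameters fail fast", {
  expect_error(simulate_isoform_annotation(
    list(terminal_coding_aa = 2000L), seed = 1), "infeasible")
  expect_error(simulate_element_genome(
    list(n_elements = 500L, n_contigs = 1L), seed = 1), "placement")
  expect_error(simulate_codon_alignment(default_sim_tree(0.1), omega = -1,
                                        kappa = 1, n_codons = 10, seed = 1))
})
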