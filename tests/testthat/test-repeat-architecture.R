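mk_hits <- function(starts, ends, strand = "+", contig = "c1",
                    label = "RT_DIRS1") {
  data.frame(query_id = label, contig = contig, start = starts, end = ends,
             strand = strand, percent_identity = 95, evalue = 1e-10,
             label = label, stringsAsFactors = FALSE)
}

test_that("hit chaining respects gap, contig and strand boundaries", {
  h <- mk_hits(c(100L, 250L), c(200L, 350L))
  one <- cluster_hits(h, max_gap_bp = 100L)
  expect_length(one, 1L)
  expect_equal(c(one[[1]]$start, one[[1]]$end), c(100L, 350L))
  two <- cluster_hits(h, max_gap_bp = 10L)
  expect_length(two, 2L)
  opp <- rbind(mk_hits(100L, 200L, "+"), mk_hits(150L, 350L, "-"))
  expect_length(cluster_hits(opp, max_gap_bp = 1000L), 2L)
})

test_that("chaining partitions the input hits", {
  set.seed(8)
  h <- mk_hits(starts <- sample(1:50000, 120),
               starts + sample(100:900, 120, replace = TRUE),
               strand = sample(c("+", "-"), 120, replace = TRUE),
               contig = sample(c("c1", "c2", "c3"), 120, replace = TRUE))
  loci <- cluster_hits(h, max_gap_bp = 500L)
  got <- do.call(rbind, lapply(loci, `[[`, "member_hits"))
  key <- function(d) sort(paste(d$contig, d$start, d$end, d$strand))
  expect_equal(key(got), key(h))
  expect_equal(sum(vapply(loci, function(l) nrow(l$member_hits), 0L)),
               nrow(h))
})

test_that("flank extraction clamps to contig bounds and honours strand", {
  genome <- Biostrings::DNAStringSet(c(c1 = random_dna_str(8000)))
  mklocus <- function(s, e, strand = "+")
    structure(list(id = "L1", contig = "c1", strand = strand, start = s,
                   end = e, member_hits = mk_hits(s, e, strand)),
              class = "locus")
  fl <- extract_flanks(mklocus(6000L, 7000L), genome, 5000L)
  expect_equal(c(fl$interval$start, fl$interval$end), c(1000L, 8000L))
  expect_equal(nchar(fl$seq), 7000L)
  fl2 <- extract_flanks(mklocus(0L, 100L), genome, 5000L)
  expect_equal(c(fl2$interval$start, fl2$interval$end), c(0L, 5100L))
  plus <- extract_flanks(mklocus(3000L, 3500L, "+"), genome, 200L)
  minus <- extract_flanks(mklocus(3000L, 3500L, "-"), genome, 200L)
  expect_identical(minus$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus$seq))))
  expect_error(extract_flanks(mklocus(0L, 10L), genome["c1" != names(genome)]),
               "absent")
})

test_that("architecture classification follows the GAG<RT<RNase(<YR) order", {
  mkl <- function(hits) structure(
    list(id = "L1", contig = "c1", strand = "+", start = 0L,
         end = max(hits$end), member_hits = hits), class = "locus")
  full <- data.frame(
    query_id = c("LAP2alpha", "RT_DIRS1", "RNase_HI_RT_DIRS1", "INT_phage"),
    contig = "c1", start = c(0L, 2000L, 4100L, 4700L),
    end = c(1400L, 4000L, 4600L, 5800L), strand = "+",
    percent_identity = 95, evalue = 1e-12,
    label = c("LAP2alpha", "RT_DIRS1", "RNase_HI_RT_DIRS1", "INT_phage"),
    stringsAsFactors = FALSE)
  a <- infer_architecture(mkl(full), full)
  expect_equal(a$classification, "DIRS1-like")
  expect_equal(a$ordered_labels$role, c("GAG", "RT", "RNase", "YR"))

  part <- full[c(1, 3), ]
  expect_equal(infer_architecture(mkl(part), part)$classification, "partial")

  swapped <- full
  swapped$start[1:2] <- c(2000L, 0L); swapped$end[1:2] <- c(3400L, 1900L)
  expect_equal(infer_architecture(mkl(swapped), swapped)$classification,
               "inconsistent")

  unk <- full; unk$label <- "mystery"
  expect_equal(infer_architecture(mkl(unk), unk)$classification,
               "unclassified")
})

test_that("terminal repeat detector separates planted ITRs, LTRs and errors", {
  set.seed(21)
  core <- random_dna_str(6000 - 60)
  term <- random_dna_str(30)
  itr_seq <- paste0(term, core, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(term))))
  call_itr <- detect_terminal_repeats(itr_seq, window = 1500L)
  expect_equal(call_itr$kind, "ITR")
  expect_equal(call_itr$repeat_length_bp, 30L)
  expect_equal(call_itr$percent_identity, 100)
  expect_equal(call_itr$five_prime_span, c(0L, 30L))
  expect_equal(call_itr$three_prime_span, c(5970L, 6000L))

  ltr_seq <- paste0(term, core, term)
  expect_equal(detect_terminal_repeats(ltr_seq, window = 1500L)$kind, "LTR")

  expect_error(detect_terminal_repeats(random_dna_str(2000), window = 1500L),
               "shorter")
})

test_that("label summaries are deterministic and permutation-invariant", {
  empty <- summarize_labels(list())
  expect_equal(nrow(empty$labels), 0L)
  sim <- simulate_element_genome(list(n_elements = 4L, n_decoys = 2L,
                                      n_contigs = 3L), seed = 3)
  loci <- cluster_hits(sim$hits)
  archs <- lapply(loci, function(l) infer_architecture(l, l$member_hits))
  s1 <- summarize_labels(archs)
  s2 <- summarize_labels(rev(archs))
  expect_equal(s1, s2)
  expect_equal(s1$labels$count[s1$labels$label == "RT_DIRS1"], 6L)
})

test_that("classification is symmetric under genome reverse-complement", {
  sim <- simulate_element_genome(list(n_elements = 3L, n_decoys = 1L,
                                      n_contigs = 2L), seed = 9)
  genome <- sim$genome
  loci <- cluster_hits(sim$hits)
  archs <- lapply(loci, classify_locus, genome = genome)

  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  flipped_hits <- sim$hits
  flipped_hits$start <- clen[sim$hits$contig] - sim$hits$end
  flipped_hits$end <- clen[sim$hits$contig] - sim$hits$start
  flipped_hits$strand <- ifelse(sim$hits$strand == "+", "-", "+")
  flipped_genome <- Biostrings::reverseComplement(genome)
  loci_f <- cluster_hits(flipped_hits)
  archs_f <- lapply(loci_f, classify_locus, genome = flipped_genome)

  # mirrored coordinates shuffle locus order; compare classification and
  # repeat-kind multisets
  tab <- function(archs) {
    cls <- sort(vapply(archs, `[[`, "", "classification"))
    kind <- sort(vapply(archs, function(a) a$terminal_repeat$kind, ""))
    list(cls = cls, kind = kind)
  }
  expect_equal(tab(archs_f), tab(archs))
  expect_length(archs_f, length(archs))
})
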