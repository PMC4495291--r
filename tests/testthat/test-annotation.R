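make_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

test_that("read_gtf builds the model and converts coordinates", {
  path <- make_gtf(c(
    'chr1\tsrc\tgene\t51\t400\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\ttranscript\t51\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t51\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t101\t160\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'))
  genes <- read_gtf(path)
  expect_length(genes, 1L)
  g <- genes[["g1"]]
  expect_length(g$transcripts, 1L)
  t <- g$transcripts[[1]]
  expect_equal(t$exons$rank, c(1L, 2L))
  expect_equal(t$exons$start, c(50L, 300L))  # 1-based -> 0-based
  expect_equal(t$exons$end, c(200L, 400L))
  expect_equal(t$cds$start, 100L)            # GTF 101..160
  expect_equal(t$cds$end, 160L)
  expect_false(t$malformed)
})

test_that("read_gtf names the line on end < start and errors on missing files", {
  path <- make_gtf(c(
    'chr1\tsrc\tgene\t51\t400\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t200\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'))
  expect_error(read_gtf(path), "line 2")
  expect_error(read_gtf(tempfile()), "cannot read")
})

test_that("transcripts violating invariants are flagged, not dropped", {
  t_ok <- transcript("t1", "g1", "chr1", "+",
                     exons = data.frame(start = 0L, end = 100L),
                     cds = data.frame(start = 10L, end = 31L))   # 21 nt
  expect_false(t_ok$malformed)
  t_bad <- transcript("t2", "g1", "chr1", "+",
                      exons = data.frame(start = 0L, end = 100L),
                      cds = data.frame(start = 10L, end = 32L))  # 22 nt
  expect_true(t_bad$malformed)
  expect_match(t_bad$malformed_reason, "divisible")
  # overlapping exons
  t_ov <- transcript("t3", "g1", "chr1", "+",
                     exons = data.frame(start = c(0L, 50L),
                                        end = c(60L, 120L)))
  expect_true(t_ov$malformed)
})

test_that("write_gtf round-trips simulated annotations", {
  for (seed in 1:5) {
    sim <- simulate_isoform_annotation(list(n_swap = 2L, n_null = 3L),
                                       seed = seed)
    path <- tempfile(fileext = ".gtf")
    write_gtf(sim$genes, path)
    back <- read_gtf(path)
    expect_equal(sort(names(back)), sort(names(sim$genes)))
    for (gid in names(sim$genes)) {
      for (tid in names(sim$genes[[gid]]$transcripts)) {
        t0 <- sim$genes[[gid]]$transcripts[[tid]]
        t1 <- back[[gid]]$transcripts[[tid]]
        expect_equal(t1$exons, t0$exons)
        expect_equal(t1$cds, t0$cds)
        expect_identical(t1$strand, t0$strand)
        expect_identical(t1$contig, t0$contig)
      }
    }
  }
})

test_that("protein_to_genomic maps simple and junction-split ranges", {
  t1 <- transcript("t1", "g1", "chr1", "+",
                   exons = data.frame(start = 100L, end = 400L),
                   cds = data.frame(start = 100L, end = 400L))
  fp <- protein_to_genomic(t1, 1L, 10L)
  expect_equal(fp$blocks$start, 100L)
  expect_equal(fp$blocks$end, 130L)

  t2 <- transcript("t2", "g1", "chr1", "+",
                   exons = data.frame(start = c(100L, 200L),
                                      end = c(110L, 220L)),
                   cds = data.frame(start = c(100L, 200L),
                                    end = c(110L, 220L)))
  fp2 <- protein_to_genomic(t2, 3L, 5L)
  expect_equal(fp2$blocks$start, c(106L, 200L))
  expect_equal(fp2$blocks$end, c(110L, 205L))

  # same geometry on the minus strand: per-base map equals the oracle
  t3 <- transcript("t3", "g1", "chr1", "-",
                   exons = data.frame(start = c(100L, 200L),
                                      end = c(110L, 220L)),
                   cds = data.frame(start = c(100L, 200L),
                                    end = c(110L, 220L)))
  fp3 <- protein_to_genomic(t3, 3L, 5L)
  expect_equal(footprint_positions(fp3), oracle_aa_positions(t3, 3L, 5L))

  expect_error(protein_to_genomic(t1, 1L, 200L), "out of bounds")
})

test_that("protein_to_genomic agrees base-for-base with the naive CDS walk", {
  set.seed(42)
  for (i in 1:200) {
    t <- random_test_transcript()
    n_aa <- cds_length(t) %/% 3L
    a <- sample(n_aa, 1L)
    b <- if (a == n_aa) a else sample(a:n_aa, 1L)
    fp <- protein_to_genomic(t, a, b)
    expect_identical(footprint_positions(fp), oracle_aa_positions(t, a, b))
    expect_equal(sum(fp$blocks$end - fp$blocks$start) %% 3L, 0L)
  }
})

test_that("footprint BED output carries transcript and accession names", {
  t1 <- transcript("t1", "g1", "chr1", "+",
                   exons = data.frame(start = 100L, end = 400L),
                   cds = data.frame(start = 100L, end = 400L))
  fp <- protein_to_genomic(t1, 1L, 10L, accession = "PF00001")
  path <- tempfile(fileext = ".bed")
  write_footprints_bed(list(fp), path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[1], "\t")[[1]][4], "t1|PF00001")
  expect_equal(strsplit(lines[1], "\t")[[1]][2], "100")
})
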