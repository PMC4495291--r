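# Synthetic-data generators with machine-readable truth. Three simulators:
# (1) gene annotations with planted domain-swap isoform pairs among null
# genes, (2) genomes with embedded DIRS1-like elements (ITR-GAG-RT-RNase-
# YR-ITR) plus direct-repeat decoys together with the similarity hits a
# translated search would plausibly report, and (3) codon alignments
# evolved on a fixed tree at a known dN/dS.

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# write `seq` into contig base vector at exon-local sense position
# `offset0` (0-based) of a feature spanning [gstart, gend) on `strand`
place_sense_seq <- function(contig_vec, gstart, gend, strand, offset0, seq) {
  n <- nchar(seq)
  if (strand == "+") {
    at <- gstart + offset0 + seq_len(n)          # 1-based genomic
    contig_vec[at] <- strsplit(seq, "")[[1]]
  } else {
    at <- gend - offset0 - n + seq_len(n)
    contig_vec[at] <- strsplit(revcomp(seq), "")[[1]]
  }
  contig_vec
}

random_codons <- function(n_aa) {
  paste(sample(sense_codons(), n_aa, replace = TRUE), collapse = "")
}

translate_codons <- function(cds_seq) {
  n <- nchar(cds_seq) %/% 3L
  paste(codon_aa(substring(cds_seq, 3L * (seq_len(n) - 1L) + 1L,
                           3L * seq_len(n))), collapse = "")
}

default_isoform_params <- function() {
  list(
    n_swap = 10L, n_null = 200L,
    n_shared_exons = c(2L, 3L),      # sampled range
    shared_exon_len = c(150L, 400L), # sampled range, bp
    utr5_len = 30L,
    intron_len = c(300L, 1500L),
    terminal_exon_len = 2812L,       # large 3' exon of the swap isoform
    terminal_coding_aa = 506L,
    domain_a_len_aa = 200L,
    domain_b_len_aa = 150L,
    polya_offset_from_end = 40L,     # hexamer start, bp from exon 3' end
    accession_a = "PF90001.2", accession_b = "PF90002.4",
    noise_hit_rate = 0.3, noise_evalue = 0.5,
    evalue_a = 1.5e-08, evalue_b = 1e-10
  )
}

# transcript-orientation layout -> genomic coordinates
# segs: data.frame(kind, len); returns cumulative [start,end) in layout
# space plus a mapper to genomic space given origin and strand
layout_segments <- function(segs, origin, strand) {
  ends <- cumsum(segs$len)
  starts <- c(0L, utils::head(ends, -1L))
  total <- ends[length(ends)]
  g <- if (strand == "+") {
    data.frame(start = origin + starts, end = origin + ends)
  } else {
    data.frame(start = origin + total - ends, end = origin + total - starts)
  }
  cbind(segs, layout_start = starts, layout_end = ends, g)
}

#' Simulate gene annotations with planted domain-swap isoforms
#'
#' Plants `n_swap` genes that reproduce the domain-substitution topology:
#' shared 5' exons; isoform A ends in one large terminal exon (default
#' 2812 bp coding 506 amino acids) that carries domain A and a planted
#' `AATAAA` hexamer near its end; isoform B skips that exon and continues
#' into two further exons carrying domain B. Null genes come in four
#' flavours (domains in shared exons, identical domain sets, single
#' transcript, one-sided domain gain) and must never be called mutually
#' exclusive. Each gene sits on its own contig.
#'
#' @param params Named list overriding `default_isoform_params()` entries.
#' @param seed Integer seed; output is byte-reproducible given
#'   `(params, seed)`.
#' @param out_dir If non-NULL, writes `annotation.gtf`, `domains.tsv`,
#'   `proteins.fasta`, `genome.fasta` and `truth.json` there.
#' @return List with `genes` (model), `hits` (data.frame),
#'   `genome` ([Biostrings::DNAStringSet]), `truth`, and `files` (paths or
#'   NULL).
#' @export
simulate_isoform_annotation <- function(params = list(), seed = 1L,
                                        out_dir = NULL) {
  p <- utils::modifyList(default_isoform_params(), params)
  if (p$terminal_coding_aa * 3L > p$terminal_exon_len)
    stop("infeasible parameters: terminal exon cannot hold ",
         p$terminal_coding_aa, " codons")
  if (p$n_swap < 0L || p$n_null < 0L) stop("negative gene counts")

  with_seed(derive_seed(seed, "isoforms"), {
    genes <- list(); hit_rows <- list(); contigs <- list()
    proteins <- character(0)
    truth_swap <- list(); truth_null <- list()
    null_types <- c("domains_in_shared", "identical_domains", "single_tx",
                    "gain_only")
    n_total <- p$n_swap + p$n_null
    kinds <- sample(c(rep("swap", p$n_swap), rep("null", p$n_null)))
    null_i <- 0L

    for (gi in seq_len(n_total)) {
      gid <- sprintf("gene_%04d", gi)
      ctg <- paste0("ctg_", gid)
      strand <- sample(c("+", "-"), 1L)
      kind <- kinds[gi]
      ns <- sample(seq(p$n_shared_exons[1], p$n_shared_exons[2]), 1L)
      sh_len <- sample(seq(p$shared_exon_len[1], p$shared_exon_len[2]), ns,
                       replace = TRUE)
      # shared coding length must be a codon multiple
      S <- sum(sh_len) - p$utr5_len
      sh_len[ns] <- sh_len[ns] + (3L - S %% 3L) %% 3L
      S <- sum(sh_len) - p$utr5_len
      introns <- function(k) sample(seq(p$intron_len[1], p$intron_len[2]), k,
                                    replace = TRUE)

      if (kind == "swap") {
        segs <- data.frame(kind = character(0), len = integer(0))
        add <- function(segs, kind, len) rbind(segs, data.frame(kind = kind,
                                                                len = len))
        for (i in seq_len(ns)) {
          segs <- add(segs, paste0("e_sh", i), sh_len[i])
          segs <- add(segs, "i", introns(1L))
        }
        segs <- add(segs, "eA", p$terminal_exon_len)
        segs <- add(segs, "i", introns(1L))
        segs <- add(segs, "eB1", 400L)
        segs <- add(segs, "i", introns(1L))
        segs <- add(segs, "eB2", 800L)
        origin <- 100L
        lay <- layout_segments(segs, origin, strand)
        span <- sum(segs$len)
        contig_len <- span + 200L
        row_of <- function(k) which(lay$kind == k)

        sh_rows <- vapply(seq_len(ns), function(i) row_of(paste0("e_sh", i)),
                          0L)
        exA <- row_of("eA"); eB1 <- row_of("eB1"); eB2 <- row_of("eB2")
        shared_exons <- data.frame(start = lay$start[sh_rows],
                                   end = lay$end[sh_rows])
        # shared CDS: exon 1 minus the 5' UTR, rest fully coding
        shared_cds <- shared_exons
        if (strand == "+") shared_cds$start[1] <- shared_cds$start[1] +
            p$utr5_len
        else shared_cds$end[1] <- shared_cds$end[1] - p$utr5_len

        cdsA_len <- p$terminal_coding_aa * 3L
        cdsA <- if (strand == "+")
          data.frame(start = lay$start[exA], end = lay$start[exA] + cdsA_len)
        else
          data.frame(start = lay$end[exA] - cdsA_len, end = lay$end[exA])
        tA <- transcript(paste0(gid, ".tA"), gid, ctg, strand,
                         exons = rbind(shared_exons,
                                       data.frame(start = lay$start[exA],
                                                  end = lay$end[exA])),
                         cds = rbind(shared_cds, cdsA))

        cdsB2_len <- 500L
        cdsB2 <- if (strand == "+")
          data.frame(start = lay$start[eB2], end = lay$start[eB2] + cdsB2_len)
        else
          data.frame(start = lay$end[eB2] - cdsB2_len, end = lay$end[eB2])
        tB <- transcript(paste0(gid, ".tB"), gid, ctg, strand,
                         exons = rbind(shared_exons,
                                       data.frame(start = lay$start[eB1],
                                                  end = lay$end[eB1]),
                                       data.frame(start = lay$start[eB2],
                                                  end = lay$end[eB2])),
                         cds = rbind(shared_cds,
                                     data.frame(start = lay$start[eB1],
                                                end = lay$end[eB1]),
                                     cdsB2))
        g <- gene(gid, list(tA, tB))
        genes[[gid]] <- g

        # contig sequence: random background, CDS overwritten with sense
        # codons, hexamer planted in the terminal-exon 3' UTR
        cv <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
        cds_shared_seq <- random_codons(S %/% 3L)
        cdsA_seq <- random_codons(p$terminal_coding_aa)
        cdsB_seq <- random_codons((400L + cdsB2_len) %/% 3L)
        # write shared CDS piecewise along layout
        off <- 0L
        for (i in seq_len(ns)) {
          r <- sh_rows[i]
          clen <- sh_len[i] - if (i == 1L) p$utr5_len else 0L
          piece <- substr(cds_shared_seq, off + 1L, off + clen)
          local0 <- if (i == 1L) p$utr5_len else 0L
          cv <- place_sense_seq(cv, lay$start[r], lay$end[r], strand,
                                local0, piece)
          off <- off + clen
        }
        cv <- place_sense_seq(cv, lay$start[exA], lay$end[exA], strand, 0L,
                              cdsA_seq)
        cv <- place_sense_seq(cv, lay$start[eB1], lay$end[eB1], strand, 0L,
                              substr(cdsB_seq, 1L, 400L))
        cv <- place_sense_seq(cv, lay$start[eB2], lay$end[eB2], strand, 0L,
                              substr(cdsB_seq, 401L, 900L))
        polya_local <- p$terminal_exon_len - p$polya_offset_from_end
        cv <- place_sense_seq(cv, lay$start[exA], lay$end[exA], strand,
                              polya_local, "AATAAA")
        contigs[[ctg]] <- paste(cv, collapse = "")

        # domains: A in the terminal exon, B spanning the B1/B2 junction
        aaS <- S %/% 3L
        domA <- c(aaS + 40L, aaS + 40L + p$domain_a_len_aa - 1L)
        domB <- c(aaS + 60L, aaS + 60L + p$domain_b_len_aa - 1L)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          transcript_id = tA$id, accession = p$accession_a,
          name = "LAP2alpha_like", aa_start = domA[1], aa_end = domA[2],
          evalue = p$evalue_a, stringsAsFactors = FALSE)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          transcript_id = tB$id, accession = p$accession_b,
          name = "zf_like", aa_start = domB[1], aa_end = domB[2],
          evalue = p$evalue_b, stringsAsFactors = FALSE)
        if (stats::runif(1) < p$noise_hit_rate)
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            transcript_id = tA$id, accession = "PF99999.1",
            name = "weak_noise", aa_start = 1L, aa_end = 20L,
            evalue = p$noise_evalue, stringsAsFactors = FALSE)

        proteins[tA$id] <- translate_codons(paste0(cds_shared_seq, cdsA_seq))
        proteins[tB$id] <- translate_codons(paste0(cds_shared_seq, cdsB_seq))

        # truth blocks from layout arithmetic (transcript-space offsets)
        ntA_lo <- (domA[1] - 1L) * 3L - S   # within terminal-exon CDS
        ntA_hi <- domA[2] * 3L - S
        blkA <- if (strand == "+")
          data.frame(contig = ctg, start = lay$start[exA] + ntA_lo,
                     end = lay$start[exA] + ntA_hi, strand = strand)
        else
          data.frame(contig = ctg, start = lay$end[exA] - ntA_hi,
                     end = lay$end[exA] - ntA_lo, strand = strand)
        ntB_lo <- (domB[1] - 1L) * 3L - S; ntB_hi <- domB[2] * 3L - S
        seg_map <- function(r, lo, hi) {    # lo,hi local to segment CDS
          if (strand == "+")
            data.frame(contig = ctg, start = lay$start[r] + lo,
                       end = lay$start[r] + hi, strand = strand)
          else
            data.frame(contig = ctg, start = lay$end[r] - hi,
                       end = lay$end[r] - lo, strand = strand)
        }
        blkB <- rbind(seg_map(eB1, ntB_lo, 400L),
                      seg_map(eB2, 0L, ntB_hi - 400L))
        truth_swap[[gid]] <- list(
          gene_id = gid, transcript_a = tA$id, transcript_b = tB$id,
          strand = strand,
          domain_a = list(accession = strip_accession_version(p$accession_a),
                          aa_start = domA[1], aa_end = domA[2],
                          blocks = blkA),
          domain_b = list(accession = strip_accession_version(p$accession_b),
                          aa_start = domB[1], aa_end = domB[2],
                          blocks = blkB),
          terminal_exon = list(length_bp = p$terminal_exon_len,
                               coding_aa = p$terminal_coding_aa,
                               polya_offset = polya_local))
      } else {
        null_i <- null_i + 1L
        ntype <- null_types[(null_i - 1L) %% length(null_types) + 1L]
        res <- simulate_null_gene(gid, ctg, strand, ntype, sh_len, p,
                                  introns)
        genes[[gid]] <- res$gene
        contigs[[ctg]] <- res$contig_seq
        hit_rows <- c(hit_rows, res$hits)
        proteins <- c(proteins, res$proteins)
        truth_null[[gid]] <- list(gene_id = gid, type = ntype)
      }
    }

    hits <- do.call(rbind, hit_rows)
    rownames(hits) <- NULL
    genome <- Biostrings::DNAStringSet(unlist(contigs))
    truth <- list(planted_swap_genes = truth_swap,
                  null_genes = truth_null,
                  simulation_params = c(p, list(seed = seed)))

    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(
        gtf = file.path(out_dir, "annotation.gtf"),
        domains = file.path(out_dir, "domains.tsv"),
        proteins = file.path(out_dir, "proteins.fasta"),
        genome = file.path(out_dir, "genome.fasta"),
        truth = file.path(out_dir, "truth.json"))
      write_gtf(genes, files$gtf)
      utils::write.table(hits, files$domains, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(proteins), files$proteins)
      Biostrings::writeXStringSet(genome, files$genome)
      jsonlite::write_json(truth, files$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    list(genes = genes, hits = hits, genome = genome, truth = truth,
         files = files)
  })
}

# one null gene; see simulate_isoform_annotation for the four flavours
simulate_null_gene <- function(gid, ctg, strand, ntype, sh_len, p, introns) {
  ns <- length(sh_len)
  S <- sum(sh_len) - p$utr5_len
  segs <- data.frame(kind = paste0("e_sh", seq_len(ns)),
                     len = sh_len)
  interleave <- data.frame(kind = rep("i", ns), len = introns(ns))
  segs <- do.call(rbind, lapply(seq_len(ns), function(i)
    rbind(segs[i, ], interleave[i, ])))
  segs <- rbind(segs, data.frame(kind = "eX", len = 500L),
                data.frame(kind = "i2", len = introns(1L)),
                data.frame(kind = "eY", len = 600L))
  lay <- layout_segments(segs, 100L, strand)
  contig_len <- sum(segs$len) + 200L
  row_of <- function(k) which(lay$kind == k)
  sh_rows <- vapply(seq_len(ns), function(i) row_of(paste0("e_sh", i)), 0L)
  shared_exons <- data.frame(start = lay$start[sh_rows],
                             end = lay$end[sh_rows])
  shared_cds <- shared_exons
  if (strand == "+") shared_cds$start[1] <- shared_cds$start[1] + p$utr5_len
  else shared_cds$end[1] <- shared_cds$end[1] - p$utr5_len
  eX <- row_of("eX"); eY <- row_of("eY")
  exX <- data.frame(start = lay$start[eX], end = lay$end[eX])
  exY <- data.frame(start = lay$start[eY], end = lay$end[eY])
  aaS <- S %/% 3L

  cv <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  cds_shared_seq <- random_codons(aaS)
  off <- 0L
  for (i in seq_len(ns)) {
    r <- sh_rows[i]
    clen <- sh_len[i] - if (i == 1L) p$utr5_len else 0L
    piece <- substr(cds_shared_seq, off + 1L, off + clen)
    cv <- place_sense_seq(cv, lay$start[r], lay$end[r], strand,
                          if (i == 1L) p$utr5_len else 0L, piece)
    off <- off + clen
  }

  hits <- list(); proteins <- character(0)
  mk_hit <- function(tid, acc, nm, a1, a2, ev) data.frame(
    transcript_id = tid, accession = acc, name = nm, aa_start = a1,
    aa_end = a2, evalue = ev, stringsAsFactors = FALSE)

  if (ntype == "domains_in_shared") {
    # both domains sit in shared coding exons; isoforms differ only by an
    # extra non-coding 3' exon, so neither domain is mutually exclusive
    tA <- transcript(paste0(gid, ".tA"), gid, ctg, strand,
                     exons = shared_exons, cds = shared_cds)
    tB <- transcript(paste0(gid, ".tB"), gid, ctg, strand,
                     exons = rbind(shared_exons, exX), cds = shared_cds)
    half <- max(2L, aaS %/% 2L)
    hits[[1]] <- mk_hit(tA$id, "PF80001.1", "sharedA", 2L,
                        min(half, aaS), 1e-12)
    hits[[2]] <- mk_hit(tB$id, "PF80002.1", "sharedB", 2L,
                        min(half, aaS), 1e-12)
    proteins[tA$id] <- proteins[tB$id] <- translate_codons(cds_shared_seq)
    g <- gene(gid, list(tA, tB))
  } else if (ntype == "identical_domains") {
    tA <- transcript(paste0(gid, ".tA"), gid, ctg, strand,
                     exons = rbind(shared_exons, exX), cds = shared_cds)
    tB <- transcript(paste0(gid, ".tB"), gid, ctg, strand,
                     exons = rbind(shared_exons, exY), cds = shared_cds)
    for (tid in c(tA$id, tB$id))
      hits[[length(hits) + 1L]] <- mk_hit(tid, "PF80003.2", "same", 2L,
                                          min(50L, aaS), 1e-10)
    proteins[tA$id] <- proteins[tB$id] <- translate_codons(cds_shared_seq)
    g <- gene(gid, list(tA, tB))
  } else if (ntype == "single_tx") {
    tA <- transcript(paste0(gid, ".tA"), gid, ctg, strand,
                     exons = shared_exons, cds = shared_cds)
    hits[[1]] <- mk_hit(tA$id, "PF80004.1", "solo", 2L, min(50L, aaS),
                        1e-10)
    proteins[tA$id] <- translate_codons(cds_shared_seq)
    g <- gene(gid, list(tA))
  } else {  # gain_only: A gains a domain in its unique exon, B loses none
    cdsX_len <- 300L
    cdsX <- if (strand == "+")
      data.frame(start = lay$start[eX], end = lay$start[eX] + cdsX_len)
    else
      data.frame(start = lay$end[eX] - cdsX_len, end = lay$end[eX])
    tA <- transcript(paste0(gid, ".tA"), gid, ctg, strand,
                     exons = rbind(shared_exons, exX),
                     cds = rbind(shared_cds, cdsX))
    tB <- transcript(paste0(gid, ".tB"), gid, ctg, strand,
                     exons = rbind(shared_exons, exY), cds = shared_cds)
    cdsX_seq <- random_codons(cdsX_len %/% 3L)
    cv <- place_sense_seq(cv, lay$start[eX], lay$end[eX], strand, 0L,
                          cdsX_seq)
    hits[[1]] <- mk_hit(tA$id, "PF80005.3", "gained", aaS + 10L,
                        aaS + 60L, 1e-09)
    proteins[tA$id] <- translate_codons(paste0(cds_shared_seq, cdsX_seq))
    proteins[tB$id] <- translate_codons(cds_shared_seq)
    g <- gene(gid, list(tA, tB))
  }
  list(gene = g, contig_seq = paste(cv, collapse = ""), hits = hits,
       proteins = proteins)
}

default_element_params <- function() {
  list(
    n_elements = 50L, n_decoys = 10L,
    n_contigs = 15L, contig_len = 70000L,
    itr_len = 300L, mutation_rate = 0.02,
    orf_len = c(GAG = 1500L, RT = 2100L, RNase = 600L, YR = 1200L),
    spacer = 100L,
    decoy_orf_len = 2000L,
    coord_jitter = 20L,
    min_gap = 7000L
  )
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(bases, b), 1L), "")
  }
  paste(v, collapse = "")
}

#' Simulate a genome with embedded DIRS1-like elements and decoys
#'
#' Builds one master element (`ITR - GAG - RT - RNase - YR - inverted
#' ITR`) and one direct-repeat decoy (`LTR - ORF - LTR`), plants mutated
#' copies at well-separated random positions on random strands, and emits
#' the outfmt-6-like similarity hits a translated homology scan would
#' plausibly produce for the internal ORFs (with coordinate jitter).
#' Element termini are deliberately absent from the hit table: finding
#' them is the terminal-repeat detector's job.
#'
#' @param params Named list overriding `default_element_params()`.
#' @param seed Integer seed.
#' @param out_dir If non-NULL, writes `genome.fasta`, `hits.tsv`,
#'   `truth.json` there.
#' @return List with `genome`, `hits` (data.frame as read by
#'   [read_similarity_hits()]), `hits_outfmt6` (the raw 13-column table as
#'   written to disk), `truth`, `files`.
#' @export
simulate_element_genome <- function(params = list(), seed = 1L,
                                    out_dir = NULL) {
  p <- utils::modifyList(default_element_params(), params)
  with_seed(derive_seed(seed, "genome"), {
    sp <- p$spacer
    itr <- random_dna(p$itr_len)
    orf_seqs <- lapply(p$orf_len, function(n) random_codons(n %/% 3L))
    parts <- c(itr, unlist(lapply(names(p$orf_len), function(r)
      paste0(random_dna(sp), orf_seqs[[r]]))), random_dna(sp),
      revcomp(itr))
    master <- paste(parts, collapse = "")
    # ORF offsets within the master element (0-based half-open)
    offs <- list(); cur <- p$itr_len
    for (r in names(p$orf_len)) {
      cur <- cur + sp
      offs[[r]] <- c(cur, cur + p$orf_len[[r]])
      cur <- cur + p$orf_len[[r]]
    }
    elem_len <- nchar(master)

    ltr <- random_dna(p$itr_len)
    decoy_master <- paste0(ltr, random_dna(sp), random_codons(
      p$decoy_orf_len %/% 3L), random_dna(sp), ltr)
    decoy_orf_off <- c(p$itr_len + sp, p$itr_len + sp + p$decoy_orf_len)
    decoy_len <- nchar(decoy_master)

    # contigs as base vectors; greedy left-to-right placement with large
    # separations so flanked windows never reach a neighbouring insert
    contigs <- lapply(seq_len(p$n_contigs), function(i)
      sample(c("A", "C", "G", "T"), p$contig_len, replace = TRUE))
    names(contigs) <- sprintf("scaf_%02d", seq_len(p$n_contigs))
    cursor <- stats::setNames(rep(2000L, p$n_contigs), names(contigs))

    feats <- c(rep("element", p$n_elements), rep("decoy", p$n_decoys))
    feats <- sample(feats)
    placements <- list()
    ci <- 0L
    for (fi in seq_along(feats)) {
      flen <- if (feats[fi] == "element") elem_len else decoy_len
      placed <- FALSE
      for (try in seq_len(p$n_contigs)) {
        ci <- ci %% p$n_contigs + 1L
        ctg <- names(contigs)[ci]
        gap <- p$min_gap + sample.int(2000L, 1L)
        pos <- cursor[ctg] + gap                      # 0-based start
        if (pos + flen + 2000L <= p$contig_len) {
          placements[[fi]] <- list(kind = feats[fi], contig = ctg,
                                   start = pos, end = pos + flen,
                                   strand = sample(c("+", "-"), 1L))
          cursor[ctg] <- pos + flen
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement error: could not place feature ", fi,
                        " without overlap; reduce counts or enlarge contigs")
    }

    label_of <- c(GAG = "LAP2alpha", RT = "RT_DIRS1",
                  RNase = "RNase_HI_RT_DIRS1", YR = "INT_phage")
    hit_rows <- list(); truth_elems <- list(); truth_decoys <- list()

    emit_hit <- function(ctg, gstart, gend, strand, label, pid) {
      j1 <- sample(seq(-p$coord_jitter, p$coord_jitter), 1L)
      j2 <- sample(seq(-p$coord_jitter, p$coord_jitter), 1L)
      s1 <- max(1L, gstart + 1L + j1)      # 1-based inclusive
      s2 <- gend + j2
      if (s2 <= s1) s2 <- s1 + 10L
      aalen <- (s2 - s1 + 1L) %/% 3L
      if (strand == "-") { tmp <- s1; s1 <- s2; s2 <- tmp }
      data.frame(qseqid = label, sseqid = ctg, pident = round(pid, 2),
                 length = aalen, mismatch = round(aalen * (100 - pid) / 100),
                 gapopen = 0L, qstart = 1L, qend = aalen,
                 sstart = s1, send = s2,
                 evalue = signif(10^-stats::runif(1, 8, 30), 3),
                 bitscore = round(aalen * 1.9), label = label,
                 stringsAsFactors = FALSE)
    }

    for (pl in placements) {
      copy <- mutate_seq(if (pl$kind == "element") master else decoy_master,
                         p$mutation_rate)
      ins <- if (pl$strand == "-") revcomp(copy) else copy
      v <- contigs[[pl$contig]]
      v[(pl$start + 1L):pl$end] <- strsplit(ins, "")[[1]]
      contigs[[pl$contig]] <- v
      flen <- nchar(copy)
      to_genomic <- function(off) {     # element offsets -> genomic
        if (pl$strand == "+") c(pl$start + off[1], pl$start + off[2])
        else c(pl$end - off[2], pl$end - off[1])
      }
      if (pl$kind == "element") {
        t5 <- substr(copy, 1L, p$itr_len)
        t3 <- revcomp(substr(copy, flen - p$itr_len + 1L, flen))
        itr_ident <- 100 * mean(strsplit(t5, "")[[1]] ==
                                  strsplit(t3, "")[[1]])
        orf_g <- list()
        for (r in names(p$orf_len)) {
          g <- to_genomic(offs[[r]])
          orf_g[[r]] <- g
          hit_rows[[length(hit_rows) + 1L]] <-
            emit_hit(pl$contig, g[1], g[2], pl$strand, label_of[[r]],
                     100 * (1 - p$mutation_rate))
        }
        truth_elems[[length(truth_elems) + 1L]] <- list(
          contig = pl$contig, start = pl$start, end = pl$end,
          strand = pl$strand, orf_genomic = orf_g,
          itr_len = p$itr_len, itr_identity = itr_ident)
      } else {
        g <- to_genomic(decoy_orf_off)
        hit_rows[[length(hit_rows) + 1L]] <-
          emit_hit(pl$contig, g[1], g[2], pl$strand, "RT_DIRS1",
                   100 * (1 - p$mutation_rate))
        truth_decoys[[length(truth_decoys) + 1L]] <- list(
          contig = pl$contig, start = pl$start, end = pl$end,
          strand = pl$strand, repeat_kind = "direct",
          repeat_len = p$itr_len)
      }
    }

    hits_raw <- do.call(rbind, hit_rows)
    rownames(hits_raw) <- NULL
    genome <- Biostrings::DNAStringSet(
      vapply(contigs, paste, "", collapse = ""))
    truth <- list(planted_elements = truth_elems, decoys = truth_decoys,
                  simulation_params = c(p[setdiff(names(p), "orf_len")],
                                        list(orf_len = as.list(p$orf_len),
                                             seed = seed)))
    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(genome = file.path(out_dir, "genome.fasta"),
                    hits = file.path(out_dir, "hits.tsv"),
                    truth = file.path(out_dir, "truth.json"))
      Biostrings::writeXStringSet(genome, files$genome)
      utils::write.table(hits_raw, files$hits, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(truth, files$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    # same table in reader form, for in-memory pipelines
    hits <- data.frame(query_id = hits_raw$qseqid, contig = hits_raw$sseqid,
                       start = pmin(hits_raw$sstart, hits_raw$send) - 1L,
                       end = pmax(hits_raw$sstart, hits_raw$send),
                       strand = ifelse(hits_raw$sstart > hits_raw$send,
                                       "-", "+"),
                       percent_identity = hits_raw$pident,
                       evalue = hits_raw$evalue, label = hits_raw$label,
                       stringsAsFactors = FALSE)
    list(genome = genome, hits = hits, hits_outfmt6 = hits_raw,
         truth = truth, files = files)
  })
}

# neighbor structure for the codon substitution model, cached
codon_neighbors <- function() {
  if (!is.null(.rd_cache$neighbors)) return(.rd_cache$neighbors)
  sc <- sense_codons()
  idx <- stats::setNames(seq_along(sc), sc)
  nb <- lapply(sc, function(cod) {
    mut <- codon_mutants(cod)
    keep <- !is_stop(mut)
    mut <- mut[keep]
    pos <- rep(1:3, each = 3)[keep]
    from_b <- substring(cod, pos, pos)
    to_b <- substring(mut, pos, pos)
    ts <- mapply(is_transition, from_b, to_b)
    syn <- codon_aa(mut) == codon_aa(cod)
    list(to = unname(idx[mut]), ts = as.logical(ts), syn = unname(syn))
  })
  names(nb) <- sc
  .rd_cache$neighbors <- nb
  nb
}

#' Simulate a codon alignment on a fixed tree at known dN/dS
#'
#' The root sequence is drawn uniformly from the 61 sense codons and
#' evolved along each branch with a continuous-time codon model in which a
#' single-nucleotide change has rate proportional to
#' `kappa^[transition] * omega^[nonsynonymous]`; changes to stop codons
#' are forbidden. The generator matrix is scaled so branch lengths are
#' expected substitutions per codon (uniform codon weights). Substitution
#' events are simulated per codon per branch (Gillespie-style).
#'
#' @param tree An ape `phylo` object or a Newick string; branch lengths
#'   required.
#' @param omega Nonsynonymous/synonymous rate ratio (> 0).
#' @param kappa Transition/transversion rate ratio (> 0). Default 1, so
#'   the counting estimator's equal-rate site definitions match the
#'   generating process.
#' @param n_codons Number of codons (>= 1).
#' @param seed Integer seed.
#' @return List with `alignment` (a [codon_alignment()]), `tree` (phylo)
#'   and `truth` (parameters incl. seed and root sequence).
#' @export
simulate_codon_alignment <- function(tree, omega, kappa = 1, n_codons,
                                     seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be phylo or Newick text")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  stopifnot(omega > 0, kappa > 0, n_codons >= 1)
  nb <- codon_neighbors()
  sc <- sense_codons()
  rates <- lapply(nb, function(x)
    ifelse(x$ts, kappa, 1) * ifelse(x$syn, 1, omega))
  total <- vapply(rates, sum, 0)
  rho <- mean(total)   # uniform-codon scaling: branch length = E[subs]/codon

  with_seed(derive_seed(seed, "codons"), {
    root_seq <- sample.int(length(sc), n_codons, replace = TRUE)
    po <- ape::reorder.phylo(tree, "postorder")
    edges <- po$edge
    elens <- po$edge.length
    n_tip <- length(tree$tip.label)
    seqs <- vector("list", n_tip + tree$Nnode)
    root <- unique(edges[, 1])[length(unique(edges[, 1]))]
    seqs[[root]] <- root_seq
    evolve_codon <- function(state, t) {
      repeat {
        r <- total[[state]] / rho
        dt <- stats::rexp(1L, r)
        if (dt > t) return(state)
        t <- t - dt
        w <- rates[[state]]
        k <- sample.int(length(w), 1L, prob = w)
        state <- nb[[state]]$to[k]
      }
    }
    for (e in rev(seq_len(nrow(edges)))) {  # root towards tips
      parent <- seqs[[edges[e, 1]]]
      t <- elens[e]
      child <- parent
      if (t > 0) for (i in seq_len(n_codons))
        child[i] <- evolve_codon(parent[i], t)
      seqs[[edges[e, 2]]] <- child
    }
    sequences <- vapply(seq_len(n_tip), function(i)
      paste(sc[seqs[[i]]], collapse = ""), "")
    names(sequences) <- tree$tip.label
    list(alignment = codon_alignment(sequences), tree = tree,
         truth = list(omega = omega, kappa = kappa, n_codons = n_codons,
                      seed = seed,
                      root_sequence = paste(sc[root_seq], collapse = "")))
  })
}

#' A fixed balanced 8-taxon tree used by the simulation defaults
#' @param branch_length Length of every branch (default 0.05 expected
#'   substitutions per codon).
#' @return An ape `phylo` object.
#' @export
default_sim_tree <- function(branch_length = 0.05) {
  nwk <- "(((t1:%1$g,t2:%1$g):%1$g,(t3:%1$g,t4:%1$g):%1$g):%1$g,((t5:%1$g,t6:%1$g):%1$g,(t7:%1$g,t8:%1$g):%1$g):%1$g);"
  ape::read.tree(text = sprintf(nwk, branch_length))
}
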