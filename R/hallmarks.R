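# Retroposition hallmarks on candidate isoforms: a single large 3'-terminal
# coding exon, an internal polyadenylation signal near its end, and reuse
# of a splice acceptor into the shared exon backbone.

#' Scan for polyadenylation-signal hexamers near the end of an exon
#'
#' Finds every occurrence of the canonical hexamers (default `AATAAA` and
#' `ATTAAA`) whose start lies within the last `window_bp` bases of `seq`.
#'
#' @param seq Terminal-exon sequence in transcript (sense) orientation.
#' @param window_bp Search window from the 3' end (default 100).
#' @param hexamers Character vector of signal hexamers.
#' @return Ascending integer vector of 0-based offsets within `seq`.
#' @export
find_polya_signals <- function(seq, window_bp = 100L,
                               hexamers = c("AATAAA", "ATTAAA")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside ACGTN")
  n <- nchar(seq)
  win_start <- max(0L, n - as.integer(window_bp))  # 0-based
  offs <- integer(0)
  for (hx in hexamers) {
    m <- gregexpr(hx, seq, fixed = TRUE)[[1]]
    if (m[1] != -1L) offs <- c(offs, as.integer(m) - 1L)
  }
  sort(unique(offs[offs >= win_start & offs + 6L <= n]))
}

# CDS-offset ranges (0-based half-open, in spliced-CDS space) of the CDS
# portion lying within one exon of the transcript
cds_ranges_in_exon <- function(t, exon_row) {
  es <- t$exons$start[exon_row]; ee <- t$exons$end[exon_row]
  out <- list(); cum <- 0L
  for (i in seq_len(nrow(t$cds))) {
    s <- t$cds$start[i]; e <- t$cds$end[i]; w <- e - s
    os <- max(s, es); oe <- min(e, ee)
    if (os < oe) {
      if (t$strand == "+") {
        lo <- cum + (os - s); hi <- cum + (oe - s)
      } else {
        lo <- cum + (e - oe); hi <- cum + (e - os)
      }
      out[[length(out) + 1L]] <- c(lo, hi)
    }
    cum <- cum + w
  }
  out
}

# amino acids whose full codon lies inside the given CDS-offset ranges
count_full_codons <- function(ranges) {
  if (!length(ranges)) return(0L)
  sum(vapply(ranges, function(r) {
    max(0L, (r[2] %/% 3L) - ((r[1] + 2L) %/% 3L))
  }, numeric(1)))
}

#' Hallmark report for one transcript of a screen candidate
#'
#' @param t The transcript to score.
#' @param other The partner transcript of the candidate pair.
#' @param swapped_accessions Accessions unique to `t` in the pair.
#' @param hits Domain-hit rows for `t`.
#' @param genome [Biostrings::DNAStringSet] with the gene's contig.
#' @param min_aa Minimum amino acids coded in the terminal exon for it to
#'   count as a single large exon (default 300).
#' @param polya_window Window passed to [find_polya_signals()].
#' @return A list of class `hallmark_report`.
#' @export
transcript_hallmarks <- function(t, other, swapped_accessions, hits, genome,
                                 min_aa = 300L, polya_window = 100L) {
  if (!t$contig %in% names(genome))
    stop("contig ", t$contig, " absent from genome FASTA")
  term <- nrow(t$exons)  # rank order: last row = 3'-most exon
  term_len <- t$exons$end[term] - t$exons$start[term]
  coding_aa <- count_full_codons(cds_ranges_in_exon(t, term))

  swapped <- hits[hits$accession %in% swapped_accessions, , drop = FALSE]
  domain_in_term <- FALSE
  if (nrow(swapped) > 0L) {
    domain_in_term <- all(vapply(seq_len(nrow(swapped)), function(i) {
      fp <- protein_to_genomic(t, swapped$aa_start[i], swapped$aa_end[i],
                               swapped$accession[i])
      all(fp$blocks$start >= t$exons$start[term] &
            fp$blocks$end <= t$exons$end[term])
    }, logical(1)))
  }

  seq <- exon_seq(t, term, genome)
  polya <- find_polya_signals(seq, polya_window)

  backbone <- paste(t$exons$start, t$exons$end) %in%
    paste(other$exons$start, other$exons$end)
  shares_acceptor <- term > 1L && backbone[term - 1L]

  structure(list(
    transcript_id = t$id,
    terminal_exon_length_bp = term_len,
    coding_aa_in_terminal_exon = coding_aa,
    single_large_exon = domain_in_term && coding_aa >= min_aa,
    polyA_signal_positions = polya,
    has_polyA_signal = length(polya) > 0L,
    shares_acceptor_with_backbone = shares_acceptor
  ), class = "hallmark_report")
}

#' Retroposition-hallmark reports for a screen candidate
#'
#' For each transcript of the pair: identifies the 3'-most exon, counts the
#' amino acids it codes, tests whether the swapped domain lies entirely in
#' that exon and is large enough (`single_large_exon`), scans for
#' polyadenylation-signal hexamers near the exon end, and tests whether the
#' exon's acceptor abuts a shared backbone exon.
#'
#' @param candidate One row of [screen_genes()] output.
#' @param genes Named list of genes.
#' @param genome [Biostrings::DNAStringSet] of contig sequences.
#' @param hits data.frame of domain hits.
#' @param min_aa,polya_window See [transcript_hallmarks()].
#' @return Named list of two `hallmark_report`s (`a` and `b`).
#' @export
hallmark_report <- function(candidate, genes, genome, hits,
                            min_aa = 300L, polya_window = 100L) {
  g <- genes[[candidate$gene_id]]
  if (is.null(g)) stop("unknown gene ", candidate$gene_id)
  ta <- g$transcripts[[candidate$transcript_a]]
  tb <- g$transcripts[[candidate$transcript_b]]
  hits$accession <- strip_accession_version(hits$accession)
  only_a <- strsplit(candidate$domains_only_in_a, ",")[[1]]
  only_b <- strsplit(candidate$domains_only_in_b, ",")[[1]]
  list(
    a = transcript_hallmarks(ta, tb, only_a,
                             hits[hits$transcript_id == ta$id, , drop = FALSE],
                             genome, min_aa, polya_window),
    b = transcript_hallmarks(tb, ta, only_b,
                             hits[hits$transcript_id == tb$id, , drop = FALSE],
                             genome, min_aa, polya_window))
}

#' @export
print.hallmark_report <- function(x, ...) {
  cat(sprintf(
    "hallmarks %s: terminal exon %d bp, %d aa coded, large=%s, polyA=%s, backbone acceptor=%s\n",
    x$transcript_id, x$terminal_exon_length_bp, x$coding_aa_in_terminal_exon,
    x$single_large_exon, x$has_polyA_signal, x$shares_acceptor_with_backbone))
  invisible(x)
}

#' Write hallmark reports for all candidates as TSV
#'
#' @param candidates Output of [screen_genes()].
#' @param genes,genome,hits See [hallmark_report()].
#' @param path Output path.
#' @param ... Passed to [hallmark_report()].
#' @return `path`, invisibly.
#' @export
write_hallmarks <- function(candidates, genes, genome, hits, path, ...) {
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    rep <- hallmark_report(candidates[i, ], genes, genome, hits, ...)
    for (r in rep) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = candidates$gene_id[i],
        transcript_id = r$transcript_id,
        terminal_exon_length_bp = r$terminal_exon_length_bp,
        coding_aa_in_terminal_exon = r$coding_aa_in_terminal_exon,
        single_large_exon = r$single_large_exon,
        polyA_signal_positions = paste(r$polyA_signal_positions,
                                       collapse = ","),
        has_polyA_signal = r$has_polyA_signal,
        shares_acceptor_with_backbone = r$shares_acceptor_with_backbone,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
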