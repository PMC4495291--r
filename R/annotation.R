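# Gene-model container: genes -> transcripts -> exons/CDS, all coordinates
# internal 0-based half-open. Exon and CDS tables are stored in transcript
# orientation (rank 1 = 5'-most exon of the mature transcript).

#' Construct a transcript
#'
#' Exon and CDS intervals are given in genomic coordinates (0-based
#' half-open) and are reordered internally so that row 1 is the 5'-most
#' exon in transcript orientation. Transcripts violating structural
#' invariants (overlapping exons, CDS not contained in exons, CDS length
#' not divisible by 3) are not rejected: they are carried with a
#' `malformed` flag and excluded from screens downstream.
#'
#' @param id,gene_id Transcript and parent gene identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, 0-based
#'   half-open).
#' @param cds Optional data.frame with columns `start`, `end`; must be a
#'   subset of exon space.
#' @param polyA_site Optional genomic position of the polyadenylation site.
#' @return A list of class `transcript`.
#' @export
transcript <- function(id, gene_id, contig, strand, exons,
                       cds = NULL, polyA_site = NULL) {
  stopifnot(nzchar(id), nzchar(gene_id), strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  ord <- order(exons$start, decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  exons$rank <- seq_len(nrow(exons))
  rownames(exons) <- NULL
  if (!is.null(cds) && nrow(cds) > 0) {
    cds <- as.data.frame(cds)[, c("start", "end")]
    cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
    cds <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(cds) <- NULL
  } else {
    cds <- data.frame(start = integer(0), end = integer(0))
  }
  t <- structure(list(id = id, gene_id = gene_id, contig = contig,
                      strand = strand, exons = exons, cds = cds,
                      polyA_site = polyA_site,
                      malformed = FALSE, malformed_reason = NA_character_),
                 class = "transcript")
  reason <- transcript_violation(t)
  if (!is.na(reason)) {
    t$malformed <- TRUE
    t$malformed_reason <- reason
  }
  t
}

# first violated invariant, or NA if well-formed
transcript_violation <- function(t) {
  ex <- t$exons[order(t$exons$start), , drop = FALSE]
  if (nrow(ex) == 0L) return("no exons")
  if (any(ex$end <= ex$start)) return("empty exon")
  if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
    return("overlapping exons")
  if (nrow(t$cds) > 0L) {
    contained <- vapply(seq_len(nrow(t$cds)), function(i) {
      any(t$exons$start <= t$cds$start[i] & t$cds$end[i] <= t$exons$end)
    }, logical(1))
    if (!all(contained)) return("CDS outside exons")
    if (cds_length(t) %% 3L != 0L) return("CDS length not divisible by 3")
  }
  NA_character_
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s (gene %s) %s%s  %d exon(s), CDS %d nt%s\n",
              x$id, x$gene_id, x$contig, x$strand, nrow(x$exons),
              cds_length(x),
              if (x$malformed) paste0("  [malformed: ", x$malformed_reason, "]")
              else ""))
  invisible(x)
}

#' Total CDS length of a transcript in nucleotides
#' @param t A `transcript`.
#' @return Integer length.
#' @export
cds_length <- function(t) {
  if (nrow(t$cds) == 0L) return(0L)
  sum(t$cds$end - t$cds$start)
}

#' Construct a gene
#'
#' @param id,name Gene identifier and display name.
#' @param transcripts List of [transcript()] objects; all must share contig
#'   and strand.
#' @return A list of class `gene` whose `interval` spans all transcripts.
#' @export
gene <- function(id, transcripts, name = id) {
  stopifnot(length(transcripts) >= 1L)
  contigs <- vapply(transcripts, `[[`, "", "contig")
  strands <- vapply(transcripts, `[[`, "", "strand")
  if (length(unique(contigs)) != 1L || length(unique(strands)) != 1L)
    stop("gene ", id, ": transcripts do not share contig/strand")
  starts <- vapply(transcripts, function(t) min(t$exons$start), integer(1))
  ends <- vapply(transcripts, function(t) max(t$exons$end), integer(1))
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  structure(list(id = id, name = name, transcripts = transcripts,
                 interval = genomic_interval(contigs[1], min(starts),
                                             max(ends), strands[1])),
            class = "gene")
}

#' @export
print.gene <- function(x, ...) {
  cat(sprintf("gene %s (%s) %s:[%d,%d)%s  %d transcript(s)\n",
              x$id, x$name, x$interval$contig, x$interval$start,
              x$interval$end, x$interval$strand, length(x$transcripts)))
  invisible(x)
}

guess_annotation_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext == "gtf") return("gtf")
  first <- readLines(path, n = 50L)
  if (any(grepl("^##gff-version", first))) return("gff3")
  if (any(grepl("\tgene_id ", first))) return("gtf")
  "gff3"
}

# named-line validation that rtracklayer's parser does not give us
validate_annotation_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i]) || startsWith(lines[i], "#")) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("parse error at line ", i, ": expected >= 8 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("parse error at line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("parse error at line ", i, ": end (", e, ") < start (", s, ")")
  }
  invisible(TRUE)
}

#' Read gene models from GTF or GFF3
#'
#' Coordinates (1-based inclusive on disk) are converted to the internal
#' 0-based half-open convention. Transcripts that violate structural
#' invariants are kept but flagged `malformed`; downstream screens skip
#' them. Codon phase across junctions is always derived from cumulative CDS
#' length; the GFF3 phase column is ignored.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return Named list of [gene()] objects, sorted by gene id.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  validate_annotation_lines(path)
  fmt <- guess_annotation_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  df$start0 <- df$start - 1L   # to 0-based half-open
  df$end0 <- df$end
  if (fmt == "gtf") {
    df$tx_id <- as.character(df$transcript_id %||% NA)
    df$g_id <- as.character(df$gene_id %||% NA)
    df$g_name <- if ("gene_name" %in% names(df))
      as.character(df$gene_name) else df$g_id
  } else {
    parent <- if ("Parent" %in% names(df))
      vapply(df$Parent, function(p) if (length(p)) as.character(p[1])
             else NA_character_, "") else rep(NA_character_, nrow(df))
    id <- if ("ID" %in% names(df)) as.character(df$ID)
          else rep(NA_character_, nrow(df))
    is_tx <- df$type %in% c("transcript", "mRNA")
    df$tx_id <- ifelse(is_tx, id, parent)
    df$g_id <- ifelse(df$type == "gene", id, ifelse(is_tx, parent, NA))
    df$g_name <- if ("Name" %in% names(df))
      as.character(df$Name) else df$g_id
  }

  tx_rows <- df[df$type %in% c("transcript", "mRNA"), , drop = FALSE]
  ex_rows <- df[df$type == "exon", , drop = FALSE]
  cds_rows <- df[df$type == "CDS", , drop = FALSE]
  tx_ids <- unique(stats::na.omit(c(tx_rows$tx_id, ex_rows$tx_id)))

  tx_gene <- stats::setNames(tx_rows$g_id, tx_rows$tx_id)
  transcripts <- lapply(tx_ids, function(tid) {
    ex <- ex_rows[ex_rows$tx_id %in% tid, , drop = FALSE]
    cd <- cds_rows[cds_rows$tx_id %in% tid, , drop = FALSE]
    if (nrow(ex) == 0L) return(NULL)
    gid <- tx_gene[tid]
    if (is.na(gid)) gid <- ex$g_id[1]
    if (is.na(gid)) gid <- tid
    transcript(id = tid, gene_id = gid, contig = as.character(ex$seqnames[1]),
               strand = ex$strand[1],
               exons = data.frame(start = ex$start0, end = ex$end0),
               cds = if (nrow(cd)) data.frame(start = cd$start0, end = cd$end0)
                     else NULL)
  })
  transcripts <- Filter(Negate(is.null), transcripts)

  gids <- vapply(transcripts, `[[`, "", "gene_id")
  gene_names <- stats::setNames(
    df$g_name[df$type == "gene"], df$g_id[df$type == "gene"])
  genes <- lapply(sort(unique(gids)), function(gid) {
    nm <- gene_names[gid]
    gene(gid, transcripts[gids == gid],
         name = if (is.na(nm) || is.null(nm)) gid else unname(nm))
  })
  stats::setNames(genes, vapply(genes, `[[`, "", "id"))
}

#' Write gene models as GTF
#'
#' Inverse of [read_gtf()] for models built in memory: internal 0-based
#' half-open coordinates are emitted as standard 1-based inclusive GTF.
#'
#' @param genes Named list of [gene()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  fmt_attr <- function(gid, tid = NULL) {
    if (is.null(tid)) sprintf('gene_id "%s";', gid)
    else sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
  }
  for (g in genes) {
    iv <- g$interval
    lines <- c(lines, paste(iv$contig, "retrodomain", "gene",
                            iv$start + 1L, iv$end, ".", iv$strand, ".",
                            fmt_attr(g$id), sep = "\t"))
    for (t in g$transcripts) {
      span <- range(c(t$exons$start, t$exons$end))
      lines <- c(lines, paste(t$contig, "retrodomain", "transcript",
                              min(t$exons$start) + 1L, max(t$exons$end),
                              ".", t$strand, ".",
                              fmt_attr(g$id, t$id), sep = "\t"))
      for (i in seq_len(nrow(t$exons)))
        lines <- c(lines, paste(t$contig, "retrodomain", "exon",
                                t$exons$start[i] + 1L, t$exons$end[i],
                                ".", t$strand, ".",
                                fmt_attr(g$id, t$id), sep = "\t"))
      for (i in seq_len(nrow(t$cds)))
        lines <- c(lines, paste(t$contig, "retrodomain", "CDS",
                                t$cds$start[i] + 1L, t$cds$end[i],
                                ".", t$strand, ".",
                                fmt_attr(g$id, t$id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Map a protein (amino-acid) range to its genomic footprint
#'
#' Amino acids `aa_start..aa_end` (1-based inclusive, relative to the CDS
#' translation) are mapped to genomic blocks, split at exon junctions. On
#' the minus strand blocks carry genomic coordinates but are ordered 5' to
#' 3' in transcript orientation.
#'
#' @param t A [transcript()] with a valid CDS.
#' @param aa_start,aa_end 1-based inclusive amino-acid range.
#' @param accession Label stored on the footprint (e.g. a Pfam accession).
#' @return A list of class `genomic_footprint` with fields `transcript_id`,
#'   `accession` and `blocks` (data.frame `contig`, `start`, `end`,
#'   `strand`).
#' @export
protein_to_genomic <- function(t, aa_start, aa_end, accession = NA_character_) {
  if (t$malformed) stop("transcript ", t$id, " is malformed: ",
                        t$malformed_reason)
  n_aa <- cds_length(t) %/% 3L
  if (aa_start < 1L || aa_end < aa_start || aa_end > n_aa)
    stop("domain out of bounds: aa ", aa_start, "..", aa_end,
         " on protein of length ", n_aa, " (", t$id, ")")
  nt_lo <- (aa_start - 1L) * 3L      # 0-based CDS offsets, half-open
  nt_hi <- aa_end * 3L
  blocks <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), strand = character(0))
  cum <- 0L
  for (i in seq_len(nrow(t$cds))) {
    s <- t$cds$start[i]; e <- t$cds$end[i]
    w <- e - s
    lo <- max(nt_lo, cum); hi <- min(nt_hi, cum + w)
    if (lo < hi) {
      if (t$strand == "+") {
        bs <- s + (lo - cum); be <- s + (hi - cum)
      } else {
        bs <- e - (hi - cum); be <- e - (lo - cum)
      }
      blocks <- rbind(blocks, data.frame(contig = t$contig, start = bs,
                                         end = be, strand = t$strand))
    }
    cum <- cum + w
  }
  rownames(blocks) <- NULL
  structure(list(transcript_id = t$id, accession = accession,
                 blocks = blocks),
            class = "genomic_footprint")
}

#' @export
print.genomic_footprint <- function(x, ...) {
  cat(sprintf("footprint %s|%s: %d block(s), %d nt\n", x$transcript_id,
              x$accession, nrow(x$blocks), sum(x$blocks$end - x$blocks$start)))
  invisible(x)
}

#' Write domain footprints as BED
#'
#' One BED line per footprint block; the name column is
#' `transcript_id|accession`.
#'
#' @param footprints List of `genomic_footprint` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_footprints_bed <- function(footprints, path) {
  lines <- unlist(lapply(footprints, function(fp) {
    b <- fp$blocks
    sprintf("%s\t%d\t%d\t%s|%s\t0\t%s", b$contig, b$start, b$end,
            fp$transcript_id, fp$accession, b$strand)
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

#' Flag transcripts whose CDS contains an internal stop codon
#'
#' @param genes Named list of genes.
#' @param genome A [Biostrings::DNAStringSet] of contig sequences.
#' @return The gene list with offending transcripts flagged `malformed`.
#' @export
flag_internal_stops <- function(genes, genome) {
  for (gi in seq_along(genes)) {
    for (ti in seq_along(genes[[gi]]$transcripts)) {
      t <- genes[[gi]]$transcripts[[ti]]
      if (t$malformed || cds_length(t) < 6L) next
      cds_seq <- transcript_cds_seq(t, genome)
      n_cod <- nchar(cds_seq) %/% 3L
      codons <- substring(cds_seq, 3L * (seq_len(n_cod) - 1L) + 1L,
                          3L * seq_len(n_cod))
      if (any(codons[-n_cod] %in% c("TAA", "TAG", "TGA"))) {
        genes[[gi]]$transcripts[[ti]]$malformed <- TRUE
        genes[[gi]]$transcripts[[ti]]$malformed_reason <- "internal stop codon"
      }
    }
  }
  genes
}

# spliced CDS sequence in transcript (sense) orientation
transcript_cds_seq <- function(t, genome) {
  contig <- as.character(genome[[t$contig]])
  parts <- vapply(seq_len(nrow(t$cds)), function(i) {
    s <- substr(contig, t$cds$start[i] + 1L, t$cds$end[i])
    if (t$strand == "-") revcomp(s) else s
  }, "")
  paste(parts, collapse = "")
}

# spliced exon sequence of one exon row in sense orientation
exon_seq <- function(t, exon_row, genome) {
  contig <- as.character(genome[[t$contig]])
  s <- substr(contig, t$exons$start[exon_row] + 1L, t$exons$end[exon_row])
  if (t$strand == "-") revcomp(s) else s
}
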