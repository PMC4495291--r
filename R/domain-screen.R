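# Screen for genes whose alternative transcripts carry different protein
# domains that are mutually exclusively spliced: each isoform has a domain
# the other lacks, neither domain's genomic footprint touches any exon of
# the other isoform, and the two isoforms share a common exon backbone.

#' Read per-transcript protein-domain hits
#'
#' Expects a TSV in hmmscan/Pfam style with columns `transcript_id`,
#' `accession`, `name`, `aa_start`, `aa_end`, `evalue` (header required;
#' extra columns ignored).
#'
#' @param path Path to the TSV.
#' @return data.frame of domain hits.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("cannot read domain hits: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "accession", "name", "aa_start", "aa_end",
            "evalue")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("domain hit table lacks column(s): ", paste(missing, collapse = ", "))
  df$aa_start <- as.integer(df$aa_start)
  df$aa_end <- as.integer(df$aa_end)
  df$evalue <- as.numeric(df$evalue)
  if (any(df$evalue < 0, na.rm = TRUE)) stop("negative e-value in hit table")
  df[, need]
}

# domain identity is by accession with any version suffix stripped
strip_accession_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Genomic footprints of a transcript's domain hits
#'
#' Hits with e-value above `evalue_max` are dropped; each retained hit is
#' mapped through [protein_to_genomic()].
#'
#' @param t A [transcript()].
#' @param hits data.frame of domain hits (see [read_domain_hits()]); all
#'   rows must reference `t`.
#' @param evalue_max Retention threshold (default `1e-5`).
#' @return List of `genomic_footprint` objects (possibly empty).
#' @export
domain_footprints <- function(t, hits, evalue_max = 1e-5) {
  if (nrow(hits) == 0L) return(list())
  if (!all(hits$transcript_id == t$id))
    stop("hit references transcript ", setdiff(hits$transcript_id, t$id)[1],
         ", not ", t$id)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  lapply(seq_len(nrow(hits)), function(i)
    protein_to_genomic(t, hits$aa_start[i], hits$aa_end[i],
                       strip_accession_version(hits$accession[i])))
}

footprint_overlaps_exons <- function(fp, t) {
  any(vapply(seq_len(nrow(fp$blocks)), function(i)
    any(ranges_overlap(fp$blocks$start[i], fp$blocks$end[i],
                       t$exons$start, t$exons$end)), logical(1)))
}

# exact-coordinate shared exons (the "backbone")
shared_backbone_count <- function(ta, tb) {
  a <- paste(ta$exons$start, ta$exons$end)
  b <- paste(tb$exons$start, tb$exons$end)
  length(intersect(a, b))
}

#' Is a pair of domain footprints mutually exclusively spliced?
#'
#' True iff (i) no block of `fa` overlaps any exon of `tb`, (ii) no block
#' of `fb` overlaps any exon of `ta`, and (iii) the two transcripts share
#' at least one exon with identical coordinates. Overlap means at least one
#' shared base.
#'
#' @param fa,fb `genomic_footprint`s carried by `ta` and `tb` respectively.
#' @param ta,tb The two [transcript()]s (same gene).
#' @return Logical scalar.
#' @export
is_mutually_exclusive <- function(fa, tb, fb, ta) {
  !footprint_overlaps_exons(fa, tb) &&
    !footprint_overlaps_exons(fb, ta) &&
    shared_backbone_count(ta, tb) >= 1L
}

#' Screen genes for mutually exclusively spliced domain isoforms
#'
#' For every gene, every unordered pair of well-formed transcripts whose
#' retained-domain accession sets differ is evaluated. A pair is flagged
#' `mutually_exclusive` when each transcript carries at least one domain
#' the other lacks and at least one such domain on each side passes
#' [is_mutually_exclusive()]. Pairs where only one side gains a domain are
#' reported with `mutually_exclusive = FALSE` for review. Output is
#' deterministic: sorted by gene id, then transcript ids.
#'
#' @param genes Named list of [gene()]s.
#' @param hits data.frame of domain hits across all transcripts.
#' @param evalue_max Domain-hit retention threshold (default `1e-5`).
#' @return data.frame with columns `gene_id`, `transcript_a`,
#'   `transcript_b`, `domains_only_in_a`, `domains_only_in_b` (comma
#'   separated), `shared_backbone_exons`, `mutually_exclusive`.
#' @export
screen_genes <- function(genes, hits, evalue_max = 1e-5) {
  hits$accession <- strip_accession_version(hits$accession)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  hits_by_tx <- split(hits, hits$transcript_id)
  rows <- list()

  for (g in genes[order(names(genes))]) {
    txs <- Filter(function(t) !t$malformed, g$transcripts)
    if (length(txs) < 2L) next
    txs <- txs[order(vapply(txs, `[[`, "", "id"))]
    for (i in seq_len(length(txs) - 1L)) {
      for (j in seq((i + 1L), length(txs))) {
        ta <- txs[[i]]; tb <- txs[[j]]
        ha <- hits_by_tx[[ta$id]]
        hb <- hits_by_tx[[tb$id]]
        acc_a <- sort(unique(if (is.null(ha)) character(0) else ha$accession))
        acc_b <- sort(unique(if (is.null(hb)) character(0) else hb$accession))
        if (identical(acc_a, acc_b)) next
        only_a <- setdiff(acc_a, acc_b)
        only_b <- setdiff(acc_b, acc_a)
        me_a <- only_a[vapply(only_a, function(acc) {
          sub <- ha[ha$accession == acc, , drop = FALSE]
          any(vapply(seq_len(nrow(sub)), function(k) {
            fa <- protein_to_genomic(ta, sub$aa_start[k], sub$aa_end[k], acc)
            !footprint_overlaps_exons(fa, tb)
          }, logical(1)))
        }, logical(1))]
        me_b <- only_b[vapply(only_b, function(acc) {
          sub <- hb[hb$accession == acc, , drop = FALSE]
          any(vapply(seq_len(nrow(sub)), function(k) {
            fb <- protein_to_genomic(tb, sub$aa_start[k], sub$aa_end[k], acc)
            !footprint_overlaps_exons(fb, ta)
          }, logical(1)))
        }, logical(1))]
        backbone <- shared_backbone_count(ta, tb)
        me <- length(me_a) >= 1L && length(me_b) >= 1L && backbone >= 1L
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$id, transcript_a = ta$id, transcript_b = tb$id,
          domains_only_in_a = paste(only_a, collapse = ","),
          domains_only_in_b = paste(only_b, collapse = ","),
          shared_backbone_exons = backbone,
          mutually_exclusive = me,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), transcript_a = character(0),
                      transcript_b = character(0),
                      domains_only_in_a = character(0),
                      domains_only_in_b = character(0),
                      shared_backbone_exons = integer(0),
                      mutually_exclusive = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$transcript_a, out$transcript_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write screen candidates as TSV
#' @param candidates Output of [screen_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
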