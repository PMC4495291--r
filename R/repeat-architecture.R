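# From genome-wide similarity hits to retroelement models: chain hits into
# loci, pull flanked sequence, order conserved-domain hits relative to the
# GAG-homologous region, and discriminate inverted vs direct terminal
# repeats by aligning the element termini against each other.

#' Default mapping from conserved-domain labels to element ORF roles
#'
#' Maps CDD-style subtype labels to the four ORF roles of a DIRS1-like
#' element. User-extensible: supply your own named vector wherever a
#' `role_map` argument is accepted.
#' @return Named character vector label -> role in `{GAG, RT, RNase, YR}`.
#' @export
default_role_map <- function() {
  c(LAP2alpha = "GAG",
    GAG_DIRS1 = "GAG",
    RT_DIRS1 = "RT",
    RNase_HI_RT_DIRS1 = "RNase",
    INT_phage = "YR",
    YR_recombinase = "YR")
}

#' Read genome-wide similarity hits (BLAST outfmt-6-like TSV)
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore, and optionally a 13th label
#' column (defaults to qseqid). No header. Subject strand is inferred from
#' coordinate orientation: `sstart > send` means minus strand.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `query_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `percent_identity`, `evalue`, `label`.
#' @export
read_similarity_hits <- function(path) {
  if (!file.exists(path)) stop("cannot read similarity hits: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L)
    stop("expected >= 12 outfmt-6 columns, got ", ncol(df))
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  label <- if (ncol(df) >= 13L) as.character(df[[13L]]) else df$qseqid
  strand <- ifelse(df$sstart > df$send, "-", "+")
  start0 <- pmin(df$sstart, df$send) - 1L
  end0 <- pmax(df$sstart, df$send)
  if (any(df$evalue < 0)) stop("negative e-value in similarity hits")
  data.frame(query_id = df$qseqid, contig = df$sseqid,
             start = as.integer(start0), end = as.integer(end0),
             strand = strand, percent_identity = df$pident,
             evalue = df$evalue, label = label, stringsAsFactors = FALSE)
}

#' Chain similarity hits into loci
#'
#' Single-linkage chaining: same-contig, same-strand hits whose intervals
#' are within `max_gap_bp` of each other are merged into one locus. Every
#' input hit belongs to exactly one locus. Loci are sorted by contig then
#' start and assigned sequential ids.
#'
#' @param hits data.frame from [read_similarity_hits()].
#' @param max_gap_bp Maximum gap between chained intervals (default 1000).
#' @return List of `locus` objects: `id`, `contig`, `strand`, `start`,
#'   `end` (members' span), `member_hits`.
#' @export
cluster_hits <- function(hits, max_gap_bp = 1000L) {
  if (nrow(hits) == 0L) return(list())
  hits <- hits[order(hits$contig, hits$strand, hits$start, hits$end), ,
               drop = FALSE]
  key <- paste(hits$contig, hits$strand)
  loci <- list()
  for (k in unique(key)) {
    sub <- hits[key == k, , drop = FALSE]
    chain_start <- 1L
    cur_end <- sub$end[1]
    for (i in seq_len(nrow(sub) + 1L)) {
      new_chain <- i > nrow(sub) ||
        (i > 1L && sub$start[i] - cur_end > max_gap_bp)
      if (new_chain) {
        members <- sub[chain_start:(i - 1L), , drop = FALSE]
        rownames(members) <- NULL
        loci[[length(loci) + 1L]] <- list(
          contig = members$contig[1], strand = members$strand[1],
          start = min(members$start), end = max(members$end),
          member_hits = members)
        chain_start <- i
        if (i <= nrow(sub)) cur_end <- sub$end[i]
      } else if (i <= nrow(sub)) {
        cur_end <- max(cur_end, sub$end[i])
      }
    }
  }
  ord <- order(vapply(loci, `[[`, "", "contig"),
               vapply(loci, `[[`, 0L, "start"),
               vapply(loci, `[[`, 0L, "end"))
  loci <- loci[ord]
  for (i in seq_along(loci)) {
    loci[[i]]$id <- sprintf("locus_%05d", i)
    loci[[i]] <- structure(loci[[i]], class = "locus")
  }
  loci
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("%s %s:[%d,%d)%s  %d hit(s)\n", x$id, x$contig, x$start,
              x$end, x$strand, nrow(x$member_hits)))
  invisible(x)
}

#' Extract a locus with flanking sequence
#'
#' Returns the sequence of `[start - flank_bp, end + flank_bp)` clamped to
#' the contig bounds. Minus-strand loci are reverse-complemented so the
#' returned sequence is in element orientation.
#'
#' @param locus A `locus` from [cluster_hits()].
#' @param genome [Biostrings::DNAStringSet].
#' @param flank_bp Flank size on each side (default 5000).
#' @return List with `seq` (character), `interval` (the resolved genomic
#'   interval) and `locus_id`.
#' @export
extract_flanks <- function(locus, genome, flank_bp = 5000L) {
  if (!locus$contig %in% names(genome))
    stop("contig ", locus$contig, " absent from genome")
  clen <- Biostrings::width(genome[names(genome) == locus$contig])[1]
  s <- max(0L, locus$start - as.integer(flank_bp))
  e <- min(clen, locus$end + as.integer(flank_bp))
  seq <- as.character(Biostrings::subseq(genome[[locus$contig]], s + 1L, e))
  if (locus$strand == "-") seq <- revcomp(seq)
  list(seq = seq,
       interval = genomic_interval(locus$contig, s, e, locus$strand),
       locus_id = locus$id)
}

#' Infer element architecture from co-located domain hits
#'
#' Hit labels are mapped to ORF roles, ordered by offset from the locus 5'
#' end in element orientation, and the locus is classified: `DIRS1-like`
#' when GAG, RT and RNase are all present in that 5' to 3' order (YR, when
#' present, must follow RNase); `partial` when a required role is missing;
#' `inconsistent` when the order is violated; `unclassified` when no label
#' maps to a role.
#'
#' @param locus A `locus`.
#' @param domain_hits data.frame of hits within the flanked region (same
#'   columns as [read_similarity_hits()]).
#' @param role_map Named vector label -> role; see [default_role_map()].
#' @return List of class `element_architecture` with `locus_id`,
#'   `ordered_labels` (data.frame `label`, `role`, `offset_bp`) and
#'   `classification`.
#' @export
infer_architecture <- function(locus, domain_hits,
                               role_map = default_role_map()) {
  offs <- if (locus$strand == "+") domain_hits$start - locus$start
          else locus$end - domain_hits$end
  roles <- unname(role_map[domain_hits$label])
  ord <- order(offs, domain_hits$label)
  tab <- data.frame(label = domain_hits$label[ord],
                    role = roles[ord],
                    offset_bp = as.integer(offs[ord]),
                    stringsAsFactors = FALSE)
  role_off <- function(r) {
    o <- tab$offset_bp[!is.na(tab$role) & tab$role == r]
    if (length(o)) min(o) else NA_integer_
  }
  g <- role_off("GAG"); rt <- role_off("RT"); rn <- role_off("RNase")
  yr <- role_off("YR")
  cls <- if (all(is.na(c(g, rt, rn, yr)))) {
    "unclassified"
  } else if (any(is.na(c(g, rt, rn)))) {
    "partial"
  } else if (g < rt && rt < rn && (is.na(yr) || yr > rn)) {
    "DIRS1-like"
  } else {
    "inconsistent"
  }
  structure(list(locus_id = locus$id, ordered_labels = tab,
                 classification = cls, terminal_repeat = NULL),
            class = "element_architecture")
}

#' @export
print.element_architecture <- function(x, ...) {
  cat(sprintf("%s: %s [%s]%s\n", x$locus_id, x$classification,
              paste(x$ordered_labels$label, collapse = " < "),
              if (!is.null(x$terminal_repeat))
                paste0(" terminal repeat: ", x$terminal_repeat$kind) else ""))
  invisible(x)
}

#' Discriminate inverted vs direct terminal repeats
#'
#' Locally aligns the 5'-terminal window of the sequence against (a) the
#' 3'-terminal window (a direct match implies LTRs) and (b) its reverse
#' complement (a match implies ITRs), with match/mismatch/gap scores of
#' +1/-1/-2 by default. The better-scoring qualifying alignment (length at
#' least `min_repeat_len`, identity at least `min_identity` percent)
#' determines the call; ties are broken toward ITR with a warning.
#'
#' @param element_seq Nucleotide string; length must be at least
#'   `2 * window`.
#' @param window Terminal window size (default 1500).
#' @param min_repeat_len Minimum qualifying alignment length (default 20).
#' @param min_identity Minimum qualifying percent identity (default 80).
#' @param match,mismatch,gap Alignment scores (gap is per gapped column).
#' @return List of class `terminal_repeat_call`: `kind` in
#'   `{ITR, LTR, none}`, `repeat_length_bp`, `percent_identity`,
#'   `five_prime_span`, `three_prime_span` (0-based half-open offsets
#'   within `element_seq`).
#' @export
detect_terminal_repeats <- function(element_seq, window = 1500L,
                                    min_repeat_len = 20L,
                                    min_identity = 80,
                                    match = 1L, mismatch = -1L, gap = -2L) {
  n <- nchar(element_seq)
  window <- as.integer(window)
  if (n < 2L * window)
    stop("sequence (", n, " nt) shorter than twice the terminal window (",
         window, " nt)")
  w5 <- substr(element_seq, 1L, window)
  w3 <- substr(element_seq, n - window + 1L, n)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)

  align_stats <- function(subject_seq, inverted) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(w5), Biostrings::DNAString(subject_seq),
      type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = abs(gap))
    len <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- if (len > 0L) 100 * Biostrings::nmatch(aln) / len else 0
    p <- Biostrings::pattern(aln)
    s <- Biostrings::subject(aln)
    # subject offsets back into element coordinates (0-based half-open)
    ss <- Biostrings::start(s) - 1L
    se <- Biostrings::end(s)
    if (inverted) { tmp <- ss; ss <- window - se; se <- window - tmp }
    list(score = Biostrings::score(aln), length = len, identity = ident,
         five = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
         three = c(n - window + ss, n - window + se))
  }

  direct <- align_stats(w3, inverted = FALSE)
  inverted <- align_stats(revcomp(w3), inverted = TRUE)

  qualifies <- function(a) a$length >= min_repeat_len &&
    a$identity >= min_identity
  dq <- qualifies(direct); iq <- qualifies(inverted)
  if (!dq && !iq) {
    best <- if (inverted$score >= direct$score) inverted else direct
    return(structure(list(kind = "none",
                          repeat_length_bp = best$length,
                          percent_identity = best$identity,
                          five_prime_span = best$five,
                          three_prime_span = best$three),
                     class = "terminal_repeat_call"))
  }
  if (dq && iq && direct$score == inverted$score)
    warning("direct and inverted terminal alignments tie; calling ITR")
  pick_itr <- iq && (!dq || inverted$score >= direct$score)
  best <- if (pick_itr) inverted else direct
  structure(list(kind = if (pick_itr) "ITR" else "LTR",
                 repeat_length_bp = best$length,
                 percent_identity = best$identity,
                 five_prime_span = best$five,
                 three_prime_span = best$three),
            class = "terminal_repeat_call")
}

#' @export
print.terminal_repeat_call <- function(x, ...) {
  cat(sprintf("terminal repeat: %s (%d bp, %.1f%% identity)\n", x$kind,
              x$repeat_length_bp, x$percent_identity))
  invisible(x)
}

#' Classify one locus end to end
#'
#' Extracts the flanked sequence, infers ORF architecture from the locus's
#' member hits, and scans for terminal repeats. Because similarity hits
#' mark the ORF region while the element's termini lie just outside it,
#' the terminal-repeat scan widens its window to `flank_bp +
#' terminal_window` so each window covers one flank plus the element edge.
#'
#' @param locus A `locus`.
#' @param genome [Biostrings::DNAStringSet].
#' @param role_map Label-to-role map.
#' @param flank_bp Flank size (default 5000).
#' @param terminal_window Extra window reaching into the locus (default
#'   1500).
#' @param ... Passed to [detect_terminal_repeats()].
#' @return An `element_architecture` with `terminal_repeat` filled in.
#' @export
classify_locus <- function(locus, genome, role_map = default_role_map(),
                           flank_bp = 5000L, terminal_window = 1500L, ...) {
  arch <- infer_architecture(locus, locus$member_hits, role_map)
  fl <- extract_flanks(locus, genome, flank_bp)
  win <- min(flank_bp + terminal_window, nchar(fl$seq) %/% 2L)
  arch$terminal_repeat <- detect_terminal_repeats(fl$seq, window = win, ...)
  arch$flank_interval <- fl$interval
  arch
}

#' Tabulate label and classification counts
#'
#' @param architectures List of `element_architecture`s.
#' @return List with `labels` (data.frame `label`, `count`, sorted by
#'   label) and `classifications` (data.frame `classification`, `count`).
#' @export
summarize_labels <- function(architectures) {
  labels <- unlist(lapply(architectures,
                          function(a) a$ordered_labels$label))
  cls <- vapply(architectures, `[[`, "", "classification")
  lab_tab <- if (length(labels)) {
    tt <- table(labels)
    data.frame(label = names(tt), count = as.integer(tt),
               stringsAsFactors = FALSE)
  } else data.frame(label = character(0), count = integer(0))
  cls_tab <- if (length(cls)) {
    tt <- table(cls)
    data.frame(classification = names(tt), count = as.integer(tt),
               stringsAsFactors = FALSE)
  } else data.frame(classification = character(0), count = integer(0))
  lab_tab <- lab_tab[order(lab_tab$label), , drop = FALSE]
  rownames(lab_tab) <- NULL
  cls_tab <- cls_tab[order(cls_tab$classification), , drop = FALSE]
  rownames(cls_tab) <- NULL
  list(labels = lab_tab, classifications = cls_tab)
}

#' Write loci as BED
#' @param loci List of `locus` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  lines <- vapply(loci, function(l)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", l$contig, l$start, l$end, l$id,
            nrow(l$member_hits), l$strand), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write element models as GFF3
#'
#' Emits one `element` feature per architecture plus `orf_region` children
#' for each mapped role hit and `terminal_repeat` children when a repeat
#' was called.
#'
#' @param architectures List of `element_architecture`s from
#'   [classify_locus()].
#' @param loci The matching list of `locus` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_gff3 <- function(architectures, loci, path) {
  by_id <- stats::setNames(loci, vapply(loci, `[[`, "", "id"))
  lines <- "##gff-version 3"
  for (a in architectures) {
    l <- by_id[[a$locus_id]]
    lines <- c(lines, sprintf(
      "%s\tretrodomain\telement\t%d\t%d\t.\t%s\t.\tID=%s;classification=%s",
      l$contig, l$start + 1L, l$end, l$strand, a$locus_id, a$classification))
    m <- l$member_hits
    for (i in seq_len(nrow(m))) {
      lines <- c(lines, sprintf(
        "%s\tretrodomain\torf_region\t%d\t%d\t.\t%s\t.\tParent=%s;label=%s",
        m$contig[i], m$start[i] + 1L, m$end[i], m$strand[i], a$locus_id,
        m$label[i]))
    }
    tr <- a$terminal_repeat
    if (!is.null(tr) && tr$kind != "none" && !is.null(a$flank_interval)) {
      fi <- a$flank_interval
      for (span in list(tr$five_prime_span, tr$three_prime_span)) {
        gs <- if (fi$strand == "+") fi$start + span[1]
              else fi$end - span[2]
        ge <- gs + (span[2] - span[1])
        lines <- c(lines, sprintf(
          "%s\tretrodomain\tterminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s;kind=%s",
          fi$contig, gs + 1L, ge, fi$strand, a$locus_id, tr$kind))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-locus architecture summary as TSV
#' @param architectures List of `element_architecture`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_summary <- function(architectures, path) {
  rows <- lapply(architectures, function(a) data.frame(
    locus_id = a$locus_id,
    classification = a$classification,
    labels = paste(a$ordered_labels$label, collapse = ","),
    terminal_repeat = if (is.null(a$terminal_repeat)) "NA"
                      else a$terminal_repeat$kind,
    repeat_length_bp = if (is.null(a$terminal_repeat)) NA_integer_
                       else a$terminal_repeat$repeat_length_bp,
    repeat_identity = if (is.null(a$terminal_repeat)) NA_real_
                      else round(a$terminal_repeat$percent_identity, 2),
    stringsAsFactors = FALSE))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
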