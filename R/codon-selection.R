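# Counting-based dN/dS on a codon alignment with a fixed rooted tree.
# Sites are counted per codon in the Nei-Gojobori style (mutations to stop
# codons excluded, S + N renormalised to 3); substitutions are counted per
# branch after codon-level Fitch parsimony reconstruction of ancestral
# states, averaging synonymous/nonsynonymous changes over all minimal
# mutational pathways that avoid stop codons.

.rd_cache <- new.env(parent = emptyenv())

# codons in classic genetic-code table order (T, C, A, G); this order is
# also the deterministic tie-break in ancestral reconstruction
all_codons <- function() {
  if (!is.null(.rd_cache$codons)) return(.rd_cache$codons)
  b <- c("T", "C", "A", "G")
  cods <- character(64)
  k <- 0L
  for (n1 in b) for (n2 in b) for (n3 in b) {
    k <- k + 1L
    cods[k] <- paste0(n1, n2, n3)
  }
  .rd_cache$codons <- cods
  cods
}

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

sense_codons <- function() {
  cods <- all_codons()
  cods[codon_aa(cods) != "*"]
}

is_stop <- function(codon) codon_aa(codon) == "*"

# the nine single-nucleotide mutants of a codon
codon_mutants <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (pos in 1:3) {
    cur <- substr(codon, pos, pos)
    for (bse in setdiff(bases, cur)) {
      m <- codon
      substr(m, pos, pos) <- bse
      out <- c(out, m)
    }
  }
  out
}

is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") && b2 %in% c("A", "G")) ||
    (b1 %in% c("C", "T") && b2 %in% c("C", "T"))
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Over the nine single-nucleotide mutants of the codon, mutations to stop
#' codons are excluded from the denominator, and the synonymous fraction is
#' rescaled to three sites: `S = 3 * syn / non_stop`, `N = 3 - S`.
#'
#' @param codon A sense codon (3-mer over ACGT).
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% all_codons() || is_stop(codon))
    stop("count_sites requires a sense codon, got '", codon, "'")
  aa0 <- codon_aa(codon)
  mut <- codon_mutants(codon)
  aam <- codon_aa(mut)
  nonstop <- aam != "*"
  syn <- sum(aam[nonstop] == aa0)
  S <- 3 * syn / sum(nonstop)
  c(S = S, N = 3 - S)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Pathway-averaged substitution counts between two codons
#'
#' Averages synonymous and nonsynonymous change counts over all minimal
#' mutational pathways from `codon_a` to `codon_b` that avoid stop-codon
#' intermediates. If every pathway passes through a stop, all minimal
#' pathways are used and the result carries the attribute
#' `stop_blocked = TRUE`.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(Sd = ..., Nd = ...)`; symmetric in its
#'   arguments.
#' @export
count_substitutions <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (is_stop(codon_a) || is_stop(codon_b))
    stop("count_substitutions requires sense codons")
  diffpos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  if (!length(diffpos)) return(c(Sd = 0, Nd = 0))
  paths <- permutations_of(diffpos)
  walk <- function(perm) {
    cur <- codon_a
    S <- 0; N <- 0; valid <- TRUE
    for (pos in perm) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop(nxt)) valid <- FALSE
      # steps touching a stop codon (possible only on fallback paths)
      # are never counted as synonymous
      if (!is_stop(nxt) && !is_stop(cur) &&
          codon_aa(cur) == codon_aa(nxt)) S <- S + 1 else N <- N + 1
      cur <- nxt
    }
    list(S = S, N = N, valid = valid)
  }
  res <- lapply(paths, walk)
  ok <- vapply(res, `[[`, logical(1), "valid")
  blocked <- !any(ok)
  if (blocked) ok <- rep(TRUE, length(res))
  S <- mean(vapply(res[ok], `[[`, numeric(1), "S"))
  N <- mean(vapply(res[ok], `[[`, numeric(1), "N"))
  out <- c(Sd = S, Nd = N)
  if (blocked) attr(out, "stop_blocked") <- TRUE
  out
}

# cached 61 x 61 pathway-count matrices and per-codon site counts
substitution_tables <- function() {
  if (!is.null(.rd_cache$subs)) return(.rd_cache$subs)
  sc <- sense_codons()
  n <- length(sc)
  Sd <- matrix(0, n, n, dimnames = list(sc, sc))
  Nd <- matrix(0, n, n, dimnames = list(sc, sc))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (i < j) {
        cs <- count_substitutions(sc[i], sc[j])
        Sd[i, j] <- cs[["Sd"]]; Nd[i, j] <- cs[["Nd"]]
      } else {
        Sd[i, j] <- Sd[j, i]; Nd[i, j] <- Nd[j, i]
      }
    }
  }
  sites <- t(vapply(sc, count_sites, c(S = 0, N = 0)))
  .rd_cache$subs <- list(Sd = Sd, Nd = Nd, sites = sites)
  .rd_cache$subs
}

#' Construct a codon alignment
#'
#' @param sequences Named character vector of aligned nucleotide
#'   sequences. All must have equal length divisible by 3; gaps must be
#'   whole-codon (`---`); stop codons are only tolerated as the final
#'   codon of a sequence.
#' @return List of class `codon_alignment` with `sequences` and
#'   `length_nt`.
#' @export
codon_alignment <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 2L,
            !is.null(names(sequences)))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences differ in length")
  if (lens[1] %% 3L != 0L) stop("alignment length not divisible by 3")
  n_cod <- lens[1] %/% 3L
  for (nm in names(sequences)) {
    cods <- substring(sequences[[nm]], 3L * (seq_len(n_cod) - 1L) + 1L,
                      3L * seq_len(n_cod))
    gapped <- grepl("-", cods, fixed = TRUE)
    if (any(gapped & cods != "---"))
      stop("sequence ", nm, " has a partial-codon gap")
    sense <- cods[!gapped & !grepl("N", cods)]
    internal <- utils::head(sense, -1L)
    if (any(internal %in% c("TAA", "TAG", "TGA")))
      stop("sequence ", nm, " contains an internal stop codon")
  }
  structure(list(sequences = sequences, length_nt = unname(lens[1])),
            class = "codon_alignment")
}

#' Read a codon alignment from FASTA
#' @param path FASTA path.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  if (!file.exists(path)) stop("cannot read alignment: ", path)
  x <- Biostrings::readDNAStringSet(path)
  codon_alignment(stats::setNames(as.character(x), names(x)))
}

#' Write a codon alignment as FASTA
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  x <- Biostrings::DNAStringSet(aln$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# codon matrix (taxa x columns) from an alignment
codon_matrix <- function(aln) {
  n_cod <- aln$length_nt %/% 3L
  m <- vapply(aln$sequences, function(s)
    substring(s, 3L * (seq_len(n_cod) - 1L) + 1L, 3L * seq_len(n_cod)),
    character(n_cod))
  t(matrix(m, nrow = n_cod, ncol = length(aln$sequences),
           dimnames = list(NULL, names(aln$sequences))))
}

check_tree_alignment <- function(aln, tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  taxa <- names(aln$sequences)
  if (!setequal(tree$tip.label, taxa))
    stop("tree tips and alignment taxa differ: ",
         paste(union(setdiff(tree$tip.label, taxa),
                     setdiff(taxa, tree$tip.label)), collapse = ", "))
  invisible(TRUE)
}

#' Codon-level Fitch parsimony reconstruction of ancestral states
#'
#' Per unmasked column, a Fitch down-pass computes candidate state sets
#' and an up-pass assigns one codon per internal node. Ambiguities (at the
#' root, or where the parent state is not in a child's set) are broken
#' deterministically by genetic-code table order (bases ordered T, C, A,
#' G). Columns containing a gap or N in any taxon are masked.
#'
#' @param aln A [codon_alignment()].
#' @param tree Rooted `phylo` tree whose tips match the alignment taxa.
#' @return List: `states` (matrix, rows = tree nodes in ape numbering,
#'   columns = codon columns; `NA` where masked), `used_columns` (logical).
#' @export
reconstruct_ancestors <- function(aln, tree) {
  check_tree_alignment(aln, tree)
  cm <- codon_matrix(aln)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_col <- ncol(cm)
  cm <- cm[tree$tip.label, , drop = FALSE]  # rows follow tip numbering

  used <- apply(cm, 2, function(col) all(col %in% sense_codons()))
  rank <- stats::setNames(seq_along(all_codons()), all_codons())

  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  parents_po <- unique(edges[, 1])  # children always precede parents
  children_of <- split(edges[, 2], edges[, 1])
  root <- parents_po[length(parents_po)]

  states <- matrix(NA_character_, nrow = n_tip + n_node, ncol = n_col)
  sets <- vector("list", n_tip + n_node)

  first_by_rank <- function(set) set[which.min(rank[set])]

  for (j in which(used)) {
    for (i in seq_len(n_tip)) sets[[i]] <- cm[i, j]
    for (p in parents_po) {
      kids <- children_of[[as.character(p)]]
      s <- sets[[kids[1]]]
      for (k in kids[-1]) {
        inter <- intersect(s, sets[[k]])
        s <- if (length(inter)) inter else union(s, sets[[k]])
      }
      sets[[p]] <- s
    }
    states[root, j] <- first_by_rank(sets[[root]])
    for (e in rev(seq_len(nrow(edges)))) {  # preorder: root towards tips
      p <- edges[e, 1]; ch <- edges[e, 2]
      if (ch <= n_tip) { states[ch, j] <- cm[ch, j]; next }
      states[ch, j] <- if (states[p, j] %in% sets[[ch]]) states[p, j]
                       else first_by_rank(sets[[ch]])
    }
  }
  states[seq_len(n_tip), used] <- cm[, used]
  list(states = states, used_columns = used, root = root, edges = edges)
}

#' Counting-based (SLAC-style) overall dN/dS
#'
#' For every branch and unmasked column, pathway-averaged synonymous and
#' nonsynonymous changes between the reconstructed parent codon and the
#' child codon are accumulated. Site totals are the across-taxa average of
#' leaf-codon site counts per column, summed over columns and multiplied
#' by the number of tree branches, so that `dN = N_subs / N_sites` and
#' `dS = S_subs / S_sites` are per-branch-comparable; the ratio
#' `omega = dN/dS` is invariant to this common scale.
#'
#' @param aln A [codon_alignment()].
#' @param tree Rooted `phylo` tree matching the alignment taxa.
#' @return List of class `dnds_result`: `N_sites`, `S_sites`, `N_subs`,
#'   `S_subs`, `dN`, `dS`, `omega`, `omega_defined`, `n_columns_used`,
#'   `n_branches`, `per_branch` (data.frame), `per_column` (data.frame).
#' @export
slac_dnds <- function(aln, tree) {
  check_tree_alignment(aln, tree)
  tab <- substitution_tables()
  rec <- reconstruct_ancestors(aln, tree)
  cm <- codon_matrix(aln)[tree$tip.label, , drop = FALSE]
  used <- rec$used_columns
  n_taxa <- nrow(cm)
  edges <- rec$edges
  n_branch <- nrow(edges)

  # per-column site counts: across-taxa average of leaf-codon sites
  S_col <- rep(NA_real_, ncol(cm)); N_col <- rep(NA_real_, ncol(cm))
  for (j in which(used)) {
    s <- mean(tab$sites[cm[, j], "S"])
    S_col[j] <- s; N_col[j] <- 3 - s
  }
  S_sites <- sum(S_col[used]) * n_branch
  N_sites <- sum(N_col[used]) * n_branch

  Sd_col <- rep(0, ncol(cm)); Nd_col <- rep(0, ncol(cm))
  Sd_br <- rep(0, n_branch); Nd_br <- rep(0, n_branch)
  for (j in which(used)) {
    st <- rec$states[, j]
    for (e in seq_len(n_branch)) {
      p <- st[edges[e, 1]]; ch <- st[edges[e, 2]]
      if (p != ch) {
        sd <- tab$Sd[p, ch]; nd <- tab$Nd[p, ch]
        Sd_col[j] <- Sd_col[j] + sd; Nd_col[j] <- Nd_col[j] + nd
        Sd_br[e] <- Sd_br[e] + sd; Nd_br[e] <- Nd_br[e] + nd
      }
    }
  }
  S_subs <- sum(Sd_col[used]); N_subs <- sum(Nd_col[used])
  dS <- if (S_sites > 0) S_subs / S_sites else 0
  dN <- if (N_sites > 0) N_subs / N_sites else 0
  omega_defined <- dS > 0
  node_name <- function(i)
    ifelse(i <= length(tree$tip.label), tree$tip.label[i],
           paste0("node", i))
  structure(list(
    N_sites = N_sites, S_sites = S_sites,
    N_subs = N_subs, S_subs = S_subs,
    dN = dN, dS = dS,
    omega = if (omega_defined) dN / dS else NA_real_,
    omega_defined = omega_defined,
    n_columns_used = sum(used), n_branches = n_branch,
    per_branch = data.frame(parent = node_name(edges[, 1]),
                            child = node_name(edges[, 2]),
                            Sd = Sd_br, Nd = Nd_br,
                            stringsAsFactors = FALSE),
    per_column = data.frame(column = seq_len(ncol(cm)), used = used,
                            S_sites = S_col, N_sites = N_col,
                            Sd = Sd_col, Nd = Nd_col)
  ), class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "dN/dS (counting method): dN = %.4g, dS = %.4g, omega = %s\n  %d column(s), %d branch(es); N subs %.2f / N sites %.1f, S subs %.2f / S sites %.1f\n",
    x$dN, x$dS, if (x$omega_defined) sprintf("%.4g", x$omega)
    else "undefined (dS = 0)",
    x$n_columns_used, x$n_branches, x$N_subs, x$N_sites, x$S_subs,
    x$S_sites))
  invisible(x)
}

#' Write a dN/dS result as JSON
#' @param result A `dnds_result`.
#' @param path Output path.
#' @param breakdowns Include per-branch and per-column tables (default
#'   TRUE).
#' @return `path`, invisibly.
#' @export
write_dnds_json <- function(result, path, breakdowns = TRUE) {
  x <- unclass(result)
  if (!breakdowns) x$per_branch <- x$per_column <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
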