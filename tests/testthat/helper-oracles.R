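# Independent oracles, deliberately coded without reusing package
# internals: a naive per-base CDS walk for coordinate mapping, exhaustive
# enumeration for codon site/pathway counting, and a standalone pairwise
# NG86 implementation.

# per-base CDS -> genome map: genomic position (0-based) of every CDS
# nucleotide, in transcript 5'->3' order
oracle_cds_walk <- function(t) {
  pos <- integer(0)
  for (i in seq_len(nrow(t$cds))) {
    s <- t$cds$start[i]; e <- t$cds$end[i]
    block <- if (t$strand == "+") seq(s, e - 1L) else seq(e - 1L, s)
    pos <- c(pos, block)
  }
  pos
}

# genomic positions (transcript order) of an amino-acid range
oracle_aa_positions <- function(t, aa_start, aa_end) {
  walk <- oracle_cds_walk(t)
  walk[(3L * (aa_start - 1L) + 1L):(3L * aa_end)]
}

# expand a footprint's blocks base by base in block order
footprint_positions <- function(fp) {
  out <- integer(0)
  for (i in seq_len(nrow(fp$blocks))) {
    s <- fp$blocks$start[i]; e <- fp$blocks$end[i]
    block <- if (fp$blocks$strand[i] == "+") seq(s, e - 1L)
             else seq(e - 1L, s)
    out <- c(out, block)
  }
  out
}

# a random multi-exon fully-coding transcript for property tests
random_test_transcript <- function(id = "t1") {
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(1:5, 1)
  lens <- sample(3:60, n_ex, replace = TRUE)
  total <- sum(lens)
  rem <- total %% 3L
  if (rem > 0L) lens[n_ex] <- lens[n_ex] + (3L - rem)
  gaps <- sample(1:20, n_ex, replace = TRUE)
  starts <- cumsum(c(10L, head(lens, -1L) + head(gaps, -1L)))
  exons <- data.frame(start = starts, end = starts + lens)
  transcript(id, "g1", "chr_test", strand, exons = exons, cds = exons)
}

GC <- Biostrings::GENETIC_CODE
oracle_aa <- function(codon) unname(GC[codon])

# independent site counter: direct enumeration, no shared helpers
oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  syn <- 0L; nonstop <- 0L
  for (p in 1:3) for (b in bases) {
    if (b == substr(codon, p, p)) next
    m <- codon; substr(m, p, p) <- b
    if (oracle_aa(m) == "*") next
    nonstop <- nonstop + 1L
    if (oracle_aa(m) == oracle_aa(codon)) syn <- syn + 1L
  }
  S <- 3 * syn / nonstop
  c(S = S, N = 3 - S)
}

# exhaustive minimal-pathway enumeration (recursive, stop-avoiding)
oracle_paths <- function(a, b) {
  dif <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(dif)) return(list(valid = list(c(S = 0, N = 0)),
                                all = list(c(S = 0, N = 0))))
  valid <- list(); all_p <- list()
  recurse <- function(cur, remaining, S, N, ok) {
    if (!length(remaining)) {
      all_p[[length(all_p) + 1L]] <<- c(S = S, N = N)
      if (ok) valid[[length(valid) + 1L]] <<- c(S = S, N = N)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      step_stop <- oracle_aa(nxt) == "*"
      syn <- !step_stop && oracle_aa(cur) == oracle_aa(nxt)
      recurse(nxt, setdiff(remaining, p),
              S + as.integer(syn && !step_stop),
              N + as.integer(!syn),
              ok && !step_stop)
    }
  }
  recurse(a, dif, 0L, 0L, TRUE)
  list(valid = valid, all = all_p)
}

oracle_substitutions <- function(a, b) {
  res <- oracle_paths(a, b)
  use <- if (length(res$valid)) res$valid else res$all
  m <- colMeans(do.call(rbind, use))
  c(Sd = unname(m["S"]), Nd = unname(m["N"]))
}

# standalone pairwise NG86 on two equal-length gap-free coding sequences
oracle_ng86_pair <- function(s1, s2) {
  n_cod <- nchar(s1) %/% 3L
  Sd <- 0; Nd <- 0; S_sites <- 0; N_sites <- 0
  for (k in seq_len(n_cod)) {
    c1 <- substr(s1, 3L * k - 2L, 3L * k)
    c2 <- substr(s2, 3L * k - 2L, 3L * k)
    st1 <- oracle_sites(c1); st2 <- oracle_sites(c2)
    S_sites <- S_sites + (st1["S"] + st2["S"]) / 2
    N_sites <- N_sites + (st1["N"] + st2["N"]) / 2
    sub <- oracle_substitutions(c1, c2)
    Sd <- Sd + sub["Sd"]; Nd <- Nd + sub["Nd"]
  }
  dS <- if (S_sites > 0) Sd / S_sites else 0
  dN <- if (N_sites > 0) Nd / N_sites else 0
  list(Sd = unname(Sd), Nd = unname(Nd), S_sites = unname(S_sites),
       N_sites = unname(N_sites), dS = unname(dS), dN = unname(dN),
       omega = if (dS > 0) unname(dN / dS) else NA_real_)
}

sense_codon_list <- function() {
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cods <- sort(cods)
  cods[GC[cods] != "*"]
}

random_codon_seq <- function(n) {
  paste(sample(sense_codon_list(), n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
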