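# Orchestration: run the full chain (simulate -> screen -> hallmarks ->
# element architecture -> dN/dS) from one validated configuration, writing
# a machine-readable manifest with checksums for reproducibility checks.

#' Default run configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; stage generators derive independent streams.
#' @return Nested named list; see sections for per-stage parameters.
#' @export
default_run_config <- function(out_dir = "retrodomain_run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    log_level = "info",
    isoforms = list(n_swap = 10L, n_null = 200L, evalue = 1e-05,
                    min_aa = 300L, polya_window = 100L),
    elements = list(n_elements = 50L, n_decoys = 10L,
                    mutation_rate = 0.02, itr_len = 300L,
                    flank_bp = 5000L, max_gap_bp = 1000L,
                    terminal_window = 1500L, min_repeat_len = 20L,
                    min_identity = 80),
    dnds = list(omega = 0.2, kappa = 1, n_codons = 500L,
                branch_length = 0.05)
  )
}

#' Validate a run configuration
#'
#' Rejects unknown keys and out-of-range values before any stage runs.
#'
#' @param config Nested list as in [default_run_config()].
#' @return The validated config (with defaults filled in), invisibly
#'   usable; stops on any violation.
#' @export
validate_run_config <- function(config) {
  def <- default_run_config()
  check_keys <- function(x, ref, where) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(config, def, "top level")
  for (sec in c("isoforms", "elements", "dnds"))
    if (!is.null(config[[sec]])) check_keys(config[[sec]], def[[sec]], sec)
  full <- utils::modifyList(def, config)
  with(full$isoforms, {
    if (n_swap < 0 || n_null < 0) stop("gene counts must be >= 0")
    if (evalue <= 0) stop("evalue threshold must be > 0")
    if (min_aa < 1) stop("min_aa must be >= 1")
    if (polya_window < 6) stop("polya_window must cover a hexamer")
  })
  with(full$elements, {
    if (flank_bp < 0) stop("flank_bp must be >= 0")
    if (max_gap_bp < 0) stop("max_gap_bp must be >= 0")
    if (mutation_rate < 0 || mutation_rate > 1)
      stop("mutation_rate must be in [0, 1]")
    if (min_identity < 0 || min_identity > 100)
      stop("min_identity must be in [0, 100]")
    if (min_repeat_len < 1) stop("min_repeat_len must be >= 1")
    if (terminal_window < min_repeat_len)
      stop("terminal_window must be >= min_repeat_len")
  })
  with(full$dnds, {
    if (omega <= 0 || kappa <= 0) stop("omega and kappa must be > 0")
    if (n_codons < 1) stop("n_codons must be >= 1")
    if (branch_length <= 0) stop("branch_length must be > 0")
  })
  if (!full$log_level %in% c("debug", "info", "warn"))
    stop("log_level must be one of debug, info, warn")
  full
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror [default_run_config()].
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

pipeline_log <- function(config, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[config$log_level]])
    message(sprintf("[retrodomain:%s] %s", level, paste0(...)))
}

#' Run the full synthetic pipeline
#'
#' Executes, in dependency order: isoform simulation, the domain-swap
#' screen, hallmark scoring, element-genome simulation plus architecture
#' classification, and codon-alignment simulation plus dN/dS estimation.
#' All stage outputs land under `config$out_dir`; a JSON manifest listing
#' every artifact with its MD5 checksum plus the config snapshot is
#' written last. The manifest contains no timestamps, so two runs with
#' identical config and seed produce byte-identical manifests.
#'
#' @param config A configuration list; validated before any stage runs.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  seed <- config$seed

  pipeline_log(config, "info", "stage simulate-isoforms: n_swap=",
               config$isoforms$n_swap, " n_null=", config$isoforms$n_null)
  iso_dir <- file.path(out, "isoforms")
  iso <- simulate_isoform_annotation(
    list(n_swap = config$isoforms$n_swap, n_null = config$isoforms$n_null),
    seed = seed, out_dir = iso_dir)
  artifacts <- c(artifacts, unlist(iso$files))

  pipeline_log(config, "info", "stage screen-isoforms")
  genes <- read_gtf(iso$files$gtf)
  hits <- read_domain_hits(iso$files$domains)
  candidates <- screen_genes(genes, hits,
                             evalue_max = config$isoforms$evalue)
  cand_path <- file.path(out, "candidates.tsv")
  write_candidates(candidates, cand_path)
  artifacts <- c(artifacts, cand_path)
  pipeline_log(config, "info", "  candidates: ", nrow(candidates),
               " pair(s), ", sum(candidates$mutually_exclusive),
               " mutually exclusive")

  pipeline_log(config, "info", "stage te-hallmarks")
  genome <- Biostrings::readDNAStringSet(iso$files$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  hm_path <- file.path(out, "hallmarks.tsv")
  me <- candidates[candidates$mutually_exclusive, , drop = FALSE]
  write_hallmarks(me, genes, genome, hits, hm_path,
                  min_aa = config$isoforms$min_aa,
                  polya_window = config$isoforms$polya_window)
  artifacts <- c(artifacts, hm_path)

  pipeline_log(config, "info", "stage element-arch: n_elements=",
               config$elements$n_elements)
  el_dir <- file.path(out, "elements")
  el <- simulate_element_genome(
    list(n_elements = config$elements$n_elements,
         n_decoys = config$elements$n_decoys,
         mutation_rate = config$elements$mutation_rate,
         itr_len = config$elements$itr_len),
    seed = seed, out_dir = el_dir)
  artifacts <- c(artifacts, unlist(el$files))
  el_hits <- read_similarity_hits(el$files$hits)
  loci <- cluster_hits(el_hits, max_gap_bp = config$elements$max_gap_bp)
  el_genome <- Biostrings::readDNAStringSet(el$files$genome)
  names(el_genome) <- sub("\\s.*", "", names(el_genome))
  archs <- lapply(loci, classify_locus, genome = el_genome,
                  flank_bp = config$elements$flank_bp,
                  terminal_window = config$elements$terminal_window,
                  min_repeat_len = config$elements$min_repeat_len,
                  min_identity = config$elements$min_identity)
  loci_path <- file.path(out, "loci.bed")
  gff_path <- file.path(out, "elements.gff3")
  sum_path <- file.path(out, "element_summary.tsv")
  write_loci_bed(loci, loci_path)
  write_architecture_gff3(archs, loci, gff_path)
  write_architecture_summary(archs, sum_path)
  artifacts <- c(artifacts, loci_path, gff_path, sum_path)
  counts <- summarize_labels(archs)
  pipeline_log(config, "info", "  loci: ", length(loci), "; DIRS1-like: ",
               sum(vapply(archs, `[[`, "", "classification") == "DIRS1-like"))

  pipeline_log(config, "info", "stage dnds: omega=", config$dnds$omega,
               " n_codons=", config$dnds$n_codons)
  tree <- default_sim_tree(config$dnds$branch_length)
  sim <- simulate_codon_alignment(tree, omega = config$dnds$omega,
                                  kappa = config$dnds$kappa,
                                  n_codons = config$dnds$n_codons,
                                  seed = seed)
  aln_path <- file.path(out, "alignment.fasta")
  tree_path <- file.path(out, "tree.nwk")
  dnds_path <- file.path(out, "dnds.json")
  write_codon_alignment(sim$alignment, aln_path)
  ape::write.tree(sim$tree, tree_path)
  res <- slac_dnds(read_codon_alignment(aln_path),
                   ape::read.tree(tree_path))
  write_dnds_json(res, dnds_path, breakdowns = FALSE)
  artifacts <- c(artifacts, aln_path, tree_path, dnds_path)
  pipeline_log(config, "info", "  estimated omega: ",
               if (res$omega_defined) sprintf("%.3f", res$omega)
               else "undefined")

  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out), "/?"),
             "", artifacts)
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    artifacts = lapply(seq_along(artifacts), function(i)
      list(path = rel[i],
           md5 = unname(tools::md5sum(artifacts[i]))))
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pipeline_log(config, "info", "manifest written: ", manifest_path)
  invisible(manifest)
}
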