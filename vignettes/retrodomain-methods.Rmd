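---
title: "Methods: tracing alternatively spliced domains to retroelement ORFs"
author: "retrodomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing alternatively spliced domains to retroelement ORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrodomain)
```

## The scientific question

Occasionally a transposable element inserts into a host gene and one of
its open reading frames is recruited as a new, alternatively spliced
coding exon — *exonization* followed by *domestication*. The canonical
vertebrate example is the LAP2alpha domain: a C-terminal domain present
in one isoform each of two genes (*TMPO*'s LAP2α and the homologous
ZNF451 isoform) that is homologous to the GAG ORF of a DIRS1-like
retrotransposon. Establishing such an origin computationally involves
four independent lines of evidence, each of which this package
implements as a testable stage:

1. **A domain-substitution splice pattern.** Two isoforms of one gene
   share a 5′ exon backbone and then diverge into alternative 3′ paths,
   each path coding a Pfam-style domain the other lacks — *mutually
   exclusive splicing* of protein domains.
2. **Retroposition hallmarks on the candidate exon.** A single large
   3′-terminal coding exon (hundreds of codons with no introns), an
   internal polyadenylation signal that prevents inclusion of the
   downstream exons, and reuse of a splice acceptor into the shared
   backbone.
3. **Retroelement architecture around genomic homologs.** Genome-wide
   similarity hits to the candidate domain cluster into loci whose
   flanks carry reverse transcriptase (RT), RNase H and tyrosine
   recombinase (YR) homologies *downstream* of the domain-homologous
   (GAG-like) region, bounded by inverted terminal repeats (ITRs) rather
   than the direct repeats (LTRs) of conventional LTR retroelements.
4. **Purifying selection on the domesticated domain**, quantified as
   dN/dS (ω) on a codon alignment over a fixed phylogeny.

Because the reference datasets behind any particular published analysis
(annotation snapshots, domain databases, genome assemblies) are moving
targets, every stage here is exercised against synthetic data with
machine-readable truth: the package ships generators that plant known
domain-swap genes, known elements, and alignments evolved at known ω,
and the test suite measures recovery of that truth.

## Stage 1: the domain-swap screen

**Data model.** Annotations (GTF or GFF3) are parsed into a
gene → transcript → exon/CDS model. Internally all coordinates are
0-based half-open; conversion happens only at the file boundary (GTF and
GFF3 are 1-based inclusive, BED is 0-based half-open). Transcripts whose
structure is inconsistent — overlapping exons, CDS outside exons, CDS
length not divisible by three, internal stop codons (checked against the
genome when one is supplied) — are carried with a `malformed` flag and
excluded from screening rather than rejected at parse time, since real
annotations contain such records. Codon phase across junctions is always
derived from cumulative CDS length; the GFF3 phase column is ignored, so
there is a single source of truth.

**Protein-to-genome mapping.** A domain hit given in amino-acid
coordinates is mapped to its genomic footprint by walking the spliced
CDS: amino acids `a..b` occupy CDS nucleotides `3(a-1)+1 .. 3b`, split
into blocks at exon junctions; on the minus strand blocks carry genomic
coordinates but are ordered 5′→3′ in transcript orientation. The test
suite checks this operation base-for-base against an independently coded
per-base CDS walk on randomly generated transcripts of both strands.

**The predicate.** For a transcript pair (A, B) of one gene, a pair of
domains (one unique to each side) is *mutually exclusively spliced* when

* no block of A's domain footprint overlaps any exon of B (one shared
  base counts as overlap),
* no block of B's domain footprint overlaps any exon of A, and
* A and B share at least one exon with *identical* coordinates — the
  common backbone. Exact identity rather than overlap is deliberate and
  conservative: overlapping-but-different first exons are not evidence
  of a shared backbone.

Domains are identified by accession with any version suffix stripped,
never by name. Hits are retained below an e-value threshold
(default 1e-05, configurable). A pair in which only one isoform gains a
domain while the other loses nothing is reported with
`mutually_exclusive = FALSE` rather than suppressed: the substitution
pattern requires a domain on *both* sides, but the one-sided cases are
useful diagnostics for manual review. No automatic curation beyond the
predicate is attempted — distinguishing annotation artifacts from real
domain swaps is a judgement call the screen deliberately leaves to a
human, which is why the output carries per-condition diagnostics
(`domains_only_in_a/b`, `shared_backbone_exons`) rather than a verdict
alone.

## Stage 2: retroposition hallmarks

For each transcript of a candidate pair the package reports:

* `terminal_exon_length_bp` and `coding_aa_in_terminal_exon` — the
  3′-most exon and the number of amino acids whose full codon lies
  within it (computed from CDS-offset arithmetic; an internal test
  recomputes it from the per-base walk).
* `single_large_exon` — true when the swapped domain's footprint lies
  entirely within that exon **and** the exon codes at least `min_aa`
  amino acids. The default `min_aa = 300` is a deliberately loose bound:
  known domesticated cases code ~500 amino acids in one exon, while
  ordinary internal exons rarely exceed ~100 codons, so 300 separates
  the regimes with margin on both sides. It is a configuration knob, not
  a biological constant.
* polyadenylation signals — offsets of the hexamers `AATAAA`/`ATTAAA`
  within the last `polya_window` (default 100) bases of the terminal
  exon, in sense orientation. Only the two canonical hexamers are
  scanned by default because they are the minimal defensible set; the
  vector is configurable. Functional signals sit near the cleavage
  site, hence the windowed search rather than a whole-exon scan. The
  scan is a motif search, not a trained polyadenylation-site model:
  positions are recorded so a reviewer can audit each call.
* `shares_acceptor_with_backbone` — whether the exon immediately
  upstream of the terminal exon is one of the exact-coordinate shared
  exons, i.e. the candidate exon splices into the common backbone.

## Stage 3: element architecture

**Hit ingestion and chaining.** Genome-wide similarity hits arrive as
BLAST tabular (outfmt-6-like) rows; subject strand is inferred from
coordinate orientation (`sstart > send` ⇒ minus), the standard TBLASTN
convention. Same-contig, same-strand hits are chained into loci by
single-linkage whenever the gap between intervals is at most
`max_gap_bp` (default 1000 — the ORFs of a single element sit within a
few hundred bases of each other, while independent insertions in our
simulations and in real genomes are typically kilobases apart). The
chaining partitions the input: every hit belongs to exactly one locus.

**Flanks.** Each locus is extracted with ±5000 bp flanks (clamped to
contig bounds; minus-strand loci are reverse-complemented into element
orientation). 5 kb on each side comfortably covers the distance from an
internal ORF hit to an element terminus for elements in the 5–10 kb
range.

**ORF ordering.** Hit labels map to element roles through a
user-extensible vocabulary (defaults: `LAP2alpha → GAG`,
`RT_DIRS1 → RT`, `RNase_HI_RT_DIRS1 → RNase`, phage-integrase labels →
`YR`). A locus is classified `DIRS1-like` when GAG, RT and RNase are all
present in that 5′→3′ order in element orientation; YR is optional but,
when present, must follow RNase. The YR relaxation reflects how
integrase-family hits behave in practice: profile matches to
recombinases are weaker and less uniformly recovered than RT/RNase
matches, so requiring them would cost sensitivity without adding
discriminatory power — the positional argument rests on RT and RNase
lying downstream of the GAG-homologous region. Missing required roles
give `partial`, order violations give `inconsistent`, and loci with no
mapped role give `unclassified`.

**Terminal repeats.** The discriminator between DIRS1-like and
LTR-element architecture is the orientation of the terminal repeats. The
detector locally aligns the 5′-terminal window of the element sequence
against (a) the 3′-terminal window and (b) its reverse complement, with
match/mismatch/gap scores +1/−1/−2 (Smith–Waterman, linear gaps; element
windows are small enough that the O(nm) alignment is affordable without
seeding heuristics). A qualifying alignment must span at least
`min_repeat_len = 20` columns at `min_identity = 80%`; the
better-scoring qualifying orientation determines the call (direct ⇒
LTR, inverted ⇒ ITR), ties go to ITR with a warning, and no qualifying
alignment means `none`. When the detector is run inside the pipeline the
element boundaries are unknown — hits mark only the internal ORFs — so
the scan window is widened to `flank_bp + terminal_window`, covering one
flank plus the element edge on each side.

**Known limitation — spurious short repeats.** With this scoring scheme
a 20-column alignment at 80% identity scores about 12, which is close to
the score of the best chance local alignment between two random 1500-mer
windows (for +1/−1 scoring the extreme-value scale is λ = ln 3, putting
the null optimum near ln(nm)/λ ≈ 13–14). Compact chance optima therefore
qualify at a rate of several percent, and on random sequence the
detector reports a short ITR or LTR rather than `none` in roughly one
case in ten. The acceptance script measures this null false-call rate
explicitly. Real terminal repeats are not affected — a 300 bp repeat at
a few percent divergence scores an order of magnitude above the null
optimum and dominates both orientations — but callers who need a
conservative `none` on repeat-free input should raise `min_repeat_len`
(e.g. to 50) or the identity bound; the defaults favour sensitivity to
short degenerate termini.

## Stage 4: counting-based dN/dS

The estimator is a counting method in the Nei–Gojobori tradition,
generalized from a sequence pair to a tree the way single-ancestor
counting (SLAC-style) methods do:

* **Sites.** For a sense codon, each of its nine single-nucleotide
  mutants is classified; mutants that create a stop are excluded and the
  synonymous fraction is renormalized so S + N = 3 exactly:
  `S = 3 · syn / non-stop`. Per alignment column the site counts of the
  leaf codons are averaged across taxa; column totals are multiplied by
  the number of tree branches so that dN and dS are per-branch
  comparable. Any common scale cancels in ω, which is the quantity of
  interest; the normalization is recorded here so dN and dS themselves
  are interpretable.
* **Substitutions.** For a parent/child codon pair differing at *d*
  positions, the *d*! orderings of the changes are enumerated; orderings
  that pass through a stop codon are discarded and synonymous /
  nonsynonymous step counts are averaged over the survivors. If every
  ordering is blocked by a stop, all orderings are used and the result
  is flagged; steps into or out of a stop are never counted synonymous.
  The 61×61 pair table is computed once and cached.
* **Ancestral states.** SLAC proper reconstructs ancestors by maximum
  likelihood. This implementation substitutes codon-level Fitch
  parsimony: it is deterministic, has no free parameters, and at the
  modest divergences where counting methods are appropriate parsimony
  and ML reconstructions agree almost everywhere. Ambiguities are
  resolved deterministically by classic genetic-code table order (bases
  ordered T, C, A, G) — at the root, and wherever a parent state is not
  contained in a child's candidate set. Columns containing a gap or `N`
  in any sequence are masked entirely (whole-codon gaps only; partial
  codon gaps are rejected at parse time).
* **The estimate.** Substitution counts accumulated over all branches
  and unmasked columns give `dN = N_subs / N_sites`,
  `dS = S_subs / S_sites`, `ω = dN/dS`; ω is flagged undefined when
  dS = 0 rather than reported as infinite.

On a two-taxon tree the reconstruction places the ancestor on one of the
two observed codons, and the procedure reduces *exactly* to pairwise
NG86 counting; the test suite asserts this against an independent
brute-force pairwise implementation to 1e-9, and checks the site and
pathway tables against exhaustive enumeration for all sense codons and
codon pairs.

## The synthetic generators

All three generators are deterministic given `(params, seed)`; a single
integer seed drives one named substream per generator so that adding a
stage never perturbs another stage's stream.

**Isoform annotations.** Swap genes reproduce the domain-substitution
topology: 2–3 shared exons (150–400 bp, with a 30 bp 5′ UTR), then one
large terminal exon of 2812 bp coding 506 amino acids — the geometry of
the known *TMPO* case — carrying domain A (200 aa) and an `AATAAA`
planted 40 bp from the exon end; the alternative path skips that exon
into two further exons (400 + 800 bp) whose domain B (150 aa) spans
their junction, so the partner isoform also exercises the
multi-block footprint path. Null genes cycle through four flavours
designed to probe each failure mode of the predicate separately: both
domains in shared exons (footprint overlap), identical domain sets
(trivial skip), single-transcript genes, and one-sided domain gains.
Genes land on their own contig with random strand; CDS bases are
rewritten with sense codons so translations are stop-free. What this
generator does **not** emulate: overlapping genes, annotation errors
beyond frame violations, UTR introns, alternative promoters, and
paralogy between genes — a perfect score on it shows the predicate and
coordinate machinery are correct, not that screening a real annotation
needs no curation.

**Element genomes.** One master element
(ITR 300 bp – GAG 1500 – RT 2100 – RNase 600 – YR 1200, 100 bp spacers,
inverted 3′ ITR) and one direct-repeat decoy (LTR – 2 kb ORF – LTR) are
copied with i.i.d. per-base substitutions (default 2%, so sister ITRs
within a copy diverge ~4%) onto random strands of 15 × 70 kb contigs,
with at least ~7 kb between inserts so a flanked window never reaches a
neighbouring insert (two same-orientation copies inside one window
would masquerade as a direct repeat). The emitted hit table mimics what
a translated homology scan would report for the internal ORFs — with
coordinate jitter (±20 bp) and plausible identities/e-values — and
deliberately omits the termini: finding those is the detector's job.
Not emulated: nested/fragmented insertions, indels, element families of
varying age, and host-gene context.

**Codon alignments.** A root sequence drawn uniformly from the 61 sense
codons evolves along a fixed tree under a continuous-time model where a
single-nucleotide change has rate ∝ κ^[transition] · ω^[nonsynonymous]
and changes to stops are forbidden; the generator matrix is scaled
(uniform codon weights) so branch lengths are expected substitutions
per codon, and events are simulated per codon per branch. The default
study tree is a balanced 8-taxon phylogeny with every branch 0.05
substitutions/codon: long enough that a 500-codon alignment accumulates
several hundred substitutions (stable estimates), short enough that
multiple hits per branch stay rare (the counting estimator does not
correct for them). The default κ = 1 matches the estimator's
equal-rate site definitions; raising κ is the natural experiment for
studying the well-known transition-bias of unweighted counting
estimators, and the parameter is exposed for exactly that purpose.
Substitution-only evolution (no indels) is a stated non-goal.

## Orchestration and reproducibility

`run_pipeline()` validates its configuration first — unknown keys and
out-of-range values abort before any stage runs — then executes the five
stages in dependency order, logging stage names, parameters and counts
to standard error, and writes a JSON manifest listing every artifact
with its MD5 checksum plus the configuration snapshot. The manifest
contains no timestamps or absolute paths, so two runs with the same
configuration and seed are byte-identical — the reproducibility test is
literally `identical(manifest1, manifest2)`. The screen re-reads the
GTF/TSV the simulator wrote rather than short-circuiting through memory,
so file round-trips are exercised on every run. There is no separate
shell executable: the exported functions and `run_pipeline()` are the
package's interface, and `scripts/acceptance.R` shows the intended
headless usage.

## Study sizes used by the checks

The shipped checks use: 20 seeds of 10 swap among 200 null genes for
the screen; 1000 random transcripts for the coordinate oracle; all 61
codons, all 61² codon pairs and 1000 random two-taxon alignments for
the counting oracles; 20 replicates × ω ∈ {0.1, 0.5, 1, 2} at 8 taxa ×
500 codons for parameter recovery; 50 elements + 10 decoys at 2%
mutation plus 200 random null sequences for architecture; 200 random
loci for the flank contract; and two full pipeline runs for
determinism. These sizes give the recovery statistics comfortable
margins (e.g. the standard error of a 20-replicate ω mean is a few
percent of ω) while keeping a full run on one CPU in the tens of
minutes.

## Known limitations

* The screen's backbone condition requires exact exon identity; genes
  whose shared exons differ by a few bases of UTR annotation would be
  missed. This is the conservative side of the trade-off.
* Fitch parsimony slightly undercounts on long branches and the
  pathway average slightly overcounts nonsynonymous steps at low ω
  (uniform ordering weights ignore that syn-first orderings are likelier
  under purifying selection); at the study branch lengths the combined
  bias on ω stays within a few percent, which is why parameter-recovery
  tolerances are ±15%.
* The terminal-repeat detector's default thresholds admit spurious
  short calls on random sequence (see Stage 3); its strength is
  discriminating ITR from LTR on real repeats, not certifying absence.
* Counting-based ω is an *overall* estimate; per-site selection tests,
  confidence intervals and ML ancestral reconstruction are out of
  scope.
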