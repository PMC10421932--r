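---
title: "Models and methods behind ly6tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ly6tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ly6tools` reconstructs and classifies genes of the LY6/3FTX
(three-finger-fold) cluster. This vignette is the package's own account of
the models it implements, the parameters that matter, what the synthetic
study system does and does not emulate, and the design choices that were
genuinely open.

## The study system the generator emulates

The LY6/UPAR superfamily encodes compact, disulfide-stabilised
three-finger-fold domains of roughly 60–74 mature residues, built from
three exons: exon 1 carries the signal peptide, exon 2 the core of the
mature domain, exon 3 the C-terminus, including — in membrane-bound forms
— a hydrophobic membrane-anchoring region (MaD) that is exchanged for a
GPI anchor post-translationally. Within a genomic cluster flanked by or
containing the single-copy marker *TOP1MT*, these genes are born, die and
duplicate: clusters hold roughly 8–35 members (around 10 in a typical
non-venomous species), plus pseudogenes, stranded "orphan" exons, and
occasional 4-exon genes whose extra exon is a duplicated, pseudogenized
copy of exon 3 inserted 5' of the functional one. Most LY6-lineage
proteins (~86% in curated data) carry a long C-terminal tail; loss of that
tail — for instance by a stop codon arising just before the MaD — creates
a secreted protein, the presumed first step toward a toxin.

The generator reproduces this structure with full ground truth:

* **Cysteine-slot template.** A fixed 64-residue reference core carries 10
  cysteine slots at positions 3, 7, 16, 23, 34, 40, 49, 56, 59, 64; loop
  II is the region between slots 4 and 5. The template spacing is a
  package constant: residue-exact exon/domain boundaries of real LY6 genes
  are not tabulated anywhere, so the template is an idealisation chosen to
  land mature cores in the 60–74-residue range.
* **Groups.** Each of the seven default groups (anchored LY6, secreted
  LY6, pre-3FTX-like, plesiotypic, short-chain, long-chain, non-standard)
  draws one consensus core: the reference point-substituted at rate 0.30
  (non-cysteine positions only), with unoccupied slots mutated C→S, extra
  loop-II cysteines recruited at fixed template positions, and any loop-II
  insertion applied. Group members are consensus copies substituted at
  rate 0.08. The two rates model ancient between-paralog divergence that
  still aligns to the family reference (~70% identity) versus recent
  within-group divergence; both are fixed package defaults.
* **Signal peptides and tails.** Signals are 18–24 residues: the group's
  start tripeptide (MKT in toxins, MK-other in LY6 groups), a hydrophobic
  h-region, and a 3-residue polar c-region. MaD tails are 14–20 residues
  from the strongly hydrophobic alphabet, giving mean Kyte–Doolittle
  hydropathy ≥ 1.8 by construction.
* **Genes.** Proteins are back-translated with a fixed table (most
  frequent human codon per amino acid — any fixed table works; fixing one
  makes output reproducible) and split at the signal/core boundary and
  after slot 6, so exon 3 encodes the region from loop III onward plus the
  stub and tail. The slot-6 boundary keeps every exon-3 peptide above ~24
  residues: all three exons of real LY6 genes encode substantial protein
  segments, and much shorter exon peptides (a boundary at slot 8 would
  leave 8 residues) yield translated-search alignments that are
  statistically indistinguishable from noise.
  Introns and intergenic spacers are random DNA (introns GT..AG,
  80–300 bp; spacers 300–800 bp); gene order follows the protein table so
  that synteny is conserved across generated species, while strands and
  lengths are drawn per seed. Pseudogene lesions (one in-frame TAA or one
  1-bp deletion) never fall in an exon's first or last codon, keeping
  boundary detection well-posed. The default lesion mode is the in-frame
  stop; frameshift lesions are generated on request but are intrinsically
  harder for a translated-homology search to delimit, as they were for the
  original BLAST-plus-curation route.
* **Truth.** Every implanted feature has exactly one truth record;
  coordinates are 0-based half-open on the forward scaffold strand
  internally and convert to 1-based inclusive only at the GFF3 boundary.

What the generator does **not** emulate: substitution processes over a
phylogeny, codon-usage evolution, indels between orthologs, repeats,
sequencing error, or assembly gaps. Perfect recovery on synthetic genomes
therefore demonstrates algorithmic correctness of the search-and-chain
route under controlled divergence, not performance on real assemblies.

## Gene finding

The two-round homology search of the original route (nucleotide BLAST to
locate scaffolds, tblastx against curated exons, manual merging in a
genome browser) is re-expressed as one algorithm:

1. **Six-frame translation** with exact coordinate maps (N→X).
2. **Seed-and-extend Smith–Waterman** per exon-peptide query: exact 4-mer
   seeds window the frame peptide; full affine-gap DP (authored in Rcpp;
   gap of length *k* costs `open + k·extend`, defaults 11/1; X scores 0)
   runs inside each window. An `exhaustive` flag forces whole-frame DP
   with iterative masking, used by the oracle tests.
3. **Filters.** BLAST e-value cutoffs do not port to raw scores, so hits
   must clear: `min_normalized_score` (1.0 per aligned column),
   `min_identity` (0.35), `min_query_coverage` (0.6) and `min_raw_score`
   (30). The last two are necessary companions of the first two: a lone
   cysteine pair scores 9 per column at identity 1.0, and low-complexity
   hydrophobic signal-peptide queries find score-~20 matches in random
   DNA. The raw-score floor plays the role of the e-value cutoff at a
   fixed search-space scale. Reported intervals are extended by unaligned
   query overhangs (3 bp per residue), so a full-length exon match maps
   exact boundaries even when terminal residues are diverged.
4. **Chaining.** Dynamic programming over hits maximises total raw score
   minus an intron cost (`intron_penalty_per_bp`, default 0.1) subject to:
   same strand; exon order E1 < E2 < E3 in gene orientation; intron length
   in [20, 10000] bp; GT..AG at intron boundaries in gene orientation
   (switchable off for degraded loci); at most one repeated exon-3, whose
   5' copy is labelled E3dup; and no other hit contained inside a
   candidate intron. The containment rule is the algorithmic form of the
   curation principle that exons are merged only when order and count
   accord — without it, the maximal-score chain happily bridges a
   neighbouring gene to steal its exon 3. Chains are extracted greedily by
   score; hits overlapping an extracted chain are discarded; leftover
   single hits become orphan-exon models.
5. **Status.** Intact iff the spliced CDS (excluding E3dup) translates
   without internal stop and has length ≡ 0 mod 3; single-exon models are
   orphan exon sets; otherwise pseudogene.

Synteny maps anchor on the marker orthogroup (exactly one copy required),
order entries by coordinate, and compare across species by shared
orthogroup count and Kendall τ over the shared gene order.

## Classification

Signal peptides are removed at an annotated site when given; otherwise a
transparent heuristic stands in for the external predictors the original
analysis used: the h-region is the first run of ≥ 6 residues with
Kyte–Doolittle hydropathy ≥ 1.5 starting within the first 8 positions, and
cleavage is placed 3 residues after it, accepted only within positions
15–30. The heuristic matches the generator's signal model exactly and is
deliberately simple; on real sequences, annotations should be supplied.

Frameworks are read off a global Needleman–Wunsch alignment
(BLOSUM62, gap open 10 / extend 0.5, via Biostrings) against the reference
core: slot columns with an aligned C are occupied; unslotted core
cysteines are extras; loop-II extension is the aligned loop length minus
the 10-residue reference; the tail is everything after the last occupied
slot (or slot 10's column when unoccupied). Anchoring requires tail length
≥ 12 and mean tail hydropathy ≥ 0.5. The four classes apply in rule
order: plesiotypic (all 10 slots, no extras, extension < 4), short-chain
(exactly the 8-slot derived-loss pattern; the lost pair is fixed as slots
2–3 of the template, a documented constant since the source figures show
the lost bond graphically rather than by number), long-chain (≥ 8 slots,
exactly 2 extra loop-II cysteines, extension ≥ 4), else non-standard. The
extension threshold of 4 residues and the tail thresholds are package
constants exposed as arguments; they cleanly separate the generator's
groups and are the kind of constants a user would re-fit on real data.

## Feature space, projection, clustering

Feature modes: 20D composition (non-standard residues dropped from both
numerator and denominator), 400D 2-mer frequencies, a 16D cysteine
descriptor (occupancy mask, extras, loop-II extension, tail length,
anchored flag, total core cysteines, mature length), and imported vectors
(e.g. mean-pooled 1024D protein-language-model embeddings) joined by id.
Non-composition blocks are z-scored per dimension; when blocks are
combined each is additionally scaled to unit total variance
(multiple-factor-analysis convention), because raw composition lives on a
~0.03 scale and would otherwise be numerically invisible next to a
z-scored block.

UMAP runs with the study parameters (n_neighbors 25, min_dist 0.5, 3
components, seed 42), single-threaded for bit-reproducibility. Clustering
defaults follow the study settings: k-means k = 7 (k-means++ seeding, 10
restarts, Lloyd to convergence), DBSCAN ε = 0.55 / minPts = 5, OPTICS
ξ = 0.01 with minPts 5 reused from DBSCAN (the study leaves OPTICS minPts
unstated). Clustering operates on the projected 3D coordinates by default,
matching the statement that the embedding-space results were used as
coordinates; the binary anchored-vs-secreted comparison is made with
k = 2 in feature space, because inter-island spacing in a UMAP layout is
not metric-faithful and a 2-cluster cut of the layout measures island
adjacency rather than the anchoring axis. Both routes are exposed.

DBSCAN and OPTICS are authored in the package and verified against
brute-force density-reachability oracles on exhaustive small instances;
OPTICS ξ-extraction follows the steep-area scheme with an infinite
sentinel closing trailing clusters and the whole dataset always present as
the hierarchy root. Noise points enter the adjusted Rand index as one
extra class (configurable choice, documented) rather than being dropped.

## Trees

Distance options are alignment p-distance (mismatches over non-gap
comparable columns), Euclidean and cosine over features. Neighbor joining
delegates to `ape::nj` with negative branch lengths clamped to zero under
a warning; Robinson–Foulds uses `phangorn::RF.dist` on unrooted trees and
is cross-checked in tests against explicit split enumeration; monophyly is
tested in the unrooted sense (a subset is monophyletic iff it or its
complement is a rooted clade under an arbitrary rooting). Bayesian and
maximum-likelihood phylogenetics are deliberately out of scope — published
trees enter via Newick import. Framework-descriptor distances cannot, even
in principle, separate plesiotypic toxins from secreted LY6 (identical
frameworks), so joint toxin monophyly is reported but not expected from
this metric; per-group monophyly is.

## Numerical and reproducibility choices

* Alignment tie-breaks: smallest query end, then target end; chain
  extraction ties: lowest scaffold coordinate then query id.
* All coordinates 0-based half-open internally; conversion happens only in
  GFF3 I/O.
* One global seed derives per-stage seeds as
  `(seed·131 + 9973·stage) mod (2^31 − 1)`, so stages rerun in isolation;
  every run writes a manifest with parameters, stage seeds, md5 hashes and
  line counts of all outputs, and two runs under one seed are
  byte-identical.
* Default problem sizes — a 10–12-gene genome (~16 kb scaffold), a
  203-protein classification cohort (29 per group), 50 8-leaf NJ
  recoveries, 40 density-oracle instances — are the package's test-scale
  choices: large enough that every failure mode the generator can express
  (pseudogene, orphan, dup3, truncation, all seven groups) is present,
  small enough that the whole suite runs in minutes on one core.

## Known limitations

* The generator's divergence model is fixed-rate point substitution;
  no indels between orthologs, so exact-boundary recovery rates on real
  genomes will be lower than the synthetic 100%.
* The signal-peptide and membrane-anchor heuristics are stand-ins with
  the right shape, not re-implementations of learned predictors; supplied
  annotations always win.
* Whether non-standard secreted LY6K-like forms belong in the
  non-standard category is ambiguous in the literature; the classifier
  simply reports the rule that fired.
* The frameshift pseudogene mode degrades translated-search boundary
  precision by design; status calls for such loci are only reliable when
  the lesion leaves a detectable length or stop signal in the chained
  model.
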