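# ly6tools

Snake three-finger toxins (3FTXs) arose inside the LY6/UPAR superfamily of
three-finger-fold proteins, in a genomic cluster that tetrapods carry next
to the single-copy marker gene *TOP1MT*. Working out how membrane-anchored
LY6 receptors turned into secreted neurotoxins requires reconstructing
every gene in that cluster — including pseudogenes and orphan exons — from
raw genome scaffolds, classifying the encoded proteins by their cysteine
framework, and asking whether sequence-derived feature spaces group the
proteins the way their biology does.

`ly6tools` implements that computational route as a tested R package for
molecular-evolution researchers:

* **Synthetic study system** — a generator that emulates the LY6/3FTX
  cluster with full ground truth: seven protein groups differing in
  cysteine framework (the ancestral 10-cysteine arrangement; 8-cysteine
  short-chain; long-chain with a novel loop-II cysteine pair and extended
  loop; non-standard) and in the presence of a hydrophobic C-terminal
  membrane-anchoring tail (MaD); 3-exon genes (exon 1 = signal peptide,
  exon 3 = C-terminus/MaD) with GT..AG introns; pseudogenes with in-frame
  stops or frameshifts; orphan exons; 4-exon genes whose extra exon is a
  pseudogenized copy of exon 3 inserted 5' of the original; and a
  truncation mode where a stop lands before the MaD — the mechanism that
  births secreted forms.
* **Exon-homology gene finding** — a translated search (six-frame
  translation, seed-and-extend Smith–Waterman with affine gaps, BLOSUM62)
  whose hits are chained into gene models by dynamic programming under
  exon-order, intron-length, splice-motif and locus-containment
  constraints, with intact/pseudogene/orphan status calls and
  marker-anchored synteny maps (shared orthogroups, Kendall tau on gene
  order).
* **Cysteine-framework classification** — signal-peptide removal, global
  alignment onto a canonical 10-slot reference, loop-II extension and
  tail measurement, membrane-anchor detection (tail length >= 12 and mean
  Kyte–Doolittle hydropathy >= 0.5), and the four-category call
  (plesiotypic / short_chain / long_chain / non_standard).
* **Feature space and clustering** — 20D amino-acid composition, 400D
  2-mer, 16D cysteine-descriptor and imported (e.g. 1024D language-model)
  vectors; UMAP projection (n_neighbors = 25, min_dist = 0.5,
  n_components = 3, seed 42); k-means (k-means++ seeding, k = 7), DBSCAN
  (eps = 0.55, minPts = 5), OPTICS with xi = 0.01; adjusted Rand index
  concordance.
* **Tree kit** — p-distance / feature distances, neighbor joining,
  Robinson–Foulds distance and unrooted monophyly tests; published trees
  import via Newick.

## Worked example

```r
library(ly6tools)

# a 10-gene cluster family plus the TOP1MT marker, and a diverged species
fam     <- generate_protein_family(default_groups(c(5, 1, 1, 1, 1, 1, 0)), seed = 42)
species <- mutate_proteins(fam, 0.10, seed = 43)
genome  <- generate_genome(genome_config("demo", seed = 44), species)

hits   <- find_exon_hits(genome$scaffold, exon_query_panel(fam))
models <- chain_hits_to_genes(hits, genome$scaffold)
evaluate_recovery(models, genome)[1:3]
#> $exon_recovery
#> [1] 1
#> $status_accuracy
#> [1] 1
#> $dup3_recall
#> [1] 1

calls <- classify_proteins(setNames(fam$sequence[fam$group != "marker"],
                                    fam$id[fam$group != "marker"]))
table(calls$class)
#>  long_chain plesiotypic short_chain
#>           1           8           1
```

Every truth exon is recovered with exact boundaries, all status labels
(intact / pseudogene / orphan exon set) are correct, the duplicated exon-3
copy is flagged `E3dup` 5' of the functional exon 3, and each protein
receives its generating class (the eight plesiotypic calls are the
anchored and secreted LY6 and pre-3FTX proteins — which share the
ancestral framework and differ only in anchoring — plus the plesiotypic
toxin itself).

The numbered scripts under `analysis/` run the same flow as a narrative
(simulate, find genes, classify, embed + cluster, trees), writing their
tables under `results/run/`.

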