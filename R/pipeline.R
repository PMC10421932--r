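# Stage orchestration: wires the generator, gene finder, classifier,
# embedding/clustering and tree stages into one reproducible flow with a
# manifest.  Stages write plain-text tables into a run directory and are
# idempotent given identical inputs and seed.

PIPELINE_STAGES <- c("simulate", "find_genes", "classify", "embed",
                     "cluster", "trees", "concord")

#' Derive a per-stage seed from the global seed
#'
#' Deterministic derivation (global * 131 + 9973 * stage index, mod 2^31-1)
#' so that any stage can be rerun in isolation.
#'
#' @param seed global integer seed
#' @param stage stage name or index
#' @return integer seed
#' @export
stage_seed <- function(seed, stage) {
  k <- if (is.character(stage)) match(stage, PIPELINE_STAGES) else as.integer(stage)
  if (is.na(k)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 131 + 9973 * k) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param seed global seed; per-stage seeds derive from it via [stage_seed()]
#' @param groups list of [group_spec()]s for the synthetic family
#' @param genome [genome_config()] template (its seed field is overridden by
#'   the derived stage seed)
#' @param search [search_params()]
#' @param projection [projection_params()]
#' @param clustering [clustering_params()]
#' @param panel_divergence protein-level divergence between the query panel
#'   species and the surveyed synthetic genome
#' @param classify_n proteins per group for the classification cohort
#' @return configuration list
#' @export
pipeline_config <- function(seed = 42L,
                            groups = default_groups(),
                            genome = genome_config(),
                            search = search_params(),
                            projection = projection_params(),
                            clustering = clustering_params(),
                            panel_divergence = 0.10,
                            classify_n = 29L) {
  list(seed = as.integer(seed), groups = groups, genome = genome,
       search = search, projection = projection, clustering = clustering,
       panel_divergence = panel_divergence,
       classify_n = as.integer(classify_n))
}

#' Run the analysis pipeline
#'
#' Stages: \code{simulate} (synthetic family + genome with truth),
#' \code{find_genes} (translated search, chaining, status, synteny),
#' \code{classify} (signal removal, framework, tail, class on a noise-free
#' cohort), \code{embed} (composition + cysteine-descriptor features, UMAP),
#' \code{cluster} (k-means / DBSCAN / OPTICS + concordance vs truth),
#' \code{trees} (NJ from descriptor distances, monophyly), \code{concord}
#' (recovery report and manifest).  Each stage reads only the files earlier
#' stages wrote, so later stages can be rerun in isolation; requesting a
#' stage whose inputs are missing is an error naming the stage to run
#' first.  A manifest (seeds, parameters, file hashes, row counts) is
#' written at the end.
#'
#' @param config [pipeline_config()]
#' @param outdir run directory (created)
#' @param stages subset of stages to run, in order
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = PIPELINE_STAGES) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(outdir)
  need <- function(stage, files) {
    miss <- files[!file.exists(files)]
    if (length(miss)) {
      stop("stage inputs missing (", basename(miss[1]),
           "); run stage '", stage, "' first")
    }
  }

  if ("simulate" %in% stages) {
    fam <- generate_protein_family(config$groups, stage_seed(config$seed, 1))
    gcfg <- config$genome
    gcfg$seed <- stage_seed(config$seed, 1) + 1L
    species <- mutate_proteins(fam, config$panel_divergence,
                               stage_seed(config$seed, 1) + 2L)
    genome <- generate_genome(gcfg, species)
    write_genome(genome, file.path(outdir, "genome"))
    utils::write.table(fam, paths$family, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_fasta(stats::setNames(fam$sequence, fam$id), paths$family_fasta)
  }

  if ("find_genes" %in% stages) {
    need("simulate", c(paths$family, paths$scaffold))
    fam <- utils::read.delim(paths$family, stringsAsFactors = FALSE)
    scaffold <- read_fasta(paths$scaffold)
    panel <- exon_query_panel(fam)
    hits <- find_exon_hits(scaffold, panel, config$search)
    models <- chain_hits_to_genes(hits, scaffold, config$search)
    utils::write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_gff3(models_to_gff(models), paths$models)
    map <- build_synteny_map(models, species_id = config$genome$species_id)
    utils::write.table(map$entries, paths$synteny, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("classify" %in% stages) {
    need("simulate", paths$family)
    cohort <- classification_cohort(config)
    calls <- classify_proteins(stats::setNames(cohort$sequence, cohort$id))
    calls$truth_class <- cohort$class_truth
    calls$truth_secretion <- cohort$secretion_truth
    calls$group <- cohort$group
    utils::write.table(calls, paths$classes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("embed" %in% stages) {
    need("classify", paths$classes)
    cohort <- classification_cohort(config)
    matures <- matures_of_cohort(cohort)
    feats <- compose_features(matures, c("composition20", "cys_descriptor"))
    coords <- project(feats, config$projection)
    colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
    write_vectors(coords, paths$coords)
  }

  if ("cluster" %in% stages) {
    need("embed", paths$coords)
    coords <- read_vectors(paths$coords)
    cohort <- classification_cohort(config)
    cp <- config$clustering
    km <- kmeans_cluster(coords, cp$kmeans_k, seed = stage_seed(config$seed, 5))
    db <- dbscan_cluster(coords, cp$dbscan_eps, cp$dbscan_min_pts)
    op <- optics_xi(coords, cp$optics_min_pts, cp$optics_xi)
    # the anchored-vs-secreted split is measured in feature space, where
    # distances are metric-faithful (UMAP inter-island spacing is not)
    feats <- compose_features(matures_of_cohort(cohort),
                              c("composition20", "cys_descriptor"))
    km2 <- kmeans_cluster(feats, 2L, seed = stage_seed(config$seed, 5) + 1L)
    labels <- data.frame(id = rownames(coords), kmeans = km, dbscan = db,
                         optics = op$labels, kmeans2 = km2,
                         truth_group = cohort$group,
                         truth_secretion = cohort$secretion_truth,
                         stringsAsFactors = FALSE)
    utils::write.table(labels, paths$labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report <- data.frame(
      comparison = c("kmeans_vs_group", "dbscan_vs_group",
                     "optics_vs_group", "kmeans2_vs_secretion"),
      ari = c(concordance(km, cohort$group),
              concordance(db, cohort$group),
              concordance(op$labels, cohort$group),
              concordance(km2, cohort$secretion_truth)),
      stringsAsFactors = FALSE)
    utils::write.table(report, paths$concordance, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("trees" %in% stages) {
    need("classify", paths$classes)
    cohort <- classification_cohort(config)
    matures <- matures_of_cohort(cohort)
    feats <- compose_features(matures, c("composition20", "cys_descriptor"))
    D <- distance_matrix(feats, "feature_euclidean")
    tree <- neighbor_joining(D)
    write_newick(tree, paths$tree)
    # per-group monophyly: each paralog group should form its own clade in
    # feature space; the full toxin set is added for contrast (plesiotypic
    # toxins are indistinguishable from secreted LY6 by framework alone, so
    # joint toxin monophyly is not expected from these distances)
    grps <- unique(cohort$group)
    toxin <- cohort$id[cohort$group %in% c("plesiotypic", "short_chain",
                                           "long_chain", "non_standard")]
    mono <- rbind(
      data.frame(clade = grps,
                 n_leaves = as.integer(table(cohort$group)[grps]),
                 monophyletic = vapply(grps, function(g) {
                   is_monophyletic(tree, cohort$id[cohort$group == g])
                 }, TRUE), stringsAsFactors = FALSE),
      data.frame(clade = "all_toxin_groups", n_leaves = length(toxin),
                 monophyletic = is_monophyletic(tree, toxin),
                 stringsAsFactors = FALSE))
    utils::write.table(mono, paths$monophyly, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("concord" %in% stages) {
    need("find_genes", paths$models)
    # recovery report: truth vs recovered annotation, per category
    genome <- reload_genome(outdir)
    models <- models_from_gff(paths$models)
    rec <- evaluate_recovery(models, genome)
    report <- data.frame(
      metric = c("exon_recovery", "status_accuracy", "dup3_recall"),
      value = c(rec$exon_recovery, rec$status_accuracy, rec$dup3_recall),
      stringsAsFactors = FALSE)
    utils::write.table(report, paths$recovery, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  manifest <- build_manifest(config, outdir, stages)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_paths <- function(outdir) {
  list(
    family = file.path(outdir, "family.tsv"),
    family_fasta = file.path(outdir, "family.fasta"),
    scaffold = file.path(outdir, "genome", "scaffold.fasta"),
    truth_gff = file.path(outdir, "genome", "truth.gff3"),
    truth_proteins = file.path(outdir, "genome", "proteins.tsv"),
    hits = file.path(outdir, "hits.tsv"),
    models = file.path(outdir, "models.gff3"),
    synteny = file.path(outdir, "synteny.tsv"),
    classes = file.path(outdir, "classes.tsv"),
    coords = file.path(outdir, "coords.tsv"),
    labels = file.path(outdir, "cluster_labels.tsv"),
    concordance = file.path(outdir, "concordance.tsv"),
    tree = file.path(outdir, "nj_tree.nwk"),
    monophyly = file.path(outdir, "monophyly.tsv"),
    recovery = file.path(outdir, "recovery.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
}

# noise-free cohort used by classify/embed/cluster/trees: regenerated from
# the config (deterministic), marker excluded
classification_cohort <- function(config) {
  groups <- lapply(config$groups, function(g) {
    g$n_genes <- config$classify_n
    g
  })
  fam <- generate_protein_family(groups, stage_seed(config$seed, 3))
  fam[fam$group != "marker", , drop = FALSE]
}

matures_of_cohort <- function(cohort) {
  stats::setNames(cohort$mature, cohort$id)
}

reload_genome <- function(outdir) {
  paths <- pipeline_paths(outdir)
  scaffold <- read_fasta(paths$scaffold)
  ann <- read_gff3(paths$truth_gff)
  genes <- ann[ann$feature_type == "gene", , drop = FALSE]
  exons <- ann[ann$feature_type == "exon", , drop = FALSE]
  list(
    scaffold = scaffold,
    genes = data.frame(gene_id = genes$ID, scaffold_id = genes$scaffold_id,
                       strand = genes$strand, status = genes$status,
                       orthogroup = genes$orthogroup,
                       start = genes$start, end = genes$end,
                       n_exons = as.integer(table(exons$Parent)[genes$ID]),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = exons$Parent, role = exons$role,
                       start = exons$start, end = exons$end,
                       strand = exons$strand, status = exons$status,
                       stringsAsFactors = FALSE))
}

models_from_gff <- function(path) {
  ann <- read_gff3(path)
  genes <- ann[ann$feature_type == "gene", , drop = FALSE]
  exons <- ann[ann$feature_type == "exon", , drop = FALSE]
  lapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[exons$ID %in% paste0(genes$ID[i], ".",
                                     c("E1", "E2", "E3", "E3dup")), ]
    ex <- ex[order(ex$start), , drop = FALSE]
    list(id = genes$ID[i], scaffold_id = genes$scaffold_id[i],
         strand = genes$strand[i],
         exons = data.frame(role = ex$role, start = ex$start, end = ex$end,
                            stringsAsFactors = FALSE),
         status = genes$status[i], orthogroup = genes$orthogroup[i])
  })
}

build_manifest <- function(config, outdir, stages) {
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", outdir, "/?"), "", files)
  counts <- vapply(files, function(f) length(readLines(f, warn = FALSE)),
                   0L)
  names(counts) <- names(hashes)
  list(
    package_version = as.character(utils::packageVersion("ly6tools")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(seq_along(PIPELINE_STAGES), function(k) stage_seed(config$seed, k)),
      PIPELINE_STAGES),
    stages_run = stages,
    parameters = list(
      search = unclass(config$search),
      projection = config$projection,
      clustering = config$clustering,
      panel_divergence = config$panel_divergence,
      classify_n = config$classify_n,
      genome = unclass(config$genome)[setdiff(names(unclass(config$genome)),
                                              "seed")]
    ),
    outputs = list(md5 = as.list(hashes), lines = as.list(counts))
  )
}
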