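# End-to-end orchestration: extract -> similarity -> clustering ->
# post-processing -> core tree -> gain/loss -> association -> export,
# with per-stage caching so completed runs resume for free.

#' Pipeline configuration
#'
#' @param input_dir directory of GenBank files (`*.gbk`/`*.gb`), one per
#'   strain; ignored when `genomes` is given.
#' @param genomes optional list of [strain_genome] objects.
#' @param output_dir where results and the stage cache are written.
#' @param evalue_cutoff similarity significance cutoff (default 0.001).
#' @param batch_size divide-and-conquer batch size (default 50); collections
#'   larger than one batch are clustered with [divide_and_conquer()].
#' @param inflation MCL inflation (default 1.5).
#' @param split a [split_config()] for the post-processing step.
#' @param core_fraction fraction of strains a cluster must cover to count
#'   as core (default 1, strict: the single-copy core feeding the
#'   diversity estimate and the SNP tree is always strict).
#' @param phenotypes optional named numeric vector strain_id -> phenotype,
#'   or `metadata_path` + `phenotype_column` to read one from a TSV.
#' @param metadata_path,phenotype_column see above.
#' @param export_per_cluster write per-cluster FASTA/newick files
#'   (default TRUE).
#' @param seed RNG seed recorded with the run.
#' @return a validated `run_config`.
#' @export
run_config <- function(input_dir = NULL, genomes = NULL, output_dir,
                       evalue_cutoff = 0.001, batch_size = 50,
                       inflation = 1.5, split = split_config(),
                       core_fraction = 1.0, phenotypes = NULL,
                       metadata_path = NULL, phenotype_column = NULL,
                       export_per_cluster = TRUE, seed = 1) {
  if (is.null(genomes) && (is.null(input_dir) || !dir.exists(input_dir)))
    fatal("either genomes or an existing input_dir is required")
  if (inflation <= 1) fatal("inflation must be > 1")
  if (evalue_cutoff <= 0) fatal("evalue_cutoff must be > 0")
  if (batch_size < 1) fatal("batch_size must be >= 1")
  if (core_fraction <= 0 || core_fraction > 1) fatal("core_fraction in (0, 1]")
  if (!is.null(metadata_path) && is.null(phenotype_column))
    fatal("phenotype_column required with metadata_path")
  structure(list(input_dir = input_dir, genomes = genomes,
                 output_dir = output_dir, evalue_cutoff = evalue_cutoff,
                 batch_size = batch_size, inflation = inflation,
                 split = split, core_fraction = core_fraction,
                 phenotypes = phenotypes, metadata_path = metadata_path,
                 phenotype_column = phenotype_column,
                 export_per_cluster = export_per_cluster, seed = seed),
            class = "run_config")
}

stage_cached <- function(outdir, name, fun) {
  cache <- file.path(outdir, "cache", paste0(name, ".rds"))
  if (file.exists(cache)) return(readRDS(cache))
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e)
    fatal("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  saveRDS(res, cache)
  line <- sprintf("[%s] done in %.1fs", name,
                  as.numeric(Sys.time() - t0, units = "secs"))
  message(line)
  cat(line, "\n", file = file.path(outdir, "pipeline.log"), append = TRUE)
  res
}

#' Run the full pan-genome pipeline
#'
#' Executes all stages in order with per-stage caching under
#' `output_dir/cache`; a rerun on a completed directory recomputes
#' nothing.  See [run_config()] for the knobs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with genomes, clusters, post-processing
#'   report, alignments/trees, strain tree, gain/loss model, events,
#'   association table and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$output_dir
  dir.create(file.path(outdir, "cache"), recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  # persist the configuration (minus in-memory genomes) for provenance
  prov <- config[setdiff(names(config), c("genomes", "phenotypes"))]
  prov$split <- unclass(prov$split)
  jsonlite::write_json(prov, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  genomes <- stage_cached(outdir, "01_extract", function() {
    if (!is.null(config$genomes)) return(config$genomes)
    files <- list.files(config$input_dir, pattern = "\\.(gbk|gb|gbff)$",
                        full.names = TRUE)
    if (!length(files)) fatal("no GenBank files in %s", config$input_dir)
    gs <- lapply(files, function(f)
      read_genbank(f, sub("\\.(gbk|gb|gbff)$", "", basename(f))))
    setNames(gs, vapply(gs, function(g) g$strain_id, character(1)))
  })
  genes <- combined_gene_table(genomes)
  strains <- sort(vapply(genomes, function(g) g$strain_id, character(1)))

  clusters <- stage_cached(outdir, "02_cluster", function() {
    if (length(genomes) > config$batch_size) {
      divide_and_conquer(genomes, batch_size = config$batch_size,
                         evalue_cutoff = config$evalue_cutoff,
                         inflation = config$inflation)
    } else {
      g <- build_graph(genes, evalue_cutoff = config$evalue_cutoff)
      mcl(g, inflation = config$inflation)
    }
  })

  post <- stage_cached(outdir, "03_postprocess", function()
    postprocess_all(clusters, genes, strains, config$split))

  phylo <- stage_cached(outdir, "04_phylo", function() {
    alns <- list(); trees <- list()
    for (id in names(post$clusters)) {
      cp <- cluster_phylo(post$clusters[[id]], genes, config$split)
      alns[[id]] <- cp$aln_nt
      if (!is.null(cp$tree)) trees[[id]] <- cp$tree
    }
    list(alignments = alns, trees = trees)
  })

  coretree <- stage_cached(outdir, "05_coretree", function()
    core_snp_tree(post$clusters, genes, strains,
                  alignments = phylo$alignments, config = config$split))

  gl <- stage_cached(outdir, "06_gainloss", function() {
    pam <- presence_absence_matrix(post$clusters, genes, strains)
    model <- fit_gain_loss(coretree$tree, pam)
    anc <- ancestral_presence(coretree$tree, pam, model)
    list(pam = pam, model = model, events = anc$events, states = anc$states)
  })

  phen <- config$phenotypes
  if (is.null(phen) && !is.null(config$metadata_path))
    phen <- phenotype_vector(read_metadata(config$metadata_path),
                             config$phenotype_column)
  assoc <- if (!is.null(phen)) {
    stage_cached(outdir, "07_assoc", function()
      rank_associations(post$clusters, genes, phen, gl$pam, gl$events,
                        trees = phylo$trees))
  } else NULL

  stage_cached(outdir, "08_export", function() {
    export_results(outdir, genomes, genes, strains, post, phylo, coretree,
                   gl, assoc, config)
    TRUE
  })

  invisible(list(genomes = genomes, genes = genes, strains = strains,
                 initial_clusters = clusters, clusters = post$clusters,
                 post = post, phylo = phylo, coretree = coretree,
                 gainloss = gl, assoc = assoc, output_dir = outdir))
}

cluster_table <- function(post, genes, strains, phylo, gl, assoc, core_fraction) {
  info <- cluster_info(post$clusters, genes, strains)
  info$diversity <- vapply(info$cluster_id, function(id) {
    aln <- phylo$alignments[[id]]
    if (length(aln) < 2) return(0)
    P <- pdist_cpp(unname(aln))
    mean(P[upper.tri(P)], na.rm = TRUE)
  }, numeric(1))
  info$soft_core <- info$n_strains >= core_fraction * length(strains)
  info$n_events <- event_counts(gl$events, info$cluster_id)
  if (!is.null(assoc)) {
    m <- match(info$cluster_id, assoc$cluster_id)
    info$branch_assoc <- assoc$branch_assoc[m]
    info$presence_assoc <- assoc$presence_assoc[m]
  }
  info
}

export_results <- function(outdir, genomes, genes, strains, post, phylo,
                           coretree, gl, assoc, config) {
  tab <- cluster_table(post, genes, strains, phylo, gl, assoc, config$core_fraction)
  write_clusters(post$clusters, file.path(outdir, "clusters.tsv"))
  write.table(tab, file.path(outdir, "cluster_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(post$report, file.path(outdir, "postprocess_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pam_out <- data.frame(cluster_id = rownames(gl$pam),
                        gl$pam * 1L, check.names = FALSE)
  write.table(pam_out, file.path(outdir, "presence_absence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gl$events, file.path(outdir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(coretree$tree, file.path(outdir, "strain_tree.nwk"))
  if (isTRUE(config$export_per_cluster)) {
    cdir <- file.path(outdir, "clusters")
    dir.create(cdir, showWarnings = FALSE)
    for (id in names(post$clusters)) {
      write_fasta(phylo$alignments[[id]],
                  file.path(cdir, paste0(id, "_na_aln.fasta")), type = "nt")
      if (!is.null(phylo$trees[[id]]))
        ape::write.tree(phylo$trees[[id]], file.path(cdir, paste0(id, ".nwk")))
    }
  }
  export_json(outdir, tab, post, phylo, coretree, gl)
  invisible(outdir)
}

#' Write the JSON bundle for downstream visualization
#'
#' One bundle with a versioned schema: the cluster table (counts, flags,
#' diversity, association scores, events), per-cluster newick strings, the
#' strain tree, the gain/loss rates, and the presence/absence map.
#'
#' @param outdir output directory.
#' @param tab cluster table (internal).
#' @param post,phylo,coretree,gl pipeline stage results (internal).
#' @return the path of the written JSON file.
#' @export
export_json <- function(outdir, tab, post, phylo, coretree, gl) {
  bundle <- list(
    schema = "orthopan-export-1",
    clusters = tab,
    members = lapply(post$clusters, identity),
    gene_trees = lapply(phylo$trees, function(tr)
      ape::write.tree(tr)),
    strain_tree = ape::write.tree(coretree$tree),
    gain_loss = list(gain = gl$model$gain, loss = gl$model$loss,
                     ratio = gl$model$ratio),
    presence_absence = apply(gl$pam, 1, function(r)
      paste(as.integer(r), collapse = ""))
  )
  path <- file.path(outdir, "pangenome.json")
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  path
}
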