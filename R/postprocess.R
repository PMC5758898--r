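# Phylogeny-aware refinement of the initial MCL clusters: split distantly
# related homologs at long branches (adaptive cutoff from core diversity),
# split closely related paralogs by a per-branch paralogy score, and merge
# unclustered fragments detected as peaks in the gene-length distribution.

#' Post-processing configuration
#'
#' @param b_c branch-length cutoff; derived from `d_c` via
#'   [adaptive_cutoff()] when `NULL`.
#' @param paralogy_coeff coefficient of the paralogy term (default 1.5).
#' @param criterion_threshold split when the combined score exceeds this
#'   (default 1.0, strict inequality).
#' @param max_rounds cap on split/re-tree rounds per cluster (default 20;
#'   heavily duplicated genes can need more than five).
#' @param long_branch_splitting `TRUE`, `FALSE` or `"auto"` (default):
#'   auto disables long-branch splitting when core diversity exceeds 0.25,
#'   where threshold splitting under-clusters.
#' @param peak_window,peak_factor,peak_min_count length-peak detection:
#'   moving-average window (bins of 1 nt), the factor over the smoothed
#'   background and the minimum count a peak must reach.
#' @param align_gap linear gap penalty of the internal aligner.
#' @param align_command,tree_command optional external tool templates
#'   (see [align_proteins()], [build_tree()]).
#' @return a `split_config` list.
#' @export
split_config <- function(b_c = NULL, paralogy_coeff = 1.5,
                         criterion_threshold = 1.0, max_rounds = 20,
                         long_branch_splitting = "auto",
                         peak_window = 21, peak_factor = 3, peak_min_count = 5,
                         align_gap = 8, align_command = NULL, tree_command = NULL) {
  structure(list(b_c = b_c, paralogy_coeff = paralogy_coeff,
                 criterion_threshold = criterion_threshold,
                 max_rounds = max_rounds,
                 long_branch_splitting = long_branch_splitting,
                 peak_window = peak_window, peak_factor = peak_factor,
                 peak_min_count = peak_min_count, align_gap = align_gap,
                 align_command = align_command, tree_command = tree_command),
            class = "split_config")
}

#' Adaptive branch-length cutoff from core diversity
#'
#' `b_c = (0.1 + 2 d_c) / (1 + 2 d_c)`: grows as `0.1 + 2 d_c` for very
#' similar strains and saturates at 1.  Above `d_c = 0.25` a warning is
#' emitted — threshold splitting under-clusters very diverse pan-genomes
#' and should be switched off there.
#'
#' @param d_c average diversity of single-copy core genes
#'   (substitutions/site, >= 0).
#' @return cutoff in substitutions/site, in `[0.1, 1)`.
#' @export
adaptive_cutoff <- function(d_c) {
  if (any(d_c < 0)) fatal("core diversity d_c must be >= 0")
  if (any(d_c > 0.25))
    warning("core diversity d_c > 0.25: long-branch splitting under-clusters very diverse pan-genomes and should be switched off")
  (0.1 + 2 * d_c) / (1 + 2 * d_c)
}

#' Average diversity of single-copy core genes
#'
#' For every single-copy core cluster the mean pairwise nucleotide
#' difference per ungapped site is computed over all strain pairs of its
#' codon alignment; `d_c` is the mean over those clusters.
#'
#' @param clusters list of clusters (gene-id vectors), pre-splitting.
#' @param genes gene table.
#' @param strains all strain ids of the dataset.
#' @param alignments optional list of precomputed nucleotide alignments
#'   keyed by cluster name.
#' @param config a [split_config()] (aligner settings).
#' @return `d_c` in substitutions/site.
#' @export
core_diversity <- function(clusters, genes, strains = unique(genes$strain_id),
                           alignments = NULL, config = split_config(),
                           min_strain_fraction = 1.0) {
  info <- cluster_info(clusters, genes, strains)
  sc <- which(info$is_core & info$is_single_copy & info$n_members >= 2)
  if (!length(sc) && min_strain_fraction < 1) {
    # diverse pan-genomes can fragment every strict core cluster at the
    # clustering stage; fall back to soft single-copy core clusters
    sc <- which(info$is_single_copy & !info$duplicated &
                  info$n_strains >= min_strain_fraction * length(strains) &
                  info$n_members >= 2)
    if (length(sc))
      warning(sprintf("no strict single-copy core clusters; estimating core diversity from %d soft-core clusters (>= %d%% of strains)",
                      length(sc), round(100 * min_strain_fraction)))
  }
  if (!length(sc))
    fatal("no single-copy core clusters found; set b_c manually in split_config()")
  per_cluster <- vapply(sc, function(i) {
    aln <- alignments[[names(clusters)[i]]]
    if (is.null(aln)) aln <- cluster_phylo(clusters[[i]], genes, config, tree = FALSE)$aln_nt
    P <- pdist_cpp(unname(aln))
    mean(P[upper.tri(P)], na.rm = TRUE)
  }, numeric(1))
  mean(per_cluster)
}

# Memo cache for per-cluster alignments/trees: the same member set is
# aligned repeatedly across post-processing stages; results are
# deterministic given members + aligner settings.
.phylo_cache <- new.env(parent = emptyenv())

clear_phylo_cache <- function() {
  rm(list = ls(.phylo_cache), envir = .phylo_cache)
}

# Alignment + gene tree for one cluster (codon alignment; protein-guided).
cluster_phylo <- function(members, genes, config = split_config(), tree = TRUE) {
  nt <- genes$nt_seq[match(members, genes$gene_id)]
  # sequence checksum: member ids repeat across datasets (e.g. simulator
  # replicates), so the key must depend on the sequences themselves
  fp <- sum(utf8ToInt(paste(substr(nt, 1, 32), collapse = ""))) +
    3 * sum(utf8ToInt(paste(substring(nt, pmax(1, nchar(nt) - 31)), collapse = ""))) +
    7 * sum(nchar(nt))
  key <- paste(c(fp, config$align_gap, config$align_command %||% "",
                 config$tree_command %||% "", tree, members), collapse = "\1")
  hit <- .phylo_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- cluster_phylo_compute(members, genes, config, tree)
  if (length(ls(.phylo_cache)) > 20000) clear_phylo_cache()
  .phylo_cache[[key]] <- res
  res
}

cluster_phylo_compute <- function(members, genes, config = split_config(), tree = TRUE) {
  m <- match(members, genes$gene_id)
  if (anyNA(m)) fatal("unknown gene_id: %s", members[which(is.na(m))[1]])
  aa <- setNames(genes$aa_seq[m], members)
  nt <- setNames(strip_terminal_stop(genes$nt_seq[m], genes$aa_seq[m]), members)
  if (length(members) == 1)
    return(list(aln_aa = aa, aln_nt = nt, tree = NULL))
  aln_aa <- align_proteins(aa, gap = config$align_gap, command = config$align_command)
  aln_nt <- codon_align(aln_aa, nt)
  list(aln_aa = aln_aa, aln_nt = aln_nt,
       tree = if (tree) build_tree(aln_nt, command = config$tree_command) else NULL)
}

#' Cut a gene tree at branches exceeding the cutoff
#'
#' All branches longer than `b_c` are removed simultaneously; the leaf sets
#' of the resulting connected components are returned.
#'
#' @param tree rooted gene tree.
#' @param b_c branch-length cutoff.
#' @return list of leaf-label groups (length 1 when nothing is cut).
#' @export
cut_long_branches <- function(tree, b_c) {
  long <- which(tree$edge.length > b_c)
  if (!length(long)) return(list(tree$tip.label))
  cut_tree_components(tree, long)
}

#' Split distantly related homologs at long branches
#'
#' Iteratively cuts all branches longer than `b_c`, re-aligns and re-trees
#' each resulting sub-cluster, and repeats until no long branch remains
#' (capped at `config$max_rounds` rounds).
#'
#' @param members gene ids of one cluster.
#' @param genes gene table.
#' @param b_c branch-length cutoff from [adaptive_cutoff()].
#' @param config a [split_config()].
#' @param tree optional precomputed gene tree for the first round.
#' @return list of sub-clusters (gene-id vectors).
#' @export
split_long_branches <- function(members, genes, b_c, config = split_config(),
                                tree = NULL) {
  rec <- function(mem, tr, rounds) {
    if (length(mem) < 2 || rounds <= 0) return(list(mem))
    if (is.null(tr)) tr <- cluster_phylo(mem, genes, config)$tree
    parts <- cut_long_branches(tr, b_c)
    if (length(parts) == 1) return(list(mem))
    unlist(lapply(parts, rec, tr = NULL, rounds = rounds - 1), recursive = FALSE)
  }
  rec(members, tree, config$max_rounds)
}

#' Per-branch paralogy scores
#'
#' The paralogy score of a branch is the number of strains represented on
#' both sides of that branch.  Computed for all branches simultaneously:
#' one post-order pass accumulates per-strain leaf counts below each edge
#' and the side above follows by subtraction from the totals.
#'
#' @param tree rooted gene tree with gene-id tip labels.
#' @param strain_map named character vector gene_id -> strain_id covering
#'   every tip.
#' @return data.frame with one row per edge of `tree$edge`: `edge`, `child`
#'   (node id), `length`, and `phi`.
#' @export
paralogy_scores <- function(tree, strain_map) {
  tips <- tree$tip.label
  if (any(!tips %in% names(strain_map)))
    fatal("no strain mapping for tip '%s'", tips[!tips %in% names(strain_map)][1])
  st <- factor(strain_map[tips])
  ns <- nlevels(st)
  nt <- length(tips)
  counts <- matrix(0L, nt + tree$Nnode, ns)
  counts[cbind(seq_len(nt), as.integer(st))] <- 1L
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge)))
    counts[eo$edge[k, 1], ] <- counts[eo$edge[k, 1], ] + counts[eo$edge[k, 2], ]
  total <- colSums(counts[seq_len(nt), , drop = FALSE])
  below <- counts[tree$edge[, 2], , drop = FALSE]
  above <- rep(total, each = nrow(below)) - below
  phi <- rowSums(below > 0 & above > 0)
  data.frame(edge = seq_len(nrow(tree$edge)), child = tree$edge[, 2],
             length = tree$edge.length, phi = as.integer(phi))
}

#' One paralogy-split decision
#'
#' Selects the branch with the highest paralogy score (ties: longer branch,
#' then smaller child node id) and splits the cluster into the two sides of
#' that branch iff `phi_max > 0` and
#' `l / b_c + phi_max / (coeff * n_strains) > threshold` (strict), where
#' `n_strains` counts the distinct strains represented in the cluster.
#'
#' @param tree rooted gene tree.
#' @param strain_map gene_id -> strain_id for every tip.
#' @param b_c branch-length cutoff.
#' @param coeff,threshold criterion parameters (defaults 1.5 and 1.0).
#' @return `NULL` (no split) or a list of the two leaf-label groups.
#' @export
paralog_split_decision <- function(tree, strain_map, b_c, coeff = 1.5,
                                   threshold = 1.0) {
  ps <- paralogy_scores(tree, strain_map)
  ord <- order(-ps$phi, -ps$length, ps$child)
  best <- ps[ord[1], ]
  if (best$phi == 0) return(NULL)
  n_strains <- length(unique(strain_map[tree$tip.label]))
  score <- best$length / b_c + best$phi / (coeff * n_strains)
  if (!(score > threshold)) return(NULL)
  below <- edge_leaf_matrix(tree)[best$edge, ]
  side1 <- tree$tip.label[below]
  side2 <- setdiff(tree$tip.label, side1)
  if (!length(side2)) return(NULL)
  list(side1, side2)
}

#' Split closely related paralogs
#'
#' Applies [paralog_split_decision()] recursively to both sides until no
#' cluster meets the criterion, re-aligning and re-treeing after every
#' split (capped at `config$max_rounds` rounds).
#'
#' @inheritParams split_long_branches
#' @return list of sub-clusters (gene-id vectors).
#' @export
split_paralogs <- function(members, genes, b_c, config = split_config(),
                           tree = NULL) {
  rec <- function(mem, tr, rounds) {
    if (length(mem) < 2 || rounds <= 0) return(list(mem))
    if (is.null(tr)) tr <- cluster_phylo(mem, genes, config)$tree
    sm <- strain_of(mem, genes)
    parts <- paralog_split_decision(tr, sm, b_c, config$paralogy_coeff,
                                    config$criterion_threshold)
    if (is.null(parts)) return(list(mem))
    unlist(lapply(parts, rec, tr = NULL, rounds = rounds - 1), recursive = FALSE)
  }
  rec(members, tree, config$max_rounds)
}

#' Detect peaks in the cluster length distribution
#'
#' Histogram of cluster mean lengths at 1-nt resolution; the background is
#' a centered moving average (window `peak_window` bins); a length is a
#' peak when its count exceeds `max(peak_min_count, peak_factor * background)`.
#'
#' @param mean_lengths numeric vector of cluster mean lengths (nt).
#' @param config a [split_config()].
#' @return integer vector of peak lengths.
#' @export
length_peaks <- function(mean_lengths, config = split_config()) {
  if (!length(mean_lengths)) return(integer(0))
  L <- round(mean_lengths)
  rng <- range(L)
  counts <- tabulate(L - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  w <- config$peak_window
  half <- w %/% 2
  padded <- c(rep(0, half), counts, rep(0, half))
  bg <- vapply(seq_along(counts), function(i) mean(padded[i:(i + w - 1)]), numeric(1))
  peaks <- which(counts > pmax(config$peak_min_count, config$peak_factor * bg))
  peaks + rng[1] - 1L
}

#' Merge fragmented clusters detected as gene-length peaks
#'
#' For every peak length L, all singleton clusters whose gene has exactly
#' length L are pooled into one tentative cluster, aligned and treed, and
#' passed through long-branch splitting (always, since the pool is formed
#' on length identity alone) and paralogy splitting; the resulting groups
#' replace the pooled singletons.
#'
#' @param clusters named list of clusters (gene-id vectors).
#' @param genes gene table.
#' @param b_c branch-length cutoff.
#' @param config a [split_config()].
#' @return list with `clusters` (updated list) and `pooled` (gene ids that
#'   entered a tentative cluster).
#' @export
merge_fragments <- function(clusters, genes, b_c, config = split_config()) {
  lens <- setNames(nchar(genes$nt_seq), genes$gene_id)
  mean_len <- vapply(clusters, function(m) mean(lens[m]), numeric(1))
  peaks <- length_peaks(mean_len, config)
  if (!length(peaks)) return(list(clusters = clusters, pooled = character(0)))
  singleton <- vapply(clusters, length, integer(1)) == 1
  pooled_ids <- character(0)
  keep <- rep(TRUE, length(clusters))
  new_groups <- list()
  for (L in peaks) {
    idx <- which(singleton & keep & round(mean_len) == L)
    if (length(idx) < 2) next
    pool <- unlist(clusters[idx], use.names = FALSE)
    keep[idx] <- FALSE
    pooled_ids <- c(pooled_ids, pool)
    # pre-partition the pool by similarity: genes without a significant hit
    # sit at the saturated JC distance, which exceeds any cutoff b_c < 1, so
    # they could never stay together through long-branch splitting anyway
    sub <- genes[match(pool, genes$gene_id), , drop = FALSE]
    class(sub) <- c("gene_table", "data.frame")
    pg <- build_graph(sub)
    cg <- igraph::graph_from_data_frame(pg$edges[, 1:2], directed = FALSE,
                                        vertices = pg$nodes)
    comps <- split(pg$nodes, igraph::components(cg)$membership[pg$nodes])
    for (comp in comps) {
      if (length(comp) == 1) { new_groups <- c(new_groups, list(comp)); next }
      groups <- split_long_branches(comp, genes, b_c, config)
      groups <- unlist(lapply(groups, split_paralogs, genes = genes, b_c = b_c,
                              config = config), recursive = FALSE)
      new_groups <- c(new_groups, groups)
    }
  }
  out <- c(clusters[keep], new_groups)
  list(clusters = canonical_clusters(out), pooled = pooled_ids)
}

#' Phylogeny-aware post-processing of MCL clusters
#'
#' The three-step refinement: (1) split distantly related homologs at
#' branches longer than the adaptive cutoff, (2) split closely related
#' paralogs by the per-branch paralogy criterion, (3) merge fragmented
#' singleton clusters found as peaks of the gene-length distribution.  The
#' report records, for every initial cluster, whether and how it was
#' modified.
#'
#' @param clusters named list of initial clusters.
#' @param genes gene table.
#' @param strains all strain ids.
#' @param config a [split_config()]; when `config$b_c` is `NULL` the cutoff
#'   is derived from the single-copy core diversity.
#' @return list with `clusters` (final named list), `report` (data.frame:
#'   cluster_id, action, round), `d_c`, `b_c`, and `fraction_modified`.
#' @export
postprocess_all <- function(clusters, genes, strains = unique(genes$strain_id),
                            config = split_config()) {
  clusters <- canonical_clusters(clusters)
  clear_phylo_cache()
  d_c <- NA_real_
  b_c <- config$b_c
  if (is.null(b_c)) {
    d_c <- core_diversity(clusters, genes, strains, config = config,
                          min_strain_fraction = 0.5)
    b_c <- suppressWarnings(adaptive_cutoff(d_c))
  }
  lb_on <- isTRUE(config$long_branch_splitting) ||
    (identical(config$long_branch_splitting, "auto") &&
       (is.na(d_c) || d_c <= 0.25))

  origin <- setNames(names(clusters), names(clusters))
  action <- setNames(rep("kept", length(clusters)), names(clusters))
  work <- clusters  # named by current id; origin maps current -> initial

  # stage 1: long branches
  if (lb_on) {
    out <- list(); out_origin <- character(0)
    for (id in names(work)) {
      parts <- split_long_branches(work[[id]], genes, b_c, config)
      if (length(parts) > 1) action[origin[[id]]] <- "split-long-branch"
      for (p in seq_along(parts)) {
        nid <- if (length(parts) == 1) id else sprintf("%s.%d", id, p)
        out[[nid]] <- parts[[p]]
        out_origin[nid] <- origin[[id]]
      }
    }
    work <- out; origin <- out_origin
  }

  # stage 2: paralogs
  out <- list(); out_origin <- character(0)
  for (id in names(work)) {
    parts <- split_paralogs(work[[id]], genes, b_c, config)
    if (length(parts) > 1 && action[origin[[id]]] == "kept")
      action[origin[[id]]] <- "split-paralog"
    for (p in seq_along(parts)) {
      nid <- if (length(parts) == 1) id else sprintf("%s.p%d", id, p)
      out[[nid]] <- parts[[p]]
      out_origin[nid] <- origin[[id]]
    }
  }
  work <- out; origin <- out_origin

  # stage 3: fragment merging
  mf_config <- config
  mf_config$b_c <- b_c
  mf <- merge_fragments(work, genes, b_c, mf_config)
  if (length(mf$pooled)) {
    # a pooled singleton counts as modified iff it ended up co-clustered
    gene_to_initial <- setNames(rep(origin, lengths(work)),
                                unlist(work, use.names = FALSE))
    for (cl in mf$clusters) {
      if (length(cl) > 1) {
        merged_in <- intersect(cl, mf$pooled)
        for (g in merged_in) {
          init <- gene_to_initial[[g]]
          if (action[init] == "kept") action[init] <- "merged"
        }
      }
    }
  }
  final <- canonical_clusters(mf$clusters)

  report <- data.frame(cluster_id = names(action), action = unname(action),
                       round = NA_integer_, stringsAsFactors = FALSE)
  list(clusters = final, report = report, d_c = d_c, b_c = b_c,
       fraction_modified = mean(action != "kept"))
}
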