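# Coalescent pan-genome simulator: correlated gene trees on a clonal
# genealogy, gene gain at uniform points on branches, exponential loss,
# and HKY sequence evolution — emitting both pipeline inputs and a truth
# table for benchmarking.

#' Simulation configuration
#'
#' Defaults follow the reference simulation design: 2803 genes of which
#' 2100 are ancestral (present at the MRCA) and 300 of those persistent
#' (never lost), loss rate 2.1 per unit coalescent branch length, HKY
#' substitution with transition-transversion bias 1.1.  When `n_genes`
#' differs from 2803, `n_ancestral` and `n_persistent` default to the same
#' proportions.  About half of the gene seeds are drawn as members of
#' paralogous families (ancient duplications), mirroring the paralogy
#' structure of a real enterobacterial gene complement; see the methods
#' vignette.
#'
#' @param n_strains number of genomes.
#' @param n_genes,n_ancestral,n_persistent gene counts
#'   (`n_persistent <= n_ancestral <= n_genes`).
#' @param loss_rate loss events per unit coalescent branch length.
#' @param rate_dist substitution-rate distribution: one of
#'   `rate_exponential(mean)`, `rate_uniform(min, max)`, `rate_constant(mu)`.
#' @param kappa HKY transition-transversion bias.
#' @param base_freqs stationary base frequencies (A, C, G, T).
#' @param transfer_mode `"none"`, `"occasional"` or `"frequent"` gene
#'   transfer (prune-regraft perturbations of gene trees).
#' @param gene_length gene length in nt (multiple of 3).
#' @param paralog_fraction fraction of gene seeds belonging to paralogous
#'   families.
#' @param family_divergence range (nt substitutions/site) of the divergence
#'   of a family member from its family ancestor.
#' @param drop_genes optional fraction of genes randomly removed from every
#'   emitted genome (incomplete-assembly emulation).
#' @param time_scale conversion from the clonal tree's coalescent units
#'   (2N; [simulate_clonal_tree()]) to the time units the loss and
#'   substitution rates are quoted in (4N generations, the unit used by
#'   standard coalescent/sequence simulators); default 0.5.
#' @param seed RNG seed used by [simulate_pangenome()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_strains = 30, n_genes = 2803,
                       n_ancestral = NULL, n_persistent = NULL,
                       loss_rate = 2.1, rate_dist = rate_exponential(0.06),
                       kappa = 1.1, base_freqs = c(0.25, 0.25, 0.25, 0.25),
                       transfer_mode = c("none", "occasional", "frequent"),
                       gene_length = 900, paralog_fraction = 0.5,
                       family_divergence = c(0.3, 0.9),
                       drop_genes = 0, time_scale = 0.5, seed = 1) {
  transfer_mode <- match.arg(transfer_mode)
  n_ancestral <- n_ancestral %||% round(n_genes * 2100 / 2803)
  n_persistent <- n_persistent %||% round(n_genes * 300 / 2803)
  if (!(n_persistent <= n_ancestral && n_ancestral <= n_genes))
    fatal("need n_persistent <= n_ancestral <= n_genes")
  if (loss_rate < 0 || gene_length %% 3 != 0)
    fatal("loss_rate must be >= 0 and gene_length a multiple of 3")
  structure(list(n_strains = n_strains, n_genes = n_genes,
                 n_ancestral = n_ancestral, n_persistent = n_persistent,
                 loss_rate = loss_rate, rate_dist = rate_dist, kappa = kappa,
                 base_freqs = base_freqs / sum(base_freqs),
                 transfer_mode = transfer_mode, gene_length = gene_length,
                 paralog_fraction = paralog_fraction,
                 family_divergence = family_divergence,
                 drop_genes = drop_genes, time_scale = time_scale, seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @param mean,min,max,mu distribution parameters.
#' @export
rate_exponential <- function(mean = 0.06) list(kind = "exponential", mean = mean)
#' @rdname sim_config
#' @export
rate_uniform <- function(min, max) list(kind = "uniform", min = min, max = max)
#' @rdname sim_config
#' @export
rate_constant <- function(mu) list(kind = "constant", mu = mu)

draw_rates <- function(n, rd) {
  switch(rd$kind,
         exponential = rexp(n, 1 / rd$mean),
         uniform = runif(n, rd$min, rd$max),
         constant = rep(rd$mu, n),
         fatal("unknown rate distribution '%s'", rd$kind))
}

#' Simulate a clonal genealogy
#'
#' Standard Kingman coalescent (exponential pairwise-merger waiting times)
#' in coalescent units.
#'
#' @param n number of strains (>= 2).
#' @param seed optional RNG seed.
#' @return ultrametric `phylo` with tips `S001...`.
#' @export
simulate_clonal_tree <- function(n, seed = NULL) {
  if (n < 2) fatal("need at least 2 strains")
  if (!is.null(seed)) set.seed(seed)
  ape::rcoal(n, tip.label = sprintf("S%03d", seq_len(n)))
}

# One leaf prune-regraft move preserving ultrametry and total depth.
spr_perturb <- function(tree) {
  nt <- length(tree$tip.label)
  if (nt < 3) return(tree)
  depth <- max(ape::node.depth.edgelength(tree))
  leaf <- sample(tree$tip.label, 1)
  pruned <- ape::drop.tip(tree, leaf)
  dd <- ape::node.depth.edgelength(pruned)
  # choose an attachment point uniformly on the pruned tree's branches
  wts <- pruned$edge.length
  e <- sample(seq_len(nrow(pruned$edge)), 1, prob = wts)
  pos <- runif(1, 0, pruned$edge.length[e])
  v <- pruned$edge[e, 2]
  attach_depth <- dd[v] - pos
  out <- phytools::bind.tip(pruned, leaf, edge.length = depth - attach_depth,
                            where = v, position = pos)
  out
}

#' Simulate per-gene trees correlated with the clonal tree
#'
#' With no transfer every gene tree equals the clonal genealogy; with
#' occasional (frequent) transfer each gene independently receives one
#' prune-regraft perturbation with probability 0.3 (up to two, each with
#' probability `1 - sqrt(0.4)`, i.e. at least one with probability 0.6),
#' leaving the leaf set and total tree depth unchanged.
#'
#' @param clonal_tree the clonal genealogy.
#' @param n_genes number of gene trees.
#' @param transfer_mode `"none"`, `"occasional"` or `"frequent"`.
#' @param seed optional RNG seed.
#' @return list of `phylo` trees.
#' @export
simulate_gene_trees <- function(clonal_tree, n_genes,
                                transfer_mode = c("none", "occasional", "frequent"),
                                seed = NULL) {
  transfer_mode <- match.arg(transfer_mode)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_genes), function(j) {
    k <- switch(transfer_mode,
                none = 0L,
                occasional = rbinom(1, 1, 0.3),
                frequent = rbinom(1, 2, 1 - sqrt(0.4)))
    tr <- clonal_tree
    while (k > 0) { tr <- spr_perturb(tr); k <- k - 1L }
    tr
  })
}

#' Evolve gene content: gains at uniform branch points, exponential loss
#'
#' The first `n_ancestral` genes are present at the MRCA; the remaining
#' genes gain an origin at a point drawn uniformly over the total branch
#' length of their gene tree.  Non-persistent genes are lost at
#' `loss_rate` per unit branch length below their origin; a loss removes
#' the gene from the entire descendant clade.  Genes surviving nowhere are
#' dropped from the truth set.
#'
#' @param gene_trees list of gene trees from [simulate_gene_trees()].
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return list with `presence` (logical matrix genes x strains, only
#'   surviving genes), `origin` (data.frame gene, ancestral, persistent,
#'   origin_edge), and `gene_ids`.
#' @export
evolve_gene_content <- function(gene_trees, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_genes <- length(gene_trees)
  strains <- gene_trees[[1]]$tip.label
  pres <- matrix(FALSE, n_genes, length(strains),
                 dimnames = list(sprintf("G%04d", seq_len(n_genes)), strains))
  origin_edge <- integer(n_genes)
  for (j in seq_len(n_genes)) {
    tr <- gene_trees[[j]]
    ancestral <- j <= config$n_ancestral
    persistent <- j <= config$n_persistent
    below <- edge_leaf_matrix(tr)
    if (ancestral) {
      origin_edge[j] <- 0L
      alive <- rep(TRUE, length(tr$tip.label))
      sub_edges <- seq_len(nrow(tr$edge))
      efflen <- tr$edge.length
    } else {
      e0 <- sample(seq_len(nrow(tr$edge)), 1, prob = tr$edge.length)
      origin_edge[j] <- e0
      frac <- runif(1)                  # position of the origin on its edge
      alive <- below[e0, ]
      # clades nest, so an edge lies below the origin iff its leaf set is a
      # subset of the origin edge's clade
      e0_set <- below[e0, ]
      sub_edges <- which(vapply(seq_len(nrow(below)), function(e)
        all(below[e, ] <= e0_set), logical(1)))
      efflen <- tr$edge.length[sub_edges]
      efflen[sub_edges == e0] <- tr$edge.length[e0] * frac  # part below the origin point
    }
    if (!persistent && config$loss_rate > 0) {
      p_loss <- 1 - exp(-config$loss_rate * efflen)
      lost <- sub_edges[runif(length(sub_edges)) < p_loss]
      for (e in lost) alive <- alive & !below[e, ]
    }
    pres[j, match(tr$tip.label, strains)] <- alive
  }
  surviving <- rowSums(pres) > 0
  list(presence = pres[surviving, , drop = FALSE],
       origin = data.frame(gene = rownames(pres),
                           ancestral = seq_len(n_genes) <= config$n_ancestral,
                           persistent = seq_len(n_genes) <= config$n_persistent,
                           origin_edge = origin_edge,
                           surviving = surviving),
       gene_ids = rownames(pres)[surviving])
}

# --- HKY machinery -----------------------------------------------------------

#' HKY rate matrix (normalized to one expected substitution per unit time)
#' @param kappa transition-transversion bias.
#' @param bf base frequencies (A, C, G, T).
#' @return 4x4 rate matrix.
#' @export
hky_Q <- function(kappa, bf) {
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ts <- (bases[i] %in% c("A", "G") && bases[j] %in% c("A", "G")) ||
      (bases[i] %in% c("C", "T") && bases[j] %in% c("C", "T"))
    Q[i, j] <- bf[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  beta <- -sum(bf * diag(Q))
  Q / beta
}

#' HKY transition probabilities over branch length t
#' @param t branch length in expected substitutions/site.
#' @param kappa transition-transversion bias.
#' @param bf base frequencies.
#' @return 4x4 transition probability matrix.
#' @export
hky_P <- function(t, kappa, bf) {
  eig <- eigen(hky_Q(kappa, bf))
  P <- eig$vectors %*% diag(exp(eig$values * t)) %*% solve(eig$vectors)
  P[P < 0] <- 0
  P / rowSums(P)
}

random_codon_seq <- function(len_nt, bf) {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T"))[, 3:1], 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_codons <- len_nt / 3
  body <- sample(sense, n_codons - 1, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

evolve_down_tree <- function(tree, root_seq_int, mu, kappa, bf) {
  nn <- length(tree$tip.label) + tree$Nnode
  eo <- ape::reorder.phylo(tree, "postorder")
  root <- eo$edge[nrow(eo$edge), 1]
  L <- length(root_seq_int)
  seqs <- matrix(NA_integer_, nn, L)
  seqs[root, ] <- root_seq_int
  eig <- eigen(hky_Q(kappa, bf))
  Vinv <- solve(eig$vectors)
  for (k in rev(seq_len(nrow(eo$edge)))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    t <- mu * eo$edge.length[k]
    P <- eig$vectors %*% diag(exp(eig$values * t)) %*% Vinv
    P[P < 0] <- 0; P <- P / rowSums(P)
    parent <- seqs[p, ]
    child <- integer(L)
    for (s in 1:4) {
      idx <- which(parent == s)
      if (length(idx))
        child[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
    }
    seqs[ch, ] <- child
  }
  seqs
}

#' Evolve sequences and emit strain genomes plus the truth table
#'
#' Each surviving gene's ancestral sequence is evolved down its gene tree
#' under HKY (per-gene substitution rate drawn from the configured
#' distribution); leaf sequences of strains carrying the gene are packaged
#' into [strain_genome] objects, and the truth table records the true
#' cluster of every emitted gene.
#'
#' @param gene_trees list of gene trees.
#' @param content output of [evolve_gene_content()].
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return list with `genomes` (list of [strain_genome]), `truth`
#'   (data.frame gene_id, strain_id, true_cluster, rate), `rates`, and
#'   `ancestors` (named nt sequences).
#' @export
evolve_sequences <- function(gene_trees, content, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  genes <- content$gene_ids
  gidx <- match(genes, rownames(content$presence))
  n_total <- length(gene_trees)
  ancestors <- sim_ancestral_pool(n_total, config)
  rates <- draw_rates(n_total, config$rate_dist)
  strains <- colnames(content$presence)
  per_strain <- setNames(lapply(strains, function(s) list()), strains)
  truth <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    j <- as.integer(sub("^G", "", g))
    tr <- gene_trees[[j]]
    anc_int <- match(strsplit(ancestors[[j]], "")[[1]], bases)
    seqs <- evolve_down_tree(tr, anc_int, rates[j], config$kappa, config$base_freqs)
    present <- strains[content$presence[gidx[gi], ]]
    for (s in present) {
      tip <- match(s, tr$tip.label)
      nt <- paste(bases[seqs[tip, ]], collapse = "")
      per_strain[[s]][[g]] <- nt
    }
    truth[[gi]] <- data.frame(gene_id = paste0(present, "|", g),
                              strain_id = present, true_cluster = g,
                              rate = rates[j], stringsAsFactors = FALSE)
  }
  if (config$drop_genes > 0) {
    for (s in strains) {
      gs <- names(per_strain[[s]])
      drop <- gs[runif(length(gs)) < config$drop_genes]
      per_strain[[s]][drop] <- NULL
    }
    kept <- unlist(lapply(strains, function(s)
      paste0(s, "|", names(per_strain[[s]]))), use.names = FALSE)
    truth <- lapply(truth, function(df) df[df$gene_id %in% kept, , drop = FALSE])
  }
  genomes <- lapply(strains, function(s) {
    gs <- names(per_strain[[s]])
    if (!length(gs)) {
      return(strain_genome(s, gene_table(character(0), character(0), character(0),
                                         integer(0), integer(0), character(0),
                                         character(0), character(0))))
    }
    nt <- unlist(per_strain[[s]], use.names = FALSE)
    aa <- translate_cds(nt)
    spacer <- 50L
    starts <- cumsum(c(0L, head(nchar(nt), -1) + spacer))
    df <- gene_table(gene_id = paste0(s, "|", gs), strain_id = s,
                     contig_id = "chr1", start = starts,
                     end = starts + nchar(nt), strand = "+",
                     nt_seq = nt, aa_seq = aa, annotation = "simulated gene")
    contig_len <- max(df$end) + spacer
    contig <- paste(sample(bases, contig_len, replace = TRUE,
                           prob = config$base_freqs), collapse = "")
    for (i in seq_len(nrow(df)))
      substr(contig, df$start[i] + 1, df$end[i]) <- df$nt_seq[i]
    strain_genome(s, df, contigs = c(chr1 = contig))
  })
  names(genomes) <- strains
  list(genomes = genomes, truth = do.call(rbind, truth), rates = rates,
       ancestors = ancestors)
}

# Ancestral gene pool with paralogous-family structure: a fraction of the
# gene seeds are diverged copies of shared family ancestors.
sim_ancestral_pool <- function(n_genes, config) {
  L <- config$gene_length
  out <- character(n_genes)
  n_fam_genes <- round(config$paralog_fraction * n_genes)
  idx <- sample.int(n_genes)        # random assignment of genes to families
  fam_members <- idx[seq_len(n_fam_genes)]
  singles <- idx[-seq_len(n_fam_genes)]
  bases <- c("A", "C", "G", "T")
  # family sizes follow a truncated power law (exponent 2, sizes 2..50),
  # the documented shape of paralogous-family sizes in bacterial genomes:
  # a few large families carry much of the paralogy
  sizes_support <- 2:50
  sizes_prob <- sizes_support^-2
  pos <- 1L
  while (pos <= length(fam_members)) {
    size <- min(sample(sizes_support, 1, prob = sizes_prob),
                length(fam_members) - pos + 1L)
    if (size == 1L) { singles <- c(singles, fam_members[pos]); break }
    members <- fam_members[pos:(pos + size - 1L)]
    pos <- pos + size
    root <- random_codon_seq(L, config$base_freqs)
    root_int <- match(strsplit(root, "")[[1]], bases)
    for (m in members) {
      d <- runif(1, config$family_divergence[1] / 2, config$family_divergence[2] / 2)
      P <- hky_P(d, config$kappa, config$base_freqs)
      seq_int <- vapply(root_int, function(s)
        sample.int(4, 1, prob = P[s, ]), integer(1))
      out[m] <- paste(bases[seq_int], collapse = "")
    }
  }
  for (m in singles) out[m] <- random_codon_seq(L, config$base_freqs)
  out
}

#' Simulate a complete pan-genome with known truth
#'
#' Runs the full generator: clonal tree, per-gene trees, gene content, and
#' sequence evolution.  Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genomes`, `truth`, `clonal_tree`, `gene_trees`,
#'   `presence`, `origin`, `rates`, `ancestors`, and `config`.
#' @export
simulate_pangenome <- function(config = sim_config()) {
  set.seed(config$seed)
  clonal <- simulate_clonal_tree(config$n_strains)
  # rates (loss, substitution) are quoted per 4N-generation unit; the
  # coalescent tree is in 2N units
  clonal$edge.length <- clonal$edge.length * config$time_scale
  gts <- simulate_gene_trees(clonal, config$n_genes, config$transfer_mode)
  content <- evolve_gene_content(gts, config)
  seqs <- evolve_sequences(gts, content, config)
  c(seqs, list(clonal_tree = clonal, gene_trees = gts,
               presence = content$presence, origin = content$origin,
               config = config))
}

#' Write simulator outputs to disk
#'
#' Emits per-strain genomes (GenBank or nucleotide+protein FASTA pairs),
#' the truth table as TSV, and gene trees as newick.
#'
#' @param sim output of [simulate_pangenome()].
#' @param dir output directory (created).
#' @param format `"genbank"` or `"fasta"`.
#' @export
write_pangenome <- function(sim, dir, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in sim$genomes) {
    if (!nrow(g$genes)) next
    if (format == "genbank") {
      write_genbank(g, file.path(dir, paste0(g$strain_id, ".gbk")))
    } else {
      write_fasta(setNames(g$genes$nt_seq, g$genes$gene_id),
                  file.path(dir, paste0(g$strain_id, ".fna")), type = "nt")
      write_fasta(setNames(g$genes$aa_seq, g$genes$gene_id),
                  file.path(dir, paste0(g$strain_id, ".faa")), type = "aa")
    }
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$clonal_tree, file.path(dir, "clonal_tree.nwk"))
  invisible(dir)
}
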