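# Core-genome SNP tree, joint ancestral sequence reconstruction on gene
# trees, and ancestral inference of gene presence/absence under a two-state
# (gain/loss) Markov model with maximum-likelihood rates.

#' Core-genome SNP matrix and strain tree
#'
#' Extracts all variable positions (at least two distinct non-gap
#' characters) from the codon alignments of every single-copy core cluster,
#' concatenates them per strain, and builds the strain tree from the
#' resulting SNP matrix with [build_tree()].
#'
#' @param clusters named list of clusters.
#' @param genes gene table.
#' @param strains all strain ids (need >= 3).
#' @param alignments optional precomputed nucleotide alignments by cluster.
#' @param config a [split_config()] (aligner/tree settings).
#' @return list with `snp` (strains x positions character matrix),
#'   `positions` (data.frame cluster_id, column) and `tree` (phylo with
#'   strain tip labels).
#' @export
core_snp_tree <- function(clusters, genes, strains = unique(genes$strain_id),
                          alignments = NULL, config = split_config()) {
  if (length(strains) < 3) fatal("need at least 3 strains for a strain tree")
  info <- cluster_info(clusters, genes, strains)
  sc <- which(info$is_core & info$is_single_copy)
  if (!length(sc)) {
    # fall back to soft single-copy core (single copy where present,
    # covering most strains); absent strains contribute gap columns
    sc <- which(info$is_single_copy & !info$duplicated &
                  info$n_strains >= 0.7 * length(strains) & info$n_members >= 3)
    if (length(sc))
      warning("no strict single-copy core clusters; SNP matrix built from soft-core clusters (absent strains as gaps)")
  }
  if (!length(sc)) fatal("no single-copy core clusters; cannot build a core SNP tree")
  snp_cols <- list(); pos <- list()
  for (i in sc) {
    cid <- names(clusters)[i]
    aln <- alignments[[cid]]
    if (is.null(aln)) aln <- cluster_phylo(clusters[[i]], genes, config, tree = FALSE)$aln_nt
    sm <- strain_of(names(aln), genes)
    have <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
    rows <- matrix("-", length(strains), ncol(have),
                   dimnames = list(strains, NULL))
    rows[unname(sm), ] <- have
    is_var <- apply(rows, 2, function(col) {
      nu <- unique(col[col %in% c("A", "C", "G", "T")])
      length(nu) >= 2
    })
    if (any(is_var)) {
      snp_cols[[cid]] <- rows[, is_var, drop = FALSE]
      pos[[cid]] <- data.frame(cluster_id = cid, column = which(is_var))
    }
  }
  if (!length(snp_cols))
    fatal("core genomes are identical (no variable positions); supply a strain tree manually")
  snp <- do.call(cbind, snp_cols)
  aln <- setNames(apply(snp, 1, paste, collapse = ""), strains)
  tree <- build_tree(aln, command = config$tree_command)
  list(snp = snp, positions = do.call(rbind, pos), tree = tree)
}

# JC69 transition log-probabilities for branch length t.
jc_logP <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  # guard zero-length branches: diff=0 -> -Inf is fine in max-product
  m <- matrix(log(diff), 4, 4)
  diag(m) <- log(same)
  m
}

#' Joint ML ancestral sequences on a gene tree
#'
#' Joint maximum-likelihood reconstruction (max-product dynamic programming
#' over the tree) under a JC69 substitution model with the tree's branch
#' lengths; gap or ambiguous characters are treated as missing.  Mutations
#' are assigned to the branches where parent and child states differ.
#'
#' @param tree rooted `phylo`; tip labels must be alignment row names.
#' @param aln named character vector of aligned nucleotide rows.
#' @return list with `states` (character matrix, internal nodes x sites)
#'   and `mutations` (data.frame: edge, child, site, from, to).
#' @export
ancestral_sequences <- function(tree, aln) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  L <- if (length(aln)) nchar(aln[[1]]) else 0L
  if (L == 0) return(list(states = matrix(character(0), 0, 0),
                          mutations = data.frame()))
  bases <- c("A", "C", "G", "T")
  X <- do.call(rbind, strsplit(toupper(unname(aln[tree$tip.label])), ""))
  obs <- matrix(match(X, bases), nt, L)     # NA = missing
  eo <- ape::reorder.phylo(tree, "postorder")
  root <- eo$edge[nrow(eo$edge), 1]
  # A[[node]] = 4 x L matrix of summed child C-scores
  A <- vector("list", nn)
  Cs <- vector("list", nn)                   # C_s given parent state, 4 x L
  Ptr <- vector("list", nn)                  # chosen own state, 4 x L
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]; t <- eo$edge.length[k]
    lp <- jc_logP(max(t, 1e-9))
    if (ch <= nt) {
      x <- obs[ch, ]
      C <- matrix(0, 4, L); P <- matrix(NA_integer_, 4, L)
      known <- !is.na(x)
      C[, known] <- lp[, x[known]]
      P[, known] <- rep(x[known], each = 4)
      # missing leaf: contributes nothing; state imputed as parent's
      Cs[[ch]] <- C; Ptr[[ch]] <- P
    } else {
      Asub <- A[[ch]]
      C <- matrix(0, 4, L); P <- matrix(NA_integer_, 4, L)
      for (s in 1:4) {
        cand <- lp[s, ] + Asub                 # 4 x L: own-state candidates
        best <- max.col(t(cand), ties.method = "first")
        P[s, ] <- best
        C[s, ] <- cand[cbind(best, seq_len(L))]
      }
      Cs[[ch]] <- C; Ptr[[ch]] <- P
    }
    A[[p]] <- (A[[p]] %||% matrix(0, 4, L)) + Cs[[ch]]
  }
  # root choice and preorder backtrack
  states <- matrix(NA_integer_, nn, L)
  root_cand <- log(0.25) + A[[root]]
  states[root, ] <- max.col(t(root_cand), ties.method = "first")
  po <- rev(seq_len(nrow(eo$edge)))
  for (k in po) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    ps <- states[p, ]
    own <- Ptr[[ch]][cbind(ps, seq_len(L))]
    own[is.na(own)] <- ps[is.na(own)]          # missing leaves follow parent
    states[ch, ] <- own
  }
  muts <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    comparable <- if (ch <= nt) !is.na(obs[ch, ]) else rep(TRUE, L)
    dif <- which(states[p, ] != states[ch, ] & comparable)
    if (length(dif))
      muts[[length(muts) + 1]] <- data.frame(
        edge = k, child = ch, site = dif,
        from = bases[states[p, dif]], to = bases[states[ch, dif]])
  }
  internal <- (nt + 1):nn
  smat <- matrix(bases[states[internal, , drop = FALSE]], length(internal), L)
  rownames(smat) <- paste0("node", internal)
  list(states = smat,
       mutations = if (length(muts)) do.call(rbind, muts) else
         data.frame(edge = integer(0), child = integer(0), site = integer(0),
                    from = character(0), to = character(0)))
}

#' Two-state transition probabilities
#'
#' Continuous-time Markov chain on {absent = 0, present = 1} with gain rate
#' `g` (0 to 1) and loss rate `l` (1 to 0), over branch length `t`:
#' `P(1->1) = (g + l e^{-(g+l)t})/(g+l)` etc.
#'
#' @param t branch length.
#' @param g,l gain and loss rates (> 0).
#' @return 2x2 matrix, rows = from-state (absent, present).
#' @export
gainloss_P <- function(t, g, l) {
  s <- g + l
  e <- exp(-s * t)
  matrix(c((l + g * e) / s, (g - g * e) / s,
           (l - l * e) / s, (g + l * e) / s),
         2, 2, byrow = TRUE,
         dimnames = list(c("absent", "present"), c("absent", "present")))
}

#' Build the presence/absence matrix of clusters over strains
#' @param clusters named list of clusters.
#' @param genes gene table.
#' @param strains all strain ids (column order).
#' @return logical matrix clusters x strains.
#' @export
presence_absence_matrix <- function(clusters, genes, strains = unique(genes$strain_id)) {
  st <- strain_of(genes$gene_id, genes)
  pam <- t(vapply(clusters, function(m) strains %in% st[m], logical(length(strains))))
  colnames(pam) <- strains
  rownames(pam) <- names(clusters)
  pam
}

# Felsenstein pruning log-likelihood, vectorized across clusters (pam rows).
gainloss_loglik <- function(tree, pam, g, l) {
  tips <- tree$tip.label
  X <- pam[, tips, drop = FALSE]             # clusters x tips
  ncl <- nrow(X)
  nt <- length(tips)
  nn <- nt + tree$Nnode
  P0 <- matrix(1, nn, ncl); P1 <- matrix(1, nn, ncl)
  P0[seq_len(nt), ] <- t(!X); P1[seq_len(nt), ] <- t(X)
  eo <- ape::reorder.phylo(tree, "postorder")
  root <- eo$edge[nrow(eo$edge), 1]
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    M <- gainloss_P(eo$edge.length[k], g, l)
    c0 <- M[1, 1] * P0[ch, ] + M[1, 2] * P1[ch, ]
    c1 <- M[2, 1] * P0[ch, ] + M[2, 2] * P1[ch, ]
    P0[p, ] <- P0[p, ] * c0
    P1[p, ] <- P1[p, ] * c1
  }
  pi1 <- g / (g + l)
  lik <- (1 - pi1) * P0[root, ] + pi1 * P1[root, ]
  sum(log(pmax(lik, 1e-300)))
}

#' Fit gain and loss rates by maximum likelihood
#'
#' Two-state continuous-time Markov model of gene presence on the strain
#' tree; per-cluster likelihoods by Felsenstein pruning with the stationary
#' root prior, summed over clusters and maximized over (g, l) by bounded
#' quasi-Newton optimization on the log scale.
#'
#' @param tree strain tree (tips = pam columns).
#' @param pam logical presence/absence matrix (clusters x strains).
#' @param lower,upper rate bounds.
#' @return a `gain_loss_model`: list with `gain`, `loss`, `ratio` (loss/gain),
#'   `logLik`, and `degenerate` flag (all-present matrix drives loss to its
#'   lower bound).
#' @export
fit_gain_loss <- function(tree, pam, lower = 1e-4, upper = 1e3) {
  stopifnot(all(tree$tip.label %in% colnames(pam)))
  nll <- function(par) -gainloss_loglik(tree, pam, exp(par[1]), exp(par[2]))
  fit <- optim(c(log(0.1), log(1)), nll, method = "L-BFGS-B",
               lower = log(lower), upper = log(upper))
  g <- exp(fit$par[1]); l <- exp(fit$par[2])
  degenerate <- all(pam) && l <= lower * 1.01
  if (all(pam)) warning("all-present matrix: loss rate is not identifiable (driven to its lower bound)")
  structure(list(gain = g, loss = l, ratio = l / g, logLik = -fit$value,
                 degenerate = degenerate),
            class = "gain_loss_model")
}

#' @export
print.gain_loss_model <- function(x, ...) {
  cat(sprintf("<gain_loss_model> gain=%.4g loss=%.4g loss/gain=%.3g logLik=%.2f\n",
              x$gain, x$loss, x$ratio, x$logLik))
  invisible(x)
}

#' Joint ML ancestral presence/absence and gain/loss events
#'
#' Joint maximum-likelihood states at the internal nodes of the strain tree
#' under the fitted two-state model; a gain (loss) event is placed on every
#' branch where the state flips from absent to present (present to absent).
#'
#' @param tree strain tree.
#' @param pam logical presence/absence matrix.
#' @param model a [fit_gain_loss()] model.
#' @return list with `states` (logical matrix, all nodes x clusters) and
#'   `events` (data.frame: cluster_id, edge, child, event).
#' @export
ancestral_presence <- function(tree, pam, model) {
  g <- model$gain; l <- model$loss
  tips <- tree$tip.label
  X <- t(pam[, tips, drop = FALSE])          # tips x clusters
  ncl <- ncol(X)
  nt <- length(tips)
  nn <- nt + tree$Nnode
  eo <- ape::reorder.phylo(tree, "postorder")
  root <- eo$edge[nrow(eo$edge), 1]
  A0 <- matrix(0, nn, ncl); A1 <- matrix(0, nn, ncl)
  C0 <- vector("list", nn); C1 <- vector("list", nn)   # given parent state
  S0 <- vector("list", nn); S1 <- vector("list", nn)   # chosen own state
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    M <- log(gainloss_P(max(eo$edge.length[k], 1e-9), g, l))
    if (ch <= nt) {
      x <- X[ch, ]
      c0 <- ifelse(x, M[1, 2], M[1, 1])
      c1 <- ifelse(x, M[2, 2], M[2, 1])
      s0 <- s1 <- as.integer(x)
    } else {
      cand00 <- M[1, 1] + A0[ch, ]; cand01 <- M[1, 2] + A1[ch, ]
      cand10 <- M[2, 1] + A0[ch, ]; cand11 <- M[2, 2] + A1[ch, ]
      s0 <- as.integer(cand01 > cand00)
      s1 <- as.integer(cand11 >= cand10)     # ties keep the parent's state
      c0 <- pmax(cand00, cand01)
      c1 <- pmax(cand10, cand11)
    }
    C0[[ch]] <- c0; C1[[ch]] <- c1; S0[[ch]] <- s0; S1[[ch]] <- s1
    A0[p, ] <- A0[p, ] + c0
    A1[p, ] <- A1[p, ] + c1
  }
  pi1 <- g / (g + l)
  states <- matrix(NA_integer_, nn, ncl)
  states[root, ] <- as.integer(log(pi1) + A1[root, ] > log(1 - pi1) + A0[root, ])
  for (k in rev(seq_len(nrow(eo$edge)))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    ps <- states[p, ]
    states[ch, ] <- ifelse(ps == 1, S1[[ch]], S0[[ch]])
  }
  ev <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    flip <- which(states[p, ] != states[ch, ])
    if (length(flip))
      ev[[length(ev) + 1]] <- data.frame(
        cluster_id = rownames(pam)[flip], edge = k, child = ch,
        event = ifelse(states[ch, flip] == 1, "gain", "loss"))
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cluster_id = character(0), edge = integer(0),
               child = integer(0), event = character(0))
  smat <- states == 1
  rownames(smat) <- c(tips, paste0("node", (nt + 1):nn))
  colnames(smat) <- rownames(pam)
  list(states = smat, events = events)
}

#' Count gain/loss events per cluster
#' @param events event table from [ancestral_presence()].
#' @param cluster_ids clusters to count for.
#' @return named integer vector.
#' @export
event_counts <- function(events, cluster_ids) {
  n <- table(factor(events$cluster_id, levels = cluster_ids))
  setNames(as.integer(n), cluster_ids)
}

#' Simulate presence/absence patterns under the two-state model
#'
#' Draws the root state from the stationary distribution and propagates it
#' down the tree with [gainloss_P()] transition probabilities; used for
#' parameter-recovery checks.
#'
#' @param tree strain tree.
#' @param g,l gain and loss rates.
#' @param n number of clusters (rows).
#' @return logical matrix n x tips.
#' @export
simulate_pam <- function(tree, g, l, n) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  eo <- ape::reorder.phylo(tree, "postorder")
  root <- eo$edge[nrow(eo$edge), 1]
  states <- matrix(NA_integer_, nn, n)
  pi1 <- g / (g + l)
  states[root, ] <- as.integer(runif(n) < pi1)
  for (k in rev(seq_len(nrow(eo$edge)))) {
    p <- eo$edge[k, 1]; ch <- eo$edge[k, 2]
    M <- gainloss_P(eo$edge.length[k], g, l)
    pr1 <- ifelse(states[p, ] == 1, M[2, 2], M[1, 2])
    states[ch, ] <- as.integer(runif(n) < pr1)
  }
  out <- t(states[seq_len(nt), , drop = FALSE]) == 1
  colnames(out) <- tree$tip.label
  out
}
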