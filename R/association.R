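# Association of numeric strain phenotypes with gene-tree branches and with
# gene presence/absence.

#' Branch association score of a gene tree with a phenotype
#'
#' For every branch, the phenotyped leaves are partitioned into the two
#' sides of the branch and the score `|mu1 - mu2| / sqrt(s1^2 + s2^2)` is
#' computed with population variances (ddof 0); the maximum over branches
#' is returned.  A zero denominator with distinct means yields an infinite
#' score, flagged via the `"degenerate"` attribute.  Branches with an empty
#' phenotyped side are skipped; with fewer than 3 phenotyped leaves the
#' result is `NULL`.
#'
#' @param tree gene tree; tip labels are mapped to strains via `strain_map`
#'   when given, else used as strain ids directly.
#' @param phenotypes named numeric vector strain_id -> value (`NA` allowed).
#' @param strain_map optional named map tip label -> strain_id.
#' @return maximum branch score (or `NULL`), with attributes `edge` (the
#'   maximizing branch) and `degenerate`.
#' @export
branch_association <- function(tree, phenotypes, strain_map = NULL) {
  tips <- tree$tip.label
  strains <- if (is.null(strain_map)) tips else unname(strain_map[tips])
  ph <- phenotypes[strains]
  ok <- !is.na(ph)
  if (sum(ok) < 3) return(NULL)
  below <- edge_leaf_matrix(tree)
  best <- -Inf; best_edge <- NA_integer_; degenerate <- FALSE
  for (k in seq_len(nrow(below))) {
    in1 <- below[k, ] & ok
    in2 <- !below[k, ] & ok
    if (!any(in1) || !any(in2)) next
    m1 <- mean(ph[in1]); m2 <- mean(ph[in2])
    v1 <- mean((ph[in1] - m1)^2); v2 <- mean((ph[in2] - m2)^2)
    denom <- sqrt(v1 + v2)
    s <- if (denom == 0) { if (m1 == m2) 0 else Inf } else abs(m1 - m2) / denom
    if (s > best) { best <- s; best_edge <- k; degenerate <- is.infinite(s) }
  }
  if (is.infinite(best) && best < 0) return(NULL)
  structure(best, edge = best_edge, degenerate = degenerate)
}

#' Presence/absence association score
#'
#' `p_a = sqrt(n) * (mu_a - mu_p) / sigma` with `mu_p`/`mu_a` the mean
#' phenotype of strains carrying/lacking the gene, `sigma` the overall
#' population standard deviation of the phenotype, and `n` the number of
#' inferred gain/loss events of the cluster.  Undefined (`NULL`) when the
#' gene is present or absent in all phenotyped strains or `sigma` is 0.
#'
#' @param present logical vector named by strain: does the strain carry the
#'   gene?
#' @param phenotypes named numeric vector strain_id -> value.
#' @param n_events number of gain/loss events (from [ancestral_presence()]).
#' @return signed score (ranking uses its absolute value), or `NULL`.
#' @export
presence_association <- function(present, phenotypes, n_events) {
  strains <- intersect(names(present), names(phenotypes))
  ph <- phenotypes[strains]
  ok <- !is.na(ph)
  ph <- ph[ok]; pres <- present[strains][ok]
  if (length(ph) < 2 || all(pres) || !any(pres)) return(NULL)
  sigma <- sqrt(mean((ph - mean(ph))^2))
  if (sigma == 0) return(NULL)
  sqrt(n_events) * (mean(ph[!pres]) - mean(ph[pres])) / sigma
}

#' Rank clusters by phenotype association
#'
#' Computes both scores for every cluster and sorts by decreasing absolute
#' score (undefined scores last, stable order).
#'
#' @param clusters named list of clusters.
#' @param genes gene table.
#' @param phenotypes named numeric vector strain_id -> value.
#' @param pam presence/absence matrix from [presence_absence_matrix()].
#' @param events event table from [ancestral_presence()].
#' @param trees optional named list of gene trees for the branch score.
#' @param sort_by `"presence"` (default) or `"branch"`.
#' @return data.frame: cluster_id, branch_assoc, presence_assoc, n_events,
#'   sorted.
#' @export
rank_associations <- function(clusters, genes, phenotypes, pam, events,
                              trees = NULL, sort_by = c("presence", "branch")) {
  sort_by <- match.arg(sort_by)
  ids <- names(clusters)
  nev <- event_counts(events, ids)
  res <- data.frame(cluster_id = ids, branch_assoc = NA_real_,
                    presence_assoc = NA_real_, n_events = unname(nev),
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    p <- presence_association(pam[ids[i], ], phenotypes, nev[[ids[i]]])
    if (!is.null(p)) res$presence_assoc[i] <- p
    tr <- trees[[ids[i]]]
    if (!is.null(tr)) {
      sm <- strain_of(tr$tip.label, genes)
      b <- branch_association(tr, phenotypes, strain_map = sm)
      if (!is.null(b)) res$branch_assoc[i] <- as.numeric(b)
    }
  }
  key <- if (sort_by == "presence") abs(res$presence_assoc) else abs(res$branch_assoc)
  res[order(-key, na.last = TRUE), , drop = FALSE]
}
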