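# Benchmarking inferred clusters against a simulator truth table.

#' Score inferred clusters against the simulated truth
#'
#' Each inferred cluster falls into one of four outcomes: (i) correct — it
#' contains all and only genes of one true cluster; (ii) incomplete — only
#' genes of one true cluster, but not all of them; (iii) contaminated — all
#' genes of one true cluster plus genes of others; (iv) both — neither
#' pure nor complete for any true cluster.  The misclustered gene fraction
#' is the fraction of genes not sitting in a correct cluster.
#'
#' @param inferred list of clusters (gene-id vectors).
#' @param truth data.frame with columns `gene_id` and `true_cluster`.
#' @return list with `counts` (named vector over the four outcomes),
#'   `n_true` (number of true clusters), `n_correct`,
#'   `misclustered_gene_fraction`, and `per_cluster` (data.frame).
#' @export
cluster_accuracy <- function(inferred, truth) {
  tc <- setNames(truth$true_cluster, truth$gene_id)
  true_sets <- split(truth$gene_id, truth$true_cluster)
  all_genes <- unlist(inferred, use.names = FALSE)
  unknown <- setdiff(all_genes, names(tc))
  if (length(unknown)) fatal("gene_id not in truth table: %s", unknown[1])
  category <- character(length(inferred))
  for (i in seq_along(inferred)) {
    m <- inferred[[i]]
    tcs <- unique(tc[m])
    if (length(tcs) == 1) {
      category[i] <- if (setequal(m, true_sets[[tcs]])) "correct" else "incomplete"
    } else {
      complete_any <- any(vapply(tcs, function(t)
        all(true_sets[[t]] %in% m), logical(1)))
      category[i] <- if (complete_any) "contaminated" else "both"
    }
  }
  counts <- table(factor(category,
                         levels = c("correct", "incomplete", "contaminated", "both")))
  n_genes_correct <- sum(lengths(inferred)[category == "correct"])
  list(counts = setNames(as.integer(counts), names(counts)),
       n_true = length(true_sets),
       n_correct = unname(counts["correct"]),
       misclustered_gene_fraction = 1 - n_genes_correct / length(all_genes),
       per_cluster = data.frame(cluster = seq_along(inferred),
                                size = lengths(inferred), category = category,
                                stringsAsFactors = FALSE))
}
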