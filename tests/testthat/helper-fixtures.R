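# Fixtures built in code at test time.

# A small two-contig GenBank file: a plus-strand CDS, a complement CDS, a
# joined CDS, and a pseudogene that must be skipped.
write_genbank_fixture <- function(path) {
  txt <- c(
    "LOCUS       ctgA 60 bp    DNA     linear   BCT",
    "DEFINITION  fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..9",
    '                     /locus_tag="gA"',
    '                     /product="first gene"',
    "     CDS             complement(13..21)",
    '                     /locus_tag="gB"',
    "     CDS             31..36",
    '                     /locus_tag="gP"',
    "                     /pseudo",
    "ORIGIN",
    "        1 atgaaataaa cgttacttca tggggggggg atgtgatctt tttttttttt tttttttttt",
    "//",
    "LOCUS       ctgB 45 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..6,10..15)",
    '                     /locus_tag="gC"',
    "ORIGIN",
    "        1 atgaaattta aagtttggta aggggggggg ggggggggga aaaa",
    "//")
  writeLines(txt, path)
  path
}

# Random valid gene records across a few strains.
random_gene_table <- function(n = 10, strains = c("s1", "s2"), len_aa = 40) {
  aa <- random_protein(n, len_aa)
  nt <- vapply(aa, function(p) {
    codons <- c(A="GCT",R="CGT",N="AAT",D="GAT",C="TGT",Q="CAA",E="GAA",
                G="GGT",H="CAT",I="ATT",L="CTT",K="AAA",M="ATG",F="TTT",
                P="CCT",S="TCT",T="ACT",W="TGG",Y="TAT",V="GTT")
    paste(codons[strsplit(p, "")[[1]]], collapse = "")
  }, character(1))
  st <- rep_len(strains, n)
  gene_table(gene_id = sprintf("%s|g%03d", st, seq_len(n)),
             strain_id = st, contig_id = "c1",
             start = (seq_len(n) - 1) * 200L,
             end = (seq_len(n) - 1) * 200L + nchar(nt),
             strand = "+", nt_seq = nt, aa_seq = aa)
}

# Similarity graph from a plain edge description (for MCL tests).
graph_fixture <- function(nodes, from, to, w = 1) {
  edges <- data.frame(gene_a = from, gene_b = to,
                      bitscore = rep_len(w, length(from)),
                      evalue = 1e-6, stringsAsFactors = FALSE)
  orthopan:::similarity_graph(nodes, edges)
}

# Cached pipeline runs shared between acceptance checks (the same five
# low-diversity pan-genomes feed several criteria).
.run_cache <- new.env(parent = emptyenv())

sim_bench <- function(seed, rate, n_strains = 30, n_genes = 500) {
  key <- sprintf("sim_%d_%g_%d_%d", seed, rate, n_strains, n_genes)
  if (is.null(.run_cache[[key]])) {
    cfg <- sim_config(n_strains = n_strains, n_genes = n_genes, seed = seed,
                      rate_dist = rate_constant(rate))
    .run_cache[[key]] <- simulate_pangenome(cfg)
  }
  .run_cache[[key]]
}

run_bench <- function(seed, rate, n_strains = 30, n_genes = 500) {
  key <- sprintf("run_%d_%g_%d_%d", seed, rate, n_strains, n_genes)
  if (is.null(.run_cache[[key]])) {
    sim <- sim_bench(seed, rate, n_strains, n_genes)
    out <- file.path(tempdir(), sprintf("bench_%s", key))
    res <- suppressWarnings(suppressMessages(
      run_pipeline(run_config(genomes = sim$genomes, output_dir = out,
                              export_per_cluster = FALSE))))
    .run_cache[[key]] <- list(sim = sim, res = res,
                              acc = cluster_accuracy(res$clusters, sim$truth))
  }
  .run_cache[[key]]
}
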