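test_that("the clonal tree is a Kingman coalescent with the right depth", {
  expect_error(simulate_clonal_tree(1), "at least 2")
  set.seed(61)
  # n = 2: E[TMRCA] = 1
  t2 <- replicate(4000, max(ape::node.depth.edgelength(simulate_clonal_tree(2))))
  expect_equal(mean(t2), 1, tolerance = 0.06)
  # n = 30: E[TMRCA] = 2(1 - 1/30)
  t30 <- replicate(1500, max(ape::node.depth.edgelength(simulate_clonal_tree(30))))
  expect_equal(mean(t30), 2 * (1 - 1 / 30), tolerance = 0.06)
  # determinism under a fixed seed
  expect_identical(ape::write.tree(simulate_clonal_tree(12, seed = 7)),
                   ape::write.tree(simulate_clonal_tree(12, seed = 7)))
})

test_that("gene-tree perturbations preserve leaves and depth, and move topology", {
  clonal <- simulate_clonal_tree(15, seed = 62)
  none <- simulate_gene_trees(clonal, 5, "none", seed = 1)
  for (tr in none)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(clonal))[1], 0)
  freq <- simulate_gene_trees(clonal, 40, "frequent", seed = 2)
  depth0 <- max(ape::node.depth.edgelength(clonal))
  rf <- vapply(freq, function(tr) {
    expect_setequal(tr$tip.label, clonal$tip.label)
    expect_equal(max(ape::node.depth.edgelength(tr)), depth0, tolerance = 1e-8)
    ape::dist.topo(ape::unroot(tr), ape::unroot(clonal))[1]
  }, numeric(1))
  expect_gt(mean(rf > 0), 0.3)   # a positive fraction of gene trees moved
})

test_that("gene content: persistence, loss-free limit, and survival decay", {
  cfg <- sim_config(n_strains = 12, n_genes = 60, seed = 63,
                    rate_dist = rate_constant(0.05))
  set.seed(63)
  clonal <- simulate_clonal_tree(12)
  clonal$edge.length <- clonal$edge.length * cfg$time_scale
  gts <- simulate_gene_trees(clonal, 60, "none")
  content <- evolve_gene_content(gts, cfg, seed = 64)
  pers <- content$origin$gene[content$origin$persistent]
  expect_true(all(rowSums(content$presence[intersect(pers, rownames(content$presence)), , drop = FALSE]) == 12))
  expect_true(all(pers %in% rownames(content$presence)))

  # loss rate 0: every ancestral gene present everywhere
  cfg0 <- sim_config(n_strains = 12, n_genes = 40, seed = 65, loss_rate = 0,
                     rate_dist = rate_constant(0.05))
  content0 <- evolve_gene_content(gts[1:40], cfg0, seed = 66)
  anc <- content0$origin$gene[content0$origin$ancestral]
  expect_true(all(rowSums(content0$presence[anc, ]) == 12))

  # survival along a fixed path of length t is e^{-2.1 t}
  two <- ape::read.tree(text = "(x:1.0,y:1.0);")
  cfg2 <- sim_config(n_strains = 2, n_genes = 5000, n_ancestral = 5000,
                     n_persistent = 0, rate_dist = rate_constant(0.01), seed = 67)
  set.seed(67)
  content2 <- evolve_gene_content(rep(list(two), 5000), cfg2)
  surv_x <- sum(content2$presence[, "x"]) / 5000
  expect_equal(surv_x, exp(-2.1 * 1.0), tolerance = 0.05)
})

test_that("HKY machinery matches the matrix exponential and stays stationary", {
  kappa <- 1.1; bf <- c(0.3, 0.2, 0.25, 0.25)
  Q <- hky_Q(kappa, bf)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(bf * diag(Q)), 1)                  # unit substitution rate
  expect_equal(unname(as.numeric(bf %*% Q)), rep(0, 4), tolerance = 1e-12)  # stationarity
  for (t in c(0.05, 0.4, 2)) {
    expect_equal(unname(hky_P(t, kappa, bf)),
                 unname(as.matrix(Matrix::expm(Q * t))), tolerance = 1e-8)
  }
})

test_that("sequence evolution reproduces the printed divergence law", {
  # mu = 0: all leaves identical to the ancestor
  two <- ape::read.tree(text = "(x:1.0,y:1.0);")
  bases <- c("A", "C", "G", "T")
  set.seed(68)
  anc <- sample(1:4, 600, replace = TRUE)
  seqs0 <- orthopan:::evolve_down_tree(two, anc, 0, 1.1, rep(0.25, 4))
  expect_equal(seqs0[1, ], anc)
  expect_equal(seqs0[2, ], anc)

  # mu = 0.1, T = 2, 10-kb gene: mismatch ~ 1 - e^{-0.2} within 3 binomial SE
  set.seed(69)
  anc10 <- sample(1:4, 10000, replace = TRUE)
  seqs <- orthopan:::evolve_down_tree(two, anc10, 0.1, 1.1, rep(0.25, 4))
  p_obs <- mean(seqs[1, ] != seqs[2, ])
  p_exp <- 1 - exp(-0.2)
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("emitted genomes agree with the truth table and respect determinism", {
  cfg <- sim_config(n_strains = 6, n_genes = 25, seed = 70,
                    rate_dist = rate_constant(0.02))
  sim1 <- simulate_pangenome(cfg)
  sim2 <- simulate_pangenome(cfg)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(combined_gene_table(sim1$genomes),
                   combined_gene_table(sim2$genomes))
  # gene copies emitted == presence marked in truth
  genes <- combined_gene_table(sim1$genomes)
  expect_setequal(genes$gene_id, sim1$truth$gene_id)
  # genes absent from a strain contribute no sequence
  for (g in sim1$genomes) {
    expect_true(all(g$genes$strain_id == g$strain_id))
    in_truth <- sim1$truth$gene_id[sim1$truth$strain_id == g$strain_id]
    expect_setequal(g$genes$gene_id, in_truth)
  }
})

test_that("pan-genome emission writes readable files", {
  cfg <- sim_config(n_strains = 3, n_genes = 10, seed = 71,
                    rate_dist = rate_constant(0.02))
  sim <- simulate_pangenome(cfg)
  d <- tempfile("emit")
  write_pangenome(sim, d, format = "fasta")
  expect_true(file.exists(file.path(d, "truth.tsv")))
  expect_true(file.exists(file.path(d, "clonal_tree.nwk")))
  s1 <- sim$genomes[[1]]$strain_id
  back <- read_fasta(file.path(d, paste0(s1, ".fna")), "nt")
  expect_setequal(names(back), sim$genomes[[1]]$genes$gene_id)
  d2 <- tempfile("emitgb")
  write_pangenome(sim, d2, format = "genbank")
  g <- suppressMessages(read_genbank(file.path(d2, paste0(s1, ".gbk")), s1))
  expect_equal(nrow(g$genes), nrow(sim$genomes[[1]]$genes))
})

test_that("cluster accuracy reproduces the four-outcome classification", {
  truth <- data.frame(gene_id = c("1", "2", "3", "4", "5"),
                      true_cluster = c("A", "A", "A", "B", "B"))
  # perfect
  acc0 <- cluster_accuracy(list(c("1", "2", "3"), c("4", "5")), truth)
  expect_equal(unname(acc0$counts), c(2L, 0L, 0L, 0L))
  expect_equal(acc0$misclustered_gene_fraction, 0)
  # split: 1 correct + 2 incomplete
  acc1 <- cluster_accuracy(list(c("1", "2"), "3", c("4", "5")), truth)
  expect_equal(acc1$counts[["correct"]], 1L)
  expect_equal(acc1$counts[["incomplete"]], 2L)
  expect_equal(acc1$misclustered_gene_fraction, 3 / 5)
  # merged: one contaminated cluster, every gene misclustered
  acc2 <- cluster_accuracy(list(c("1", "2", "3", "4", "5")), truth)
  expect_equal(sum(acc2$counts[c("contaminated", "both")]), 1L)
  expect_equal(acc2$misclustered_gene_fraction, 1)
  # mixed but complete for neither -> both
  acc3 <- cluster_accuracy(list(c("1", "4"), c("2", "3", "5")), truth)
  expect_equal(acc3$counts[["both"]], 2L)
  expect_error(cluster_accuracy(list("99"), truth), "not in truth")
})
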