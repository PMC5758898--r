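test_that("the adaptive cutoff follows its closed form and bounds", {
  expect_identical(adaptive_cutoff(0), 0.1)
  expect_equal(adaptive_cutoff(0.05), 0.2 / 1.1)
  expect_equal(adaptive_cutoff(0.05), 0.181818, tolerance = 1e-5)
  d <- seq(0, 5, by = 0.01)
  b <- suppressWarnings(adaptive_cutoff(d))
  expect_true(all(diff(b) > 0))            # strictly increasing
  expect_true(all(b >= 0.1 & b < 1))
  expect_warning(adaptive_cutoff(0.3), "0.25")
  expect_error(adaptive_cutoff(-0.1), ">= 0")
})

test_that("core diversity is the mean pairwise difference over single-copy core clusters", {
  genes <- random_gene_table(4, strains = c("s1", "s2"), len_aa = 40)
  cl <- list(A = genes$gene_id[1:2], B = genes$gene_id[3:4])
  # identical alignments -> d_c = 0
  alns <- list(A = setNames(rep(strrep("ACGT", 25), 2), genes$gene_id[1:2]),
               B = setNames(rep(strrep("ACGT", 25), 2), genes$gene_id[3:4]))
  expect_equal(core_diversity(cl, genes, c("s1", "s2"), alignments = alns), 0)
  # 5 differences over 100 ungapped sites -> 0.05
  s <- strrep("A", 100)
  s2 <- paste0(strrep("C", 5), strrep("A", 95))
  alns$A <- setNames(c(s, s2), genes$gene_id[1:2])
  alns$B <- setNames(c(s, s), genes$gene_id[3:4])
  expect_equal(core_diversity(cl, genes, c("s1", "s2"), alignments = alns),
               0.05 / 2)  # mean over the two clusters: (0.05 + 0)/2
  # permutation invariance
  expect_equal(core_diversity(rev(cl), genes, c("s1", "s2"),
                              alignments = alns),
               core_diversity(cl, genes, c("s1", "s2"), alignments = alns))
  # no single-copy core -> instructive error
  cl_bad <- list(A = genes$gene_id[c(1, 3)])  # both s1
  expect_error(core_diversity(cl_bad, genes, c("s1", "s2")), "b_c manually")
})

test_that("long-branch cutting removes exactly the super-threshold branches", {
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.5,(c:0.01,d:0.01):0.5);")
  parts <- cut_long_branches(tr, 0.3)
  expect_equal(length(parts), 2)
  expect_setequal(vapply(parts, paste, character(1), collapse = ""),
                  c("ab", "cd"))
  expect_equal(cut_long_branches(tr, 2), list(tr$tip.label))
})

test_that("paralogy scores equal the brute-force intersection oracle", {
  # worked example: ((A1,B1),(A2,B2)) with strains duplicated -> central branch phi = 2
  tr <- ape::read.tree(text = "((A1:0.1,B1:0.1):0.2,(A2:0.1,B2:0.1):0.2);")
  sm <- c(A1 = "A", B1 = "B", A2 = "A", B2 = "B")
  ps <- paralogy_scores(tr, sm)
  internal <- ps$child > 4
  expect_true(all(ps$phi[internal] == 2))
  expect_true(all(ps$phi[!internal] == 1))

  # single-copy tree: phi = 0 everywhere
  tr1 <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  ps1 <- paralogy_scores(tr1, c(a = "sa", b = "sb", c = "sc"))
  expect_true(all(ps1$phi == 0))

  # property: random trees, random strain maps == oracle
  set.seed(17)
  for (r in 1:30) {
    nt <- sample(5:20, 1)
    tr <- ape::rtree(nt)
    sm <- setNames(sample(sprintf("s%d", 1:8), nt, replace = TRUE),
                   tr$tip.label)
    expect_equal(paralogy_scores(tr, sm)$phi, oracle_paralogy(tr, sm))
  }
  expect_error(paralogy_scores(tr1, c(a = "sa")), "strain mapping")
})

test_that("the paralogy split criterion is evaluated strictly", {
  # 10 strains duplicated across two clades; central branch length controls
  mk <- function(len) {
    tips1 <- paste0("s", 1:10, "_1"); tips2 <- paste0("s", 1:10, "_2")
    nwk <- sprintf("((%s):%f,(%s):0.001);",
                   paste0(tips1, ":0.001", collapse = ","), len,
                   paste0(tips2, ":0.001", collapse = ","))
    ape::read.tree(text = nwk)
  }
  sm <- setNames(rep(paste0("s", 1:10), 2),
                 c(paste0("s", 1:10, "_1"), paste0("s", 1:10, "_2")))
  b_c <- 0.2
  # phi_max = 10, l = 0: score = 10/15 < 1 -> no split
  expect_null(paralog_split_decision(mk(0), sm, b_c))
  # l = 0.4 * b_c: 0.4 + 0.667 = 1.067 > 1 -> split into the two clades
  parts <- paralog_split_decision(mk(0.4 * b_c), sm, b_c)
  expect_length(parts, 2)
  expect_setequal(parts[[1]], paste0("s", 1:10, "_1"))
  # phi_max = 0 -> never split regardless of branch length
  tr0 <- ape::read.tree(text = "((a:5,b:5):5,(c:5,d:5):5);")
  sm0 <- c(a = "s1", b = "s2", c = "s3", d = "s4")
  expect_null(paralog_split_decision(tr0, sm0, b_c))
})

test_that("length-peak detection flags spikes over the smoothed background", {
  cfg <- split_config()
  # uniform spread of lengths: no peaks
  expect_length(length_peaks(seq(300, 900, by = 7), cfg), 0)
  # 30 singletons at length 300 over a diffuse background
  lens <- c(rep(300, 30), seq(150, 450, by = 3))
  peaks <- length_peaks(lens, cfg)
  expect_true(300 %in% peaks)
  expect_length(peaks, 1)
  # below the minimum count no peak fires (4 extras + 1 background = 5, not > 5)
  expect_length(length_peaks(c(rep(300, 4), seq(150, 450, by = 3)), cfg), 0)
})

test_that("merge_fragments pools same-length singletons and re-splits frauds", {
  set.seed(30)
  # two true groups of identical-length genes left as singletons, plus noise
  cfg <- sim_config(n_strains = 12, n_genes = 30, seed = 31,
                    rate_dist = rate_constant(0.02))
  sim <- simulate_pangenome(cfg)
  genes <- combined_gene_table(sim$genomes)
  tc <- setNames(sim$truth$true_cluster, sim$truth$gene_id)
  # pick one true cluster with >= 6 members and shatter it into singletons
  sizes <- table(tc)
  big <- names(sizes)[sizes >= 6][1]
  expect_false(is.na(big))   # the fixture guarantees a large cluster
  members <- names(tc)[tc == big]
  others <- setdiff(genes$gene_id, members)
  clusters <- c(as.list(members),
                split(others, tc[others]))
  names(clusters) <- sprintf("C%05d", seq_along(clusters))
  out <- merge_fragments(clusters, genes, b_c = 0.2, config = split_config())
  expect_true(length(out$pooled) >= 6)
  merged <- out$clusters[vapply(out$clusters, function(m)
    any(members %in% m), logical(1))]
  expect_true(any(lengths(merged) >= 6))     # the shattered cluster reunited
  expect_setequal(unlist(out$clusters, use.names = FALSE),
                  unlist(clusters, use.names = FALSE))  # gene conservation
})

test_that("postprocess_all conserves genes, reports accounting, and is idempotent", {
  run <- run_bench(4, 0.05, n_strains = 8, n_genes = 40)
  post <- run$res$post
  expect_setequal(unlist(post$clusters, use.names = FALSE),
                  unlist(run$res$initial_clusters, use.names = FALSE))
  expect_equal(nrow(post$report), length(run$res$initial_clusters))
  expect_equal(sum(post$report$action == "kept") +
                 sum(post$report$action != "kept"),
               length(run$res$initial_clusters))
  # idempotence: a second pass changes nothing
  genes <- run$res$genes
  again <- suppressWarnings(
    postprocess_all(post$clusters, genes, run$res$strains, split_config()))
  expect_identical(unname(lapply(again$clusters, sort)),
                   unname(lapply(post$clusters, sort)))
  expect_equal(again$fraction_modified, 0)
})
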