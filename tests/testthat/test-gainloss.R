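test_that("core SNP matrix extracts exactly the variable positions", {
  genes <- random_gene_table(6, strains = c("s1", "s2", "s3"))
  cl <- list(A = genes$gene_id[1:3], B = genes$gene_id[4:6])
  # cluster A: two variable columns (1 and 5); cluster B invariant
  alns <- list(
    A = setNames(c("ACGTAC", "CCGTAC", "ACGTGC"), genes$gene_id[1:3]),
    B = setNames(rep("TTTTTT", 3), genes$gene_id[4:6]))
  st <- core_snp_tree(cl, genes, c("s1", "s2", "s3"), alignments = alns)
  expect_equal(dim(st$snp), c(3L, 2L))
  expect_equal(unname(st$snp[, 1]), c("A", "C", "A"))
  expect_equal(unname(st$snp[, 2]), c("A", "A", "G"))
  expect_setequal(st$tree$tip.label, c("s1", "s2", "s3"))
  expect_equal(st$positions$column, c(1L, 5L))
  # permuting cluster order leaves the topology unchanged
  st2 <- core_snp_tree(rev(cl), genes, c("s1", "s2", "s3"), alignments = alns)
  expect_equal(ape::dist.topo(ape::unroot(st$tree), ape::unroot(st2$tree))[1], 0)
  # identical core genomes -> instructive error
  alns$A <- setNames(rep("ACGTAC", 3), genes$gene_id[1:3])
  expect_error(core_snp_tree(cl, genes, c("s1", "s2", "s3"), alignments = alns),
               "no variable positions|manually")
  expect_error(core_snp_tree(cl, genes, c("s1", "s2")), "at least 3")
})

test_that("joint ancestral sequences match exhaustive enumeration", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  # invariant column: same state everywhere, no mutations
  res <- ancestral_sequences(tr, c(a = "A", b = "A", c = "A"))
  expect_equal(unname(res$states[1, 1]), "A")
  expect_equal(nrow(res$mutations), 0)
  # (A, A, G): root A, single mutation on the G branch
  res2 <- ancestral_sequences(tr, c(a = "A", b = "A", c = "G"))
  expect_equal(unname(res2$states[1, 1]), "A")
  expect_equal(nrow(res2$mutations), 1)
  expect_equal(res2$mutations$child, which(tr$tip.label == "c"))
  expect_equal(res2$mutations$from, "A")
  expect_equal(res2$mutations$to, "G")

  # random small trees: joint reconstruction equals the enumeration oracle
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (r in 1:10) {
    tr <- ape::rtree(5)
    col <- setNames(sample(1:4, 5, replace = TRUE), tr$tip.label)
    aln <- setNames(bases[col], tr$tip.label)
    got <- ancestral_sequences(tr, aln)
    ref <- oracle_jc_joint(tr, col)
    nt <- length(tr$tip.label)
    got_internal <- match(got$states[, 1], bases)
    expect_equal(got_internal, ref$states[(nt + 1):(nt + tr$Nnode)])
  }
})

test_that("joint reconstruction beats random internal assignments", {
  set.seed(29)
  tr <- ape::rtree(6)
  bases <- c("A", "C", "G", "T")
  aln <- setNames(vapply(1:6, function(i)
    paste(sample(bases, 12, replace = TRUE), collapse = ""), character(1)),
    tr$tip.label)
  got <- ancestral_sequences(tr, aln)
  logp_of <- function(states_internal, site) {
    col <- match(substring(aln[tr$tip.label], site, site), bases)
    st <- c(col, states_internal)
    lp <- log(0.25)
    for (k in seq_len(nrow(tr$edge))) {
      t <- max(tr$edge.length[k], 1e-9)
      same <- 0.25 + 0.75 * exp(-4 * t / 3); diff <- 0.25 - 0.25 * exp(-4 * t / 3)
      lp <- lp + log(if (st[tr$edge[k, 1]] == st[tr$edge[k, 2]]) same else diff)
    }
    lp
  }
  site <- 3
  joint <- match(got$states[, site], bases)
  lp_joint <- logp_of(joint, site)
  rand_lp <- replicate(1000, logp_of(sample(1:4, tr$Nnode, replace = TRUE), site))
  expect_gte(lp_joint, max(rand_lp))
})

test_that("two-state transition probabilities match the matrix exponential", {
  g <- 0.07; l <- 1.3
  Q <- matrix(c(-g, g, l, -l), 2, 2, byrow = TRUE)
  for (t in c(0.01, 0.3, 2)) {
    expect_equal(unname(gainloss_P(t, g, l)),
                 unname(as.matrix(Matrix::expm(Q * t))), tolerance = 1e-10)
  }
  # the closed form printed for presence persistence
  t <- 0.7
  expect_equal(gainloss_P(t, g, l)["present", "present"],
               (g + l * exp(-(g + l) * t)) / (g + l))
})

test_that("pruning likelihood equals brute-force enumeration on small trees", {
  set.seed(31)
  for (r in 1:10) {
    nt <- sample(4:7, 1)
    tr <- ape::rtree(nt)
    x <- setNames(sample(c(TRUE, FALSE), nt, replace = TRUE), tr$tip.label)
    pam <- matrix(x, 1, dimnames = list("cl", names(x)))
    g <- runif(1, 0.02, 0.5); l <- runif(1, 0.2, 3)
    expect_equal(orthopan:::gainloss_loglik(tr, pam, g, l),
                 log(oracle_gainloss_lik(tr, x, g, l)), tolerance = 1e-8)
  }
})

test_that("an all-present star cluster pushes the loss rate to zero", {
  tr <- ape::read.tree(text = "(a:0.5,b:0.5,c:0.5,d:0.5);")
  pam <- matrix(TRUE, 1, 4, dimnames = list("cl", tr$tip.label))
  ll <- vapply(c(1, 0.3, 0.1, 0.01),
               function(l) orthopan:::gainloss_loglik(tr, pam, 0.5, l),
               numeric(1))
  expect_true(all(diff(ll) > 0))   # likelihood increases as l -> 0
  expect_warning(m <- fit_gain_loss(tr, pam), "not identifiable")
  expect_true(m$degenerate)
})

test_that("fitted rates recover the simulation truth", {
  set.seed(33)
  tr <- simulate_clonal_tree(30)
  pam <- simulate_pam(tr, g = 0.05, l = 1.0, n = 2000)
  rownames(pam) <- sprintf("c%04d", 1:2000)
  fit <- fit_gain_loss(tr, pam)
  expect_equal(fit$ratio, 20, tolerance = 0.25)
  expect_gt(fit$loss, fit$gain)   # losses dominate gains
})

test_that("joint ancestral presence equals enumeration and yields consistent events", {
  set.seed(37)
  for (r in 1:10) {
    tr <- ape::rtree(5)
    x <- setNames(sample(c(TRUE, FALSE), 5, replace = TRUE), tr$tip.label)
    if (!any(x)) x[1] <- TRUE
    pam <- matrix(x, 1, dimnames = list("cl", names(x)))
    g <- 0.05; l <- 1.1
    model <- structure(list(gain = g, loss = l), class = "gain_loss_model")
    got <- ancestral_presence(tr, pam, model)
    ref <- oracle_gainloss_joint(tr, x, g, l)
    expect_equal(as.integer(got$states[, 1]), ref$states)
    # events exactly where parent and child states differ
    st <- got$states[, 1]
    for (k in seq_len(nrow(tr$edge))) {
      flip <- unname(st[tr$edge[k, 1]] != st[tr$edge[k, 2]])
      expect_equal(k %in% got$events$edge, flip)
    }
  }
})

test_that("under fitted rates, core clusters show no events and a unique gene one terminal gain", {
  tr <- simulate_clonal_tree(8, seed = 40)
  strains <- tr$tip.label
  pam <- rbind(core = rep(TRUE, 8), core2 = rep(TRUE, 8),
               uniq = strains == strains[3],
               half = seq_along(strains) <= 4)
  colnames(pam) <- strains
  model <- fit_gain_loss(tr, pam)
  anc <- ancestral_presence(tr, pam, model)
  expect_equal(sum(anc$events$cluster_id %in% c("core", "core2")), 0)
  ev <- anc$events[anc$events$cluster_id == "uniq", ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event, "gain")
  expect_equal(ev$child, 3L)   # the carrying leaf's terminal branch
  expect_equal(event_counts(anc$events, c("core", "uniq")),
               c(core = 0L, uniq = 1L))
})
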