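test_that("branch association evaluates the normalized mean difference", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  # identical phenotypes: zero everywhere
  expect_equal(as.numeric(branch_association(tr, c(a = 1, b = 1, c = 1, d = 1))), 0)
  # sides {0,2} vs {4,6}: |1-5|/sqrt(1+1) = 2*sqrt(2)
  b <- branch_association(tr, c(a = 0, b = 2, c = 4, d = 6))
  expect_equal(as.numeric(b), 2 * sqrt(2))
  # a tight clade against a tight background maximizes at the clade stem
  tr8 <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  ph <- c(a = 10.1, b = 9.9, c = 10.05, d = 9.95, e = 0.1, f = -0.1, g = 0.05, h = -0.05)
  b8 <- branch_association(tr8, ph)
  below <- orthopan:::edge_leaf_matrix(tr8)
  side <- tr8$tip.label[below[attr(b8, "edge"), ]]
  expect_true(setequal(side, c("a", "b", "c", "d")) ||
                setequal(side, c("e", "f", "g", "h")))
  # brute-force check of the maximum over every branch
  scores <- apply(below, 1, function(in1) {
    s1 <- ph[tr8$tip.label[in1]]; s2 <- ph[tr8$tip.label[!in1]]
    if (!length(s1) || !length(s2)) return(NA_real_)
    abs(mean(s1) - mean(s2)) /
      sqrt(mean((s1 - mean(s1))^2) + mean((s2 - mean(s2))^2))
  })
  expect_equal(as.numeric(b8), max(scores, na.rm = TRUE))
  # fewer than 3 phenotyped leaves -> NULL, not an error
  expect_null(branch_association(tr, c(a = 1, b = 2, c = NA, d = NA)))
  # zero denominator with distinct means -> flagged infinity
  tr3 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  binf <- branch_association(tr3, c(a = 1, b = 1, c = 2, d = 2))
  expect_true(is.infinite(as.numeric(binf)))
  expect_true(attr(binf, "degenerate"))
})

test_that("presence association follows its closed form and scaling", {
  ph <- c(s1 = 1, s2 = 1, s3 = 0, s4 = 0)
  present <- c(s1 = TRUE, s2 = TRUE, s3 = FALSE, s4 = FALSE)
  # mu_a = mu_p -> 0
  expect_equal(presence_association(c(s1 = TRUE, s2 = FALSE, s3 = TRUE, s4 = FALSE),
                                    ph, n_events = 3), 0)
  # n = 4, mu_a = 1, mu_p = 0, sigma = 0.5 -> 4 (sign: absent minus present)
  p <- presence_association(!present, ph, n_events = 4)
  expect_equal(p, 4)
  # doubling n multiplies by sqrt(2)
  p2 <- presence_association(!present, ph, n_events = 8)
  expect_equal(p2 / p, sqrt(2))
  # undefined cases
  expect_null(presence_association(c(s1 = TRUE, s2 = TRUE, s3 = TRUE, s4 = TRUE),
                                   ph, 1))
  expect_null(presence_association(present, c(s1 = 1, s2 = 1, s3 = 1, s4 = 1), 1))
})

test_that("scores are invariant to phenotype shift and positive scaling", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ph <- c(a = 0.3, b = 1.2, c = 4.5, d = 3.3)
  b0 <- as.numeric(branch_association(tr, ph))
  expect_equal(as.numeric(branch_association(tr, ph + 7)), b0)
  expect_equal(as.numeric(branch_association(tr, ph * 3.5)), b0)
  present <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  p0 <- presence_association(present, ph, 2)
  expect_equal(presence_association(present, ph + 7, 2), p0)
  expect_equal(presence_association(present, ph * 3.5, 2), p0)
})

test_that("a planted presence/absence signal ranks first", {
  set.seed(51)
  tr <- simulate_clonal_tree(24)
  strains <- tr$tip.label
  genes <- random_gene_table(length(strains), strains = strains)
  clusters <- c(list(planted = genes$gene_id[1]),
                as.list(setNames(genes$gene_id[-1],
                                 sprintf("bg%02d", seq_len(nrow(genes) - 1)))))
  wins <- 0
  for (r in 1:30) {
    ph <- setNames(rnorm(length(strains)), strains)
    planted <- ph > median(ph)
    pam <- rbind(planted = planted,
                 simulate_pam(tr, g = 0.3, l = 0.9, n = length(clusters) - 1))
    rownames(pam) <- names(clusters)
    keep <- rowSums(pam) > 0; keep["planted"] <- TRUE
    pam[!keep, sample(length(strains), 1)] <- TRUE
    model <- suppressWarnings(fit_gain_loss(tr, pam))
    anc <- ancestral_presence(tr, pam, model)
    tab <- rank_associations(clusters[rownames(pam)], genes, ph, pam, anc$events)
    if (tab$cluster_id[1] == "planted") wins <- wins + 1
  }
  expect_gte(wins, 27)
})

test_that("rank_associations returns all-null scores without phenotypes", {
  genes <- random_gene_table(4, strains = c("s1", "s2"))
  clusters <- list(A = genes$gene_id[1:2], B = genes$gene_id[3:4])
  pam <- presence_absence_matrix(clusters, genes, c("s1", "s2"))
  ev <- data.frame(cluster_id = character(0), edge = integer(0),
                   child = integer(0), event = character(0))
  tab <- rank_associations(clusters, genes,
                           c(s1 = NA_real_, s2 = NA_real_), pam, ev)
  expect_true(all(is.na(tab$presence_assoc)))
  expect_true(all(is.na(tab$branch_assoc)))
})
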