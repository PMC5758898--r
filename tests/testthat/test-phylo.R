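test_that("protein alignment handles identity, gaps, and matches the NW oracle", {
  a <- align_proteins(c(x = "MKVLWA", y = "MKVLWA"))
  expect_equal(unname(a), c("MKVLWA", "MKVLWA"))

  a2 <- align_proteins(c(x = "MKVF", y = "MKF"))
  ref <- oracle_nw("MKVF", "MKF")
  expect_equal(unname(a2), c(ref$a, ref$b))
  expect_equal(sum(strsplit(a2[["y"]], "")[[1]] == "-"), 1)

  set.seed(3)
  for (r in 1:10) {
    seqs <- setNames(random_protein(2, sample(8:25, 1)), c("p", "q"))
    al <- align_proteins(seqs)
    expect_equal(ungap(al), seqs)           # ungapping recovers the input
    expect_equal(nchar(al[[1]]), nchar(al[[2]]))
  }
  single <- align_proteins(c(only = "MKV"))
  expect_equal(single, c(only = "MKV"))
})

test_that("codon back-translation expands residues to codons and gaps to ---", {
  expect_equal(codon_align(c(x = "MK-F"), list(x = "ATGAAATTT")),
               c(x = "ATGAAA---TTT"))
  # gapless alignment: identity on the sequences
  expect_equal(codon_align(c(x = "MKF"), list(x = "ATGAAATTT")),
               c(x = "ATGAAATTT"))
  expect_error(codon_align(c(x = "MKF"), list(x = "ATGAAATT")), "x")

  # random multi-row fixture checked codon-by-codon against a per-row oracle
  set.seed(8)
  genes <- random_gene_table(5, strains = "s1", len_aa = 20)
  aa <- setNames(genes$aa_seq, genes$gene_id)
  aln <- align_proteins(aa)
  nt <- setNames(genes$nt_seq, genes$gene_id)
  ca <- codon_align(aln, as.list(nt))
  expect_equal(unname(nchar(ca)), rep(3 * nchar(aln[[1]]), 5))
  for (id in names(aln)) {
    cod <- strsplit(nt[[id]], "(?<=.{3})", perl = TRUE)[[1]]
    expected <- character(0); p <- 0
    for (ch in strsplit(aln[[id]], "")[[1]]) {
      if (ch == "-") expected <- c(expected, "---")
      else { p <- p + 1; expected <- c(expected, cod[p]) }
    }
    expect_equal(ca[[id]], paste(expected, collapse = ""))
  }
  expect_equal(ungap(ca[[1]]), nt[[1]])
})

test_that("terminal stop codons are stripped only when they explain the length", {
  expect_equal(strip_terminal_stop("ATGAAATAA", "MK"), "ATGAAA")
  expect_equal(strip_terminal_stop("ATGAAA", "MK"), "ATGAAA")
  expect_equal(strip_terminal_stop("ATGAAATAC", "MK"), "ATGAAATAC")
})

test_that("Jukes-Cantor transform matches the closed form and saturates safely", {
  expect_equal(jc_distance(0.1), -0.75 * log(1 - 4 * 0.1 / 3))
  expect_equal(jc_distance(0.1), 0.10732, tolerance = 1e-4)
  expect_equal(jc_distance(0), 0)
  expect_true(is.finite(jc_distance(0.9)))
  expect_equal(jc_distance(0.9), jc_distance(0.74))
})

test_that("neighbor joining recovers additive distances and handles degenerate cases", {
  # 3 identical sequences -> star with zero branch lengths
  tr <- build_tree(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  expect_equal(sum(tr$edge.length), 0)

  # 2 rows: a cherry with the distance split equally
  tr2 <- build_tree(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))
  d <- jc_distance(0.1)
  expect_equal(unname(ape::cophenetic.phylo(tr2)["a", "b"]), d, tolerance = 1e-9)
  expect_equal(tr2$edge.length, c(d / 2, d / 2))

  # classic 4-taxon additive matrix: NJ must recover topology and lengths;
  # hand-computed: D below is additive on the tree ((a:2,b:3):1,(c:4,d:5)) up
  # to placement of the root
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 0, 0), 4, 4)
  D[4, 3] <- 9; D[3, 4] <- 9; D[4, 4] <- 0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr4 <- ape::nj(as.dist(D))
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr4))[letters[1:4], letters[1:4]]),
               unname(D), tolerance = 1e-9)
  expect_true(ape::is.monophyletic(tr4, c("a", "b")))

  expect_error(build_tree(c(a = "ACGT")), "at least 2")
})

test_that("build_tree is invariant to row order up to isomorphism", {
  set.seed(12)
  genes <- random_gene_table(6, strains = "s1", len_aa = 30)
  aln <- align_proteins(setNames(genes$aa_seq, genes$gene_id))
  nt <- codon_align(aln, as.list(setNames(genes$nt_seq, genes$gene_id)))
  t1 <- build_tree(nt)
  t2 <- build_tree(rev(nt))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("external aligner and tree-builder adapters round-trip", {
  set.seed(44)
  genes <- random_gene_table(6, strains = "s1", len_aa = 40)
  aa <- setNames(genes$aa_seq, genes$gene_id)
  aln <- align_proteins(aa, command = "mafft --quiet {in} > {out}")
  expect_equal(ungap(aln), aa)
  expect_equal(length(unique(nchar(aln))), 1L)
  nt <- codon_align(align_proteins(aa), as.list(setNames(genes$nt_seq, genes$gene_id)))
  tr <- build_tree(nt, command = "fasttree -quiet -nt -gtr {in} > {out} 2> /dev/null")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, names(aa))
  expect_true(ape::is.rooted(tr))
  expect_error(suppressWarnings(
    align_proteins(aa, command = "no_such_tool_xyz {in} {out}")), "failed")
})
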