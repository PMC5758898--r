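# Independent oracles, written without reference to the package internals:
# straightforward (slow) implementations used to pin down expected values.

# BLOSUM62 pulled from Biostrings (independent of the package's embedded copy)
.b62 <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

# Brute-force Smith-Waterman with affine gaps: gap of length L costs
# open + ext * L.  Full three-state DP over the complete matrix.
oracle_sw <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - ext)
    Y[i, j] <- max(M[i - 1, j] - open - ext, Y[i - 1, j] - ext)
    M[i, j] <- max(0, M[i - 1, j - 1] + .b62[A[i - 1], B[j - 1]], X[i, j], Y[i, j])
    best <- max(best, M[i, j])
  }
  best
}

# Brute-force global Needleman-Wunsch (linear gap), returns the two aligned
# strings; deterministic tie-break (diag > up > left).
oracle_nw <- function(a, b, gap = 8) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -gap * (0:n); D[1, ] <- -gap * (0:m)
  for (i in 2:(n + 1)) for (j in 2:(m + 1))
    D[i, j] <- max(D[i - 1, j - 1] + .b62[A[i - 1], B[j - 1]],
                   D[i - 1, j] - gap, D[i, j - 1] - gap)
  ra <- rb <- character(0); i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (i > 1 && j > 1 && D[i, j] == D[i - 1, j - 1] + .b62[A[i - 1], B[j - 1]]) {
      ra <- c(A[i - 1], ra); rb <- c(B[j - 1], rb); i <- i - 1; j <- j - 1
    } else if (i > 1 && D[i, j] == D[i - 1, j] - gap) {
      ra <- c(A[i - 1], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j - 1], rb); j <- j - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = D[n + 1, m + 1])
}

# Independent dense MCL (base R matrices only).
oracle_mcl <- function(nodes, edges, inflation = 1.5, max_iter = 200,
                       prune = 1e-5) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    i <- edges$gene_a[k]; j <- edges$gene_b[k]
    A[i, j] <- A[j, i] <- edges$bitscore[k]
  }
  loop <- apply(A, 2, max); loop[loop == 0] <- 1
  diag(A) <- loop
  norm <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  M <- norm(A)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- norm(M2^inflation)
    M2[M2 < prune] <- 0
    M2 <- norm(M2)
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; break }
    M <- M2
  }
  attr_nodes <- which(diag(M) > 0)
  S <- (M + t(M))[attr_nodes, attr_nodes, drop = FALSE] > 0
  # connected components among attractors by repeated expansion
  comp <- seq_along(attr_nodes)
  repeat {
    changed <- FALSE
    for (i in seq_along(attr_nodes)) for (j in seq_along(attr_nodes))
      if (S[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
    if (!changed) break
  }
  assign <- integer(n)
  for (v in seq_len(n)) {
    mass <- tapply(M[attr_nodes, v], comp, sum)
    assign[v] <- if (all(mass == 0)) NA_integer_ else
      as.integer(names(mass)[which.max(mass)])
  }
  out <- split(nodes[!is.na(assign)], assign[!is.na(assign)])
  out <- c(unname(out), as.list(nodes[is.na(assign)]))
  out <- lapply(out, sort)
  out[order(-lengths(out), vapply(out, `[`, character(1), 1))]
}

# Brute-force per-branch paralogy score: set intersection of strains below
# and above each edge.
oracle_paralogy <- function(tree, strain_map) {
  tips <- tree$tip.label
  vapply(seq_len(nrow(tree$edge)), function(k) {
    ch <- tree$edge[k, 2]
    below_tips <- if (ch <= length(tips)) tips[ch] else
      ape::extract.clade(tree, ch)$tip.label
    above_tips <- setdiff(tips, below_tips)
    length(intersect(unique(strain_map[below_tips]),
                     unique(strain_map[above_tips])))
  }, integer(1))
}

# Brute-force two-state likelihood: sum over every internal-state assignment.
oracle_gainloss_lik <- function(tree, x, g, l) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1
  pi1 <- g / (g + l)
  P <- function(t) {
    s <- g + l; e <- exp(-s * t)
    matrix(c((l + g * e)/s, (g - g * e)/s, (l - l * e)/s, (g + l * e)/s),
           2, 2, byrow = TRUE)
  }
  internals <- (nt + 1):nn
  total <- 0
  grid <- expand.grid(rep(list(0:1), length(internals)))
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(nt)] <- as.integer(x[tree$tip.label])
    st[internals] <- as.integer(grid[r, ])
    pr <- if (st[root] == 1) pi1 else 1 - pi1
    for (k in seq_len(nrow(tree$edge))) {
      M <- P(tree$edge.length[k])
      pr <- pr * M[st[tree$edge[k, 1]] + 1, st[tree$edge[k, 2]] + 1]
    }
    total <- total + pr
  }
  total
}

# Brute-force joint ML assignment for the two-state model: enumeration of
# internal states, returning the maximizing assignment's probability and
# internal states.
oracle_gainloss_joint <- function(tree, x, g, l) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1
  pi1 <- g / (g + l)
  P <- function(t) {
    s <- g + l; e <- exp(-s * t)
    matrix(c((l + g * e)/s, (g - g * e)/s, (l - l * e)/s, (g + l * e)/s),
           2, 2, byrow = TRUE)
  }
  internals <- (nt + 1):nn
  grid <- expand.grid(rep(list(0:1), length(internals)))
  best <- -Inf; best_st <- NULL
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(nt)] <- as.integer(x[tree$tip.label])
    st[internals] <- as.integer(grid[r, ])
    pr <- log(if (st[root] == 1) pi1 else 1 - pi1)
    for (k in seq_len(nrow(tree$edge))) {
      M <- P(tree$edge.length[k])
      pr <- pr + log(M[st[tree$edge[k, 1]] + 1, st[tree$edge[k, 2]] + 1])
    }
    if (pr > best) { best <- pr; best_st <- st }
  }
  list(logp = best, states = best_st)
}

# Brute-force JC likelihood of a one-column alignment by enumerating all
# internal nucleotide assignments.
oracle_jc_joint <- function(tree, column) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1
  pmat <- function(t) {
    same <- 0.25 + 0.75 * exp(-4 * t / 3)
    diff <- 0.25 - 0.25 * exp(-4 * t / 3)
    m <- matrix(diff, 4, 4); diag(m) <- same; m
  }
  internals <- (nt + 1):nn
  grid <- expand.grid(rep(list(1:4), length(internals)))
  best <- -Inf; best_st <- NULL
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn)
    st[seq_len(nt)] <- column[tree$tip.label]
    st[internals] <- as.integer(grid[r, ])
    pr <- log(0.25)
    for (k in seq_len(nrow(tree$edge))) {
      M <- pmat(max(tree$edge.length[k], 1e-9))
      pr <- pr + log(M[st[tree$edge[k, 1]], st[tree$edge[k, 2]]])
    }
    if (pr > best) { best <- pr; best_st <- st }
  }
  list(logp = best, states = best_st)
}

random_protein <- function(n, len = 60) {
  alpha <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(alpha, len, replace = TRUE), collapse = ""), character(1))
}
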