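# Independent oracles and fixture builders used across the test files.
# Every oracle is a deliberately naive reimplementation (enumeration or
# closed form) that shares no code with the package internals.

ORACLE_BASES <- c("A", "C", "G", "T")

make_block <- function(texts, quals = NULL, start = NULL) {
  sp <- names(texts)
  sizes <- vapply(texts, function(t) sum(strsplit(t, "")[[1]] != "-"), 0L,
                  USE.NAMES = FALSE)
  qmaf_block(src = sp,
             start = if (is.null(start)) rep(0L, length(sp)) else start,
             size = sizes, strand = rep("+", length(sp)),
             src_size = sizes + 50L, text = unname(texts),
             qual = if (is.null(quals)) NULL else unname(quals[sp]))
}

# brute-force column likelihood: sum over all internal-node base labelings
oracle_prune <- function(column, model, rho = 1) {
  tree <- model$tree
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e)
    ape::matexpo(model$Q * (rho * tree$edge.length[e])))
  obs <- toupper(column)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    lab <- integer(ntip + tree$Nnode)
    lab[internal] <- grid[g, ]
    p <- model$freq[lab[ntip + 1]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= ntip) {
        b <- obs[tree$tip.label[ch]]
        if (is.na(b) || !b %in% ORACLE_BASES) next  # missing leaf: factor 1
        p <- p * Pm[[e]][lab[par], match(b, ORACLE_BASES)]
      } else p <- p * Pm[[e]][lab[par], lab[ch]]
    }
    tot <- tot + p
  }
  tot
}

# exhaustive Sankoff: minimum total cost and, per node, the set of states
# attained in some minimum-cost labeling.  leaf_states: named integer
# vector (0-based state encodings), NA = unconstrained.
oracle_parsimony <- function(leaf_states, tree, W) {
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- nrow(W)
  fixed <- rep(NA_integer_, nnode)
  for (sp in names(leaf_states))
    fixed[match(sp, tree$tip.label)] <- leaf_states[[sp]]
  free <- which(is.na(fixed) | seq_len(nnode) > ntip)
  free <- sort(unique(c(which(is.na(fixed[seq_len(ntip)])), (ntip + 1):nnode)))
  grid <- as.matrix(expand.grid(rep(list(0:(S - 1)), length(free))))
  lab <- matrix(rep(fixed, each = nrow(grid)), nrow(grid), nnode)
  lab[, free] <- grid
  cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge)))
    cost <- cost + W[cbind(lab[, tree$edge[e, 1]] + 1L,
                           lab[, tree$edge[e, 2]] + 1L)]
  best <- min(cost)
  opt <- lab[cost == best, , drop = FALSE]
  states <- lapply(seq_len(nnode), function(v) sort(unique(opt[, v])))
  list(cost = best, states = states)
}

# independent event-cost oracle: one-step costs from an explicit
# contiguity test, closed under min-plus matrix squaring
oracle_cost_matrix <- function(n) {
  S <- 2^n
  bits <- function(x) as.integer(intToBits(x))[1:n]
  one <- matrix(Inf, S, S); diag(one) <- 0
  for (i in 0:(S - 1)) for (j in 0:(S - 1)) {
    if (i == j) next
    big <- if (sum(bits(i)) > sum(bits(j))) i else j
    d <- bitwXor(i, j)
    if (bitwAnd(d, big) != d || bitwAnd(d, min(i, j)) != 0) next
    ones <- which(bits(big) == 1)
    flip <- which(bits(d) == 1)
    ranks <- match(flip, ones)
    if (all(diff(sort(ranks)) == 1)) one[i + 1, j + 1] <- 1
  }
  D <- one
  repeat {
    D2 <- D
    for (k in 1:S) D2 <- pmin(D2, outer(D[, k], D[k, ], "+"))
    if (identical(D2, D)) break
    D <- D2
  }
  D
}

# rank-based ROC AUC (probability a random positive outscores a random
# negative)
oracle_auc <- function(score, label) {
  r <- rank(score)
  np <- sum(label == 1); nn <- sum(label == 0)
  (sum(r[label == 1]) - np * (np + 1) / 2) / (np * nn)
}

# closed-form assembly error rate for a degenerate p1 (point mass q0)
# under untruncated Poisson depth conditioned on >= 1
oracle_degenerate_err <- function(q0, lambda) {
  t <- 10^(-q0 / 10)
  (exp(lambda * (t - 1)) - exp(-lambda)) / (1 - exp(-lambda))
}
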