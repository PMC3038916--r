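tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("indel regions are maximal gap runs with missing-data rules", {
  b <- make_block(c(A = "AC--GT", B = "ACTAGT", C = "ACTAGT"))
  regs <- extract_indel_regions(b)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$cols, 3:4)
  expect_equal(unname(regs[[1]]$mat["A", ]), c(0L, 0L))
  # gapless block: no regions
  expect_length(extract_indel_regions(make_block(c(A = "ACGT", B = "ACGT"))), 0)
  # long gap run becomes missing data
  long <- paste(rep("-", 12), collapse = "")
  b2 <- make_block(c(A = paste0("AC", long, "GT"),
                     B = paste0("AC", "TTT-TTTTTTTT", "GT")))
  regs2 <- extract_indel_regions(b2, max_gap = 10)
  expect_length(regs2, 1)            # only B's short gap defines a region
  expect_true(all(is.na(regs2[[1]]$mat["A", ])))
  expect_equal(unname(regs2[[1]]$mat["B", ]), 0L)
  # species absent from the block is missing throughout
  regs3 <- extract_indel_regions(b, species = c("A", "B", "C", "Z"))
  expect_true(all(is.na(regs3[[1]]$mat["Z", ])))
})

test_that("column compression merges identical runs with multiplicities", {
  mat <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 0), nrow = 3,
                dimnames = list(c("A", "B", "C"), NULL))
  reg <- compress_columns(list(mat = mat, cols = 11:13))
  expect_equal(reg$n, 3)  # all distinct: identity
  mat2 <- mat[, c(1, 1, 2), drop = FALSE]
  reg2 <- compress_columns(list(mat = mat2, cols = 11:13))
  expect_equal(reg2$n, 2)
  expect_equal(reg2$mult, c(2L, 1L))
  expect_equal(reg2$map[[1]], 11:12)
  mat3 <- mat[, c(2, 2, 2), drop = FALSE]
  expect_equal(compress_columns(list(mat = mat3, cols = 1:3))$n, 1)
})

test_that("event costs count contiguous indel runs, not columns", {
  W1 <- event_cost_matrix(1)
  expect_equal(unclass(W1), matrix(c(0L, 1L, 1L, 0L), 2), ignore_attr = TRUE)
  W3 <- event_cost_matrix(3)
  st <- function(s) strtoi(s, base = 2) + 1L  # states written col3,col2,col1
  expect_equal(W3[st("111"), st("101")], 1L)  # one deletion
  # 101 -> 010: delete both sequence-adjacent bases, insert the middle
  expect_equal(W3[st("101"), st("010")], 2L)
  # the naive per-column alternative counts 3
  expect_equal(event_cost_matrix(3, "columns")[st("101"), st("010")], 3L)
  expect_error(event_cost_matrix(11), "1..10")
})

test_that("event cost matrices match the independent shortest-path oracle", {
  for (n in 1:4) {
    W <- event_cost_matrix(n)
    O <- oracle_cost_matrix(n)
    expect_equal(matrix(as.numeric(W), nrow(W)), O)
  }
})

test_that("cost matrices are symmetric metrics for all n <= 6", {
  for (n in 1:6) {
    W <- unclass(event_cost_matrix(n))
    expect_equal(W, t(W), ignore_attr = TRUE)
    expect_true(all(diag(W) == 0))
    viol <- FALSE
    for (k in seq_len(nrow(W)))
      viol <- viol || any(W > outer(W[, k], W[k, ], "+"))
    expect_false(viol)  # triangle inequality
  }
})

test_that("parsimony state sets equal exhaustive enumeration", {
  set.seed(21)
  trees <- list(
    tree4(),
    ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);"),
    ape::read.tree(
      text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);"))
  for (tr in trees) for (n in c(1, 2, 3)) {
    W <- event_cost_matrix(n)
    for (rep in 1:6) {
      states <- sample(0:(2^n - 1), length(tr$tip.label), replace = TRUE)
      miss <- runif(length(states)) < 0.15
      leaf <- setNames(ifelse(miss, NA_integer_, states), tr$tip.label)
      mat <- vapply(seq_len(n), function(k)
        ifelse(is.na(leaf), NA_integer_,
               as.integer(bitwAnd(leaf, 2L^(k - 1L)) > 0)), integer(length(leaf)))
      mat <- matrix(mat, nrow = length(leaf),
                    dimnames = list(tr$tip.label, NULL))
      reg <- list(species = tr$tip.label, mat = mat, comp = mat,
                  mult = rep(1L, n), map = as.list(seq_len(n)),
                  cols = seq_len(n), n = n, block = 1L)
      ps <- parsimony_states(reg, tr, W)
      or <- oracle_parsimony(as.list(leaf), tr, W)
      expect_equal(ps$cost, or$cost)
      for (v in seq_along(ps$states))
        expect_equal(sort(ps$states[[v]]), or$states[[v]])
    }
  }
})

test_that("width-4 regions agree with enumeration on a 4-leaf tree", {
  set.seed(22)
  tr <- tree4()
  W <- event_cost_matrix(4)
  for (rep in 1:4) {
    leaf <- setNames(sample(0:15, 4, replace = TRUE), tr$tip.label)
    ps <- parsimony_states(list(species = tr$tip.label,
                                mat = matrix(0, 4, 4,
                                             dimnames = list(tr$tip.label, NULL)),
                                comp = t(vapply(leaf, function(s)
                                  as.integer(bitwAnd(s, 2L^(0:3)) > 0),
                                  integer(4))),
                                n = 4, block = 1L, cols = 1:4,
                                mult = rep(1L, 4), map = as.list(1:4)),
                          tr, W)
    or <- oracle_parsimony(as.list(leaf), tr, W)
    expect_equal(ps$cost, or$cost)
    for (v in seq_along(ps$states))
      expect_equal(sort(ps$states[[v]]), or$states[[v]])
  }
})

test_that("parsimony cost does not depend on the rooting", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1,(D:1,E:1):1);")  # unrooted
  b <- make_block(c(A = "ACT-GA", B = "ACTAGA", C = "ACTAGA",
                    D = "ACTAGA", E = "ACTAGA"))
  reg <- extract_indel_regions(b)[[1]]
  costs <- vapply(c("A", "C", "E"), function(out) {
    rt <- ape::root(tr, out, resolve.root = TRUE)
    parsimony_states(reg, rt)$cost
  }, 0)
  expect_equal(unname(costs), rep(costs[[1]], 3))
})

test_that("lineage-specific calls follow the forced-parent unanimity rule", {
  tr <- tree4()
  # only A has a gap: parent forced to 1 -> LS deletion for A
  b <- make_block(c(A = "AC--GT", B = "ACTAGT", C = "ACTAGT", D = "ACTAGT"),
                  quals = c(A = "91--19", B = NA, C = NA, D = NA))
  calls <- find_ls_indels(b, tr)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$species, "A")
  expect_equal(calls$type, "deletion")
  expect_equal(calls$length, 2)
  expect_equal(calls$bin, 1L)  # min over 5-base flanks
  # sister pair shares the gap: ancestral deletion, nothing lineage-specific
  b2 <- make_block(c(A = "AC--GT", B = "AC--GT", C = "ACTAGT", D = "ACTAGT"))
  expect_equal(nrow(find_ls_indels(b2, tr)), 0)
  # only A has extra bases: LS insertion
  b3 <- make_block(c(A = "ACTAGT", B = "AC--GT", C = "AC--GT", D = "AC--GT"),
                   quals = c(A = "993399", B = NA, C = NA, D = NA))
  calls3 <- find_ls_indels(b3, tr)
  expect_equal(calls3$type, "insertion")
  expect_equal(calls3$bin, 3L)  # min over inserted bases and flanks
})

test_that("missing leaves are never called", {
  tr <- tree4()
  long <- strrep("-", 12)
  b <- make_block(c(A = paste0("AC", long, "GT"),
                    B = paste0("AC", strrep("T", 12), "GT"),
                    C = paste0("AC", strrep("T", 12), "GT"),
                    D = paste0("AC", strrep("T", 12), "GT")))
  calls <- find_ls_indels(b, tr)  # A's gap run > 10 bp -> '?'
  expect_equal(sum(calls$species == "A"), 0)
})

test_that("wide regions are flagged skipped and refused by parsimony", {
  texts <- c(A = paste(rep(c("A", "-"), 11), collapse = ""),
             B = paste(rep(c("-", "A"), 11), collapse = ""),
             C = strrep("A", 22), D = strrep("A", 22))
  b <- make_block(texts)
  regs <- extract_indel_regions(b)
  expect_true(any(vapply(regs, function(r) isTRUE(r$skipped), TRUE)))
  skipped <- regs[[which(vapply(regs, function(r) isTRUE(r$skipped), TRUE))[1]]]
  expect_error(parsimony_states(skipped, tree4()), "skipped")
})

test_that("imputation reverts low-quality calls and updates geometry", {
  tr <- tree4()
  # low-quality LS insertion of 2 bp in A -> excised, row size shrinks
  b <- make_block(c(A = "ACTAGT", B = "AC--GT", C = "AC--GT", D = "AC--GT"),
                  quals = c(A = "990099", B = NA, C = NA, D = NA))
  calls <- find_ls_indels(b, tr)
  res <- impute(structure(list(b), class = "qmaf"), calls, T = 25)
  eb <- res$blocks[[1]]
  expect_equal(nchar(eb$text[1]), 4)     # all-gap columns dropped
  expect_equal(eb$text[1], "ACGT")
  expect_equal(eb$size[1], 4)
  expect_equal(res$log$action, "excised")
  # low-quality LS deletion -> filled with N at quality bin 0
  b2 <- make_block(c(A = "AC--GT", B = "ACTAGT", C = "ACTAGT", D = "ACTAGT"),
                   quals = c(A = "90--09", B = NA, C = NA, D = NA))
  calls2 <- find_ls_indels(b2, tr)
  res2 <- impute(structure(list(b2), class = "qmaf"), calls2, T = 25)
  eb2 <- res2$blocks[[1]]
  expect_equal(eb2$text[1], "ACNNGT")
  expect_equal(eb2$qual[1], "900009")
  expect_equal(eb2$size[1], 6)
  # quality above threshold -> untouched
  b3 <- make_block(c(A = "AC--GT", B = "ACTAGT", C = "ACTAGT", D = "ACTAGT"),
                   quals = c(A = "99--99", B = NA, C = NA, D = NA))
  calls3 <- find_ls_indels(b3, tr)
  res3 <- impute(structure(list(b3), class = "qmaf"), calls3, T = 25)
  expect_equal(res3$blocks[[1]]$text[1], "AC--GT")
  expect_equal(res3$log$action, "kept")
})

test_that("imputation shifts start coordinates of later blocks", {
  tr <- tree4()
  b1 <- make_block(c(A = "ACTAGT", B = "AC--GT", C = "AC--GT", D = "AC--GT"),
                   quals = c(A = "990099", B = NA, C = NA, D = NA))
  b2 <- make_block(c(A = "ACGT", B = "ACGT", C = "ACGT", D = "ACGT"),
                   quals = c(A = "9999", B = NA, C = NA, D = NA),
                   start = c(6L, 4L, 4L, 4L))
  calls <- find_ls_indels(structure(list(b1, b2), class = "qmaf"), tr)
  res <- impute(structure(list(b1, b2), class = "qmaf"), calls, T = 25)
  expect_equal(res$blocks[[2]]$start[1], 4L)  # 6 - excised length 2
  expect_equal(res$blocks[[2]]$start[2], 4L)  # other species unchanged
})

test_that("imputation reaches a fixed point on simulated data", {
  tr <- ape::read.tree(
    text = "(((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1):0.05,(E:0.2,F:0.2):0.05);")
  cfg <- sim_config(seed = 13, genome_length = 2500, tree = tr)
  sa <- simulate_alignment(cfg)
  corrupt <- inject_errors(sa$block, c("A", "C"), cfg)
  blocks <- structure(list(corrupt$block), class = "qmaf")
  res <- impute_until_stable(blocks, tr, c("A", "C"), T = 25)
  expect_lte(res$rounds, 4)   # converges quickly
  again <- find_ls_indels(res$blocks, tr)
  low <- !is.na(again$bin) & 5 * again$bin < 25
  again <- again[again$species %in% c("A", "C") & low, , drop = FALSE]
  expect_equal(nrow(again), 0)
})
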