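# helper: diff_table with prescribed per-bin sites and diffs
toy_table <- function(sites, diffs_by_type) {
  counts <- do.call(rbind, lapply(names(diffs_by_type), function(ty)
    data.frame(species = "sp", type = ty, bin = 0:9, sites = sites,
               diffs = diffs_by_type[[ty]], stringsAsFactors = FALSE)))
  structure(list(counts = counts, subst = matrix(0, 4, 4),
                 indel_calls = data.frame(), long_indels = c(0, 0),
                 draft = "sp", reference = "ref"), class = "diff_table")
}

test_that("mismatches, insertions and deletions are tabulated per bin", {
  b <- make_block(c(REF = "ACCTA", DRF = "ACGTA"),
                  quals = c(REF = "FFFFF", DRF = "99999"))
  tab <- tabulate_differences(b, "DRF", "REF")
  cn <- tab$counts
  expect_equal(sum(cn$sites[cn$type == "basecall"]), 5)
  expect_equal(cn$diffs[cn$type == "basecall" & cn$bin == 9], 1)
  expect_equal(sum(cn$diffs[cn$type != "basecall"]), 0)

  # one insertion event of length 2 (gap run in the reference)
  b2 <- make_block(c(REF = "AC--G", DRF = "ACTTG"),
                   quals = c(REF = "FF--F", DRF = "93229"))
  tab2 <- tabulate_differences(b2, "DRF", "REF")
  expect_equal(sum(tab2$counts$diffs[tab2$counts$type == "insertion"]), 1)
  # its bin: min over inserted (2,2) and flanks (9,3 / 9)
  expect_equal(tab2$counts$diffs[tab2$counts$type == "insertion" &
                                   tab2$counts$bin == 2], 1)
  expect_equal(nrow(tab2$indel_calls), 1)
  expect_equal(tab2$indel_calls$length, 2)

  # identity: zero diffs, sites = row length
  b3 <- make_block(c(REF = "ACGT", DRF = "ACGT"),
                   quals = c(REF = "FFFF", DRF = "9999"))
  tab3 <- tabulate_differences(b3, "DRF", "REF")
  expect_equal(sum(tab3$counts$diffs), 0)
  expect_equal(sum(tab3$counts$sites[tab3$counts$type == "basecall"]), 4)
})

test_that("N bases are excluded from numerator and denominator", {
  b <- make_block(c(REF = "ANGT", DRF = "NCGT"),
                  quals = c(REF = "FFFF", DRF = "9999"))
  tab <- tabulate_differences(b, "DRF", "REF")
  expect_equal(sum(tab$counts$sites[tab$counts$type == "basecall"]), 2)
  expect_equal(sum(tab$counts$diffs), 0)
})

test_that("draft rows without qualities are refused", {
  b <- make_block(c(REF = "ACGT", DRF = "ACGT"), quals = c(REF = "FFFF", DRF = NA))
  expect_error(tabulate_differences(b, "DRF", "REF"), "qualities")
})

test_that("region restriction uses reference coordinates", {
  b <- make_block(c(REF = "ACGTACGT", DRF = "AAGTACGA"),
                  quals = c(REF = "FFFFFFFF", DRF = "99999999"))
  regions <- region_set("REF", 0L, 4L)
  tab <- tabulate_differences(b, "DRF", "REF", regions = regions)
  cn <- tab$counts
  expect_equal(sum(cn$sites[cn$type == "basecall"]), 4)
  expect_equal(sum(cn$diffs[cn$type == "basecall"]), 1)  # only the col-2 mismatch
})

test_that("polymorphism correction subtracts the bin-9 rate and clamps", {
  # sites chosen so the aggregate reproduces a Table-2-style Raw/Poly pair
  sites <- c(rep(0, 4), 5e5, rep(0, 4), 5e5)
  diffs <- c(rep(0, 4), 13245, rep(0, 4), 11855)
  tab <- toy_table(sites, list(basecall = diffs))
  cr <- polymorphism_correct(tab)
  expect_equal(cr$aggregate$raw, 25.10, tolerance = 1e-12)
  expect_equal(cr$aggregate$poly, 23.71, tolerance = 1e-12)
  expect_equal(cr$aggregate$corrected, cr$aggregate$raw - cr$aggregate$poly,
               tolerance = 1e-9)
  # d_esq = d_esQ -> 0
  tab2 <- toy_table(rep(1000, 10), list(basecall = rep(3, 10)))
  cr2 <- polymorphism_correct(tab2)
  expect_equal(cr2$per_bin$corrected[cr2$per_bin$bin < 9], rep(0, 9))
  # clamped negative with warning
  tab3 <- toy_table(rep(1000, 10), list(basecall = c(1, rep(2, 9))))
  expect_warning(cr3 <- polymorphism_correct(tab3), "clamped")
  expect_equal(cr3$per_bin$corrected[cr3$per_bin$bin == 0], 0)
})

test_that("correction is flagged when bin 9 has no sites", {
  sites <- c(rep(100, 9), 0)
  tab <- toy_table(sites, list(basecall = c(rep(1, 9), 0)))
  cr <- polymorphism_correct(tab)
  expect_equal(nrow(cr$flagged), 1)
  expect_true(is.na(cr$aggregate$corrected))
})

test_that("confusion adjustment moves expected polymorphisms between cells", {
  s <- data.frame(masked_diffs = 10, masked_nondiffs = 990,
                  unmasked_diffs = 0, unmasked_nondiffs = 0, f = 0.4)
  cc <- confusion_adjusted(s)
  expect_equal(cc$TP, 6); expect_equal(cc$FP, 994)
  expect_equal(cc$FN, 0); expect_equal(cc$TN, 0)
  # nothing masked
  s2 <- data.frame(masked_diffs = 0, masked_nondiffs = 0,
                   unmasked_diffs = 10, unmasked_nondiffs = 990, f = 0.4)
  cc2 <- confusion_adjusted(s2)
  expect_equal(cc2$FN, 6); expect_equal(cc2$TN, 994)
  # f = 0 reduces to the standard table
  s3 <- data.frame(masked_diffs = 7, masked_nondiffs = 3,
                   unmasked_diffs = 2, unmasked_nondiffs = 88, f = 0)
  cc3 <- confusion_adjusted(s3)
  expect_equal(c(cc3$TP, cc3$FP, cc3$FN, cc3$TN), c(7, 3, 2, 88))
})

test_that("confusion counts are conserved for any polymorphic fraction", {
  set.seed(1)
  for (i in 1:20) {
    s <- data.frame(masked_diffs = rpois(5, 10), masked_nondiffs = rpois(5, 50),
                    unmasked_diffs = rpois(5, 10),
                    unmasked_nondiffs = rpois(5, 50), f = runif(5))
    cc <- confusion_adjusted(s)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, sum(s[, 1:4]))
  }
})

test_that("ROC sweep endpoints and monotonicity behave", {
  sites <- rep(1000, 10)
  diffs <- round(1000 * phred_to_prob(bin_representative(0:9))) + 2
  tab <- toy_table(sites, list(basecall = diffs))
  expect_error(roc_sweep(tab, numeric()), "empty")
  sw <- roc_sweep(tab, seq(0, 50, 5))
  expect_equal(sw$TPR[1], 0)   # threshold below all bins
  expect_equal(sw$FPR[1], 0)
  expect_equal(sw$TPR[nrow(sw)], 1)  # everything masked
  expect_true(all(diff(sw$TPR) >= -1e-12))
  expect_true(all(diff(sw$FPR) >= -1e-12))
})

test_that("exon error expectation is linear in rate, coverage and scale", {
  rates <- setNames(rep(1, 14), paste0("sp", 1:14))  # 1 error/kb each
  expect_equal(exon_error_expectation(rates), 2.4)
  expect_equal(exon_error_expectation(rates * 0), 0)
  half <- exon_error_expectation(rates, coverage = rep(0.5, 14))
  expect_equal(half, 1.2)
  expect_error(exon_error_expectation(numeric()), "empty")
})

test_that("exon coverage counts aligned draft bases inside exons", {
  b <- make_block(c(REF = "ACGTACGT", DRF = "ACGT--GT"),
                  quals = c(REF = "FFFFFFFF", DRF = "9999--99"))
  cov <- exon_coverage(structure(list(b), class = "qmaf"), "DRF", "REF",
                       region_set("REF", 0L, 8L))
  expect_equal(cov, 6 / 8)
})

test_that("indel length spectrum reports frame periodicity", {
  calls <- data.frame(length = c(3, 3, 6, 1))
  sp <- indel_length_spectrum(calls)
  expect_equal(sp$periodicity, 0.75)
  expect_equal(unname(sp$counts[c(1, 3, 6)]), c(1, 2, 1))
  expect_equal(indel_length_spectrum(data.frame(length = rep(1, 5)))$periodicity, 0)
  empty <- indel_length_spectrum(data.frame(length = integer()))
  expect_true(all(empty$counts == 0))
  expect_true(is.na(empty$periodicity))
})

test_that("indel quality takes the minimum over event and truncated flanks", {
  # insertion bins c(2,3) with flank minimum 4 -> bin 2
  b <- make_block(c(REF = "AAAA--AAAAA", DRF = "AAAACTAAAAA"),
                  quals = c(REF = "FFFF--FFFFF", DRF = "45672389567"))
  expect_equal(indel_quality(b, "DRF", cols = 5:6, type = "insertion"), 2L)
  # deletion: flanks only
  b3 <- make_block(c(REF = "AAAAAA", DRF = "AA--AA"),
                   quals = c(REF = "FFFFFF", DRF = "91--19"))
  expect_equal(indel_quality(b3, "DRF", cols = 3:4, type = "deletion"), 1L)
  # block edge: truncated left flank
  b4 <- make_block(c(REF = "AAAAAAAA", DRF = "--AAAAAA"),
                   quals = c(REF = "FFFFFFFF", DRF = "--356789"))
  expect_equal(indel_quality(b4, "DRF", cols = 1:2, type = "deletion"), 3L)
})
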