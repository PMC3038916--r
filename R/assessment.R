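#' Tabulate draft-vs-reference differences by quality bin
#'
#' Compares a low-coverage draft species against a high-quality
#' reference species in pairwise (or pairwise-projected) alignment
#' blocks.  Mismatches of two aligned bases are potential miscalled
#' bases; maximal gap runs in the reference (draft has bases) are
#' potential insertion errors; maximal gap runs in the draft are
#' potential deletion errors.  All counts are stratified by the draft
#' quality bin: the base's own bin for mismatches and aligned sites,
#' and for indels the minimum bin over the inserted bases (insertions
#' only) and up to \code{flank} draft bases on each side.
#'
#' Sites where either base is N are excluded from both numerator and
#' denominator.  Indel events longer than \code{max_indel} bp are kept
#' out of the per-bin counts and reported in a separate "long" bucket.
#'
#' @param blocks a \code{qmaf} object or a single \code{qmaf_block}.
#' @param draft draft (low-coverage) species; its rows must carry
#'   qualities.
#' @param reference high-quality reference species.
#' @param regions optional \code{region_set} restricting the
#'   tabulation, in reference coordinates.
#' @param flank flanking bases used for indel quality (default 5).
#' @param max_indel maximum indel length (bp) kept in per-bin counts.
#' @return an object of class \code{diff_table}: \code{$counts} (one
#'   row per species x type x bin with \code{sites} and \code{diffs}),
#'   \code{$subst} (4x4 reference-to-draft mismatch counts at bins
#'   below 9), \code{$indel_calls} (one row per indel event), and
#'   \code{$long_indels}.
#' @export
tabulate_differences <- function(blocks, draft, reference, regions = NULL,
                                 flank = 5L, max_indel = 10L) {
  if (inherits(blocks, "qmaf_block")) blocks <- list(blocks)
  bases <- c("A", "C", "G", "T")
  sites <- numeric(10)
  diffs <- matrix(0, nrow = 3, ncol = 10,
                  dimnames = list(c("basecall", "insertion", "deletion"), 0:9))
  subst <- matrix(0, 4, 4, dimnames = list(bases, bases))
  long_indels <- c(insertion = 0, deletion = 0)
  calls <- list()

  for (bi in seq_along(blocks)) {
    block <- blocks[[bi]]
    di <- block_row(block, draft)
    if (is.na(block$qual[di]))
      stop("draft row carries no qualities in block ", bi)
    pc <- pair_columns(block, ref = reference, other = draft)
    if (nrow(pc) == 0) next
    rch <- pc$ref_base; dch <- pc$other_base; dbin <- pc$other_bin
    # reference coordinate carried across reference gaps (for region lookup)
    rfill <- pc$ref_pos
    if (anyNA(rfill)) {
      idx <- cummax(ifelse(is.na(rfill), 0L, seq_along(rfill)))
      rfill <- ifelse(idx > 0L, rfill[pmax(idx, 1L)], rfill[which(!is.na(rfill))[1]])
    }
    inreg <- if (is.null(regions)) rep(TRUE, nrow(pc)) else
      in_regions(regions, species_src_chrom(block, reference), rfill)

    both <- rch != "-" & dch != "-"
    usable <- both & rch != "N" & dch != "N" & inreg
    tb <- tabulate(dbin[usable] + 1L, 10L)
    sites <- sites + tb
    mm <- usable & rch != dch
    if (any(mm)) {
      diffs["basecall", ] <- diffs["basecall", ] + tabulate(dbin[mm] + 1L, 10L)
      low <- mm & dbin < 9L
      if (any(low))
        subst <- subst + table(factor(rch[low], bases), factor(dch[low], bases))
    }

    dpos_idx <- which(dch != "-")  # kept-column indices of draft bases
    for (type in c("insertion", "deletion")) {
      gap <- if (type == "insertion") rch == "-" & dch != "-" else
        dch == "-" & rch != "-"
      r <- rle(gap)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts[k]; b <- ends[k]; len <- b - a + 1L
        if (!inreg[a]) next
        q <- indel_run_bin(dbin, dpos_idx, a, b, type, flank)
        calls[[length(calls) + 1L]] <- data.frame(
          species = draft, block = bi, type = type, start_col = pc$col[a],
          end_col = pc$col[b], length = len, bin = q,
          stringsAsFactors = FALSE)
        if (len > max_indel) {
          long_indels[type] <- long_indels[type] + 1
        } else diffs[type, q + 1L] <- diffs[type, q + 1L] + 1
      }
    }
  }

  counts <- do.call(rbind, lapply(rownames(diffs), function(ty)
    data.frame(species = draft, type = ty, bin = 0:9, sites = sites,
               diffs = diffs[ty, ], stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  structure(list(counts = counts, subst = subst,
                 indel_calls = if (length(calls)) do.call(rbind, calls) else
                   data.frame(species = character(), block = integer(),
                              type = character(), start_col = integer(),
                              end_col = integer(), length = integer(),
                              bin = integer()),
                 long_indels = long_indels, draft = draft,
                 reference = reference),
            class = "diff_table")
}

# full src name of species' row (for region chrom matching)
species_src_chrom <- function(block, species) {
  src <- block$src[block_row(block, species)]
  if (grepl("\\.", src)) sub("^[^.]*\\.", "", src) else src
}

# minimum quality bin over a gap run: for insertions, the inserted draft
# bases plus up to `flank` draft bases each side; for deletions, the
# flanking draft bases only.  Truncated flanks use what is available.
indel_run_bin <- function(dbin, dpos_idx, a, b, type, flank) {
  left <- dpos_idx[dpos_idx < a]
  right <- dpos_idx[dpos_idx > b]
  idx <- c(utils::tail(left, flank), utils::head(right, flank))
  if (type == "insertion") idx <- c(idx, seq.int(a, b))
  if (length(idx) == 0) return(9L)
  min(dbin[idx], na.rm = TRUE)
}

#' Quality bin of an indel event
#'
#' The quality of an insertion is the minimum binned score of the
#' inserted bases and up to \code{flank} draft bases on each side; the
#' quality of a deletion is the minimum over the flanking draft bases
#' only.  Flanks truncated at block edges use the available bases.
#'
#' @param block a \code{qmaf_block}.
#' @param species the draft species carrying qualities.
#' @param cols original column indices spanned by the indel.
#' @param type "insertion" or "deletion".
#' @param flank flanking bases per side (default 5).
#' @return a quality bin (0..9).
#' @export
indel_quality <- function(block, species, cols, type = c("insertion", "deletion"),
                          flank = 5L) {
  type <- match.arg(type)
  i <- block_row(block, species)
  bins <- block_bins(block, i)
  if (is.null(bins)) stop("species row carries no qualities")
  ch <- block_chars(block, i)
  dpos_idx <- which(ch != "-")
  indel_run_bin(bins, dpos_idx, min(cols), max(cols), type, flank)
}

#' Polymorphism correction of difference rates
#'
#' The difference rate at the highest-quality bases (bin 9, raw scores
#' >= 45) is taken as an estimate of the polymorphism rate (nucleotide
#' diversity between the individuals sequenced), under the assumption
#' that sequencing error is negligible at those bases.  Error rates at
#' each lower bin are corrected by subtraction: r_q = max(d_q - d_Q, 0).
#' The aggregate view reproduces the Raw / Poly. / Corrected layout:
#' corrected aggregate rate = aggregate raw rate - bin-9 rate.
#'
#' @param table a \code{diff_table}.
#' @return an object of class \code{corrected_rates}: \code{$per_bin}
#'   with per-bin rates, corrected rates and polymorphic fractions
#'   (min(d_Q/d_q, 1)); \code{$aggregate} with per-(species, type)
#'   raw, poly and corrected rates per kb; \code{$flagged} naming
#'   (species, type) combinations without bin-9 sites.
#' @export
polymorphism_correct <- function(table) {
  stopifnot(inherits(table, "diff_table"))
  cn <- table$counts
  per_bin <- NULL; agg <- NULL; flagged <- NULL
  clamped <- FALSE
  for (ty in unique(cn$type)) {
    x <- cn[cn$type == ty, ]
    d <- ifelse(x$sites > 0, 1000 * x$diffs / x$sites, NA_real_)
    q9 <- which(x$bin == 9)
    if (x$sites[q9] == 0) {
      flagged <- rbind(flagged, data.frame(species = x$species[1], type = ty))
      dQ <- NA_real_
    } else dQ <- d[q9]
    r <- d - dQ
    if (any(r < 0, na.rm = TRUE)) clamped <- TRUE
    r <- pmax(r, 0)
    r[x$bin == 9] <- NA_real_  # bin 9 is the polymorphism proxy itself
    f <- pmin(dQ / d, 1)
    f[is.na(d) | d == 0] <- NA_real_
    per_bin <- rbind(per_bin, data.frame(
      species = x$species, type = ty, bin = x$bin, sites = x$sites,
      diffs = x$diffs, rate = d, corrected = r, poly_fraction = f,
      stringsAsFactors = FALSE))
    raw <- 1000 * sum(x$diffs) / sum(x$sites)
    corr <- if (is.na(dQ)) NA_real_ else max(raw - dQ, 0)
    agg <- rbind(agg, data.frame(species = x$species[1], type = ty,
                                 raw = raw, poly = dQ, corrected = corr,
                                 stringsAsFactors = FALSE))
  }
  if (clamped) warning("negative corrected rate(s) clamped to 0")
  structure(list(per_bin = per_bin, aggregate = agg, flagged = flagged),
            class = "corrected_rates")
}

#' Polymorphism-adjusted confusion counts
#'
#' Within each stratum (an error type / species / quality bin cell), a
#' fraction \code{f} of observed differences is assumed polymorphic
#' rather than erroneous.  The expected number of masked polymorphic
#' sites is moved from true positives to false positives, and the
#' expected number of unmasked polymorphic sites from false negatives
#' to true negatives.
#'
#' @param strata data.frame with columns \code{masked_diffs},
#'   \code{masked_nondiffs}, \code{unmasked_diffs},
#'   \code{unmasked_nondiffs} and \code{f} (polymorphic fraction of
#'   diffs; NA means unavailable and the stratum contributes raw
#'   counts).
#' @return a list of class \code{confusion}: TP, FP, TN, FN, TPR, FPR,
#'   PPV, and \code{n_flagged} (strata with undefined f).
#' @export
confusion_adjusted <- function(strata) {
  need <- c("masked_diffs", "masked_nondiffs", "unmasked_diffs",
            "unmasked_nondiffs", "f")
  stopifnot(all(need %in% names(strata)))
  f <- strata$f
  n_flagged <- sum(is.na(f))
  f[is.na(f)] <- 0
  TP <- sum(strata$masked_diffs * (1 - f))
  FP <- sum(strata$masked_nondiffs + strata$masked_diffs * f)
  FN <- sum(strata$unmasked_diffs * (1 - f))
  TN <- sum(strata$unmasked_nondiffs + strata$unmasked_diffs * f)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
                 PPV = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
                 n_flagged = n_flagged),
            class = "confusion")
}

#' ROC sweep over quality thresholds
#'
#' Evaluates masking (or indel-correction) decisions by quality
#' threshold: at threshold T every site (or indel) whose bin
#' representative is below T is masked/corrected.  Counts are
#' polymorphism-adjusted per bin via \code{\link{confusion_adjusted}}.
#'
#' @param table a \code{diff_table}.
#' @param thresholds numeric vector of phred thresholds (e.g.
#'   \code{seq(0, 50, 5)}).
#' @param mode "mask" evaluates basecall masking (negatives are
#'   correctly called aligned bases); "indel" evaluates indel
#'   correction (only observed indel differences enter, and negatives
#'   are the polymorphic ones).
#' @param corrected optional precomputed \code{corrected_rates}.
#' @return data.frame with one row per threshold: TP, FP, TN, FN, TPR,
#'   FPR, PPV.
#' @export
roc_sweep <- function(table, thresholds, mode = c("mask", "indel"),
                      corrected = NULL) {
  mode <- match.arg(mode)
  if (length(thresholds) == 0) stop("empty threshold list")
  if (is.null(corrected))
    corrected <- suppressWarnings(polymorphism_correct(table))
  pb <- corrected$per_bin
  types <- if (mode == "mask") "basecall" else c("insertion", "deletion")
  out <- NULL
  for (T in sort(thresholds)) {
    strata <- NULL
    for (ty in types) {
      x <- pb[pb$type == ty, ]
      masked <- bin_representative(x$bin) < T
      nondiff <- if (mode == "mask") x$sites - x$diffs else 0
      strata <- rbind(strata, data.frame(
        masked_diffs = ifelse(masked, x$diffs, 0),
        masked_nondiffs = ifelse(masked, nondiff, 0),
        unmasked_diffs = ifelse(masked, 0, x$diffs),
        unmasked_nondiffs = ifelse(masked, 0, nondiff),
        f = x$poly_fraction))
    }
    cc <- confusion_adjusted(strata)
    out <- rbind(out, data.frame(threshold = T, TP = cc$TP, FP = cc$FP,
                                 TN = cc$TN, FN = cc$FN, TPR = cc$TPR,
                                 FPR = cc$FPR, PPV = cc$PPV))
  }
  out
}

#' Expected sequencing errors per coding exon
#'
#' Sums per-species corrected error rates over a typical exon,
#' weighting each species by the fraction of exon bases its draft
#' assembly covers in the alignment (incomplete coverage reduces the
#' expectation and is deliberately not compensated), and scaling by
#' \code{species_scale} to extrapolate from the species with reference
#' sequence to the full species panel (20/14 in the default setting).
#'
#' @param rate_per_kb named numeric vector: corrected error rate per kb
#'   for each draft species (basecall or indel, caller's choice).
#' @param coverage named numeric vector of covered exon-base fractions
#'   per species (default: full coverage).
#' @param exon_length exon length in bp (default 120, a typical median).
#' @param species_scale panel extrapolation factor (default 20/14).
#' @return expected number of errors per exon.
#' @export
exon_error_expectation <- function(rate_per_kb, coverage = NULL,
                                   exon_length = 120, species_scale = 20 / 14) {
  if (length(rate_per_kb) == 0) stop("empty species set")
  if (is.null(coverage)) coverage <- rep(1, length(rate_per_kb))
  if (!is.null(names(rate_per_kb)) && !is.null(names(coverage)))
    coverage <- coverage[names(rate_per_kb)]
  stopifnot(length(coverage) == length(rate_per_kb))
  sum(rate_per_kb / 1000 * coverage) * exon_length * species_scale
}

#' Fraction of exon bases covered by a draft species
#'
#' @param blocks a \code{qmaf} object.
#' @param draft,reference species names.
#' @param exons a \code{region_set} in reference coordinates.
#' @return fraction of exon reference bases aligned to a draft base.
#' @export
exon_coverage <- function(blocks, draft, reference, exons) {
  if (nrow(exons) == 0) stop("empty exon set")
  total <- sum(exons$end - exons$start)
  covered <- 0
  for (block in blocks) {
    pc <- pair_columns(block, ref = reference, other = draft)
    ok <- !is.na(pc$ref_pos) & pc$other_base != "-" &
      in_regions(exons, species_src_chrom(block, reference), pc$ref_pos)
    covered <- covered + sum(ok)
  }
  covered / total
}

#' Indel length spectrum and reading-frame periodicity
#'
#' @param calls data.frame of indel calls with a \code{length} column
#'   (bp), e.g. \code{diff_table$indel_calls} or lineage-specific calls.
#' @param max_len histogram upper bound (default 10).
#' @return list with \code{counts} (named vector, lengths 1..max_len)
#'   and \code{periodicity} (fraction of calls with length a multiple
#'   of 3; NA if no calls).
#' @export
indel_length_spectrum <- function(calls, max_len = 10L) {
  len <- calls$length
  len <- len[len >= 1 & len <= max_len]
  counts <- tabulate(len, max_len)
  names(counts) <- seq_len(max_len)
  list(counts = counts,
       periodicity = if (length(len) == 0) NA_real_ else
         mean(len %% 3 == 0))
}
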