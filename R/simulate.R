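#' Default single-read quality profile
#'
#' A capillary-read-like quality profile for the generator: 13.7% of
#' single-read bases fall below phred 20 (the low-quality read ends),
#' the remainder is concentrated at high scores, and the implied
#' single-read error rate is ~8.6e-3 (Q ~ 20.7).
#'
#' @return a \code{quality_dist}.
#' @export
sim_p1_default <- function() {
  quality_dist(c(8L, 13L, 18L, 25L, 35L, 45L),
               c(0.030, 0.047, 0.060, 0.060, 0.100, 0.703))
}

# conditional substitution spectrum given an error/mutation occurred:
# transitions twice as likely as each transversion
default_spectrum <- function() {
  M <- matrix(0.25, 4, 4, dimnames = list(BASES, BASES))
  diag(M) <- 0
  M["A", "G"] <- M["G", "A"] <- M["C", "T"] <- M["T", "C"] <- 0.5
  M
}

#' Simulation configuration
#'
#' Bundles the generator parameters.  Defaults encode the study
#' conditions the methods assume: Poisson read depth with mean
#' \code{lambda} = 2, quality-dependent basecall errors at
#' 10^(-q/10), insertion and deletion error rates at 0.2 of the
#' basecall rate each, nucleotide diversity \code{pi} = 5e-3, true
#' indels 20-fold rarer than substitutions with lengths <= 10 bp, and
#' a coding mode in which 90% of true indels preserve the reading
#' frame.
#'
#' @param seed mandatory integer seed; all generator output is
#'   deterministic given the seed.
#' @param genome_length reference length in bp.
#' @param gc G+C fraction.
#' @param lambda expected read coverage.
#' @param p1 single-read \code{quality_dist}.
#' @param pi polymorphism (nucleotide diversity) rate.
#' @param ins_ratio,del_ratio indel-error rate relative to the
#'   basecall error rate at the same base.
#' @param spectrum 4x4 conditional substitution matrix (zero
#'   diagonal) used for both errors and mutations.
#' @param err_indel_lengths probabilities of error-indel lengths 1..k.
#' @param tree \code{ape::phylo} for alignment simulation.
#' @param indel_rate true-indel events per site per unit branch length.
#' @param coding constrain true-indel lengths to favor multiples of 3.
#' @param frame_frac fraction of frame-preserving true indels in
#'   coding mode.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed, genome_length = 20000L, gc = 0.41, lambda = 2,
                       p1 = sim_p1_default(), pi = 0.005,
                       ins_ratio = 0.2, del_ratio = 0.2,
                       spectrum = default_spectrum(),
                       err_indel_lengths = c(0.75, 0.17, 0.08),
                       tree = NULL, indel_rate = 0.05, coding = FALSE,
                       frame_frac = 0.9) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(lambda > 0, pi >= 0, pi <= 1, gc >= 0, gc <= 1)
  structure(as.list(environment()), class = "sim_config")
}

rand_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                            (1 - gc) / 2))
}

substitute_bases <- function(bases, spectrum) {
  out <- bases
  for (b in BASES) {
    i <- which(bases == b)
    if (length(i))
      out[i] <- sample(BASES, length(i), replace = TRUE, prob = spectrum[b, ])
  }
  out
}

# truncated-Poisson depths (>= 1) and assembled qualities (sums of
# single-read draws); returns raw and 50-capped encoded scores
sim_qualities <- function(n, lambda, p1) {
  x <- stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
  sup <- qd_support(p1)
  draws <- sample(sup, sum(x), replace = TRUE, prob = as.numeric(p1))
  cs <- cumsum(draws)
  ends <- cumsum(x)
  q <- cs[ends] - c(0, cs[utils::head(ends, -1)])
  list(depth = x, q = q, q_enc = pmin(q, 50L))
}

#' Simulate a draft assembly aligned to a finished reference
#'
#' Generates a clean reference sequence, a sampled individual
#' (polymorphisms at rate \code{pi}, independent of quality), and a
#' draft assembly of that individual with quality-dependent basecall
#' errors (probability 10^(-q/10) at encoded quality q) plus
#' insertion and deletion errors at the configured ratios.  The
#' result is returned as a pairwise quality-MAF block ("reference"
#' with finished qualities vs "draft" with binned qualities) along
#' with a truth table of every injected event.
#'
#' @param config a \code{sim_config}.
#' @return list: \code{block} (a \code{qmaf_block}), \code{truth}
#'   (data.frame: kind, pos (0-based reference coordinate), length,
#'   q_enc), \code{q} (uncapped per-base quality sums), \code{q_enc},
#'   \code{depth}.
#' @export
simulate_assembly <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$genome_length
  ref <- rand_bases(n, config$gc)
  qq <- sim_qualities(n, config$lambda, config$p1)
  perr <- phred_to_prob(qq$q_enc)

  sampled <- ref
  poly <- stats::runif(n) < config$pi
  sampled[poly] <- substitute_bases(ref[poly], config$spectrum)
  draft <- sampled
  bce <- stats::runif(n) < perr
  draft[bce] <- substitute_bases(sampled[bce], config$spectrum)

  lens <- seq_along(config$err_indel_lengths)
  del <- stats::runif(n) < perr * config$del_ratio
  ins <- stats::runif(n) < perr * config$ins_ratio
  del_start <- which(del); ins_at <- which(ins)
  del_len <- if (length(del_start))
    sample(lens, length(del_start), TRUE, config$err_indel_lengths) else integer()
  ins_len <- if (length(ins_at))
    sample(lens, length(ins_at), TRUE, config$err_indel_lengths) else integer()

  is_del <- rep(FALSE, n)
  for (k in seq_along(del_start))
    is_del[del_start[k]:min(n, del_start[k] + del_len[k] - 1L)] <- TRUE

  truth <- rbind(
    if (any(poly)) data.frame(kind = "polymorphism", pos = which(poly) - 1L,
                              length = 1L, q_enc = qq$q_enc[poly]),
    if (any(bce)) data.frame(kind = "basecall_error", pos = which(bce) - 1L,
                             length = 1L, q_enc = qq$q_enc[bce]),
    if (length(del_start)) data.frame(kind = "deletion_error",
                                      pos = del_start - 1L, length = del_len,
                                      q_enc = qq$q_enc[del_start]),
    if (length(ins_at)) data.frame(kind = "insertion_error", pos = ins_at - 1L,
                                   length = ins_len, q_enc = qq$q_enc[ins_at]))
  if (is.null(truth))
    truth <- data.frame(kind = character(), pos = integer(),
                        length = integer(), q_enc = integer())

  # assemble gapped columns; insertions are spliced in after their anchor
  qchar <- as.character(bin_quality(qq$q_enc))
  ref_l <- as.list(ref)
  drf_l <- as.list(ifelse(is_del, "-", draft))
  qus_l <- as.list(ifelse(is_del, "-", qchar))
  for (k in seq_along(ins_at)) {
    i <- ins_at[k]; L <- ins_len[k]
    ref_l[[i]] <- c(ref_l[[i]], rep("-", L))
    drf_l[[i]] <- c(drf_l[[i]], rand_bases(L, config$gc))
    qus_l[[i]] <- c(qus_l[[i]], rep(qchar[i], L))
  }
  ref_c <- unlist(ref_l); drf_c <- unlist(drf_l); qus_c <- unlist(qus_l)
  refq <- ifelse(ref_c == "-", "-", "F")  # finished reference
  block <- qmaf_block(
    src = c("reference", "draft"), start = c(0L, 0L),
    size = c(sum(ref_c != "-"), sum(drf_c != "-")), strand = c("+", "+"),
    src_size = c(sum(ref_c != "-"), sum(drf_c != "-")),
    text = c(paste(ref_c, collapse = ""), paste(drf_c, collapse = "")),
    qual = c(paste(refq, collapse = ""), paste(qus_c, collapse = "")))
  list(block = block, truth = truth, q = qq$q, q_enc = qq$q_enc,
       depth = qq$depth)
}

# sample true-indel lengths (<= 10 bp); coding mode favors multiples of 3
true_indel_len <- function(k, config) {
  if (k == 0) return(integer())
  base_p <- c(0.45, 0.18, 0.12, 0.07, 0.05, 0.04, 0.03, 0.025, 0.02, 0.015)
  if (!config$coding) return(sample(1:10, k, TRUE, base_p))
  inframe <- stats::runif(k) < config$frame_frac
  out <- integer(k)
  out[inframe] <- sample(c(3L, 6L, 9L), sum(inframe), TRUE, c(0.6, 0.25, 0.15))
  off <- c(1L, 2L, 4L, 5L, 7L, 8L, 10L)
  out[!inframe] <- sample(off, sum(!inframe), TRUE, base_p[off])
  out
}

#' Simulate a true multi-species alignment down a tree
#'
#' Evolves a root sequence along the phylogeny under the substitution
#' model (Jukes-Cantor by default), placing true insertion/deletion
#' events on each branch at \code{indel_rate} events per site per
#' unit branch length with lengths <= 10 bp.  The emitted MAF block
#' is the true homology — no aligner is involved — and the truth
#' table records every indel event with its branch.
#'
#' @param config a \code{sim_config} with a \code{tree}.
#' @param root_length root sequence length (default
#'   \code{config$genome_length}).
#' @return list: \code{block} (a \code{qmaf_block} of the tip rows,
#'   no qualities), \code{truth} (data.frame: species (tip label or
#'   internal node id), type, length, cols (final column indices,
#'   comma-joined)).
#' @export
simulate_alignment <- function(config, root_length = NULL) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$tree))
  set.seed(config$seed + 1L)
  tree <- config$tree
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  model <- phylo_model(tree)
  n <- if (is.null(root_length)) config$genome_length else root_length
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  aln <- list(); aln[[as.character(root)]] <- rand_bases(n, config$gc)
  colid <- seq_len(n); next_id <- n + 1L
  truth <- list()
  children <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])

  visit <- function(node) {
    for (child in children[[as.character(node)]]) {
      t <- edge_len[[as.character(child)]]
      seq_p <- aln[[as.character(node)]]
      child_seq <- seq_p
      nongap <- which(child_seq != "-")
      # substitutions
      P <- pmat(model, t)
      for (b in BASES) {
        i <- nongap[child_seq[nongap] == b]
        if (length(i))
          child_seq[i] <- sample(BASES, length(i), TRUE, P[b, ])
      }
      label <- if (child <= ntip) tree$tip.label[child] else
        paste0("node", child)
      # deletions
      n_events <- stats::rpois(1, config$indel_rate * t * length(nongap))
      if (n_events > 0) {
        lens <- true_indel_len(n_events, config)
        for (k in seq_len(n_events)) {
          nongap_now <- which(child_seq != "-")
          if (length(nongap_now) < 12) break
          s0 <- sample(length(nongap_now) - lens[k], 1)
          pos <- nongap_now[s0:(s0 + lens[k] - 1L)]
          child_seq[pos] <- "-"
          truth[[length(truth) + 1L]] <<- data.frame(
            species = label, type = "deletion", length = lens[k],
            ids = paste(colid[pos], collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
      # insertions (pad every materialized row)
      n_events <- stats::rpois(1, config$indel_rate * t * length(nongap))
      if (n_events > 0) {
        lens <- true_indel_len(n_events, config)
        for (k in seq_len(n_events)) {
          at <- sample(length(child_seq), 1)
          L <- lens[k]
          ids <- next_id:(next_id + L - 1L); next_id <<- next_id + L
          splice <- function(v, fill) append(v, fill, after = at)
          for (nm in names(aln)) aln[[nm]] <<- splice(aln[[nm]], rep("-", L))
          child_seq <- splice(child_seq, rand_bases(L, config$gc))
          colid <<- splice(colid, ids)
          truth[[length(truth) + 1L]] <<- data.frame(
            species = label, type = "insertion", length = L,
            ids = paste(ids, collapse = ","), stringsAsFactors = FALSE)
        }
      }
      aln[[as.character(child)]] <<- child_seq
      visit(child)
    }
  }
  visit(root)

  tips <- tree$tip.label
  texts <- vapply(seq_len(ntip), function(i)
    paste(aln[[as.character(i)]], collapse = ""), "")
  # drop columns that are gaps in every tip (events confined to internal
  # lineages that later disappeared)
  chm <- do.call(rbind, strsplit(texts, ""))
  keep <- colSums(chm != "-") > 0
  texts <- apply(chm[, keep, drop = FALSE], 1, paste, collapse = "")
  colid <- colid[keep]
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(), type = character(),
               length = integer(), ids = character())
  truth$cols <- vapply(truth$ids, function(s) {
    ids <- as.integer(strsplit(s, ",")[[1]])
    paste(match(ids, colid), collapse = ",")
  }, "", USE.NAMES = FALSE)
  sizes <- vapply(texts, function(t) sum(strsplit(t, "")[[1]] != "-"), 0L,
                  USE.NAMES = FALSE)
  block <- qmaf_block(src = tips, start = rep(0L, ntip), size = sizes,
                      strand = rep("+", ntip), src_size = sizes,
                      text = texts)
  list(block = block, truth = truth, tree = tree)
}

#' Inject sequencing errors into designated species of an alignment
#'
#' Creates the "low-coverage draft" condition: each designated row
#' receives a simulated quality track (truncated-Poisson depth, p1
#' sums) and quality-dependent basecall, insertion and deletion
#' errors, exactly as in \code{\link{simulate_assembly}}.  Insertion
#' errors add alignment columns (gap in every other row); deletion
#' errors blank the row's bases in place.  The truth table permits
#' exact reversal via \code{\link{revert_errors}}.
#'
#' @param block a \code{qmaf_block} (e.g. from
#'   \code{\link{simulate_alignment}}).
#' @param species character vector of rows to corrupt.
#' @param config a \code{sim_config}.
#' @return list: \code{block} (corrupted, with quality lines on the
#'   designated rows), \code{truth} (data.frame: species, kind, col
#'   (final column index of the event start), length, q_enc, orig).
#' @export
inject_errors <- function(block, species, config) {
  stopifnot(inherits(block, "qmaf_block"))
  set.seed(config$seed + 2L)
  ncol0 <- nchar(block$text[1])
  colid <- seq_len(ncol0); next_id <- ncol0 + 1L
  rows <- lapply(seq_along(block$src), function(r) block_chars(block, r))
  quals <- lapply(seq_along(block$src), function(r)
    if (is.na(block$qual[r])) NULL else strsplit(block$qual[r], "")[[1]])
  truth <- list()
  lens_p <- config$err_indel_lengths

  for (sp in species) {
    ri <- block_row(block, sp)
    ch <- rows[[ri]]
    idx <- which(ch != "-")
    nb <- length(idx)
    qq <- sim_qualities(nb, config$lambda, config$p1)
    perr <- phred_to_prob(qq$q_enc)
    qchar <- rep("-", length(ch))
    qchar[idx] <- as.character(bin_quality(qq$q_enc))

    bce <- stats::runif(nb) < perr
    for (k in which(bce)) {
      col <- idx[k]
      orig <- ch[col]
      ch[col] <- substitute_bases(orig, config$spectrum)
      truth[[length(truth) + 1L]] <- data.frame(
        species = sp, kind = "basecall_error", ids = as.character(colid[col]),
        length = 1L, q_enc = qq$q_enc[k], orig = orig, stringsAsFactors = FALSE)
    }
    del <- stats::runif(nb) < perr * config$del_ratio
    for (k in which(del)) {
      L <- sample(seq_along(lens_p), 1, prob = lens_p)
      pos <- idx[k:min(nb, k + L - 1L)]
      pos <- pos[ch[pos] != "-"]
      if (length(pos) == 0) next
      truth[[length(truth) + 1L]] <- data.frame(
        species = sp, kind = "deletion_error",
        ids = paste(colid[pos], collapse = ","), length = length(pos),
        q_enc = qq$q_enc[k], orig = paste(ch[pos], collapse = ""),
        stringsAsFactors = FALSE)
      ch[pos] <- "-"; qchar[pos] <- "-"
    }
    ins <- stats::runif(nb) < perr * config$ins_ratio
    for (k in rev(which(ins))) {  # right-to-left keeps earlier anchors valid
      L <- sample(seq_along(lens_p), 1, prob = lens_p)
      at <- idx[k]
      ids <- next_id:(next_id + L - 1L); next_id <- next_id + L
      newb <- rand_bases(L, config$gc)
      for (r in seq_along(rows)) {
        fill <- if (r == ri) newb else rep("-", L)
        rows[[r]] <- append(rows[[r]], fill, after = at)
        if (!is.null(quals[[r]]))
          quals[[r]] <- append(quals[[r]], rep("-", L), after = at)
      }
      ch <- append(ch, newb, after = at)
      qchar <- append(qchar, rep(qchar[at], L), after = at)
      colid <- append(colid, ids, after = at)
      idx <- which(ch != "-")
      truth[[length(truth) + 1L]] <- data.frame(
        species = sp, kind = "insertion_error",
        ids = paste(ids, collapse = ","), length = L,
        q_enc = qq$q_enc[k], orig = "", stringsAsFactors = FALSE)
    }
    rows[[ri]] <- ch
    quals[[ri]] <- qchar
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(), kind = character(), ids = character(),
               length = integer(), q_enc = integer(), orig = character())
  truth$col <- vapply(truth$ids, function(s)
    match(as.integer(strsplit(s, ",")[[1]][1]), colid), 0L, USE.NAMES = FALSE)
  out <- block
  out$text <- vapply(rows, paste, "", collapse = "")
  out$qual <- vapply(quals, function(q)
    if (is.null(q)) NA_character_ else paste(q, collapse = ""), "")
  out$size <- vapply(rows, function(r) sum(r != "-"), 0L)
  validate_qmaf_block(out)
  list(block = out, truth = truth, colid = colid)
}

#' Revert injected errors using the truth table
#'
#' Exact inverse of \code{\link{inject_errors}}: substituted bases are
#' restored, deleted bases re-filled, inserted columns removed, and
#' quality lines dropped, reproducing the input block bit-exactly.
#'
#' @param corrupt result of \code{\link{inject_errors}}.
#' @return the restored \code{qmaf_block}.
#' @export
revert_errors <- function(corrupt) {
  block <- corrupt$block
  truth <- corrupt$truth
  colid <- corrupt$colid
  rows <- lapply(seq_along(block$src), function(r) block_chars(block, r))
  drop_cols <- integer()
  # deletions are reverted before basecall errors: a base that was first
  # miscalled and then deleted must end up with its pre-error identity
  ord <- order(match(truth$kind, c("deletion_error", "basecall_error",
                                   "insertion_error")))
  truth <- truth[ord, , drop = FALSE]
  for (k in seq_len(nrow(truth))) {
    ev <- truth[k, ]
    ri <- block_row(block, ev$species)
    cols <- match(as.integer(strsplit(ev$ids, ",")[[1]]), colid)
    if (ev$kind == "basecall_error") {
      rows[[ri]][cols] <- ev$orig
    } else if (ev$kind == "deletion_error") {
      rows[[ri]][cols] <- strsplit(ev$orig, "")[[1]]
    } else if (ev$kind == "insertion_error") {
      drop_cols <- c(drop_cols, cols)
    }
  }
  keep <- setdiff(seq_along(colid), drop_cols)
  out <- block
  out$text <- vapply(rows, function(r) paste(r[keep], collapse = ""), "")
  out$qual <- rep(NA_character_, length(block$src))
  out$size <- vapply(rows, function(r) sum(r[keep] != "-"), 0L)
  validate_qmaf_block(out)
  out
}
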