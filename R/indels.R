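#' Extract indel regions from alignment blocks
#'
#' An indel region (IR) is a maximal run of alignment columns each
#' containing at least one gap character (among the selected species),
#' flanked by gapless columns (block edges count as flanks).  Species
#' absent from a block are missing ('?', stored as NA); so is any
#' maximal gap run longer than \code{max_gap} bp in one species — only
#' short gaps are modelled as single events.  Each region's column
#' matrix is compressed by merging runs of identical columns; regions
#' whose compressed width exceeds \code{max_width} are emitted flagged
#' as skipped and receive no calls.
#'
#' @param blocks a \code{qmaf} object or single block.
#' @param species species to include (default: all species present in
#'   each block).
#' @param max_gap maximum modelled gap length in bp (default 10).
#' @param max_width maximum compressed width n (default 10; states are
#'   2^n).
#' @return list of \code{indel_region} objects, each with
#'   \code{block} (index), \code{cols} (original column indices),
#'   \code{species}, \code{mat} (species x columns presence matrix:
#'   1 base, 0 gap, NA missing), \code{comp}, \code{mult}, \code{map},
#'   \code{n}, \code{skipped}.
#' @export
extract_indel_regions <- function(blocks, species = NULL, max_gap = 10L,
                                  max_width = 10L) {
  if (inherits(blocks, "qmaf_block")) blocks <- list(blocks)
  regions <- list()
  for (bi in seq_along(blocks)) {
    block <- blocks[[bi]]
    sp_block <- species_of(block$src)
    sp <- if (is.null(species)) sp_block else species
    ncols <- nchar(block$text[1])
    P <- matrix(NA_integer_, length(sp), ncols, dimnames = list(sp, NULL))
    for (s in seq_along(sp)) {
      r <- which(sp_block == sp[s])
      if (length(r) == 0) next
      ch <- block_chars(block, r[1])
      row <- as.integer(ch != "-")
      runs <- rle(row)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      for (k in which(runs$values == 0L & runs$lengths > max_gap))
        row[starts[k]:ends[k]] <- NA_integer_
      P[s, ] <- row
    }
    has_gap <- apply(P, 2, function(col) any(col == 0L, na.rm = TRUE))
    r <- rle(has_gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cols <- starts[k]:ends[k]
      reg <- compress_columns(list(block = bi, cols = cols, species = sp,
                                   mat = P[, cols, drop = FALSE]))
      reg$skipped <- reg$n > max_width
      regions[[length(regions) + 1L]] <- structure(reg, class = "indel_region")
    }
  }
  regions
}

#' Compress identical adjacent columns of an indel region
#'
#' Because every indel event costs 1 regardless of length, runs of
#' identical columns (identical across all species, missing entries
#' included) are interchangeable; each run is replaced by one
#' representative column with a recorded multiplicity.
#'
#' @param region a (possibly uncompressed) \code{indel_region} with
#'   elements \code{mat} and \code{cols}.
#' @return the region with \code{comp} (species x n matrix),
#'   \code{mult} (multiplicities), \code{map} (list: compressed column
#'   -> original column indices) and \code{n} filled in.
#' @export
compress_columns <- function(region) {
  m <- region$mat
  nc <- ncol(m)
  key <- apply(m, 2, function(col) paste(ifelse(is.na(col), "?", col),
                                         collapse = ""))
  grp <- cumsum(c(TRUE, key[-1] != key[-nc]))
  reps <- which(!duplicated(grp))
  region$comp <- m[, reps, drop = FALSE]
  region$mult <- as.integer(table(grp))
  region$map <- split(region$cols, grp)
  names(region$map) <- NULL
  region$n <- length(reps)
  region
}

.cost_cache <- new.env(parent = emptyenv())

#' Indel-event cost matrix over presence/absence states
#'
#' A state is a bit vector over the n compressed columns of an indel
#' region (bit k set = base present in column k), encoded as the
#' integer 0..2^n-1 with column 1 as the least significant bit.
#' \code{W[i, j]} is the minimum number of indel events transforming
#' state i into state j.  One event inserts or deletes a run of bases
#' contiguous in sequence coordinates: the flipped set must be
#' consecutive among the 1-columns of the larger state (so deleting
#' two bases separated only by ancestral gap columns is a single
#' event: 101 -> 010 costs 2, not 3).  Costs are shortest path lengths
#' by breadth-first search; \code{method = "columns"} gives the naive
#' per-column (Hamming) alternative for comparison.
#'
#' @param n compressed width, 1..10.
#' @param method "events" (default) or "columns".
#' @return a 2^n x 2^n integer matrix of class \code{cost_matrix}.
#' @export
event_cost_matrix <- function(n, method = c("events", "columns")) {
  method <- match.arg(method)
  if (n < 1 || n > 10) stop("width n must be in 1..10")
  S <- 2L^n
  if (method == "columns") {
    W <- matrix(0L, S, S)
    for (i in 0:(S - 1)) for (j in 0:(S - 1))
      W[i + 1, j + 1] <- sum(bitwAnd(bitwXor(i, j), 2L^(0:(n - 1))) > 0)
    return(structure(W, class = c("cost_matrix", "matrix")))
  }
  key <- paste0("n", n)
  if (!is.null(.cost_cache[[key]])) return(.cost_cache[[key]])
  # adjacency: from each state, delete any run contiguous among its ones
  adj <- vector("list", S)
  for (t in 0:(S - 1)) {
    ones <- which(bitwAnd(t, 2L^(0:(n - 1))) > 0)
    nb <- integer(0)
    if (length(ones)) for (a in seq_along(ones)) for (b in a:length(ones)) {
      rm_bits <- sum(2L^(ones[a:b] - 1L))
      nb <- c(nb, t - rm_bits)
    }
    adj[[t + 1]] <- nb
  }
  # symmetrize (insertion = reverse deletion)
  full <- vector("list", S)
  for (t in seq_len(S)) full[[t]] <- adj[[t]]
  for (t in seq_len(S)) for (u in adj[[t]]) full[[u + 1]] <- c(full[[u + 1]], t - 1L)
  W <- matrix(NA_integer_, S, S)
  for (s0 in 0:(S - 1)) {
    dist <- rep(NA_integer_, S)
    dist[s0 + 1] <- 0L
    frontier <- s0
    while (length(frontier)) {
      nxt <- integer(0)
      for (t in frontier) for (u in full[[t + 1]]) if (is.na(dist[u + 1])) {
        dist[u + 1] <- dist[t + 1] + 1L
        nxt <- c(nxt, u)
      }
      frontier <- unique(nxt)
    }
    W[s0 + 1, ] <- dist
  }
  W <- structure(W, class = c("cost_matrix", "matrix"))
  .cost_cache[[key]] <- W
  W
}

# leaf state integer from a compressed matrix row; NA if any entry missing
leaf_state <- function(bits) {
  if (anyNA(bits)) return(NA_integer_)
  sum(as.integer(bits) * 2L^(seq_along(bits) - 1L))
}

#' Parsimonious indel states at every tree node
#'
#' Exact min-sum (Sankoff) message passing over the phylogeny with the
#' event cost matrix W: an upward pass computes subtree costs per
#' state, a downward pass adds the cost of the rest of the tree, and
#' the returned per-node sets contain exactly the states attained by
#' some globally minimum-cost labeling.  Leaves with missing entries
#' ('?') are unconstrained (zero cost for every state).
#'
#' @param region a compressed \code{indel_region} (not skipped).
#' @param tree an \code{ape::phylo}; region species must be tip labels
#'   (tree tips absent from the region are unconstrained).
#' @param W optional precomputed \code{event_cost_matrix(region$n)}.
#' @return list with \code{states} (per tree node, integer vector of
#'   optimal state encodings; nodes indexed as in ape), \code{cost}
#'   (the minimum total event count), \code{n}.
#' @export
parsimony_states <- function(region, tree, W = NULL) {
  if (isTRUE(region$skipped))
    stop("region skipped (compressed width ", region$n, " > limit)")
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  absent <- setdiff(region$species[!apply(is.na(region$mat), 1, all)],
                    tree$tip.label)
  if (length(absent))
    stop("species not on tree: ", paste(absent, collapse = ", "))
  n <- region$n
  if (is.null(W)) W <- event_cost_matrix(n)
  S <- 2L^n
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cost <- matrix(0, nnode, S)  # subtree cost per node per state
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    st <- if (sp %in% region$species) leaf_state(region$comp[sp, ]) else NA
    if (!is.na(st)) {
      cost[i, ] <- Inf
      cost[i, st + 1L] <- 0
    }
  }
  tr <- stats::reorder(tree, "postorder")
  msg <- vector("list", nnode)  # msg[[child]] = message child -> parent
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    m <- vapply(seq_len(S), function(s) min(W[s, ] + cost[child, ]), 0)
    msg[[child]] <- m
    cost[parent, ] <- cost[parent, ] + m
  }
  root <- ntip + 1L
  total <- min(cost[root, ])
  # downward pass: out[v, s] = best cost of everything outside subtree(v)
  out <- matrix(0, nnode, S)
  preorder <- rev(seq_len(nrow(tr$edge)))
  for (e in preorder) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    ctx <- out[parent, ] + cost[parent, ] - msg[[child]]
    out[child, ] <- vapply(seq_len(S), function(t) min(ctx + W[, t]), 0)
  }
  states <- lapply(seq_len(nnode), function(v) {
    tot <- cost[v, ] + out[v, ]
    which(tot <= total + 1e-9) - 1L
  })
  list(states = states, cost = total, n = n)
}

#' Call lineage-specific indels in a region
#'
#' Column-by-column comparison of each leaf with its parent's
#' parsimony-optimal states: a leaf showing a base (1) in a compressed
#' column where every optimal parent state has a gap (0) is a
#' lineage-specific insertion; a leaf gap where every optimal parent
#' state has a base is a lineage-specific deletion.  Ambiguous parent
#' columns (both 0 and 1 attainable) yield no call, and missing ('?')
#' leaves are never called.  Calls are expanded to original columns
#' and adjacent same-type columns are merged into single events.
#'
#' @param region a compressed \code{indel_region}.
#' @param ps result of \code{\link{parsimony_states}}.
#' @param tree the tree used (rooted as in \code{parsimony_states}).
#' @param blocks the \code{qmaf} blocks (for quality annotation); may
#'   be NULL to skip quality.
#' @param flank flanking bases for indel quality (default 5).
#' @return data.frame of calls: species, block, start_col, end_col,
#'   type, length, bin, eligible.
#' @export
call_ls_indels <- function(region, ps, tree, blocks = NULL, flank = 5L) {
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  calls <- list()
  for (sp in intersect(region$species, tree$tip.label)) {
    bits <- region$comp[sp, ]
    if (anyNA(bits)) next
    tipid <- match(sp, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == tipid, 1]
    pstates <- ps$states[[parent]]
    type_at <- character(region$n)
    for (k in seq_len(region$n)) {
      pbits <- bitwAnd(pstates, 2L^(k - 1L)) > 0
      if (bits[k] == 1L && all(!pbits)) type_at[k] <- "insertion"
      else if (bits[k] == 0L && all(pbits)) type_at[k] <- "deletion"
    }
    # expand to original columns and merge adjacent same-type columns
    orig_type <- character(length(region$cols))
    for (k in seq_len(region$n))
      orig_type[match(region$map[[k]], region$cols)] <- type_at[k]
    r <- rle(orig_type)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values != "")) {
      cols <- region$cols[starts[k]:ends[k]]
      ty <- r$values[k]
      blk <- if (is.null(blocks)) NULL else blocks[[region$block]]
      q <- if (is.null(blk) || is.na(blk$qual[block_row(blk, sp)]))
        NA_integer_ else indel_quality(blk, sp, cols, ty, flank)
      calls[[length(calls) + 1L]] <- data.frame(
        species = sp, block = region$block, start_col = min(cols),
        end_col = max(cols), type = ty, length = length(cols), bin = q,
        eligible = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(calls)) do.call(rbind, calls) else
    data.frame(species = character(), block = integer(),
               start_col = integer(), end_col = integer(),
               type = character(), length = integer(), bin = integer(),
               eligible = logical())
}

#' Detect lineage-specific indels across all blocks
#'
#' Convenience wrapper: extracts indel regions, runs the parsimony
#' machinery per region, and concatenates lineage-specific calls.
#'
#' @inheritParams extract_indel_regions
#' @param tree an \code{ape::phylo} covering the species.
#' @param flank flanking bases for indel quality.
#' @return data.frame of calls as in \code{\link{call_ls_indels}}.
#' @export
find_ls_indels <- function(blocks, tree, species = NULL, max_gap = 10L,
                           max_width = 10L, flank = 5L) {
  if (inherits(blocks, "qmaf_block")) blocks <- list(blocks)
  regions <- extract_indel_regions(blocks, species, max_gap, max_width)
  out <- list()
  for (reg in regions) {
    if (isTRUE(reg$skipped)) next
    ps <- parsimony_states(reg, tree)
    cl <- call_ls_indels(reg, ps, tree, blocks, flank)
    if (nrow(cl)) out[[length(out) + 1L]] <- cl
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(species = character(), block = integer(),
               start_col = integer(), end_col = integer(),
               type = character(), length = integer(), bin = integer(),
               eligible = logical())
}

#' Impute (revert) low-quality lineage-specific indels
#'
#' Lineage-specific calls whose quality-bin representative is below
#' the phred threshold \code{T} are reverted to the inferred ancestral
#' state: an insertion's bases are excised (replaced by gaps; columns
#' left all-gap are dropped), and a deletion's gap is filled with 'N'
#' characters carrying quality bin 0 (so they are ignored by
#' downstream tabulation).  Row size fields and the start coordinates
#' of later blocks on the same source are updated; the alignment is
#' not re-computed.
#'
#' @param blocks a \code{qmaf} object.
#' @param calls data.frame of calls (as from
#'   \code{\link{find_ls_indels}}).
#' @param T phred threshold (default 25): calls with 5 * bin < T are
#'   corrected.
#' @return list with \code{blocks} (edited \code{qmaf}) and \code{log}
#'   (BED-like edit log: src, start, end in original source
#'   coordinates, species, type, length, bin, action).
#' @export
impute <- function(blocks, calls, T = 25) {
  if (inherits(blocks, "qmaf_block")) blocks <- structure(list(blocks), class = "qmaf")
  log <- list()
  if (nrow(calls)) {
    calls <- calls[order(calls$block, calls$start_col), , drop = FALSE]
    touched <- list()  # per block x species: edited columns (first-wins)
    shift <- list()    # per src: list(block, pos, delta)
    for (ci in seq_len(nrow(calls))) {
      cl <- calls[ci, ]
      low <- !is.na(cl$bin) && bin_representative(cl$bin) < T
      b <- blocks[[cl$block]]
      ri <- block_row(b, cl$species)
      cols <- cl$start_col:cl$end_col
      src <- b$src[ri]
      ch <- block_chars(b, ri)
      pos0 <- b$start[ri] + sum(ch[seq_len(cl$start_col - 1L)] != "-")
      key <- paste(cl$block, cl$species)
      if (!is.null(touched[[key]]) && any(cols %in% touched[[key]])) {
        warning("overlapping call skipped (first wins): block ", cl$block,
                " cols ", cl$start_col, "-", cl$end_col)
        next
      }
      action <- if (!low) "kept" else if (cl$type == "insertion")
        "excised" else "filled"
      log[[length(log) + 1L]] <- data.frame(
        src = src, start = pos0,
        end = pos0 + if (cl$type == "insertion") cl$length else 0L,
        species = cl$species, type = cl$type, length = cl$length,
        bin = cl$bin, action = action, stringsAsFactors = FALSE)
      if (!low) next
      touched[[key]] <- c(touched[[key]], cols)
      qch <- strsplit(b$qual[ri], "")[[1]]
      if (cl$type == "insertion") {
        ch[cols] <- "-"
        if (!is.na(b$qual[ri])) { qch[cols] <- "-"; b$qual[ri] <- paste(qch, collapse = "") }
        b$size[ri] <- b$size[ri] - cl$length
        delta <- -cl$length
      } else {
        ch[cols] <- "N"
        if (!is.na(b$qual[ri])) { qch[cols] <- "0"; b$qual[ri] <- paste(qch, collapse = "") }
        b$size[ri] <- b$size[ri] + cl$length
        delta <- cl$length
      }
      b$text[ri] <- paste(ch, collapse = "")
      blocks[[cl$block]] <- b
      shift[[src]] <- c(shift[[src]], list(list(block = cl$block, delta = delta)))
    }
    # propagate coordinate shifts to later blocks on the same source
    for (src in names(shift)) for (ev in shift[[src]]) {
      if (ev$block < length(blocks)) for (bj in (ev$block + 1L):length(blocks)) {
        b <- blocks[[bj]]
        hit <- b$src == src
        b$start[hit] <- b$start[hit] + ev$delta
        blocks[[bj]] <- b
      }
    }
  }
  # drop columns left all-gap, recompacting texts and quality strings
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    chm <- do.call(rbind, lapply(seq_along(b$src), function(r) block_chars(b, r)))
    allgap <- colSums(chm != "-") == 0
    if (any(allgap)) {
      keep <- !allgap
      for (r in seq_along(b$src)) {
        b$text[r] <- paste(chm[r, keep], collapse = "")
        if (!is.na(b$qual[r])) {
          qch <- strsplit(b$qual[r], "")[[1]]
          b$qual[r] <- paste(qch[keep], collapse = "")
        }
      }
      blocks[[bi]] <- b
    }
  }
  list(blocks = structure(blocks, class = "qmaf"),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(src = character(), start = integer(), end = integer(),
                    species = character(), type = character(),
                    length = integer(), bin = integer(), action = character()))
}

#' Iterate imputation to a fixed point
#'
#' Correcting one species can change the indel-region decomposition
#' and hence the parsimony verdicts for other columns, occasionally
#' revealing further low-quality lineage-specific calls.  This
#' wrapper alternates detection (\code{\link{find_ls_indels}}) and
#' correction (\code{\link{impute}}) until no correctable call
#' remains (usually 1-2 rounds).
#'
#' @param blocks a \code{qmaf} object.
#' @param tree an \code{ape::phylo}.
#' @param species draft species eligible for correction.
#' @param T phred threshold (default 25).
#' @param max_iter safety bound on rounds (default 10).
#' @return list with \code{blocks}, concatenated \code{log} (with a
#'   \code{round} column), and \code{rounds}.
#' @export
impute_until_stable <- function(blocks, tree, species, T = 25,
                                max_iter = 10L) {
  logs <- list()
  for (round in seq_len(max_iter)) {
    calls <- find_ls_indels(blocks, tree)
    calls <- calls[calls$species %in% species, , drop = FALSE]
    low <- !is.na(calls$bin) & bin_representative(ifelse(is.na(calls$bin), 9L,
                                                         calls$bin)) < T
    if (!any(low)) break
    res <- impute(blocks, calls, T)
    blocks <- res$blocks
    if (nrow(res$log)) {
      res$log$round <- round
      logs[[round]] <- res$log
    }
  }
  list(blocks = blocks,
       log = if (length(logs)) do.call(rbind, logs) else NULL,
       rounds = length(logs))
}
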