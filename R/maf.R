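#' Alignment blocks with per-base quality
#'
#' A \code{qmaf_block} is one MAF alignment block: per-row gapped text
#' with MAF coordinates (0-based start, ungapped size, strand, source
#' length), optionally augmented with a per-base quality string in the
#' reduced representation ('0'-'9' binned phred characters, 'F' for
#' finished sequence, '-' at gaps).  A \code{qmaf} object is a list of
#' such blocks.
#'
#' @param src character vector of row source names ("species.chrom" or
#'   plain species names).
#' @param start integer vector, 0-based offsets on the source sequence
#'   (MAF semantics; on '-' strand, offset on the reverse-complemented
#'   source).
#' @param size integer vector of ungapped row lengths.
#' @param strand character vector, "+" or "-".
#' @param src_size integer vector of source sequence lengths.
#' @param text character vector of gapped row texts over A,C,G,T,N,-.
#' @param qual optional character vector of quality strings (NA for
#'   rows without qualities), aligned character-for-character with
#'   \code{text}.
#' @param score optional block score.
#' @return an object of class \code{qmaf_block}.
#' @export
qmaf_block <- function(src, start, size, strand, src_size, text,
                       qual = NULL, score = NA_real_) {
  n <- length(src)
  if (is.null(qual)) qual <- rep(NA_character_, n)
  text <- toupper(text)
  bad <- grepl("[^ACGTN-]", text)
  if (any(bad)) {
    warning("non-ACGTN characters in row(s) ",
            paste(which(bad), collapse = ","), " mapped to N")
    text[bad] <- gsub("[^ACGTN-]", "N", text[bad])
  }
  b <- structure(list(src = as.character(src), start = as.integer(start),
                      size = as.integer(size), strand = as.character(strand),
                      src_size = as.integer(src_size), text = text,
                      qual = as.character(qual), score = score),
                 class = "qmaf_block")
  validate_qmaf_block(b)
  b
}

validate_qmaf_block <- function(b) {
  widths <- nchar(b$text)
  if (length(unique(widths)) > 1)
    stop("row texts differ in length: ", paste(widths, collapse = ","))
  ungapped <- nchar(gsub("-", "", b$text))
  if (any(ungapped != b$size))
    stop("row size does not match non-gap character count for row(s) ",
         paste(which(ungapped != b$size), collapse = ","))
  has_q <- !is.na(b$qual)
  if (any(nchar(b$qual[has_q]) != widths[has_q]))
    stop("quality string length does not match text length")
  for (i in which(has_q)) {
    tgap <- strsplit(b$text[i], "")[[1]] == "-"
    qgap <- strsplit(b$qual[i], "")[[1]] == "-"
    if (!identical(tgap, qgap))
      stop("quality '-' characters do not align with gaps in row ", i)
  }
  invisible(b)
}

#' @export
print.qmaf_block <- function(x, ...) {
  cat("qmaf_block:", length(x$src), "rows,", nchar(x$text[1]), "columns\n")
  for (i in seq_along(x$src)) {
    cat(sprintf(" s %-12s %8d %6d %s %9d %s\n", x$src[i], x$start[i],
                x$size[i], x$strand[i], x$src_size[i],
                substr(x$text[i], 1, 50)))
  }
  invisible(x)
}

# species name = src up to the first '.'
species_of <- function(src) sub("\\..*$", "", src)

# index of the row for `species` (matched against species prefix or full src)
block_row <- function(block, species) {
  i <- which(species_of(block$src) == species | block$src == species)
  if (length(i) == 0) stop("species '", species, "' not present in block")
  i[1]
}

# character matrix helpers
block_chars <- function(block, row) strsplit(block$text[row], "")[[1]]
block_bins <- function(block, row) {
  if (is.na(block$qual[row])) return(NULL)
  decode_qual_chars(strsplit(block$qual[row], "")[[1]])
}

#' Read a quality-augmented MAF file
#'
#' Parses MAF alignment blocks; 'q' lines (UCSC quality dialect, one
#' character per text column: '0'-'9', 'F' for finished, '-' at gaps)
#' following an 's' line attach binned qualities to that row.  Blocks
#' missing 'q' lines are valid and carry no qualities.
#'
#' @param path path to a MAF file.
#' @return a \code{qmaf} object (list of \code{qmaf_block}).
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || length(cur$src) == 0) return()
    b <- tryCatch(
      qmaf_block(cur$src, cur$start, cur$size, cur$strand, cur$src_size,
                 cur$text, cur$qual, cur$score),
      error = function(e) stop("malformed block ending near line ",
                               cur$line, ": ", conditionMessage(e)))
    blocks[[length(blocks) + 1L]] <<- b
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^#", line) || grepl("^##", line)) next
    if (grepl("^a", line)) {
      flush()
      sc <- regmatches(line, regexec("score=([-0-9.eE+]+)", line))[[1]]
      cur <- list(src = character(), start = integer(), size = integer(),
                  strand = character(), src_size = integer(),
                  text = character(), qual = character(),
                  score = if (length(sc) == 2) as.numeric(sc[2]) else NA_real_,
                  line = ln)
    } else if (grepl("^s[[:space:]]", line)) {
      if (is.null(cur)) stop("s line outside block at line ", ln)
      f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      if (length(f) != 7) stop("malformed s line at line ", ln)
      cur$src <- c(cur$src, f[2])
      cur$start <- c(cur$start, as.integer(f[3]))
      cur$size <- c(cur$size, as.integer(f[4]))
      cur$strand <- c(cur$strand, f[5])
      cur$src_size <- c(cur$src_size, as.integer(f[6]))
      cur$text <- c(cur$text, f[7])
      cur$qual <- c(cur$qual, NA_character_)
      cur$line <- ln
    } else if (grepl("^q[[:space:]]", line)) {
      if (is.null(cur) || length(cur$src) == 0)
        stop("q line without preceding s line at line ", ln)
      f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      if (length(f) != 3) stop("malformed q line at line ", ln)
      i <- length(cur$src)
      if (f[2] != cur$src[i])
        stop("q line src '", f[2], "' does not match preceding s line at line ", ln)
      cur$qual[i] <- f[3]
      cur$line <- ln
    } else if (grepl("^[ei][[:space:]]", line) || !nzchar(trimws(line))) {
      next  # e/i status lines and blanks are ignored
    } else {
      stop("unrecognized line ", ln, ": ", substr(line, 1, 40))
    }
  }
  flush()
  structure(blocks, class = "qmaf")
}

#' Write a quality-augmented MAF file
#'
#' Inverse of \code{\link{read_maf}}: \code{read_maf(write_maf(x, p))}
#' reproduces \code{x} exactly.  Rows without qualities emit no 'q'
#' line.
#'
#' @param x a \code{qmaf} object or single \code{qmaf_block}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_maf <- function(x, path) {
  if (inherits(x, "qmaf_block")) x <- structure(list(x), class = "qmaf")
  out <- c("##maf version=1", "")
  for (bi in seq_along(x)) {
    b <- x[[bi]]
    tryCatch(validate_qmaf_block(b),
             error = function(e) stop("invalid block ", bi, ": ",
                                      conditionMessage(e)))
    out <- c(out, if (is.na(b$score)) "a" else sprintf("a score=%g", b$score))
    w_src <- max(nchar(b$src))
    for (i in seq_along(b$src)) {
      out <- c(out, sprintf("s %-*s %d %d %s %d %s", w_src, b$src[i],
                            b$start[i], b$size[i], b$strand[i],
                            b$src_size[i], b$text[i]))
      if (!is.na(b$qual[i]))
        out <- c(out, sprintf("q %-*s %s", w_src, b$src[i], b$qual[i]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Pairwise column view of a block
#'
#' Walks the alignment columns of one block for a (reference, other)
#' species pair.  Columns gapped in both rows (gaps induced by third
#' species) are skipped.  Source coordinates advance only at non-gap
#' characters.
#'
#' @param block a \code{qmaf_block}.
#' @param ref,other species (or src) names present in the block.
#' @return a data.frame with one row per retained column: \code{col}
#'   (original column index), \code{ref_base}, \code{other_base},
#'   \code{ref_bin}, \code{other_bin} (quality bins, NA if absent or at
#'   gaps), \code{ref_pos}, \code{other_pos} (0-based source
#'   coordinates, NA at gaps).
#' @export
pair_columns <- function(block, ref, other) {
  ri <- block_row(block, ref)
  oi <- block_row(block, other)
  rch <- block_chars(block, ri); och <- block_chars(block, oi)
  rb <- block_bins(block, ri);   ob <- block_bins(block, oi)
  n <- length(rch)
  rpos <- rep(NA_integer_, n); opos <- rep(NA_integer_, n)
  rng <- rch != "-"; ong <- och != "-"
  rpos[rng] <- block$start[ri] + seq_len(sum(rng)) - 1L
  opos[ong] <- block$start[oi] + seq_len(sum(ong)) - 1L
  keep <- rng | ong
  data.frame(col = seq_len(n)[keep],
             ref_base = rch[keep], other_base = och[keep],
             ref_bin = if (is.null(rb)) NA_integer_ else rb[keep],
             other_bin = if (is.null(ob)) NA_integer_ else ob[keep],
             ref_pos = rpos[keep], other_pos = opos[keep],
             stringsAsFactors = FALSE)
}
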