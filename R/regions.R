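#' Read a BED3+ region file
#'
#' Intervals are kept 0-based half-open, exactly as in the file;
#' overlapping intervals are preserved (merge explicitly with
#' \code{\link{merge_regions}}).
#'
#' @param path path to a BED3+ file (tab- or space-separated).
#' @return a data.frame with columns \code{chrom}, \code{start},
#'   \code{end} and, when a 4th column exists, \code{label}; class
#'   \code{region_set}.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(region_set(character(), integer(), integer()))
  f <- strsplit(trimws(lines), "[[:space:]]+")
  ncol <- vapply(f, length, 1L)
  if (any(ncol < 3)) stop("fewer than 3 BED fields at line ",
                          which(ncol < 3)[1])
  start <- suppressWarnings(as.integer(vapply(f, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(f, `[`, "", 3)))
  if (any(is.na(start) | is.na(end)))
    stop("non-integer coordinates at line ", which(is.na(start) | is.na(end))[1])
  if (any(start >= end))
    stop("start >= end at line ", which(start >= end)[1])
  region_set(vapply(f, `[`, "", 1), start, end,
             label = ifelse(ncol >= 4, vapply(f, function(x) x[4], ""), NA))
}

#' Construct a region set
#'
#' @param chrom,start,end interval fields, 0-based half-open.
#' @param label optional labels.
#' @return a \code{region_set} data.frame.
#' @export
region_set <- function(chrom, start, end, label = NA) {
  if (length(start) && any(start >= end)) stop("start >= end")
  label <- rep(as.character(label), length.out = length(chrom))
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), label = label,
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Merge overlapping or adjacent intervals of a region set
#' @param x a \code{region_set}.
#' @return a merged \code{region_set} (labels dropped).
#' @export
merge_regions <- function(x) {
  if (nrow(x) == 0) return(x)
  x <- x[order(x$chrom, x$start, x$end), ]
  out <- x[1, , drop = FALSE]
  for (i in seq_len(nrow(x))[-1]) {
    j <- nrow(out)
    if (x$chrom[i] == out$chrom[j] && x$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], x$end[i])
    } else out <- rbind(out, x[i, ])
  }
  out$label <- NA
  rownames(out) <- NULL
  structure(out, class = c("region_set", "data.frame"))
}

# membership of 0-based positions on `chrom` in the region set
in_regions <- function(regions, chrom, pos) {
  if (is.null(regions)) return(rep(TRUE, length(pos)))
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(r)))
    out <- out | (!is.na(pos) & pos >= r$start[i] & pos < r$end[i])
  out & !is.na(pos)
}
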