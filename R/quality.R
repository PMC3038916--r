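#' Quality-score binning
#'
#' Raw phred scores are carried in alignment files in a reduced
#' representation with a resolution of 5 phred units: bin \code{b}
#' covers raw scores in \code{[5b, 5b+5)}, and all scores >= 45 share
#' the top bin (9).  The representative value of a bin is its lower
#' bound, \code{5 * bin}, so a threshold such as "q < 20" is exactly
#' "bin <= 3".
#'
#' @param q_raw integer vector of raw phred quality scores (>= 0).
#' @return integer vector of bins in 0..9.
#' @examples
#' bin_quality(c(0, 23, 47))  # 0, 4, 9
#' @export
bin_quality <- function(q_raw) {
  if (any(is.na(q_raw)) || any(q_raw < 0))
    stop("quality scores must be non-negative and non-missing")
  pmin(q_raw %/% 5L, 9L)
}

#' Representative phred value of a quality bin
#'
#' @param bin integer vector of bins in 0..9.
#' @return integer vector of representative phred values (5 * bin).
#' @export
bin_representative <- function(bin) {
  stopifnot(all(bin >= 0L & bin <= 9L))
  5L * as.integer(bin)
}

# Decode one quality-line character to a bin.  Dialect: '0'-'9' are bins,
# 'F' (finished sequence) is treated as bin 9, '-' aligns with a gap (NA).
decode_qual_chars <- function(chars) {
  out <- rep(NA_integer_, length(chars))
  digit <- chars %in% as.character(0:9)
  out[digit] <- as.integer(chars[digit])
  out[chars == "F"] <- 9L
  bad <- !digit & !chars %in% c("F", "-")
  if (any(bad))
    stop("invalid quality character(s): ", paste(unique(chars[bad]), collapse = " "))
  out
}

encode_qual_bins <- function(bins) {
  out <- rep("-", length(bins))
  out[!is.na(bins)] <- as.character(bins[!is.na(bins)])
  out
}

# phred <-> error probability
phred_to_prob <- function(q) 10^(-q / 10)
prob_to_phred <- function(p) -10 * log10(p)

#' Per-1x error-rate factor implied by a phred-per-coverage slope
#'
#' A quality gain of \code{slope} phred units per additional 1x of
#' coverage multiplies the error rate by \code{10^(-slope/10)} per 1x.
#'
#' @param slope phred units gained per additional 1x of coverage.
#' @return the multiplicative factor on the error rate per added 1x.
#' @examples
#' phred_slope_error_factor(3.62)  # ~0.43: error rate roughly halved
#' @export
phred_slope_error_factor <- function(slope) 10^(-slope / 10)
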