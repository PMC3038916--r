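#' Quality distributions
#'
#' A quality distribution is a probability mass function over integer
#' phred values q >= 0, stored as a numeric vector whose element i
#' carries the mass at q = i - 1.  Raw (unbinned) resolution is used
#' throughout the coverage model; binning is an I/O concern.
#'
#' @param q integer phred values.
#' @param p masses (recycled against q); normalized to sum to 1.
#' @return a \code{quality_dist} numeric vector.
#' @export
quality_dist <- function(q, p) {
  stopifnot(length(q) == length(p), all(q >= 0), all(p >= 0), sum(p) > 0)
  out <- numeric(max(q) + 1L)
  for (i in seq_along(q)) out[q[i] + 1L] <- out[q[i] + 1L] + p[i]
  structure(out / sum(out), class = "quality_dist")
}

qd_support <- function(d) seq_along(d) - 1L
qd_mean <- function(d) sum(qd_support(d) * d)
# expected error probability under a quality pmf
qd_error <- function(d) sum(d * phred_to_prob(qd_support(d)))

#' Estimate the single-read quality distribution p1
#'
#' Empirical pmf of raw phred scores over all bases of a set of reads.
#' Reads should already be trimmed to their assembled portions.
#'
#' @param x a FASTQ file path (read via Biostrings) or an integer
#'   vector of raw phred scores.
#' @return a \code{quality_dist}.
#' @export
estimate_p1 <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required to read FASTQ")
    reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(x))
    x <- unlist(as(Biostrings::quality(reads), "IntegerList"), use.names = FALSE)
  }
  x <- as.integer(x)
  if (length(x) == 0) stop("no quality values")
  tb <- table(x)
  quality_dist(as.integer(names(tb)), as.numeric(tb))
}

#' x-wise convolution of a quality distribution
#'
#' Distribution of the sum of \code{x} independent draws from
#' \code{p1}: the quality of a base covered by \code{x} reads is
#' modelled as the sum of the per-read scores (as assemblers that add
#' log-scale qualities across independent reads assume).
#'
#' @param p1 a \code{quality_dist}.
#' @param x read depth (integer >= 1).
#' @return a \code{quality_dist} for depth x.
#' @export
convolve_quality <- function(p1, x) {
  if (x < 1) stop("depth must be >= 1")
  out <- as.numeric(p1)
  v <- as.numeric(p1)
  if (x > 1) for (k in seq_len(x - 1)) {
    res <- numeric(length(out) + length(v) - 1L)
    for (i in seq_along(v)) if (v[i] > 0)
      res[i:(i + length(out) - 1L)] <- res[i:(i + length(out) - 1L)] + v[i] * out
    out <- res
  }
  structure(out, class = "quality_dist")
}

#' Coverage-error model
#'
#' Theoretical model linking average read coverage to assembly error:
#' read depth is Poisson(\code{lambda}) truncated to x >= 1 (an
#' assembly has no zero-coverage base), per-read quality scores are
#' i.i.d. draws from \code{p1}, and an assembled base's quality is the
#' sum of its reads' scores.  The assembly-wide quality distribution is
#' the truncated-Poisson mixture of the x-wise convolutions of p1.
#'
#' @param p1 single-read \code{quality_dist}.
#' @param lambda expected coverage (> 0).
#' @param x_max depth truncation; default max(0.999 Poisson quantile, 10).
#' @return object of class \code{coverage_model} with elements
#'   \code{p1}, \code{lambda}, \code{x_max}, \code{weights} (P(depth =
#'   x | depth >= 1), renormalized over 1..x_max), \code{px} (list of
#'   depth-wise distributions), \code{assembly_dist}.
#' @export
coverage_model <- function(p1, lambda, x_max = NULL) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (is.null(x_max)) x_max <- max(stats::qpois(0.999, lambda), 10L)
  w <- stats::dpois(seq_len(x_max), lambda)
  w <- w / sum(w)
  px <- vector("list", x_max)
  px[[1]] <- convolve_quality(p1, 1)
  if (x_max > 1) for (x in 2:x_max) {
    # recursive: p_x = p_{x-1} * p_1
    a <- as.numeric(px[[x - 1]]); b <- as.numeric(p1)
    res <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(b)) if (b[i] > 0)
      res[i:(i + length(a) - 1L)] <- res[i:(i + length(a) - 1L)] + b[i] * a
    px[[x]] <- structure(res, class = "quality_dist")
  }
  maxlen <- length(px[[x_max]])
  mix <- numeric(maxlen)
  for (x in seq_len(x_max)) {
    v <- as.numeric(px[[x]])
    mix[seq_along(v)] <- mix[seq_along(v)] + w[x] * v
  }
  structure(list(p1 = p1, lambda = lambda, x_max = x_max, weights = w,
                 px = px, assembly_dist = structure(mix, class = "quality_dist")),
            class = "coverage_model")
}

#' Assembly-wide quality distribution
#' @param model a \code{coverage_model}.
#' @return the mixture \code{quality_dist} over assembled bases.
#' @export
assembly_quality_distribution <- function(model) {
  stopifnot(inherits(model, "coverage_model"))
  model$assembly_dist
}

#' Expected assembly quality in phred units
#'
#' Q* = -10 log10 of the expected per-base error probability, i.e. the
#' generalized f-mean of the basewise scores with f(q) = 10^(-q/10) —
#' a mean dominated by the small number of low-quality bases.
#'
#' @param model a \code{coverage_model}.
#' @return Q* in phred units.
#' @export
expected_quality <- function(model) {
  prob_to_phred(qd_error(model$assembly_dist))
}

#' Error decomposition by read depth
#'
#' Splits the expected assembly error rate by read depth:
#' contribution(x) = P(depth = x | >= 1) * E[10^(-q/10) | depth = x].
#' F1 is the fraction contributed by single-coverage bases; F1_lowq
#' restricts the depth-1 numerator to reads with q below
#' \code{lowq_cut}.
#'
#' @param model a \code{coverage_model}.
#' @param lowq_cut phred cutoff defining "low quality" (default 20).
#' @return list with \code{per_depth} (data.frame: depth, weight,
#'   contribution), \code{F1}, \code{F1_lowq} and the total expected
#'   error rate \code{err}.
#' @export
error_fraction_by_depth <- function(model, lowq_cut = 20) {
  contrib <- vapply(seq_len(model$x_max), function(x)
    model$weights[x] * qd_error(model$px[[x]]), 0)
  total <- sum(contrib)
  p1v <- as.numeric(model$p1)
  qs <- qd_support(model$p1)
  low1 <- model$weights[1] * sum(p1v[qs < lowq_cut] *
                                   phred_to_prob(qs[qs < lowq_cut]))
  list(per_depth = data.frame(depth = seq_len(model$x_max),
                              weight = model$weights,
                              contribution = contrib),
       F1 = contrib[1] / total, F1_lowq = low1 / total, err = total)
}

#' Quality and error decomposition across a coverage grid
#'
#' @param p1 single-read \code{quality_dist}.
#' @param lambdas grid of average coverages (> 0, non-empty).
#' @param lowq_cut phred cutoff for F1_lowq (default 20).
#' @return data.frame with columns lambda, Qstar, F1, F1_lowq, and
#'   slope (phred gained per unit lambda between successive grid
#'   points; NA in the first row).
#' @export
quality_curve <- function(p1, lambdas, lowq_cut = 20) {
  if (length(lambdas) == 0) stop("empty lambda grid")
  lambdas <- sort(lambdas)
  rows <- lapply(lambdas, function(l) {
    m <- coverage_model(p1, l)
    fr <- error_fraction_by_depth(m, lowq_cut)
    data.frame(lambda = l, Qstar = expected_quality(m), F1 = fr$F1,
               F1_lowq = fr$F1_lowq)
  })
  out <- do.call(rbind, rows)
  out$slope <- c(NA, diff(out$Qstar) / diff(out$lambda))
  out
}
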