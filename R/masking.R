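#' Mask low-quality bases in one species of a block
#'
#' Replaces every base of \code{species} whose quality-bin
#' representative (5 * bin) is below the phred threshold \code{T} with
#' 'N'.  Alignment geometry, coordinates, other rows and the quality
#' string itself are untouched (so masking is reversible given the
#' decision log).
#'
#' @param block a \code{qmaf_block}.
#' @param species species whose row is masked; must carry qualities.
#' @param T phred threshold (default 20; bases in bins 0-3 are masked).
#' @return list with \code{block} (edited) and \code{decisions} (one
#'   row per base of the species: column, original base, bin, masked).
#' @export
mask_by_threshold <- function(block, species, T = 20) {
  i <- block_row(block, species)
  bins <- block_bins(block, i)
  if (is.null(bins)) stop("species row carries no qualities")
  ch <- block_chars(block, i)
  at_base <- ch != "-"
  mask <- at_base & bin_representative(ifelse(is.na(bins), 9L, bins)) < T
  decisions <- data.frame(species = species, column = which(at_base),
                          base = ch[at_base], bin = bins[at_base],
                          masked = mask[at_base], stringsAsFactors = FALSE)
  ch[mask] <- "N"
  block$text[i] <- paste(ch, collapse = "")
  list(block = block, decisions = decisions)
}

#' Per-base covariates for regression masking
#'
#' For every non-gap base of \code{species} in the block, computes the
#' covariates used by the regression classifier: the representative
#' quality score, the phylogenetic error log-odds (with an indicator
#' column \code{lo_missing} set, and the value imputed to 0, where no
#' aligned partner exists), and optionally the local G+C fraction and
#' the minimum and mean representative quality in a window of
#' \code{window} flanking bases (\code{window/2} on each side).
#'
#' @param block a \code{qmaf_block}.
#' @param species the draft species.
#' @param model a \code{phylo_model} (needed for "logodds").
#' @param M an \code{error_matrix} (needed for "logodds").
#' @param covariates subset of c("qual", "logodds", "gc", "minq",
#'   "meanq"); the default pair is what performs best.
#' @param window flanking window size in bases (default 10).
#' @return data.frame with one row per base: \code{column}, \code{base},
#'   \code{bin} and the requested covariate columns.
#' @export
extract_features <- function(block, species, model = NULL, M = NULL,
                             covariates = c("qual", "logodds"),
                             window = 10L) {
  i <- block_row(block, species)
  bins <- block_bins(block, i)
  if (is.null(bins)) stop("species row carries no qualities")
  ch <- block_chars(block, i)
  idx <- which(ch != "-")
  out <- data.frame(column = idx, base = ch[idx], bin = bins[idx],
                    stringsAsFactors = FALSE)
  if ("qual" %in% covariates) out$qual <- bin_representative(out$bin)
  if ("logodds" %in% covariates) {
    if (is.null(model) || is.null(M))
      stop("phylo model and error matrix required for logodds covariate")
    sp_all <- species_of(block$src)
    texts <- lapply(seq_along(block$src), function(r) block_chars(block, r))
    lo <- numeric(length(idx)); miss <- logical(length(idx))
    on_tree <- sp_all %in% model$tree$tip.label
    for (k in seq_along(idx)) {
      col <- vapply(texts[on_tree], `[`, "", idx[k])
      names(col) <- sp_all[on_tree]
      if (!species %in% names(col) || !col[[species]] %in% BASES) {
        miss[k] <- TRUE; next
      }
      v <- error_logodds(col, species, model, M)
      if (is.na(v)) miss[k] <- TRUE else lo[k] <- v
    }
    out$logodds <- lo
    out$lo_missing <- as.numeric(miss)
  }
  if (any(c("gc", "minq", "meanq") %in% covariates)) {
    half <- max(1L, window %/% 2L)
    seq_ch <- ch[idx]; seq_q <- bin_representative(ifelse(is.na(bins[idx]), 9L, bins[idx]))
    n <- length(idx)
    win <- function(k) {
      lo <- max(1L, k - half); hi <- min(n, k + half)
      setdiff(lo:hi, k)
    }
    if ("gc" %in% covariates)
      out$gc <- vapply(seq_len(n), function(k) {
        w <- c(win(k), k)  # GC content includes the base itself
        mean(seq_ch[w] %in% c("G", "C"))
      }, 0)
    if ("minq" %in% covariates)
      out$minq <- vapply(seq_len(n), function(k) min(seq_q[win(k)]), 0)
    if ("meanq" %in% covariates)
      out$meanq <- vapply(seq_len(n), function(k) mean(seq_q[win(k)]), 0)
  }
  out
}

#' Train the logistic masking classifier
#'
#' Maximum-likelihood logistic regression of the error indicator on
#' the covariates, fit with iteratively reweighted least squares.
#' Labels may be fractional (polymorphism-adjusted expected error
#' indicators): a row with weight w in (0,1) enters the likelihood as
#' an error with weight w and a non-error with weight 1-w.  The fit is
#' deterministic given the input order.
#'
#' @param features data.frame of covariate columns plus the label.
#' @param covariates character vector of covariate column names.
#' @param label name of the label column (values in [0, 1]).
#' @return object of class \code{mask_model}: \code{coef} (intercept
#'   first), \code{covariates}, \code{n}, \code{converged}.
#' @export
train_classifier <- function(features, covariates = c("qual", "logodds"),
                             label = "err") {
  stopifnot(all(covariates %in% names(features)), label %in% names(features))
  y <- features[[label]]
  if (any(y < 0 | y > 1)) stop("labels must lie in [0, 1]")
  if (all(y == 0) || all(y == 1)) stop("both classes must be present")
  X <- as.matrix(features[, covariates, drop = FALSE])
  # fractional labels -> weighted two-row expansion
  frac <- y > 0 & y < 1
  if (any(frac)) {
    X2 <- rbind(X, X[frac, , drop = FALSE])
    yy <- c(ifelse(y > 0, 1, 0), rep(0, sum(frac)))
    ww <- c(ifelse(frac, y, 1), 1 - y[frac])
  } else {
    X2 <- X; yy <- y; ww <- rep(1, length(y))
  }
  dat <- data.frame(.y = yy, X2, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", covariates),
                                               collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat, weights = ww,
                                     control = stats::glm.control(epsilon = 1e-8,
                                                                  maxit = 100)))
  coefs <- stats::coef(fit)
  converged <- fit$converged && all(is.finite(coefs)) && max(abs(coefs)) < 30
  if (!converged) {
    warning("separation or non-convergence; refitting with 1e-6 ridge")
    coefs <- ridge_logistic(cbind(1, X2), yy, ww, lambda = 1e-6)
  }
  names(coefs) <- c("(Intercept)", covariates)
  structure(list(coef = coefs, covariates = covariates,
                 n = nrow(features), converged = converged),
            class = "mask_model")
}

# IRLS with an L2 penalty on the non-intercept coefficients
ridge_logistic <- function(X, y, w, lambda = 1e-6, maxit = 200, tol = 1e-8) {
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    grad <- crossprod(X, w * (y - mu)) - pen %*% beta
    H <- crossprod(X, X * W) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(grad)) < tol) break
  }
  as.numeric(beta)
}

#' Predict error probabilities and mask
#'
#' Applies a trained \code{mask_model} to one block: bases whose
#' predicted error probability exceeds \code{cutoff} are changed to
#' 'N'.  Sweeping the cutoff traces the classifier's ROC curve.
#'
#' @param block a \code{qmaf_block}.
#' @param species the draft species.
#' @param fit a \code{mask_model}.
#' @param cutoff masking probability cutoff in [0, 1].
#' @param model,M phylogenetic model and error matrix, if the fit uses
#'   the log-odds covariate.
#' @param window window size for local covariates.
#' @return list with \code{block} (edited) and \code{decisions}
#'   (column, base, bin, probability, masked).
#' @export
predict_mask <- function(block, species, fit, cutoff = 0.5,
                         model = NULL, M = NULL, window = 10L) {
  stopifnot(inherits(fit, "mask_model"))
  covs <- setdiff(fit$covariates, "lo_missing")
  feats <- extract_features(block, species, model, M,
                           covariates = unique(c(covs,
                             if ("lo_missing" %in% fit$covariates) "logodds")),
                           window = window)
  missing_cov <- setdiff(fit$covariates, names(feats))
  if (length(missing_cov))
    stop("covariate(s) not derivable from block: ",
         paste(missing_cov, collapse = ", "))
  X <- cbind(1, as.matrix(feats[, fit$covariates, drop = FALSE]))
  p <- 1 / (1 + exp(-as.numeric(X %*% fit$coef)))
  mask <- p > cutoff
  i <- block_row(block, species)
  ch <- block_chars(block, i)
  ch[feats$column[mask]] <- "N"
  block$text[i] <- paste(ch, collapse = "")
  decisions <- data.frame(species = species, column = feats$column,
                          base = feats$base, bin = feats$bin,
                          probability = p, masked = mask,
                          stringsAsFactors = FALSE)
  list(block = block, decisions = decisions)
}
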