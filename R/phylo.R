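BASES <- c("A", "C", "G", "T")

#' Phylogenetic substitution model
#'
#' Reversible nucleotide model on a rooted tree with branch lengths in
#' expected substitutions per site.  The rate matrix is built from
#' exchangeabilities and equilibrium frequencies (GTR
#' parameterization) and normalized to one expected substitution per
#' unit branch length; Jukes-Cantor is the default.
#'
#' @param tree an \code{ape::phylo} tree (unrooted trees are rooted at
#'   their first internal node; parsimony and likelihoods used here are
#'   root-invariant for reversible models).
#' @param freq equilibrium base frequencies (A, C, G, T).
#' @param rates exchangeabilities for pairs AC, AG, AT, CG, CT, GT
#'   (default all 1: Jukes-Cantor when freq is uniform).
#' @return an object of class \code{phylo_model} with \code{tree},
#'   \code{Q} (normalized rate matrix) and \code{freq}.
#' @export
phylo_model <- function(tree, freq = rep(0.25, 4), rates = rep(1, 6)) {
  stopifnot(inherits(tree, "phylo"), length(freq) == 4, length(rates) == 6)
  freq <- freq / sum(freq)
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, 1, resolve.root = TRUE)
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S[upper.tri(S)] <- rates
  S <- S + t(S)
  Q <- S %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(BASES, BASES)
  structure(list(tree = tree, Q = Q, freq = freq), class = "phylo_model")
}

# transition probability matrix over scaled branch length
pmat <- function(model, t, rho = 1) {
  P <- ape::matexpo(model$Q * (rho * t))
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Column likelihood by Felsenstein pruning
#'
#' Probability of one alignment column under the substitution model,
#' computed by post-order pruning.  Bases N and '-' (and species on the
#' tree but absent from the column) are treated as missing data
#' (all-ones partial likelihoods).
#'
#' @param column named character vector mapping species to a base in
#'   A, C, G, T, N, '-'.
#' @param model a \code{phylo_model}.
#' @param rho branch-length scaling factor (>= 0, default 1); all
#'   branch lengths are multiplied by rho.
#' @return P(column | tree, model, rho), in (0, 1].
#' @export
prune_likelihood <- function(column, model, rho = 1) {
  tree <- model$tree
  sp <- names(column)
  if (!all(sp %in% tree$tip.label))
    stop("species not on tree: ",
         paste(setdiff(sp, tree$tip.label), collapse = ", "))
  obs <- toupper(column)
  informative <- obs %in% BASES
  if (!any(informative)) stop("column has no non-missing base")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- matrix(1, nnode, 4)
  for (i in which(informative)) {
    tipid <- match(sp[i], tree$tip.label)
    L[tipid, ] <- as.numeric(BASES == obs[i])
  }
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    P <- pmat(model, tr$edge.length[e], rho)
    L[parent, ] <- L[parent, ] * as.numeric(P %*% L[child, ])
  }
  root <- ntip + 1L
  sum(model$freq * L[root, ])
}

#' Empirical species-specific error transition matrix
#'
#' M[i, j] is the probability that a true base i is represented as j
#' given that an error occurred at the base (so the diagonal is 0 and
#' rows sum to 1).  Estimated from reference-to-draft mismatch counts
#' at quality bins below 9; rows without data fall back to a uniform
#' 1/3 off-diagonal.
#'
#' @param subst 4x4 mismatch count matrix (rows: reference/true base;
#'   columns: draft/observed base), e.g. \code{diff_table$subst}.
#' @return a 4x4 \code{error_matrix}.
#' @export
estimate_error_matrix <- function(subst) {
  stopifnot(all(dim(subst) == c(4, 4)))
  M <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  cnt <- as.matrix(subst)
  diag(cnt) <- 0
  for (i in 1:4) {
    tot <- sum(cnt[i, ])
    if (tot > 0) M[i, ] <- cnt[i, ] / tot
    else M[i, -i] <- 1 / 3
  }
  structure(M, class = c("error_matrix", "matrix"))
}

#' Phylogenetic error log-odds score
#'
#' How much more likely the observed base of species \code{s} is under
#' a single-sequencing-error model than under substitution alone.  The
#' no-error likelihood is the pruning likelihood of the column; the
#' error likelihood sums, over alternative true bases i != x_s, the
#' likelihood of the column with x_s replaced by i, weighted by the
#' error transition probability M[i, x_s] (at most one error per
#' column is assumed).  Each model's branch-length scaling factor rho
#' is optimized separately by deterministic scalar search, so an
#' apparent substitution at a conserved (short effective branch)
#' column scores as more error-like than one at a fast-evolving
#' column.
#'
#' @param column named character vector (species -> base).
#' @param s the draft species being scored (present, base in ACGT).
#' @param model a \code{phylo_model}.
#' @param M an \code{error_matrix} for species s.
#' @param rho_bounds search interval for rho (default c(0.01, 20)).
#' @param tol optimization tolerance (default 1e-4).
#' @return the log-odds score, or NA (sentinel) when no aligned
#'   partner base exists — callers fall back to quality-only masking.
#' @export
error_logodds <- function(column, s, model, M, rho_bounds = c(0.01, 20),
                          tol = 1e-4) {
  if (!s %in% names(column)) stop("species '", s, "' absent from column")
  xs <- toupper(column[[s]])
  if (!xs %in% BASES) stop("base of species '", s, "' is missing")
  partners <- toupper(column[setdiff(names(column), s)])
  if (!any(partners %in% BASES)) return(NA_real_)
  ll_noerr <- function(rho) log(prune_likelihood(column, model, rho))
  ll_err <- function(rho) {
    tot <- 0
    for (i in setdiff(BASES, xs)) {
      if (M[i, xs] <= 0) next
      col2 <- column
      col2[[s]] <- i
      tot <- tot + prune_likelihood(col2, model, rho) * M[i, xs]
    }
    if (tot <= 0) return(-Inf)
    log(tot)
  }
  o0 <- stats::optimize(ll_noerr, rho_bounds, maximum = TRUE, tol = tol)
  o1 <- stats::optimize(ll_err, rho_bounds, maximum = TRUE, tol = tol)
  o1$objective - o0$objective
}
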