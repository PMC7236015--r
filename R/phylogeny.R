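#' Neighbor-joining tree from a K2P distance matrix
#'
#' Standard neighbor joining used as the starting topology for the
#' maximum-likelihood search. Negative branch lengths produced by NJ are
#' clamped to zero. Matrices with undefined (saturated) pairs are refused:
#' silently substituting a number for a saturated distance corrupts the
#' tree.
#'
#' @param D A `k2p_dist` (see [distance_matrix()]) or a complete symmetric
#'   numeric matrix with dimnames.
#' @return An unrooted binary `phylo` tree (ape).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "k2p_dist")) {
    if (any(D$undefined[upper.tri(D$undefined)]))
      stop("saturated pairs present: distance matrix has undefined entries")
    m <- D$d
  } else {
    m <- as.matrix(D)
    if (any(is.na(m))) stop("saturated pairs present: NA entries")
  }
  if (nrow(m) < 3L) stop("need at least 3 taxa for a tree")
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' K80 transition probability matrix
#'
#' Closed-form transition probabilities of the Kimura 1980 substitution
#' process with transition/transversion rate ratio `kappa` and equal base
#' frequencies. The rate generator is normalized so that the mean
#' substitution rate is 1, making `t` the expected number of substitutions
#' per site and collapsing exactly to the JC69 model at `kappa = 1`.
#' Base order of rows/columns is A, C, G, T.
#'
#' @param t Branch length (expected substitutions/site), `t >= 0`.
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @return 4x4 row-stochastic matrix `P[i, j] = P(j at time t | i at 0)`.
#' @export
k80_transition_prob <- function(t, kappa) {
  if (t < 0) stop("invalid branch length: t must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts   <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv   <- 0.25 - 0.25 * e1
  P <- matrix(p_tv, 4, 4, dimnames = list(BASES, BASES))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- p_ts
  P
}

# Site patterns: unique alignment columns encoded as integer rows
# (1..4 = A,C,G,T; NA = missing) plus multiplicity weights.
site_patterns <- function(aln) {
  code <- matrix(match(aln$mat, BASES), nrow(aln$mat), ncol(aln$mat),
                 dimnames = list(rownames(aln$mat), NULL))
  key <- apply(code, 2, paste, collapse = ".")
  first <- !duplicated(key)
  pat <- code[, first, drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  list(pat = pat, weights = w, ids = rownames(aln$mat))
}

# Tip partial likelihoods: 4 x npat x ntip array; missing data
# (gap/ambiguity) contributes a vector of ones.
tip_partials <- function(pat) {
  ntip <- nrow(pat$pat)
  npat <- length(pat$weights)
  arr <- array(1, dim = c(4, npat, ntip))
  for (i in seq_len(ntip)) {
    obs <- pat$pat[i, ]
    known <- which(!is.na(obs))
    if (length(known) > 0L) {
      arr[, known, i] <- 0
      arr[cbind(obs[known], known, i)] <- 1
    }
  }
  arr
}

# Core pruning pass over a postorder edge matrix. Returns total
# log-likelihood under K80 with equal base frequencies.
prune_loglik <- function(edge, edge_length, ntip, nnode, tips, weights,
                         kappa) {
  npat <- length(weights)
  partial <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) partial[[i]] <- matrix(tips[, , i], 4, npat)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    P <- k80_transition_prob(edge_length[e], kappa)
    contrib <- P %*% partial[[child]]
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib
      else partial[[parent]] * contrib
  }
  root <- edge[nrow(edge), 1]
  site_lik <- colSums(partial[[root]]) * 0.25
  sum(weights * log(site_lik))
}

#' Log-likelihood of an alignment on a tree under K80
#'
#' Felsenstein pruning with equal base frequencies; gap and ambiguity
#' characters are missing data (partial likelihood vector of ones).
#' Identical alignment columns are compressed into weighted site patterns,
#' which leaves the value unchanged. Under this reversible model the value
#' does not depend on where an unrooted tree is (arbitrarily) rooted for
#' the traversal.
#'
#' @param tree A `phylo` tree whose tip labels exactly match the
#'   alignment's sequence IDs.
#' @param aln A `labeled_alignment`.
#' @param kappa Transition/transversion rate ratio.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(tree, aln, kappa = 2) {
  if (!setequal(tree$tip.label, rownames(aln$mat)))
    stop("tree/alignment mismatch: leaf IDs differ from sequence IDs")
  pat <- site_patterns(aln)
  lik_machine(tree, pat, kappa)$loglik
}

# Prepares reusable pruning inputs for one tree + pattern set.
lik_machine <- function(tree, pat, kappa) {
  tr <- ape::reorder.phylo(tree, "postorder")
  tipidx <- match(tr$tip.label, pat$ids)
  tips <- tip_partials(pat)[, , tipidx, drop = FALSE]
  ll <- prune_loglik(tr$edge, tr$edge.length, length(tr$tip.label),
                     tr$Nnode, tips, pat$weights, kappa)
  list(loglik = ll, tree = tr, tips = tips, weights = pat$weights)
}

# Optimize branch lengths one edge at a time by bounded univariate search.
# Operates in place on a postorder tree; `sweeps` full passes.
optimize_branch_lengths <- function(tr, tips, weights, kappa, sweeps = 2,
                                    upper = 10, tol = 1e-4) {
  ntip <- length(tr$tip.label)
  f_edge <- function(t, e) {
    el <- tr$edge.length
    el[e] <- t
    prune_loglik(tr$edge, el, ntip, tr$Nnode, tips, weights, kappa)
  }
  for (s in seq_len(sweeps)) {
    for (e in seq_len(nrow(tr$edge))) {
      opt <- optimize(f_edge, c(0, upper), e = e, maximum = TRUE, tol = tol)
      if (opt$objective >= f_edge(tr$edge.length[e], e))
        tr$edge.length[e] <- opt$maximum
    }
  }
  ll <- prune_loglik(tr$edge, tr$edge.length, ntip, tr$Nnode, tips, weights,
                     kappa)
  list(tree = tr, loglik = ll)
}

#' Estimate the K80 transition/transversion ratio on a fixed tree
#'
#' One-dimensional bounded maximization of the pruning log-likelihood over
#' `kappa` (log scale).
#'
#' @param tree A `phylo` tree matching the alignment.
#' @param aln A `labeled_alignment`.
#' @param bounds Search bounds for kappa.
#' @return List with `kappa` and `loglik`.
#' @export
estimate_kappa <- function(tree, aln, bounds = c(0.1, 100)) {
  pat <- site_patterns(aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  tipidx <- match(tr$tip.label, pat$ids)
  tips <- tip_partials(pat)[, , tipidx, drop = FALSE]
  ntip <- length(tr$tip.label)
  f <- function(logk)
    prune_loglik(tr$edge, tr$edge.length, ntip, tr$Nnode, tips,
                 pat$weights, exp(logk))
  opt <- optimize(f, log(bounds), maximum = TRUE, tol = 1e-3)
  list(kappa = exp(opt$maximum), loglik = opt$objective)
}

#' Maximum-likelihood tree search under K80
#'
#' Hill-climbing search alternating per-edge branch-length optimization
#' with nearest-neighbor-interchange (NNI) topology moves, scored by the
#' pruning log-likelihood. Moves are scanned in a fixed deterministic order
#' and the first improvement greater than `tol` log-units is accepted; the
#' search stops when no NNI improves the score. The returned tree's
#' log-likelihood is never below that of the starting tree.
#'
#' @param aln A `labeled_alignment`.
#' @param kappa Fixed transition/transversion ratio, or `NULL` to estimate
#'   it on the starting tree via [estimate_kappa()].
#' @param start_tree Starting `phylo`; defaults to [nj_tree()] on the K2P
#'   matrix of `aln`.
#' @param tol Minimum log-likelihood gain to accept a topology move.
#' @param sweeps Branch-length optimization passes after each accepted
#'   move.
#' @param max_moves Safety cap on accepted NNI moves.
#' @return A `phylo` tree with attributes `loglik`, `kappa` and `trace`
#'   (log-likelihood after each accepted state, non-decreasing).
#' @export
ml_search <- function(aln, kappa = NULL, start_tree = NULL, tol = 1e-6,
                      sweeps = 2, max_moves = 200) {
  if (is.null(start_tree)) start_tree <- nj_tree(distance_matrix(aln))
  if (!setequal(start_tree$tip.label, rownames(aln$mat)))
    stop("tree/alignment mismatch: leaf IDs differ from sequence IDs")
  if (is.null(kappa)) kappa <- estimate_kappa(start_tree, aln)$kappa
  pat <- site_patterns(aln)
  tipvals <- tip_partials(pat)

  prep <- function(tree) {
    tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
    tr$edge.length[is.na(tr$edge.length) | tr$edge.length < 0] <- 1e-6
    tips <- tipvals[, , match(tr$tip.label, pat$ids), drop = FALSE]
    list(tr = tr, tips = tips)
  }

  st <- prep(start_tree)
  cur <- optimize_branch_lengths(st$tr, st$tips, pat$weights, kappa,
                                 sweeps = sweeps)
  start_ll <- cur$loglik
  trace <- cur$loglik
  moves <- 0L
  repeat {
    improved <- FALSE
    neighbors <- phangorn::nni(cur$tree)
    for (k in seq_along(neighbors)) {
      cand <- prep(neighbors[[k]])   # [[ restores shared tip labels
      quick <- optimize_branch_lengths(cand$tr, cand$tips, pat$weights,
                                       kappa, sweeps = 1)
      if (quick$loglik > cur$loglik + tol) {
        cur <- optimize_branch_lengths(quick$tree, cand$tips, pat$weights,
                                       kappa, sweeps = sweeps)
        # guard: full re-optimization can only refine, never regress
        if (cur$loglik < quick$loglik) cur <- quick
        trace <- c(trace, cur$loglik)
        moves <- moves + 1L
        improved <- TRUE
        break
      }
    }
    if (!improved || moves >= max_moves) break
  }
  out <- cur$tree
  attr(out, "loglik") <- max(cur$loglik, start_ll)
  attr(out, "kappa") <- kappa
  attr(out, "trace") <- trace
  out
}

#' Root a tree at an outgroup taxon
#'
#' Places the root on the edge subtending the outgroup leaf, leaving the
#' ingroup topology unchanged.
#'
#' @param tree An unrooted (or rooted) `phylo` tree.
#' @param outgroup_id Tip label of the outgroup sequence.
#' @return A rooted `phylo` tree.
#' @export
root_at_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop("outgroup not found: ", outgroup_id)
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
}
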