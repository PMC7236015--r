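# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops and base R only.

# Site classification by explicit multiset counting.
oracle_classify <- function(column) {
  bases <- column[column %in% c("A", "C", "G", "T")]
  if (length(bases) == 0) return("all_missing")
  counts <- table(bases)
  if (length(counts) <= 1) return("constant")
  if (sum(counts >= 2) >= 2) return("parsimony_informative")
  "singleton_variable"
}

# Indel events by walking columns and comparing gap-pattern labels.
oracle_indel_events <- function(mat) {
  events <- 0
  prev <- ""
  for (j in seq_len(ncol(mat))) {
    rows <- which(mat[, j] == "-")
    if (length(rows) == 0) { prev <- ""; next }
    lab <- paste(rows, collapse = "/")
    if (lab != prev) events <- events + 1
    prev <- lab
  }
  events
}

# Per-site transition/transversion classification.
oracle_count_changes <- function(a, b) {
  purine <- c("A", "G")
  n <- 0; ts <- 0; tv <- 0
  for (k in seq_along(a)) {
    x <- a[k]; y <- b[k]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T")))
      next
    n <- n + 1
    if (x == y) next
    if ((x %in% purine) == (y %in% purine)) ts <- ts + 1 else tv <- tv + 1
  }
  list(n_compared = n, n_transitions = ts, n_transversions = tv)
}

# Exhaustive likelihood: sum over all internal-node state assignments.
# tree: rooted or unrooted phylo; works for small trees only.
oracle_loglik_enumerate <- function(tree, aln, kappa) {
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  Plist <- lapply(elen, function(t) barcodiv::k80_transition_prob(t, kappa))
  root <- setdiff(edge[, 1], edge[, 2])
  mat <- as.matrix(aln)[tree$tip.label, , drop = FALSE]
  internal <- sort(unique(edge[, 1]))
  states <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total_ll <- 0
  for (site in seq_len(ncol(mat))) {
    obs <- match(mat[, site], bases)   # NA = missing
    lik <- 0
    for (r in seq_len(nrow(states))) {
      assign_state <- function(node) {
        if (node <= ntip) return(obs[node])       # NA if missing
        states[r, match(node, internal)]
      }
      term <- 1 / 4   # uniform root frequency
      ok <- TRUE
      for (e in seq_len(nrow(edge))) {
        p <- assign_state(edge[e, 1])
        ch <- assign_state(edge[e, 2])
        if (is.na(ch)) next      # missing tip: marginalized, prob 1
        term <- term * Plist[[e]][p, ch]
      }
      lik <- lik + term
    }
    total_ll <- total_ll + log(lik)
  }
  total_ll
}

# Monophyly by enumerating all clades via ape.
oracle_monophyletic <- function(tree, ids) {
  ape::is.monophyletic(tree, ids)
}

# Best-match categories by an exhaustive per-row re-scan.
oracle_best_match <- function(dmat, species, tol = 1e-12) {
  ids <- rownames(dmat)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    d <- dmat[i, -i]; others <- ids[-i]
    keep <- !is.na(d)
    if (!any(keep)) { out[i] <- "unclassifiable"; next }
    d <- d[keep]; others <- others[keep]
    if (!any(species[others] == species[ids[i]])) { out[i] <- "incorrect"; next }
    dm <- min(d)
    tied <- others[d <= dm + tol]
    same <- species[tied] == species[ids[i]]
    out[i] <- if (all(same)) "correct" else if (any(same)) "ambiguous"
      else "incorrect"
  }
  setNames(out, ids)
}

# Brute-force region slice: walk columns counting non-gap reference chars.
oracle_extract_cols <- function(ref_chars, ref_start, ref_end) {
  count <- 0; cols <- integer(0); started <- FALSE
  for (j in seq_along(ref_chars)) {
    if (ref_chars[j] != "-") {
      count <- count + 1
      if (count == ref_start) started <- TRUE
    }
    if (started) cols <- c(cols, j)
    if (ref_chars[j] != "-" && count == ref_end) break
  }
  cols
}
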