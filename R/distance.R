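#' Count transitions and transversions between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are
#' excluded pairwise (pairwise deletion). Among the remaining sites,
#' transitions are the purine-purine and pyrimidine-pyrimidine changes
#' (A<->G, C<->T); every other base difference is a transversion.
#'
#' @param a,b Character vectors of single residues (equal length), or
#'   single strings.
#' @return A list with `n_compared`, `n_transitions`, `n_transversions`,
#'   and the proportions `P` (transitions) and `Q` (transversions).
#' @export
count_changes <- function(a, b) {
  if (length(a) == 1L && nchar(a[1]) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b[1]) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("ragged alignment: unequal lengths")
  ok <- a %in% BASES & b %in% BASES
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                    (a == "C" & b == "T") | (a == "T" & b == "C")))
  tv <- sum(diff) - ts
  list(n_compared = n, n_transitions = ts, n_transversions = tv,
       P = ts / n, Q = tv / n)
}

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' Evaluates `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, the K2P
#' divergence estimator with transition proportion `P` and transversion
#' proportion `Q`. When the logarithm's argument is non-positive
#' (saturation), the distance is undefined and `NA` is returned.
#'
#' @param P,Q Proportions of transition and transversion sites.
#' @return Non-negative distance in expected substitutions per site, or
#'   `NA_real_` if undefined.
#' @export
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  max(0, -0.5 * log(w1 * sqrt(w2)))
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' @inheritParams count_changes
#' @return Distance (substitutions/site) or `NA_real_` when saturated.
#' @seealso [k2p_from_pq()], [count_changes()]
#' @export
k2p_distance <- function(a, b) {
  cc <- count_changes(a, b)
  k2p_from_pq(cc$P, cc$Q)
}

#' Pairwise K2P distance matrix for a labeled alignment
#'
#' Computes all pairwise K2P distances with pairwise deletion. Saturated
#' pairs (undefined distance) and pairs with no comparable sites are
#' flagged rather than assigned a number; downstream consumers must decide
#' how to treat them ([nj_tree()] refuses them, [best_match()] drops them
#' from candidate sets).
#'
#' @param aln A `labeled_alignment`.
#' @return An object of class `k2p_dist`: list with `d` (symmetric numeric
#'   matrix, `NA` where undefined), `undefined` (logical matrix),
#'   `n_compared` (integer matrix) and `ids`.
#' @export
distance_matrix <- function(aln) {
  n <- nrow(aln$mat)
  if (n < 2L) stop("no sequences: need at least 2")
  ids <- rownames(aln$mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  undef <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  ncomp <- matrix(0L, n, n, dimnames = list(ids, ids))
  # integer encoding once; pairwise masks via vector ops
  code <- matrix(match(aln$mat, BASES), n, ncol(aln$mat))
  for (i in seq_len(n - 1L)) {
    ai <- code[i, ]
    for (j in (i + 1L):n) {
      bj <- code[j, ]
      ok <- !is.na(ai) & !is.na(bj)
      m <- sum(ok)
      ncomp[i, j] <- ncomp[j, i] <- m
      if (m == 0L) {
        undef[i, j] <- undef[j, i] <- TRUE
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      x <- ai[ok]; y <- bj[ok]
      ndiff <- sum(x != y)
      # transitions: A(1)<->G(3), C(2)<->T(4): |x-y| == 2
      ts <- sum(x != y & abs(x - y) == 2L)
      dist <- k2p_from_pq(ts / m, (ndiff - ts) / m)
      if (is.na(dist)) {
        undef[i, j] <- undef[j, i] <- TRUE
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- dist
      }
    }
  }
  diag(ncomp) <- as.integer(rowSums(!is.na(code)))
  structure(list(d = d, undefined = undef, n_compared = ncomp, ids = ids),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("k2p_dist: %d sequences, %d undefined pair(s)\n",
              length(x$ids), sum(x$undefined[upper.tri(x$undefined)])))
  invisible(x)
}

#' Export a distance matrix as a PHYLIP square matrix
#'
#' Undefined pairs are written as `NA`; files containing them are not valid
#' input for distance-based tree builders and a warning is emitted.
#'
#' @param D A `k2p_dist`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(D, path) {
  if (any(D$undefined[upper.tri(D$undefined)]))
    warning("matrix contains undefined (saturated) pairs; written as NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(D$ids)), con)
  for (i in seq_along(D$ids)) {
    writeLines(paste(c(formatC(D$ids[i], width = -10),
                       formatC(D$d[i, ], format = "f", digits = 6)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export a distance matrix in long format
#'
#' One row per unordered pair: `id1, id2, d, n_compared` (tab-separated).
#' Undefined distances are written as `NA`.
#'
#' @param D A `k2p_dist`.
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_distance_tsv <- function(D, path) {
  n <- length(D$ids)
  ij <- which(upper.tri(D$d), arr.ind = TRUE)
  out <- data.frame(id1 = D$ids[ij[, 1]], id2 = D$ids[ij[, 2]],
                    d = D$d[ij], n_compared = D$n_compared[ij])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
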