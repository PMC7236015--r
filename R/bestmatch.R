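# Absolute tolerance for detecting ties among nearest-neighbor distances.
# Distances are deterministic functions of site counts, so exact ties are
# exact in floating point; the tolerance only absorbs benign rounding.
TIE_TOL <- 1e-12

#' Best match classification of every sequence
#'
#' Leave-one-out nearest-neighbor species assignment: each sequence is
#' queried against all other sequences by K2P distance. If every neighbor
#' at the minimum distance (the tie set) is conspecific the query is
#' `correct`; if the tie set mixes conspecific and heterospecific
#' neighbors it is `ambiguous`; if all are heterospecific it is
#' `incorrect`. Undefined (saturated) distances are excluded from the
#' candidate set; a query with no usable neighbor at all is reported as
#' `unclassifiable`, outside the regular categories. A query whose species
#' has no other representative can never be correct: it is classified
#' `incorrect` and flagged as a singleton (optionally excluded).
#'
#' @param D A `k2p_dist` from [distance_matrix()].
#' @param table Sample table matching `D$ids`.
#' @param exclude_singletons Drop singleton queries from the output instead
#'   of classifying them `incorrect`.
#' @return Data frame with one row per query: `sequence_id`, `species`,
#'   `d_min`, `tie_ids` (comma-joined), `category`, `singleton`.
#' @export
best_match <- function(D, table, exclude_singletons = FALSE) {
  ids <- D$ids
  sp <- setNames(table$species, table$sequence_id)[ids]
  if (anyNA(sp)) stop("table/alignment mismatch: IDs missing from table")
  n <- length(ids)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D$d[i, -i]
    cand <- ids[-i]
    usable <- !is.na(d)
    singleton <- !any(sp[cand] == sp[i] & usable)
    if (!any(usable)) {
      res[[i]] <- data.frame(sequence_id = ids[i], species = sp[[i]],
                             d_min = NA_real_, tie_ids = "",
                             category = "unclassifiable",
                             singleton = singleton,
                             stringsAsFactors = FALSE)
      next
    }
    d <- d[usable]; cand <- cand[usable]
    d_min <- min(d)
    ties <- cand[abs(d - d_min) <= TIE_TOL]
    consp <- sp[ties] == sp[i]
    category <- if (singleton) "incorrect"
      else if (all(consp)) "correct"
      else if (any(consp)) "ambiguous"
      else "incorrect"
    res[[i]] <- data.frame(sequence_id = ids[i], species = sp[[i]],
                           d_min = d_min,
                           tie_ids = paste(ties, collapse = ","),
                           category = category, singleton = singleton,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (exclude_singletons) out <- out[!out$singleton, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance threshold for best close match
#'
#' Either a fixed percent value, or a percentile of all intraspecific
#' pairwise distances (the method's original calibration): the sorted
#' intraspecific distances are indexed at `ceiling(p/100 * n)` and the
#' selected distance is expressed in percent.
#'
#' @param D A `k2p_dist`.
#' @param table Sample table matching `D$ids`.
#' @param mode `"fixed"` or `"intra_percentile"`.
#' @param value Percent threshold (fixed mode) or percentile in (0, 100).
#' @return Threshold tau in percent.
#' @export
compute_threshold <- function(D, table, mode = c("fixed", "intra_percentile"),
                              value = 3) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (value <= 0) stop("fixed threshold must be > 0")
    return(value)
  }
  if (value <= 0 || value >= 100) stop("percentile must be in (0, 100)")
  sp <- setNames(table$species, table$sequence_id)[D$ids]
  same <- outer(sp, sp, "==") & upper.tri(D$d)
  intra <- D$d[same]
  intra <- intra[!is.na(intra)]
  if (length(intra) == 0L) stop("no intraspecific pairs")
  sorted <- sort(intra)
  idx <- max(1L, ceiling(value / 100 * length(sorted)))
  sorted[idx] * 100
}

#' Best close match classification
#'
#' As [best_match()], but queries whose nearest usable neighbor lies
#' further than the threshold `tau` (in percent distance) are rejected as
#' `no_match` before identification; a nearest distance exactly equal to
#' the threshold passes.
#'
#' @inheritParams best_match
#' @param tau Threshold in percent (see [compute_threshold()]).
#' @return Data frame as [best_match()], with `no_match` rows where
#'   `d_min * 100 > tau`.
#' @export
best_close_match <- function(D, table, tau, exclude_singletons = FALSE) {
  out <- best_match(D, table, exclude_singletons = exclude_singletons)
  reject <- out$category != "unclassifiable" & out$d_min * 100 > tau
  out$category[reject] <- "no_match"
  out
}

#' Summarize match records into a classification table row
#'
#' Tallies `correct`, `ambiguous`, `incorrect` and `no_match` among the
#' records of one region/mode and renders each as `"count (pct)"` with the
#' truncating percent convention, percentages taken out of the total
#' number of sequences. `unclassifiable` records are counted separately
#' and excluded from the four categories.
#'
#' @param records Output of [best_match()] or [best_close_match()].
#' @param region Optional region label carried into the row.
#' @return An object of class `match_summary`: list with `region`,
#'   `n_sequences`, per-category `*_count` and `*_pct`, formatted `*_cell`
#'   strings and `n_unclassifiable`.
#' @export
summarize_matches <- function(records, region = NULL) {
  cats <- c("correct", "ambiguous", "incorrect", "no_match")
  n_uncl <- sum(records$category == "unclassifiable")
  total <- nrow(records) - n_uncl
  if (total == 0L) stop("empty denominator: no classifiable records")
  out <- list(region = region %||% "", n_sequences = total)
  for (ct in cats) {
    cnt <- sum(records$category == ct)
    out[[paste0(ct, "_count")]] <- cnt
    out[[paste0(ct, "_pct")]] <- format_percent(cnt, total)
    out[[paste0(ct, "_cell")]] <- sprintf("%d (%s)", cnt,
                                          format_percent(cnt, total))
  }
  out$n_unclassifiable <- n_uncl
  class(out) <- "match_summary"
  out
}

#' @export
print.match_summary <- function(x, ...) {
  cat(sprintf(
    "match_summary%s: n=%d  correct %s  ambiguous %s  incorrect %s  no_match %s\n",
    if (nzchar(x$region)) paste0(" [", x$region, "]") else "",
    x$n_sequences, x$correct_cell, x$ambiguous_cell, x$incorrect_cell,
    x$no_match_cell))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
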