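BASES <- c("A", "C", "G", "T")

#' Classify one alignment column
#'
#' Standard site classification as used by alignment explorers such as MEGA:
#' gaps and IUPAC ambiguity codes are treated as missing data; among the
#' remaining unambiguous bases a column is `constant` (at most one distinct
#' base), `parsimony_informative` (at least two bases each carried by at
#' least two sequences), or `singleton_variable` (variable but not
#' informative). A column with no unambiguous base at all is `all_missing`.
#'
#' @param column Character vector of single residues (one per sequence).
#' @return A list with `category`, and `has_gap` (any `-` in the column).
#' @export
classify_column <- function(column) {
  has_gap <- any(column == "-")
  base <- column[column %in% BASES]
  if (length(base) == 0L) {
    cat_ <- "all_missing"
  } else {
    tab <- tabulate(match(base, BASES), nbins = 4L)
    n_states <- sum(tab > 0L)
    if (n_states <= 1L) {
      cat_ <- "constant"
    } else if (sum(tab >= 2L) >= 2L) {
      cat_ <- "parsimony_informative"
    } else {
      cat_ <- "singleton_variable"
    }
  }
  list(category = cat_, has_gap = has_gap)
}

#' Classify every column of an alignment
#'
#' @param aln A `labeled_alignment`.
#' @return Data frame with `column` (1-based), `category`, `has_gap`.
#' @export
classify_sites <- function(aln) {
  cls <- apply(aln$mat, 2, classify_column)
  data.frame(
    column = seq_len(aln$length),
    category = vapply(cls, `[[`, character(1), "category"),
    has_gap = vapply(cls, `[[`, logical(1), "has_gap")
  )
}

#' Count indel sites or indel events
#'
#' In `event` mode (the default) maximal runs of adjacent gap-bearing
#' columns sharing an identical gap presence/absence pattern across
#' sequences are merged into single indel events, so a 3-column deletion in
#' one sequence counts once. In `column` mode every column containing at
#' least one gap counts.
#'
#' @param aln A `labeled_alignment`.
#' @param mode `"event"` or `"column"`.
#' @return Integer count.
#' @export
count_indel_sites <- function(aln, mode = c("event", "column")) {
  mode <- match.arg(mode)
  gap <- aln$mat == "-"
  has_gap <- apply(gap, 2, any)
  if (mode == "column") return(sum(has_gap))
  events <- 0L
  prev_pattern <- NULL
  for (j in seq_len(ncol(gap))) {
    if (!has_gap[j]) {
      prev_pattern <- NULL
      next
    }
    pat <- paste(which(gap[, j]), collapse = ",")
    if (is.null(prev_pattern) || pat != prev_pattern) events <- events + 1L
    prev_pattern <- pat
  }
  events
}

#' Summarize a barcode region
#'
#' Produces the per-region comparison row used to rank barcode loci:
#' alignment length, numbers of samples and species, counts and percentages
#' of variable, parsimony-informative and singleton sites, and the indel
#' count. Percentages use the truncating two-decimal convention of
#' [format_percent()]. The variable count always equals parsimony +
#' singleton.
#'
#' @param aln A `labeled_alignment`.
#' @param region Region name; defaults to the (unique) `region` value of the
#'   sample table.
#' @param outgroup Optional outgroup species label, excluded from the
#'   species count.
#' @param indel_mode Passed to [count_indel_sites()].
#' @return An object of class `region_summary` (a list of named scalars).
#' @export
summarize_region <- function(aln, region = NULL, outgroup = NULL,
                             indel_mode = c("event", "column")) {
  indel_mode <- match.arg(indel_mode)
  sites <- classify_sites(aln)
  n_pars <- sum(sites$category == "parsimony_informative")
  n_sing <- sum(sites$category == "singleton_variable")
  n_var <- n_pars + n_sing
  len <- aln$length
  species <- unique(aln$table$species)
  if (!is.null(outgroup)) species <- setdiff(species, outgroup)
  if (is.null(region)) {
    region <- unique(aln$table$region)
    region <- if (length(region) == 1L) region else paste(region, collapse = "+")
  }
  out <- list(
    region = region,
    length = len,
    n_samples = nrow(aln$mat) - if (is.null(outgroup))
      0L else sum(aln$table$species == outgroup),
    n_species = length(species),
    variable_count = n_var,
    variable_pct = format_percent(n_var, len),
    parsimony_count = n_pars,
    parsimony_pct = format_percent(n_pars, len),
    singleton_count = n_sing,
    singleton_pct = format_percent(n_sing, len),
    indel_count = count_indel_sites(aln, indel_mode),
    indel_mode = indel_mode
  )
  class(out) <- "region_summary"
  out
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf(
    "%s: length %d, %d samples, %d species\n  variable %d (%s%%) = parsimony %d (%s%%) + singleton %d (%s%%); indels (%s): %d\n",
    x$region, x$length, x$n_samples, x$n_species,
    x$variable_count, x$variable_pct, x$parsimony_count, x$parsimony_pct,
    x$singleton_count, x$singleton_pct, x$indel_mode, x$indel_count))
  invisible(x)
}
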