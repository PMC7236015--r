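#' Truncating percentage formatter
#'
#' Renders `100 * count / total` truncated (floored, not rounded) to two
#' decimals, the convention used throughout the report tables: 19/24
#' prints as `"79.16"`, 10/68 as `"14.70"` — never rounded up. Computed in
#' exact integer arithmetic so no floating-point representation can flip
#' the truncation.
#'
#' @param count,total Non-negative counts with `count <= total`,
#'   `total > 0`.
#' @return Character scalar with exactly two decimals.
#' @export
format_percent <- function(count, total) {
  if (total <= 0) stop("empty denominator")
  if (count < 0 || count > total) stop("count must be in [0, total]")
  hundredths <- (10000 * count) %/% total   # exact for integer inputs
  sprintf("%.2f", hundredths / 100)
}

#' Run the full barcode evaluation pipeline
#'
#' For each input region: per-site summary statistics, K2P distance
#' matrix, NJ (optionally ML-refined) tree, outgroup rooting, species
#' resolution by monophyly with diagnostic-indel rescue, and best match /
#' best close match classification. A failing region is recorded as a
#' machine-readable failure without aborting the remaining regions.
#'
#' @param regions Named list of `labeled_alignment` objects (one per
#'   region), or a named list of `list(fasta =, table =)` paths read via
#'   [read_labeled_alignment()].
#' @param outgroup Outgroup *species label* used for rooting and excluded
#'   from resolution, or `NULL` to skip rooted analyses.
#' @param threshold Best-close-match threshold in percent (default the
#'   conventional 3), or a list `list(mode =, value =)` for
#'   [compute_threshold()].
#' @param tree_method `"ml"` (NJ start + K80 ML refinement) or `"nj"`.
#' @param kappa Fixed kappa for the ML refinement, or `NULL` to estimate.
#' @param indel_mode Indel counting mode for [summarize_region()].
#' @param include_outgroup_queries Keep the outgroup sequence among the
#'   best-match queries (default drops it: it is a rooting device, not a
#'   query).
#' @param seed Integer seed recorded in the report (the analysis itself is
#'   deterministic; the seed matters when regions were simulated).
#' @param out_dir Optional directory: writes per-region Newick, TSV and a
#'   JSON report.
#' @return A list of class `barcode_report`: per-region results
#'   (`summary`, `tree`, `resolution`, `best_match`, `best_close_match`,
#'   summaries) plus a `provenance` block.
#' @export
run_pipeline <- function(regions, outgroup = NULL, threshold = 3,
                         tree_method = c("ml", "nj"), kappa = NULL,
                         indel_mode = c("event", "column"),
                         include_outgroup_queries = FALSE,
                         seed = NULL, out_dir = NULL) {
  tree_method <- match.arg(tree_method)
  indel_mode <- match.arg(indel_mode)
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list()
  for (rg in names(regions)) {
    results[[rg]] <- tryCatch(
      run_region(regions[[rg]], rg, outgroup, threshold, tree_method,
                 kappa, indel_mode, include_outgroup_queries, out_dir),
      error = function(e) list(region = rg, failed = TRUE,
                               error = conditionMessage(e)))
  }
  report <- list(
    regions = results,
    provenance = list(
      seed = seed,
      tree_method = tree_method,
      threshold = threshold,
      indel_mode = indel_mode,
      outgroup = outgroup,
      package_version = as.character(utils::packageVersion("barcodiv"))
    )
  )
  class(report) <- "barcode_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

run_region <- function(input, region, outgroup, threshold, tree_method,
                       kappa, indel_mode, include_outgroup_queries,
                       out_dir) {
  aln <- if (inherits(input, "labeled_alignment")) input
    else read_labeled_alignment(input$fasta, input$table)

  summary <- summarize_region(aln, region = region, outgroup = outgroup,
                              indel_mode = indel_mode)
  D <- distance_matrix(aln)
  tree <- nj_tree(D)
  if (tree_method == "ml") tree <- ml_search(aln, kappa = kappa,
                                             start_tree = tree)

  resolution <- NULL
  rooted <- NULL
  if (!is.null(outgroup)) {
    og_ids <- aln$table$sequence_id[aln$table$species == outgroup]
    if (length(og_ids) == 0L) stop("outgroup not found: ", outgroup)
    rooted <- root_at_outgroup(tree, og_ids[1])
    statuses <- resolve_by_tree(rooted, aln$table, outgroup = outgroup)
    resolution <- combined_resolution(statuses, aln)
  } else {
    resolution <- list(note = "unrooted: resolution unavailable")
  }

  # best match: outgroup is a rooting device, not a query, unless asked
  Dq <- D
  tabq <- aln$table
  if (!is.null(outgroup) && !include_outgroup_queries) {
    keep <- tabq$species != outgroup
    ids <- tabq$sequence_id[keep]
    Dq <- structure(list(d = D$d[ids, ids, drop = FALSE],
                         undefined = D$undefined[ids, ids, drop = FALSE],
                         n_compared = D$n_compared[ids, ids, drop = FALSE],
                         ids = ids), class = "k2p_dist")
    tabq <- tabq[keep, , drop = FALSE]
  }
  bm <- best_match(Dq, tabq)
  tau <- if (is.list(threshold))
    compute_threshold(Dq, tabq, mode = threshold$mode,
                      value = threshold$value)
    else threshold
  bcm <- best_close_match(Dq, tabq, tau)
  out <- list(region = region, failed = FALSE,
              summary = summary, tree = tree, rooted_tree = rooted,
              resolution = resolution,
              best_match = bm, best_close_match = bcm,
              bm_summary = summarize_matches(bm, region),
              bcm_summary = summarize_matches(bcm, region),
              threshold = tau)
  if (!is.null(out_dir)) {
    ape::write.tree(tree, file.path(out_dir, paste0(region, ".nwk")))
    write_distance_tsv(D, file.path(out_dir, paste0(region, "_dist.tsv")))
    write.table(bm, file.path(out_dir, paste0(region, "_bestmatch.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# JSON-friendly view of a report (trees as Newick strings, data frames as
# records).
report_to_list <- function(report) {
  rg <- lapply(report$regions, function(r) {
    if (isTRUE(r$failed)) return(r)
    res <- r$resolution
    res_out <- if (inherits(res, "resolution_report")) {
      per <- res$per_species
      per$entangled_with <- vapply(per$entangled_with, paste,
                                   character(1), collapse = ",")
      list(per_species = per, resolved_by_tree = res$resolved_by_tree,
           resolved_by_indel = res$resolved_by_indel,
           total_species = res$total_species, fraction = res$fraction,
           percent = res$percent)
    } else res
    list(region = r$region,
         summary = unclass(r$summary),
         tree = ape::write.tree(r$tree),
         resolution = res_out,
         best_match = unclass(r$bm_summary),
         best_close_match = unclass(r$bcm_summary),
         threshold = r$threshold)
  })
  list(regions = rg, provenance = report$provenance)
}

#' @export
print.barcode_report <- function(x, ...) {
  cat("barcode_report\n")
  for (r in x$regions) {
    if (isTRUE(r$failed)) {
      cat(sprintf("  %s: FAILED (%s)\n", r$region, r$error))
      next
    }
    frac <- if (inherits(r$resolution, "resolution_report"))
      sprintf("%s species resolved (%s%%)", r$resolution$fraction,
              r$resolution$percent)
      else r$resolution$note
    cat(sprintf("  %s: %d seqs, variable %s%%; %s; best match correct %s\n",
                r$region, r$summary$n_samples, r$summary$variable_pct,
                frac, r$bm_summary$correct_cell))
  }
  invisible(x)
}
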