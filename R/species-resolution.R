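# Descendant tip-label sets for every node of a phylo tree (tips included:
# a tip's set is itself). Returned as a list indexed by node number.
clade_tip_sets <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Test whether a set of leaves is monophyletic
#'
#' True iff some node of the tree has exactly the given leaves as its
#' descendant tip set — i.e. the leaves form a clade with no intruders.
#'
#' @param tree A rooted `phylo` tree.
#' @param leaf_ids Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, leaf_ids) {
  missing <- setdiff(leaf_ids, tree$tip.label)
  if (length(missing) > 0L)
    stop("leaf not found: ", paste(missing, collapse = " "))
  if (length(leaf_ids) == 1L) return(TRUE)
  target <- sort(unique(leaf_ids))
  for (s in clade_tip_sets(tree)) {
    if (length(s) == length(target) && setequal(s, target)) return(TRUE)
  }
  FALSE
}

# Smallest clade containing all given leaves; returns its tip labels.
smallest_containing_clade <- function(tree, leaf_ids) {
  sets <- clade_tip_sets(tree)
  sizes <- lengths(sets)
  best <- NULL; best_size <- Inf
  for (k in seq_along(sets)) {
    if (sizes[k] < best_size && all(leaf_ids %in% sets[[k]])) {
      best <- sets[[k]]; best_size <- sizes[k]
    }
  }
  best
}

#' Species resolution by tree monophyly
#'
#' For each species (outgroup excluded), tests whether all of its
#' sequences — study samples plus reference accessions by default — form a
#' monophyletic group on the rooted tree. Species failing the test are
#' reported together with the set of species entangled with them (species
#' with leaves inside their smallest containing clade). Species represented
#' by a single sequence cannot demonstrate clustering; they are reported as
#' `singleton` and count as tree-resolved only when their leaf is not
#' nested inside another species' clade.
#'
#' @param tree A rooted `phylo` tree.
#' @param table Sample table (`sequence_id`, `species`, `source`, `region`).
#' @param outgroup Outgroup species label to exclude, or `NULL`.
#' @param include_reference Include `reference`-source sequences in each
#'   species' leaf set (default) or use study samples only.
#' @return A data frame of class `species_status` with one row per
#'   species: `species`, `n_samples`, `status` (`monophyletic`,
#'   `non_monophyletic`, `singleton`), `resolved_by_tree`, `uninformative`
#'   (singleton flag) and `entangled_with` (list column).
#' @export
resolve_by_tree <- function(tree, table, outgroup = NULL,
                            include_reference = TRUE) {
  tab <- table
  if (!include_reference) tab <- tab[tab$source == "study", , drop = FALSE]
  if (!is.null(outgroup)) tab <- tab[tab$species != outgroup, , drop = FALSE]
  species <- unique(tab$species)
  missing <- setdiff(tab$sequence_id, tree$tip.label)
  if (length(missing) > 0L)
    stop("species not represented: sequences absent from tree: ",
         paste(missing, collapse = " "))
  sp_ids <- split(tab$sequence_id, tab$species)[species]
  sp_of <- setNames(tab$species, tab$sequence_id)

  # clade machinery computed once
  sets <- clade_tip_sets(tree)
  contains_all <- function(ids) {
    best <- NULL; best_size <- Inf
    for (s in sets) {
      if (length(s) < best_size && all(ids %in% s)) {
        best <- s; best_size <- length(s)
      }
    }
    best
  }
  is_mono <- function(ids) {
    if (length(ids) == 1L) return(TRUE)
    tgt <- sort(ids)
    for (s in sets)
      if (length(s) == length(tgt) && setequal(s, tgt)) return(TRUE)
    FALSE
  }

  status <- character(length(species))
  resolved <- logical(length(species))
  uninf <- logical(length(species))
  entangled <- vector("list", length(species))
  # clades of multi-sample species, for the singleton nesting test
  multi_clades <- lapply(sp_ids[lengths(sp_ids) > 1L], contains_all)
  for (k in seq_along(species)) {
    ids <- sp_ids[[k]]
    if (length(ids) == 1L) {
      status[k] <- "singleton"
      uninf[k] <- TRUE
      nested_in <- names(multi_clades)[vapply(multi_clades, function(s)
        ids %in% s, logical(1))]
      entangled[[k]] <- nested_in
      resolved[k] <- length(nested_in) == 0L
    } else if (is_mono(ids)) {
      status[k] <- "monophyletic"
      resolved[k] <- TRUE
      entangled[[k]] <- character(0)
    } else {
      status[k] <- "non_monophyletic"
      clade <- contains_all(ids)
      others <- unique(sp_of[intersect(clade, names(sp_of))])
      entangled[[k]] <- setdiff(others, species[k])
    }
  }
  out <- data.frame(species = species,
                    n_samples = lengths(sp_ids),
                    status = status,
                    resolved_by_tree = resolved,
                    uninformative = uninf,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$entangled_with <- entangled
  class(out) <- c("species_status", "data.frame")
  out
}

#' Find diagnostic indel columns between two species
#'
#' A column is diagnostic iff every sequence of one species carries a gap
#' there while every sequence of the other carries a residue — a fixed
#' insertion/deletion difference usable for identification even when the
#' two species are not separated on the tree. Kinds are reported relative
#' to the first species: `deletion_in_A` (A gapped, B not) or
#' `insertion_in_A` (A has residues, B gapped).
#'
#' @param aln A `labeled_alignment`.
#' @param species_a,species_b Species labels present in the alignment table.
#' @return Data frame with `column` (1-based) and `kind`; zero rows when no
#'   diagnostic column exists.
#' @export
find_diagnostic_indels <- function(aln, species_a, species_b) {
  tab <- aln$table
  rows_a <- tab$sequence_id[tab$species == species_a]
  rows_b <- tab$sequence_id[tab$species == species_b]
  if (length(rows_a) == 0L)
    stop("species not in alignment: ", species_a)
  if (length(rows_b) == 0L)
    stop("species not in alignment: ", species_b)
  gap_a <- aln$mat[rows_a, , drop = FALSE] == "-"
  gap_b <- aln$mat[rows_b, , drop = FALSE] == "-"
  all_a <- apply(gap_a, 2, all); none_a <- !apply(gap_a, 2, any)
  all_b <- apply(gap_b, 2, all); none_b <- !apply(gap_b, 2, any)
  del_a <- which(all_a & none_b)
  ins_a <- which(none_a & all_b)
  out <- data.frame(
    column = c(del_a, ins_a),
    kind = c(rep("deletion_in_A", length(del_a)),
             rep("insertion_in_A", length(ins_a))),
    stringsAsFactors = FALSE)
  out[order(out$column), , drop = FALSE]
}

#' Combine tree monophyly with diagnostic-indel rescue
#'
#' The combined species-resolution criterion: a species unresolved on the
#' tree is rescued iff at least one diagnostic indel column separates it
#' from *every* species entangled with it. The report totals tree-resolved
#' and indel-resolved species and renders the fraction as `"x/y"` with a
#' truncating two-decimal percentage.
#'
#' @param tree_statuses Output of [resolve_by_tree()] on the same samples.
#' @param aln The `labeled_alignment` the tree was built from.
#' @return An object of class `resolution_report`: list with `per_species`
#'   (the input statuses plus `indel_resolved` and `final_status`),
#'   `resolved_by_tree`, `resolved_by_indel`, `total_species`, `fraction`
#'   and `percent`.
#' @export
combined_resolution <- function(tree_statuses, aln) {
  st <- tree_statuses
  indel_res <- logical(nrow(st))
  for (k in seq_len(nrow(st))) {
    if (st$status[k] != "non_monophyletic") next
    ent <- st$entangled_with[[k]]
    if (length(ent) == 0L) next
    ok <- vapply(ent, function(sp)
      nrow(find_diagnostic_indels(aln, st$species[k], sp)) >= 1L, logical(1))
    indel_res[k] <- all(ok)
  }
  final <- ifelse(st$resolved_by_tree, "tree_resolved",
                  ifelse(indel_res, "indel_resolved",
                         ifelse(st$status == "singleton", "singleton",
                                "unresolved")))
  n_tree <- sum(st$resolved_by_tree)
  n_indel <- sum(indel_res)
  total <- nrow(st)
  per <- st
  per$indel_resolved <- indel_res
  per$final_status <- final
  structure(list(
    per_species = per,
    resolved_by_tree = n_tree,
    resolved_by_indel = n_indel,
    total_species = total,
    fraction = sprintf("%d/%d", n_tree + n_indel, total),
    percent = format_percent(n_tree + n_indel, total)
  ), class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf(
    "resolution_report: %s species resolved (%s%%): %d by tree, %d by indels\n",
    x$fraction, x$percent, x$resolved_by_tree, x$resolved_by_indel))
  invisible(x)
}
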