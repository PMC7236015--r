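#' Simulation configuration
#'
#' Bundles and validates the knobs of the sequence simulator. Defaults
#' describe the kind of barcode collection the pipeline is aimed at: 24
#' species of which 19 carry 3 sequences (two study samples plus one
#' reference accession) and 5 are singletons, an ITS-length alignment of
#' 639 columns, interspecific divergence an order of magnitude above
#' intraspecific, transition bias kappa = 2, and a distant outgroup for
#' rooting.
#'
#' @param n_species Number of ingroup species.
#' @param samples_per_species Integer vector (recycled to `n_species`) of
#'   sequences per species.
#' @param length Alignment length in columns.
#' @param inter_divergence Expected substitutions/site separating species
#'   ancestors (root-to-tip depth of the species tree is
#'   `inter_divergence / 2`).
#' @param intra_divergence Expected substitutions/site from a species
#'   ancestor to each of its samples.
#' @param kappa Transition/transversion rate ratio of the K80 process.
#' @param indel_spec Optional data frame (`species`, `column`, `kind`) of
#'   gap columns to inject; see [inject_indels()].
#' @param outgroup Append a distant outgroup sequence (logical).
#' @param outgroup_label Species label of the outgroup.
#' @param confuse_pairs Optional list of species-label pairs whose
#'   ancestors are made identical, emulating synonymous names or label
#'   confusion (the pair will not be separable on the tree).
#' @param region Region name written into the sample table.
#' @param seed Mandatory integer seed; the generator is fully
#'   deterministic given the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 24,
                       samples_per_species = c(rep(3L, 19), rep(1L, 5)),
                       length = 639,
                       inter_divergence = 0.15,
                       intra_divergence = 0.01,
                       kappa = 2,
                       indel_spec = NULL,
                       outgroup = TRUE,
                       outgroup_label = "outgroup_taxon",
                       confuse_pairs = NULL,
                       region = "SIM",
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_species >= 2, length >= 1,
            inter_divergence >= 0, intra_divergence >= 0, kappa > 0)
  samples_per_species <- rep_len(as.integer(samples_per_species), n_species)
  stopifnot(all(samples_per_species >= 1L))
  if (!is.null(indel_spec)) {
    stopifnot(all(c("species", "column") %in% names(indel_spec)))
    if (any(indel_spec$column < 1 | indel_spec$column > length))
      stop("coordinate error: indel column outside alignment")
  }
  structure(list(
    n_species = n_species, samples_per_species = samples_per_species,
    length = length, inter_divergence = inter_divergence,
    intra_divergence = intra_divergence, kappa = kappa,
    indel_spec = indel_spec, outgroup = outgroup,
    outgroup_label = outgroup_label, confuse_pairs = confuse_pairs,
    region = region, seed = as.integer(seed)
  ), class = "sim_config")
}

# Evolve an integer-coded sequence (1..4) for branch length t under K80.
evolve_seq <- function(seq, t, kappa) {
  if (t == 0) return(seq)
  P <- k80_transition_prob(t, kappa)
  out <- seq
  for (b in 1:4) {
    idx <- which(seq == b)
    if (length(idx) > 0L)
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
  }
  out
}

#' Simulate a labeled alignment with known species structure
#'
#' Species ancestors are evolved from a random root sequence along a
#' random coalescent species tree (exponential internode depths) rescaled
#' so that the root-to-tip depth equals `inter_divergence / 2`; each
#' sample then evolves independently from its species ancestor for
#' `intra_divergence` substitutions/site. All substitutions follow the K80
#' process at the configured kappa through R's global RNG, seeded once
#' from the config, so the output is byte-identical across runs with the
#' same configuration. An optional outgroup evolves from the root along a
#' branch of `inter_divergence`, and indel columns are injected last.
#'
#' @param config A [sim_config()].
#' @return A list with `aln` (a `labeled_alignment`) and `truth` (list:
#'   `species_tree` as `phylo`, `labels` named by sequence ID, and
#'   `indel_registry`, the injected indel data frame).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_species
  sp_names <- sprintf("species%02d", seq_len(ns))
  sp_tree <- ape::rcoal(ns, tip.label = sp_names)
  # Node heights above the (contemporaneous) tips. A raw coalescent draw can
  # put two species ancestors arbitrarily close; compressing internal
  # heights linearly into [depth/3, depth] keeps the topology and the
  # ordering of divergences but guarantees every species pair is separated
  # by at least inter_divergence/3, so inter_divergence really controls
  # separability rather than only tree depth.
  dfr <- ape::node.depth.edgelength(sp_tree)
  depth <- max(dfr)
  target <- config$inter_divergence / 2
  if (depth > 0) {
    h <- depth - dfr
    h[seq_len(ns)] <- 0
    h[-seq_len(ns)] <- depth / 3 + h[-seq_len(ns)] * (2 / 3)
    sp_tree$edge.length <-
      (h[sp_tree$edge[, 1]] - h[sp_tree$edge[, 2]]) * target / depth
  }

  L <- config$length
  root_seq <- sample.int(4L, L, replace = TRUE)
  # preorder walk from the root assigning sequences to every node
  tr <- ape::reorder.phylo(sp_tree, "cladewise")
  nnode <- ns + tr$Nnode
  seqs <- vector("list", nnode)
  root_node <- ns + 1L
  seqs[[root_node]] <- root_seq
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    seqs[[ch]] <- evolve_seq(seqs[[p]], tr$edge.length[e], config$kappa)
  }
  ancestors <- setNames(seqs[seq_len(ns)], tr$tip.label)

  # label confusion: overwrite the second species' ancestor with the first's
  if (!is.null(config$confuse_pairs)) {
    for (pr in config$confuse_pairs) {
      stopifnot(length(pr) == 2, all(pr %in% sp_names))
      ancestors[[pr[2]]] <- ancestors[[pr[1]]]
    }
  }

  ids <- character(0); species <- character(0); source <- character(0)
  rows <- list()
  for (k in seq_len(ns)) {
    nk <- config$samples_per_species[k]
    for (s in seq_len(nk)) {
      id <- sprintf("%s_%d", sp_names[k], s)
      rows[[id]] <- evolve_seq(ancestors[[sp_names[k]]],
                               config$intra_divergence, config$kappa)
      ids <- c(ids, id)
      species <- c(species, sp_names[k])
      source <- c(source, if (s == 1L) "reference" else "study")
    }
  }
  if (isTRUE(config$outgroup)) {
    id <- paste0(config$outgroup_label, "_1")
    rows[[id]] <- evolve_seq(root_seq, config$inter_divergence, config$kappa)
    ids <- c(ids, id)
    species <- c(species, config$outgroup_label)
    source <- c(source, "reference")
  }
  mat <- do.call(rbind, lapply(rows, function(x) BASES[x]))
  rownames(mat) <- ids
  tab <- data.frame(sequence_id = ids, species = species, source = source,
                    region = config$region, stringsAsFactors = FALSE)
  aln <- labeled_alignment(mat, tab)
  registry <- NULL
  if (!is.null(config$indel_spec)) {
    aln <- inject_indels(aln, config$indel_spec)
    registry <- config$indel_spec
  }
  list(aln = aln,
       truth = list(species_tree = sp_tree,
                    labels = setNames(species, ids),
                    indel_registry = registry))
}

#' Inject species-specific gap columns into an alignment
#'
#' Places a gap at each stated column for *all* sequences of the stated
#' species, leaving every other residue untouched. Two different species
#' claiming the same column is a conflict (the column could not then be
#' diagnostic for either pair direction as specified) and is rejected.
#'
#' @param aln A `labeled_alignment`.
#' @param indel_spec Data frame with columns `species` and `column`
#'   (1-based); an optional `kind` column (`"deletion"`/`"insertion"`) is
#'   carried through as annotation only — in alignment coordinates both
#'   materialize as gaps in the named species.
#' @return The modified `labeled_alignment`.
#' @export
inject_indels <- function(aln, indel_spec) {
  if (is.null(indel_spec) || nrow(indel_spec) == 0L) return(aln)
  stopifnot(all(c("species", "column") %in% names(indel_spec)))
  if (any(indel_spec$column < 1 | indel_spec$column > aln$length))
    stop("coordinate error: indel column outside alignment")
  if (anyDuplicated(indel_spec[, c("species", "column")]))
    stop("indel spec conflict: duplicated (species, column) entry")
  per_col <- split(indel_spec$species, indel_spec$column)
  if (any(vapply(per_col, function(s) length(unique(s)) > 1L, logical(1))))
    stop("indel spec conflict: one column assigned to multiple species")
  mat <- aln$mat
  for (r in seq_len(nrow(indel_spec))) {
    sp <- indel_spec$species[r]
    ids <- aln$table$sequence_id[aln$table$species == sp]
    if (length(ids) == 0L) stop("species not in alignment: ", sp)
    mat[ids, indel_spec$column[r]] <- "-"
  }
  structure(list(mat = mat, table = aln$table, length = ncol(mat)),
            class = "labeled_alignment")
}
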