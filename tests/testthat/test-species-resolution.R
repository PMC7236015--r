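test_that("monophyly detects clades and intruders", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_true(is_monophyletic(tr, c("A1", "A2")))
  expect_false(is_monophyletic(ape::read.tree(
    text = "((A1:1,B1:1):1,(A2:1,B2:1):1);"), c("A1", "A2")))
  expect_error(is_monophyletic(tr, c("A1", "ZZ")), "leaf not found")
})

test_that("monophyly agrees with the clade-enumeration oracle", {
  set.seed(51)
  for (rep in 1:25) {
    tr <- ape::rtree(8)
    ids <- sample(tr$tip.label, sample(2:5, 1))
    expect_equal(is_monophyletic(tr, ids), oracle_monophyletic(tr, ids))
  }
})

test_that("tree resolution separates clean species and flags entangled ones", {
  cfg <- sim_config(n_species = 5, samples_per_species = 3, length = 500,
                    inter_divergence = 0.2, intra_divergence = 0.01,
                    kappa = 2, seed = 19)
  sim <- simulate_dataset(cfg)
  aln <- sim$aln
  rt <- root_at_outgroup(nj_tree(distance_matrix(aln)), "outgroup_taxon_1")
  st <- resolve_by_tree(rt, aln$table, outgroup = "outgroup_taxon")
  expect_setequal(st$status, "monophyletic")
  expect_true(all(st$resolved_by_tree))
  expect_true(all(lengths(st$entangled_with) == 0))

  # forced merge: two species share an ancestor -> mutually entangled
  cfg2 <- sim_config(n_species = 5, samples_per_species = 3, length = 500,
                     inter_divergence = 0.2, intra_divergence = 0.01,
                     kappa = 2, seed = 19,
                     confuse_pairs = list(c("species01", "species02")))
  sim2 <- simulate_dataset(cfg2)
  rt2 <- root_at_outgroup(nj_tree(distance_matrix(sim2$aln)),
                          "outgroup_taxon_1")
  st2 <- resolve_by_tree(rt2, sim2$aln$table, outgroup = "outgroup_taxon")
  s1 <- st2[st2$species == "species01", ]
  s2 <- st2[st2$species == "species02", ]
  expect_equal(s1$status, "non_monophyletic")
  expect_equal(s2$status, "non_monophyletic")
  expect_true("species02" %in% s1$entangled_with[[1]])
  expect_true("species01" %in% s2$entangled_with[[1]])
  # statuses equal an oracle recomputation from clade sets
  for (k in seq_len(nrow(st2))) {
    ids <- sim2$aln$table$sequence_id[
      sim2$aln$table$species == st2$species[k]]
    if (length(ids) < 2) next
    expect_equal(st2$status[k] == "monophyletic",
                 oracle_monophyletic(rt2, ids))
  }
})

test_that("singleton species are flagged and resolved only when unnested", {
  # D inside the (A1,A2) clade would be nested; here D sits apart
  tr <- ape::read.tree(
    text = "(((A1:1,A2:1):1,(B1:1,B2:1):1):1,(D1:1,OG:3):0.5);")
  tab <- data.frame(
    sequence_id = c("A1", "A2", "B1", "B2", "D1", "OG"),
    species = c("spA", "spA", "spB", "spB", "spD", "out"),
    source = "study", region = "ITS")
  st <- resolve_by_tree(tr, tab, outgroup = "out")
  d <- st[st$species == "spD", ]
  expect_equal(d$status, "singleton")
  expect_true(d$uninformative)
  expect_true(d$resolved_by_tree)

  # a singleton inside another species' clade is not resolved
  tr2 <- ape::read.tree(text = "(((A1:1,(D1:1,A2:1):1):1,(B1:1,B2:1):1):1,OG:3);")
  st2 <- resolve_by_tree(tr2, tab, outgroup = "out")
  expect_false(st2[st2$species == "spD", ]$resolved_by_tree)
})

test_that("diagnostic indels require within-species uniformity", {
  aln <- indel_fixture()
  # identical gap patterns: species against itself has no diagnosis
  none <- find_diagnostic_indels(aln, "primulinum", "primulinum")
  expect_equal(nrow(none), 0)
  diag <- find_diagnostic_indels(aln, "primulinum", "cretaceum")
  expect_equal(diag$column[diag$kind == "deletion_in_A"], c(86, 221, 222))
  expect_equal(diag$column[diag$kind == "insertion_in_A"], 89)
  expect_error(find_diagnostic_indels(aln, "nope", "cretaceum"),
               "species not in alignment")
})

test_that("random gap injections are recovered column-exactly", {
  set.seed(61)
  for (rep in 1:10) {
    cfg <- sim_config(n_species = 3, samples_per_species = 2, length = 60,
                      inter_divergence = 0.1, intra_divergence = 0.005,
                      kappa = 2, outgroup = FALSE, seed = 300 + rep)
    aln <- simulate_dataset(cfg)$aln
    cols <- sample(60, 4)
    spec <- data.frame(species = c("species01", "species01",
                                   "species02", "species02"),
                       column = cols)
    aln2 <- inject_indels(aln, spec)
    got <- find_diagnostic_indels(aln2, "species01", "species02")
    # brute force over columns
    g1 <- aln2$mat[aln2$table$species == "species01", , drop = FALSE] == "-"
    g2 <- aln2$mat[aln2$table$species == "species02", , drop = FALSE] == "-"
    want <- which((apply(g1, 2, all) & !apply(g2, 2, any)) |
                  (!apply(g1, 2, any) & apply(g2, 2, all)))
    expect_equal(got$column, sort(want))
  }
})

test_that("combined resolution rescues exactly the indel-separable pairs", {
  # Construct an alignment where species A/B and C/D provably interleave:
  # within each pair, sample 1 of both species shares one haplotype group
  # and sample 2 the other, so their smallest containing clades mix. A/B
  # additionally differ by fixed indels; C/D do not.
  set.seed(67)
  len <- 300
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  mutate <- function(s, cols) {
    s[cols] <- vapply(s[cols], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    s
  }
  cladeAB <- mutate(base, 1:40)
  cladeCD <- mutate(base, 81:120)
  cladeE <- mutate(base, 161:200)
  g1 <- mutate(cladeAB, 41:60); g2 <- mutate(cladeAB, 61:80)
  g3 <- mutate(cladeCD, 121:140); g4 <- mutate(cladeCD, 141:160)
  seqs <- c(
    A_1 = paste(g1, collapse = ""),
    B_1 = paste(mutate(g1, 203:204), collapse = ""),
    A_2 = paste(g2, collapse = ""),
    B_2 = paste(mutate(g2, 205:206), collapse = ""),
    C_1 = paste(g3, collapse = ""),
    D_1 = paste(mutate(g3, 207:208), collapse = ""),
    C_2 = paste(g4, collapse = ""),
    D_2 = paste(mutate(g4, 209:210), collapse = ""),
    E_1 = paste(cladeE, collapse = ""),
    E_2 = paste(mutate(cladeE, 201:202), collapse = ""),
    OG_1 = paste(mutate(base, 211:290), collapse = ""))
  aln <- make_aln(seqs, species = c("spA", "spB", "spA", "spB",
                                    "spC", "spD", "spC", "spD",
                                    "spE", "spE", "out"))
  aln <- inject_indels(aln, data.frame(species = "spA",
                                       column = c(295, 296)))
  rt <- root_at_outgroup(nj_tree(distance_matrix(aln)), "OG_1")
  st <- resolve_by_tree(rt, aln$table, outgroup = "out")
  rep_ <- combined_resolution(st, aln)
  per <- rep_$per_species
  expect_equal(unname(per$final_status[per$species %in% c("spA", "spB")]),
               c("indel_resolved", "indel_resolved"))
  expect_equal(unname(per$final_status[per$species %in% c("spC", "spD")]),
               c("unresolved", "unresolved"))
  expect_equal(per$final_status[per$species == "spE"], "tree_resolved")
  expect_equal(rep_$resolved_by_indel, 2)
  expect_equal(rep_$fraction, "3/5")
  # combination never resolves fewer than the tree alone
  expect_gte(rep_$resolved_by_tree + rep_$resolved_by_indel,
             sum(st$resolved_by_tree))
})

test_that("report fraction renders counts the table way", {
  # 17 tree-resolved + 2 indel-rescued of 24 -> "19/24"
  st <- data.frame(species = sprintf("sp%02d", 1:24),
                   n_samples = 2,
                   status = c(rep("monophyletic", 17),
                              rep("non_monophyletic", 7)),
                   resolved_by_tree = c(rep(TRUE, 17), rep(FALSE, 7)),
                   uninformative = FALSE)
  # sp19/sp20 carry a mutual diagnostic indel; the other entangled pairs
  # have identical gap patterns and cannot be rescued
  st$entangled_with <- c(rep(list(character(0)), 17),
                         list("sp20"), list("sp20"),
                         list("sp19"), list("sp22"),
                         list("sp21"), list("sp24"), list("sp23"))
  class(st) <- c("species_status", "data.frame")
  species <- character(0); rows <- list()
  for (k in seq_len(24)) for (s in 1:2) {
    id <- sprintf("sp%02d_%d", k, s)
    species <- c(species, sprintf("sp%02d", k))
    rows[[id]] <- if (k == 19) "AC-T" else "ACGT"
  }
  aln <- make_aln(unlist(rows), species = species)
  rep_ <- combined_resolution(st, aln)
  expect_equal(rep_$fraction, "19/24")
  expect_equal(rep_$percent, "79.16")
})
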