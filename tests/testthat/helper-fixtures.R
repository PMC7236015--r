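# Fixture builders shared across test files. All alignments are built in
# code; nothing is read from disk unless a test writes it first.

make_aln <- function(seqs, species = NULL, source = NULL, region = "ITS") {
  ids <- names(seqs)
  if (is.null(species)) species <- sub("_[0-9]+$", "", ids)
  if (is.null(source)) source <- rep("study", length(ids))
  labeled_alignment(seqs, data.frame(
    sequence_id = ids, species = species, source = source, region = region,
    stringsAsFactors = FALSE))
}

random_aln <- function(n, len, seed, gap_prob = 0) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                n, len)
  if (gap_prob > 0)
    mat[matrix(runif(n * len) < gap_prob, n, len)] <- "-"
  rownames(mat) <- sprintf("seq%02d_%d", seq_len(n), 1)
  make_aln(apply(mat, 1, paste, collapse = ""))
}

# Two-species alignment mimicking a fixed indel difference: species A
# (primulinum role) gapped at columns 86, 221, 222; species B (cretaceum
# role) gapped at column 89. Everything else identical except one
# substitution column so the sequences are not degenerate.
indel_fixture <- function(n_a = 2, n_b = 2, len = 250) {
  set.seed(604)
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seqs <- list()
  for (i in seq_len(n_a)) {
    s <- base
    s[c(86, 221, 222)] <- "-"
    seqs[[sprintf("primulinum_%d", i)]] <- paste(s, collapse = "")
  }
  for (i in seq_len(n_b)) {
    s <- base
    s[89] <- "-"
    s[10] <- if (base[10] == "A") "G" else "A"
    seqs[[sprintf("cretaceum_%d", i)]] <- paste(s, collapse = "")
  }
  make_aln(unlist(seqs))
}

# A sequence pair with exact transition/transversion proportions P and Q
# over n sites (all ACGT, no missing data).
pq_pair <- function(P, Q, n) {
  n_ts <- round(P * n); n_tv <- round(Q * n)
  a <- rep("A", n)
  b <- a
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"                     # A->G transitions
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"              # A->C transversions
  list(a = a, b = b)
}
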