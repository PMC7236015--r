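#' @importFrom stats optimize setNames
#' @importFrom utils read.delim write.table
NULL

# IUPAC one-letter codes accepted in an aligned DNA sequence.
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Construct a labeled alignment
#'
#' A labeled alignment couples an aligned set of DNA sequences (equal length,
#' gaps allowed) with a sample table assigning each sequence a species label
#' and a source tag (`study` sample or `reference` accession). It is the
#' common input of all downstream statistics.
#'
#' Residues are normalized on ingestion: lowercase is uppercased, `U` becomes
#' `T` and `.` becomes `-`. Any character outside the IUPAC DNA alphabet
#' (plus the gap) is rejected.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   sequence IDs), or a character matrix with one row per sequence and
#'   rownames as IDs.
#' @param table Data frame with columns `sequence_id`, `species`, `source`
#'   (`"study"` or `"reference"`) and `region`. IDs must match `seqs`
#'   one-to-one (checked in both directions).
#' @return An object of class `labeled_alignment` with elements `mat`
#'   (character matrix, rows = sequences), `table`, and `length`.
#' @export
labeled_alignment <- function(seqs, table) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (length(seqs) == 0L) stop("no sequences")
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must carry unique names")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) stop("ragged alignment")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (nrow(mat) < 2L) stop("no sequences: need at least 2")
  mat[mat == "U"] <- "T"
  mat[mat == "."] <- "-"
  bad <- setdiff(unique(as.vector(mat)), IUPAC_CODES)
  if (length(bad) > 0L)
    stop("invalid residue character(s): ", paste(bad, collapse = " "))
  if (!any(mat != "-")) stop("alignment has no non-gap column")

  table <- validate_sample_table(table, rownames(mat))
  structure(list(mat = mat, table = table, length = ncol(mat)),
            class = "labeled_alignment")
}

validate_sample_table <- function(table, ids) {
  required <- c("sequence_id", "species", "source", "region")
  if (!all(required %in% names(table)))
    stop("sample table must have columns: ", paste(required, collapse = ", "))
  table <- as.data.frame(table)[required]
  for (cn in required) table[[cn]] <- as.character(table[[cn]])
  if (anyDuplicated(table$sequence_id))
    stop("table/alignment mismatch: duplicated sequence_id in table")
  if (!setequal(table$sequence_id, ids))
    stop("table/alignment mismatch: IDs differ between table and alignment")
  bad_src <- setdiff(unique(table$source), c("study", "reference"))
  if (length(bad_src) > 0L)
    stop("source must be 'study' or 'reference', got: ",
         paste(bad_src, collapse = " "))
  # order rows to follow the alignment
  table[match(ids, table$sequence_id), , drop = FALSE]
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("labeled_alignment: %d sequences x %d columns, %d species\n",
              nrow(x$mat), x$length, length(unique(x$table$species))))
  invisible(x)
}

#' @export
as.matrix.labeled_alignment <- function(x, ...) x$mat

#' Number of sequences in a labeled alignment
#' @param aln A `labeled_alignment`.
#' @return Integer count of sequences.
#' @export
n_sequences <- function(aln) nrow(aln$mat)

#' Read an aligned FASTA plus sample table
#'
#' Reads an aligned multi-FASTA (wrapped or single-line) and a tab-separated
#' sample table with header `sequence_id  species  source  region`, validates
#' them jointly and returns a [labeled_alignment()]. FASTA IDs are taken as
#' the first whitespace-delimited token of each header.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param table_path Path to the TSV sample table.
#' @return A `labeled_alignment`.
#' @export
read_labeled_alignment <- function(fasta_path, table_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(table_path)) stop("table file not found: ", table_path)
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0L) stop("no sequences")
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  tab <- read.delim(table_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  labeled_alignment(seqs, tab)
}

#' Write a labeled alignment to FASTA + TSV
#'
#' Inverse of [read_labeled_alignment()]: sequences are written single-line
#' so that a read/write round trip preserves IDs, order and residues exactly.
#'
#' @param aln A `labeled_alignment`.
#' @param fasta_path Output FASTA path.
#' @param table_path Output TSV path.
#' @return Invisibly, `aln`.
#' @export
write_labeled_alignment <- function(aln, fasta_path, table_path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, fasta_path, width = max(20001L, aln$length))
  write.table(aln$table, table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(aln)
}

#' Extract an alignment sub-region by reference coordinates
#'
#' Slices all sequences over the alignment columns spanned by positions
#' `ref_start..ref_end` of the *ungapped* reference sequence (1-based,
#' inclusive). This is how a shorter barcode (e.g. ITS2) is cut out of a
#' longer one (full ITS) using an annotated reference present in the
#' alignment. Columns where the reference carries a gap but that fall inside
#' the spanned interval are retained, so the slice can be longer than
#' `ref_end - ref_start + 1`.
#'
#' @param aln A `labeled_alignment`.
#' @param ref_id Sequence ID of the annotated reference.
#' @param ref_start,ref_end 1-based inclusive positions on the ungapped
#'   reference.
#' @return A `labeled_alignment` over the selected columns (all sequences,
#'   reference included).
#' @export
extract_region <- function(aln, ref_id, ref_start, ref_end) {
  if (!ref_id %in% rownames(aln$mat)) stop("reference not found: ", ref_id)
  ref <- aln$mat[ref_id, ]
  nongap <- ref != "-"
  ungapped_len <- sum(nongap)
  if (ref_start < 1 || ref_end < ref_start || ref_end > ungapped_len)
    stop("coordinate error: interval [", ref_start, ",", ref_end,
         "] outside ungapped reference length ", ungapped_len)
  pos <- cumsum(nongap)           # ungapped position at each column (0 before first base)
  col_start <- which(nongap & pos == ref_start)[1]
  col_end   <- which(nongap & pos == ref_end)[1]
  sub <- aln$mat[, col_start:col_end, drop = FALSE]
  structure(list(mat = sub, table = aln$table, length = ncol(sub)),
            class = "labeled_alignment")
}

#' Subset a labeled alignment by sequence IDs
#'
#' @param aln A `labeled_alignment`.
#' @param ids Sequence IDs to keep (order preserved as given).
#' @return A `labeled_alignment` restricted to `ids`.
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, rownames(aln$mat))
  if (length(missing) > 0L)
    stop("table/alignment mismatch: unknown IDs ",
         paste(missing, collapse = " "))
  mat <- aln$mat[ids, , drop = FALSE]
  tab <- aln$table[match(ids, aln$table$sequence_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(mat = mat, table = tab, length = ncol(mat)),
            class = "labeled_alignment")
}
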