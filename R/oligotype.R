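#' Shannon entropy of one alignment column
#'
#' Entropy in bits over the characters of a column,
#' `H = -sum(p_c * log2(p_c))`.  Gaps (`-`) and ambiguity codes count as
#' ordinary characters: silently dropping them would change read counts, so
#' keeping them is the conservative choice.
#'
#' @param column Either a character vector of residues (one per read) or a
#'   named numeric vector of character counts.
#' @return Entropy in bits (>= 0).
#' @examples
#' column_entropy(c("A", "A", "C", "C"))        # 1 bit
#' column_entropy(c(A = 3, C = 1))              # 0.8113 bits
#' @export
column_entropy <- function(column) {
  if (is.numeric(column)) {
    counts <- column
    if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
    counts <- counts[counts > 0]
  } else {
    if (length(column) == 0) stop("empty column")
    counts <- table(as.character(column))
  }
  total <- sum(counts)
  if (total == 0) stop("empty column")
  p <- counts / total
  -sum(p * log2(p))
}

#' Per-column entropy profile of an alignment
#'
#' @param alignment Aligned sequences of equal length: a named character
#'   vector, or a `Biostrings` `XStringSet` (e.g. from
#'   [read_alignment_fasta()]).
#' @return An object of class `entropy_profile`: a list with
#'   `alignment_length`, `entropy` (bits, one value per column) and `counts`
#'   (character-by-column count matrix).
#' @export
entropy_profile <- function(alignment) {
  seqs <- as_aligned_chars(alignment)
  mat <- seqs$mat
  counts <- apply(mat, 2, function(col) table(factor(col, levels = sort(unique(as.vector(mat))))))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(sort(unique(as.vector(mat))), NULL))
  entropy <- apply(mat, 2, column_entropy)
  structure(list(alignment_length = ncol(mat), entropy = as.numeric(entropy),
                 counts = counts),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy profile over %d columns; max %.4f bits at column %d\n",
              x$alignment_length, max(x$entropy), which.max(x$entropy)))
  invisible(x)
}

## normalize alignment input to a reads x columns character matrix
as_aligned_chars <- function(alignment) {
  if (inherits(alignment, "XStringSet")) {
    ids <- names(alignment)
    strings <- as.character(alignment)
  } else {
    ids <- names(alignment)
    strings <- as.character(alignment)
  }
  if (length(strings) == 0) stop("alignment has no sequences")
  if (is.null(ids)) ids <- paste0("read_", seq_along(strings))
  lens <- nchar(strings)
  if (length(unique(lens)) > 1) {
    off <- which(lens != lens[1])[1]
    stop("ragged alignment: sequence '", ids[off], "' has length ", lens[off],
         ", expected ", lens[1])
  }
  if (lens[1] < 1) stop("alignment length must be >= 1")
  mat <- do.call(rbind, strsplit(toupper(strings), "", fixed = TRUE))
  rownames(mat) <- ids
  list(mat = mat, ids = ids)
}

#' Select the highest-entropy alignment columns
#'
#' Returns the indices (1-based, ascending) of the `k` columns with the
#' largest entropy; ties are broken toward the smaller index.  The classical
#' oligotyping choice for SSU rRNA amplicons is `k = 2`.
#'
#' @param profile An [entropy_profile()].
#' @param k Number of components (positive, at most the alignment length).
#' @return Integer vector of `k` column indices, ascending.
#' @export
select_components <- function(profile, k = 2) {
  stopifnot(inherits(profile, "entropy_profile"))
  if (k <= 0) stop("k must be a positive integer")
  if (k > profile$alignment_length)
    stop("k exceeds the alignment length (", profile$alignment_length, ")")
  ord <- order(-profile$entropy, seq_along(profile$entropy))
  sort(ord[seq_len(k)])
}

#' Decompose an alignment into oligotypes
#'
#' Assigns each read the label formed by its residues at the selected
#' high-entropy positions and tabulates labels per sample.  No minimum
#' abundance or sample-count filtering is applied, and decomposition is a
#' single pass (oligotypes are not recursively re-decomposed).
#'
#' Reads are mapped to samples either through `sample_of` or, by default, by
#' splitting each read identifier at its last underscore
#' (`<sample>_<serial>`, the common amplicon convention).
#'
#' @param alignment As in [entropy_profile()].
#' @param positions Integer vector of alignment columns (1-based).
#' @param sample_of Optional named character vector mapping read identifiers
#'   to sample names; every read must be covered.
#' @return An object of class `oligotype_table`: a list with `positions`,
#'   `counts` (oligotype x sample integer matrix, rows ordered by descending
#'   total count, ties alphabetical) and `percents` (same shape, per-sample
#'   percentages summing to 100).
#' @export
decompose <- function(alignment, positions, sample_of = NULL) {
  seqs <- as_aligned_chars(alignment)
  mat <- seqs$mat
  positions <- as.integer(positions)
  if (length(positions) == 0) stop("positions must not be empty")
  if (any(positions < 1 | positions > ncol(mat)))
    stop("position out of range 1..", ncol(mat))

  if (is.null(sample_of)) {
    has_us <- grepl("_", seqs$ids, fixed = TRUE)
    if (any(!has_us))
      stop("cannot infer sample for read '", seqs$ids[!has_us][1],
           "': no '<sample>_<serial>' identifier and no sample_of mapping")
    smp <- sub("_[^_]*$", "", seqs$ids)
  } else {
    missing <- setdiff(seqs$ids, names(sample_of))
    if (length(missing))
      stop("read '", missing[1], "' is absent from sample_of")
    smp <- unname(sample_of[seqs$ids])
  }

  labels <- apply(mat[, positions, drop = FALSE], 1, paste, collapse = "")
  counts <- table(labels, smp)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), colnames(counts)))
  ord <- order(-rowSums(counts), rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  totals <- colSums(counts)
  percents <- sweep(counts, 2, pmax(totals, 1), "/") * 100

  structure(list(positions = positions, counts = counts, percents = percents),
            class = "oligotype_table")
}

#' @export
print.oligotype_table <- function(x, ...) {
  cat(sprintf("oligotype table: %d oligotypes x %d samples (positions %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$positions, collapse = ", ")))
  invisible(x)
}

#' Full oligotyping pipeline
#'
#' Convenience wrapper: computes the entropy profile, selects the `k`
#' highest-entropy columns and decomposes the alignment.
#'
#' @inheritParams decompose
#' @param k Number of entropy components (default 2).
#' @return An `oligotype_table` (see [decompose()]).
#' @export
oligotype <- function(alignment, k = 2, sample_of = NULL) {
  profile <- entropy_profile(alignment)
  positions <- select_components(profile, k)
  decompose(alignment, positions, sample_of)
}
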