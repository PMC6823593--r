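read_lines_checked <- function(path) {
  if (!file.exists(path)) fail("cannot open file '", path, "'")
  readLines(path)
}

## Shared parser for the mothur tabular dialects (.relabund and .shared):
## tab-delimited, header `label<TAB>Group<TAB>numOtus<TAB><taxon>...`,
## one row per sample.  Only the first OTU-definition label block is read.
parse_mothur_table <- function(path, integer_cells = FALSE) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) fail("'", path, "': empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 || tolower(header[1]) != "label" ||
      header[2] != "Group" || tolower(header[3]) != "numotus")
    fail("'", path, "': expected mothur header 'label<TAB>Group<TAB>numOtus<TAB>...'")
  taxa <- header[-(1:3)]
  if (anyDuplicated(taxa)) fail("'", path, "': duplicated taxon column: ",
                                taxa[duplicated(taxa)][1])
  body <- lines[-1]
  if (!length(body)) fail("'", path, "': no samples")

  rows <- strsplit(body, "\t", fixed = TRUE)
  label <- vapply(rows, `[`, "", 1)
  keep <- label == label[1]
  if (!all(keep)) {
    warning("'", path, "': multiple label blocks; reading only label '",
            label[1], "'")
    rows <- rows[keep]
  }
  groups <- vapply(rows, `[`, "", 2)
  dup <- groups[duplicated(groups)]
  if (length(dup)) fail("'", path, "': duplicate sample (Group) '", dup[1], "'")

  vals <- matrix(NA_real_, nrow = length(taxa), ncol = length(rows),
                 dimnames = list(taxa, groups))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != 3 + length(taxa))
      fail("'", path, "': row for sample '", groups[i], "' has ",
           length(r) - 3, " value(s), expected ", length(taxa))
    n_declared <- suppressWarnings(as.numeric(r[3]))
    if (is.na(n_declared) || n_declared != length(taxa))
      fail("'", path, "': numOtus (", r[3], ") of sample '", groups[i],
           "' does not match the ", length(taxa), " taxon columns")
    cells <- suppressWarnings(as.numeric(r[-(1:3)]))
    if (anyNA(cells)) {
      j <- which(is.na(cells))[1]
      fail("'", path, "': non-numeric value '", r[3 + j], "' for sample '",
           groups[i], "', taxon '", taxa[j], "'")
    }
    if (integer_cells && any(cells != round(cells))) {
      j <- which(cells != round(cells))[1]
      fail("'", path, "': non-integer count '", r[3 + j], "' for sample '",
           groups[i], "', taxon '", taxa[j], "'")
    }
    vals[, i] <- cells
  }
  list(values = vals, label = label[1])
}

#' Read a mothur relative-abundance (.relabund) file
#'
#' The dialect is tab-delimited with header
#' `label Group numOtus <taxon1> ...` and one row per sample; cells already
#' hold fractions and are not rescaled.  Only the first OTU-definition label
#' block is read (a warning is raised if more exist).
#'
#' @param path Path to the file.
#' @return An [abundance_matrix()]; taxa in column order of the file, samples
#'   in row order.
#' @export
read_mothur_relabund <- function(path) {
  p <- parse_mothur_table(path)
  abundance_matrix(p$values, label = p$label)
}

#' Write a mothur relative-abundance (.relabund) file
#'
#' Inverse of [read_mothur_relabund()]; values are written with enough digits
#' that a read-back reproduces them to well below 1e-9.
#'
#' @param x An [abundance_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mothur_relabund <- function(x, path) {
  stopifnot(inherits(x, "abund_matrix"))
  label <- if (is.null(x$label)) "1" else x$label
  lines <- c(paste(c("label", "Group", "numOtus", taxa(x)), collapse = "\t"),
             vapply(seq_along(samples(x)), function(j) {
               paste(c(label, samples(x)[j], length(taxa(x)),
                       num_token(x$values[, j])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a mothur .shared count file
#'
#' Same layout as the relabund dialect but with integer read counts.
#'
#' @param path Path to the file.
#' @return A [count_matrix()].
#' @export
read_mothur_shared <- function(path) {
  p <- parse_mothur_table(path, integer_cells = TRUE)
  count_matrix(p$values, label = p$label)
}

#' Read an oligotyping matrix_percents.txt file
#'
#' Tab-delimited with header `samples <oligo1> ...` and one row per sample;
#' cells are percentages in `[0, 100]` and are converted to fractions so that
#' the package-internal unit is uniform.
#'
#' @param path Path to the file.
#' @return An [abundance_matrix()] (fractions).
#' @export
read_oligotyping_matrix_percent <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) fail("'", path, "': empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || tolower(header[1]) != "samples")
    fail("'", path, "': expected oligotyping header 'samples<TAB><oligotype>...'")
  oligos <- header[-1]
  if (anyDuplicated(oligos))
    fail("'", path, "': duplicated oligotype column: ",
         oligos[duplicated(oligos)][1])
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (!length(rows)) fail("'", path, "': no samples")
  smp <- vapply(rows, `[`, "", 1)
  dup <- smp[duplicated(smp)]
  if (length(dup)) fail("'", path, "': duplicate sample row '", dup[1], "'")

  vals <- matrix(NA_real_, nrow = length(oligos), ncol = length(rows),
                 dimnames = list(oligos, smp))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != 1 + length(oligos))
      fail("'", path, "': row '", smp[i], "' has ", length(r) - 1,
           " value(s), expected ", length(oligos))
    cells <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(cells)) {
      j <- which(is.na(cells))[1]
      fail("'", path, "': non-numeric value '", r[1 + j], "' in row '",
           smp[i], "'")
    }
    if (any(cells < 0 | cells > 100)) {
      j <- which(cells < 0 | cells > 100)[1]
      fail("'", path, "': percentage ", cells[j], " outside [0, 100] in row '",
           smp[i], "', column '", oligos[j], "'")
    }
    vals[, i] <- cells / 100
  }
  abundance_matrix(vals)
}

#' Write a matrix_percents.txt file
#'
#' Writes either an [abundance_matrix()] (fractions are converted to
#' percentages at full precision) or an `oligotype_table` from [decompose()]
#' (percentages with six decimals, the native look of the dialect).
#'
#' @param x An `abund_matrix` or `oligotype_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_percent <- function(x, path) UseMethod("write_matrix_percent")

#' @export
write_matrix_percent.abund_matrix <- function(x, path) {
  write_percent_table(taxa(x), samples(x), x$values * 100, path,
                      formatter = num_token)
}

#' @export
write_matrix_percent.oligotype_table <- function(x, path) {
  write_percent_table(rownames(x$percents), colnames(x$percents), x$percents,
                      path, formatter = function(v) sprintf("%.6f", v))
}

write_percent_table <- function(row_ids, col_ids, values, path, formatter) {
  lines <- c(paste(c("samples", row_ids), collapse = "\t"),
             vapply(seq_along(col_ids), function(j) {
               paste(c(col_ids[j], formatter(values[, j])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-to-region metadata table
#'
#' Two-column tab-delimited file `sample<TAB>region`, with or without a header
#' (a header is assumed when the first token of the first line is `sample`).
#' Any number of regions is allowed here; network annotation downstream
#' requires exactly two.
#'
#' @param path Path to the file.
#' @return Named character vector mapping sample names to region labels
#'   (empty for an empty file).
#' @export
read_sample_metadata <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(rows[[1]][1]) == "sample") rows <- rows[-1]
  if (!length(rows)) return(stats::setNames(character(0), character(0)))
  bad <- which(vapply(rows, length, 0L) != 2)
  if (length(bad)) fail("'", path, "': line ", bad[1],
                        " does not have exactly 2 tab-separated fields")
  smp <- vapply(rows, `[`, "", 1)
  dup <- smp[duplicated(smp)]
  if (length(dup)) fail("'", path, "': duplicate sample '", dup[1], "'")
  stats::setNames(vapply(rows, `[`, "", 2), smp)
}

#' Read an aligned FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; sequence descriptions are
#' truncated at the first whitespace so identifiers match mapping files.
#'
#' @param path Path to a FASTA file of equal-length aligned sequences.
#' @return A named character vector of sequences.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
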