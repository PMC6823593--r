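#' Relative-abundance matrix
#'
#' The central data container of the package: a dense taxa-by-samples table of
#' relative abundances expressed as fractions in `[0, 1]`.  Rows are taxa (OTUs,
#' genera or oligotypes), columns are samples.  An optional `region_of` mapping
#' attaches a region/site label to each sample; downstream node categorisation
#' requires exactly two regions.
#'
#' The package stores one canonical unit internally -- fractions -- regardless
#' of the on-disk dialect (the oligotyping dialect stores percents and is
#' converted at the boundary).
#'
#' @param values Numeric matrix with unique rownames (taxa) and unique colnames
#'   (samples); all entries in `[0, 1]`, no missing values.
#' @param region_of Optional named character vector mapping sample names to
#'   region labels.  Every name must be a sample of `values`.
#' @param label Optional OTU-definition label carried over from mothur files
#'   (e.g. `"0.03"`); metadata only, never used by any algorithm.
#' @return An object of class `abund_matrix` with elements `values`,
#'   `region_of` and `label`.
#' @examples
#' m <- abundance_matrix(matrix(c(0.25, 0.75, 0.1, 0.9), nrow = 2,
#'                              dimnames = list(c("OtuA", "OtuB"), c("S1", "S2"))))
#' taxa(m)
#' samples(m)
#' @export
abundance_matrix <- function(values, region_of = NULL, label = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (anyNA(values)) stop("abundance values must not contain missing values")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated taxon name: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample name: ", colnames(values)[duplicated(colnames(values))][1])
  if (any(values < 0)) stop("abundance values must be >= 0")
  if (any(values > 1 + 1e-9)) stop("abundance values must be <= 1 (fractions, not percents)")
  values[values > 1] <- 1
  if (!is.null(region_of)) {
    region_of <- check_region_map(region_of, colnames(values))
  }
  structure(list(values = values, region_of = region_of, label = label),
            class = "abund_matrix")
}

check_region_map <- function(region_of, sample_names) {
  region_of <- unlist(region_of)
  if (is.null(names(region_of)) || any(!nzchar(names(region_of))))
    stop("region_of must be a named vector (sample -> region)")
  bad <- setdiff(names(region_of), sample_names)
  if (length(bad)) stop("region_of refers to unknown sample: ", bad[1])
  storage.mode(region_of) <- "character"
  region_of
}

#' Read-count matrix
#'
#' Taxa-by-samples table of non-negative integer read counts, the input for
#' alpha-diversity estimation and rarefaction.
#'
#' @param counts Numeric matrix of non-negative integers with unique taxon
#'   rownames and sample colnames.
#' @param label Optional OTU-definition label (metadata only).
#' @return An object of class `count_matrix` with elements `counts` and `label`.
#' @export
count_matrix <- function(counts, label = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts must not contain missing values")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated taxon name: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample name: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, label = label), class = "count_matrix")
}

#' @rdname abundance_matrix
#' @param x An `abund_matrix` or `count_matrix`.
#' @export
taxa <- function(x) UseMethod("taxa")

#' @export
taxa.abund_matrix <- function(x) rownames(x$values)

#' @export
taxa.count_matrix <- function(x) rownames(x$counts)

#' @rdname abundance_matrix
#' @export
samples <- function(x) UseMethod("samples")

#' @export
samples.abund_matrix <- function(x) colnames(x$values)

#' @export
samples.count_matrix <- function(x) colnames(x$counts)

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("abundance matrix: %d taxa x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$region_of))
    cat("regions:", paste(sort(unique(x$region_of)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count matrix: %d taxa x %d samples, %s reads\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts))))
  invisible(x)
}
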