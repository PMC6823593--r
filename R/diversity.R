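#' Alpha-diversity summary for one sample
#'
#' Computes the mothur-style estimator set for a single sample's taxon counts:
#'
#' * `sobs` -- observed taxa, the number of counts > 0;
#' * `coverage` -- Good's coverage `1 - n1/N` (n1 = singletons, N = reads);
#' * `chao1` -- bias-corrected Chao1 richness
#'   `sobs + n1*(n1-1) / (2*(n2+1))` (n2 = doubletons);
#' * `shannon` -- plug-in Shannon entropy `-sum(p_i * log(p_i))` in nats;
#' * `np_shannon` -- the Chao-Shen coverage-adjusted ("non-parametric")
#'   Shannon estimator
#'   `-sum( C*p_i * log(C*p_i) / (1 - (1 - C*p_i)^N) )` with `C = 1 - n1/N`;
#' * `invsimpson` -- the unbiased finite-sample inverse Simpson index
#'   `1 / sum( n_i*(n_i-1) / (N*(N-1)) )`;
#' * `evenness` -- Shannon evenness `shannon / log(sobs)`.
#'
#' `invsimpson` is undefined (returned as `NA`) when every taxon is a
#' singleton, `evenness` when `sobs == 1`, and `np_shannon` when coverage is 0
#' (every read a singleton).
#'
#' @param counts Non-negative integer vector of per-taxon read counts for one
#'   sample; the total must be >= 1.
#' @return One-row data frame with columns `nseqs`, `sobs`, `coverage`,
#'   `chao1`, `shannon`, `np_shannon`, `invsimpson`, `evenness`.
#' @examples
#' alpha_summary(rep(100, 10))  # uniform community: evenness 1, coverage 1
#' @export
alpha_summary <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("sample has no reads (total count is 0)")
  obs <- counts[counts > 0]
  sobs <- length(obs)
  n1 <- sum(obs == 1)
  n2 <- sum(obs == 2)
  p <- obs / n

  coverage <- 1 - n1 / n
  chao1 <- sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
  shannon <- -sum(p * log(p))

  np_shannon <- if (coverage > 0) {
    cp <- coverage * p
    -sum(cp * log(cp) / (1 - (1 - cp)^n))
  } else NA_real_

  d2 <- sum(obs * (obs - 1))
  invsimpson <- if (d2 > 0) n * (n - 1) / d2 else NA_real_
  evenness <- if (sobs >= 2) shannon / log(sobs) else NA_real_

  data.frame(nseqs = n, sobs = sobs, coverage = coverage, chao1 = chao1,
             shannon = shannon, np_shannon = np_shannon,
             invsimpson = invsimpson, evenness = evenness)
}

#' Alpha diversity for every sample of a count matrix
#'
#' Applies [alpha_summary()] to each sample (column).  Column order follows
#' the usual mothur summary layout: observed richness, Good's coverage, Chao1,
#' the coverage-adjusted (non-parametric) Shannon, plug-in Shannon, inverse
#' Simpson and Shannon evenness.
#'
#' @param x A [count_matrix()]; every sample must have at least one read.
#' @return Data frame with one row per sample (`group` column first).
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  rows <- lapply(seq_len(ncol(x$counts)), function(j) alpha_summary(x$counts[, j]))
  out <- cbind(data.frame(group = colnames(x$counts)), do.call(rbind, rows))
  out <- out[, c("group", "nseqs", "sobs", "coverage", "chao1",
                 "np_shannon", "shannon", "invsimpson", "evenness")]
  rownames(out) <- NULL
  out
}

#' Rarefy a count matrix to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, emulating normalisation to the lowest sequencing effort.  One random
#' draw is taken per sample; the result is deterministic given `seed`.  A
#' taxon absent before rarefaction is never invented.
#'
#' @param x A [count_matrix()].
#' @param depth Target reads per sample; defaults to the smallest per-sample
#'   total.  Must not exceed any sample's total.
#' @param seed Integer seed.
#' @return A [count_matrix()] whose per-sample totals all equal `depth`.
#' @export
rarefy <- function(x, depth = NULL, seed = 0) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- colSums(x$counts)
  if (any(totals < 1)) stop("sample has no reads: ",
                            colnames(x$counts)[which(totals < 1)[1]])
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be a positive integer")
  low <- totals < depth
  if (any(low))
    stop("depth ", depth, " exceeds the total of sample ",
         colnames(x$counts)[which(low)[1]], " (", totals[which(low)[1]], ")")
  out <- with_seed(seed, {
    apply(x$counts, 2, function(col) {
      reads <- rep.int(seq_along(col), col)
      kept <- sample(reads, depth, replace = FALSE)
      tabulate(kept, nbins = length(col))
    })
  })
  dimnames(out) <- dimnames(x$counts)
  count_matrix(out, label = x$label)
}
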