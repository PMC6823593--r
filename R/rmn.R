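#' Parameters of the rule-based network inference
#'
#' @param theta_min Minimum relative abundance (fraction) a taxon must reach in
#'   at least one sample to enter the network and to count as "present" at a
#'   site.  Default 0.001, i.e. 0.1 % relative abundance.
#' @param epsilon Half-width of the steady band used to discretize abundance
#'   changes: a change with `|after - before| <= epsilon` is classified STEADY.
#'   Default 0.001 (fraction units).  Set to 0 on noiseless data to classify by
#'   sign alone.
#' @param pair_mode How sample pairs are formed: `"all_pairs"` (every unordered
#'   pair of samples, oriented by column order; the default, suited to
#'   cross-sectional designs) or `"consecutive"` (adjacent columns, suited to
#'   time series).
#' @param m_min Minimum number of informative (predictive) sample pairs a
#'   triplet needs before it can be accepted.  Default 3.
#' @param s_min Minimum conformity score
#'   `(support - contradiction) / informative` for acceptance, in `[-1, 1]`.
#'   The default 1.0 accepts only triplets with zero contradictions -- the
#'   strictest reading of "conforms to the model".
#' @return An object of class `rmn_params`.
#' @export
rmn_params <- function(theta_min = 0.001, epsilon = 0.001,
                       pair_mode = c("all_pairs", "consecutive"),
                       m_min = 3, s_min = 1.0) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(theta_min >= 0, epsilon >= 0, m_min >= 1,
            s_min >= -1, s_min <= 1)
  structure(list(theta_min = theta_min, epsilon = epsilon,
                 pair_mode = pair_mode, m_min = as.integer(m_min),
                 s_min = s_min),
            class = "rmn_params")
}

#' Drop taxa that never reach a minimum relative abundance
#'
#' Retains taxa whose maximum relative abundance over all samples is at least
#' `theta_min`; sample set and taxon order are unchanged.
#'
#' @param x An [abundance_matrix()].
#' @param theta_min Abundance threshold (fraction).
#' @return An `abund_matrix` with a (possibly empty) subset of the taxa.
#' @export
filter_taxa <- function(x, theta_min = 0.001) {
  stopifnot(inherits(x, "abund_matrix"), theta_min >= 0)
  keep <- apply(x$values, 1, max) >= theta_min
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out
}

#' Discretize an abundance change
#'
#' Classifies the change from `before` to `after` as `"UP"` when
#' `after - before > epsilon`, `"DOWN"` when `before - after > epsilon`, and
#' `"STEADY"` otherwise.  Vectorised over `before`/`after`.
#'
#' @param before,after Relative abundances (fractions).
#' @param epsilon Steady-band half-width.
#' @return Character vector in `{"UP", "DOWN", "STEADY"}`.
#' @export
classify_change <- function(before, after, epsilon = 0.001) {
  stopifnot(epsilon >= 0)
  d <- after - before
  out <- rep("STEADY", length(d))
  out[d > epsilon] <- "UP"
  out[d < -epsilon] <- "DOWN"
  out
}

#' Enumerate ordered sample pairs
#'
#' @param samples Ordered vector of sample identifiers.
#' @param pair_mode `"all_pairs"` or `"consecutive"` (see [rmn_params()]).
#' @return Two-column character (or integer) matrix with columns `before` and
#'   `after`; zero rows for fewer than two samples.
#' @export
sample_pairs <- function(samples, pair_mode = c("all_pairs", "consecutive")) {
  pair_mode <- match.arg(pair_mode)
  n <- length(samples)
  if (n < 2) {
    m <- matrix(samples[0], ncol = 2)
  } else if (pair_mode == "consecutive") {
    m <- cbind(samples[-n], samples[-1])
  } else {
    idx <- utils::combn(n, 2)
    m <- cbind(samples[idx[1, ]], samples[idx[2, ]])
  }
  colnames(m) <- c("before", "after")
  m
}

## Signed change codes for every taxon over every sample pair:
## +1 UP, -1 DOWN, 0 STEADY.  Rows taxa, columns pairs.
change_code_matrix <- function(values, pairs_idx, epsilon) {
  d <- values[, pairs_idx[, 2], drop = FALSE] - values[, pairs_idx[, 1], drop = FALSE]
  (d > epsilon) - (d < -epsilon)
}

pair_index_matrix <- function(n, pair_mode) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (pair_mode == "consecutive") cbind(seq_len(n - 1), 2:n)
  else t(utils::combn(n, 2))
}

#' Test one (target, cooperator, competitor) triplet against the rule model
#'
#' For every sample pair, the cooperator's and competitor's abundance changes
#' are discretized (see [classify_change()]).  A pair is *predictive* when the
#' cooperator goes UP while the competitor goes DOWN (the model then predicts
#' the target goes UP) or vice versa (target predicted DOWN).  On predictive
#' pairs, a target change matching the prediction counts as support; an
#' opposite or STEADY target change counts as contradiction.  Non-predictive
#' pairs are ignored.  The conformity score is
#' `(support - contradiction) / informative` and the triplet is accepted when
#' `informative >= m_min` and `score >= s_min`.
#'
#' @param x An [abundance_matrix()].
#' @param target,cooperator,competitor Distinct taxon identifiers present in `x`.
#' @param params An [rmn_params()] object.
#' @return A one-row data frame with columns `target`, `cooperator`,
#'   `competitor`, `support`, `contradiction`, `informative`, `score`,
#'   `accepted`.
#' @export
evaluate_triplet <- function(x, target, cooperator, competitor,
                             params = rmn_params()) {
  stopifnot(inherits(x, "abund_matrix"), inherits(params, "rmn_params"))
  trio <- c(target, cooperator, competitor)
  if (anyDuplicated(trio))
    stop("target, cooperator and competitor must be three distinct taxa")
  missing <- setdiff(trio, taxa(x))
  if (length(missing)) stop("taxon not in matrix: ", missing[1])

  pairs_idx <- pair_index_matrix(ncol(x$values), params$pair_mode)
  cls <- change_code_matrix(x$values[trio, , drop = FALSE], pairs_idx,
                            params$epsilon)
  cbind(data.frame(target = target, cooperator = cooperator,
                   competitor = competitor),
        triplet_counts(cls[1, ], cls[2, ], cls[3, ], params))
}

triplet_counts <- function(cls_target, cls_coop, cls_comp, params) {
  pred_up <- cls_coop == 1L & cls_comp == -1L
  pred_down <- cls_coop == -1L & cls_comp == 1L
  support <- sum(cls_target[pred_up] == 1L) + sum(cls_target[pred_down] == -1L)
  informative <- sum(pred_up) + sum(pred_down)
  contradiction <- informative - support
  score <- if (informative > 0) (support - contradiction) / informative else 0
  data.frame(support = support, contradiction = contradiction,
             informative = informative, score = score,
             accepted = informative >= params$m_min & score >= params$s_min)
}

#' Evaluate every ordered taxon triplet
#'
#' Runs [evaluate_triplet()] for all ordered triplets of distinct taxa in `x`
#' (after no filtering -- apply [filter_taxa()] first if desired).
#'
#' @inheritParams evaluate_triplet
#' @return Data frame with one row per ordered triplet, columns as in
#'   [evaluate_triplet()].
#' @export
evaluate_all_triplets <- function(x, params = rmn_params()) {
  stopifnot(inherits(x, "abund_matrix"), inherits(params, "rmn_params"))
  tx <- taxa(x)
  nt <- length(tx)
  if (nt < 3) stop("need at least 3 taxa to enumerate triplets")
  if (ncol(x$values) < 2) stop("need at least 2 samples")

  pairs_idx <- pair_index_matrix(ncol(x$values), params$pair_mode)
  cls <- change_code_matrix(x$values, pairs_idx, params$epsilon)

  res <- vector("list", nt * (nt - 1) * (nt - 2))
  k <- 0L
  for (ci in seq_len(nt)) for (ki in seq_len(nt)) {
    if (ki == ci) next
    pred_up <- cls[ci, ] == 1L & cls[ki, ] == -1L
    pred_down <- cls[ci, ] == -1L & cls[ki, ] == 1L
    informative <- sum(pred_up) + sum(pred_down)
    for (ti in seq_len(nt)) {
      if (ti == ci || ti == ki) next
      support <- sum(cls[ti, pred_up] == 1L) + sum(cls[ti, pred_down] == -1L)
      contradiction <- informative - support
      score <- if (informative > 0) (support - contradiction) / informative else 0
      k <- k + 1L
      res[[k]] <- list(tx[ti], tx[ci], tx[ki], support, contradiction,
                       informative, score)
    }
  }
  out <- data.frame(
    target = vapply(res, `[[`, "", 1),
    cooperator = vapply(res, `[[`, "", 2),
    competitor = vapply(res, `[[`, "", 3),
    support = vapply(res, `[[`, 0, 4),
    contradiction = vapply(res, `[[`, 0, 5),
    informative = vapply(res, `[[`, 0, 6),
    score = vapply(res, `[[`, 0, 7))
  out$accepted <- out$informative >= params$m_min & out$score >= params$s_min
  out
}

#' Infer the rule-based interaction network
#'
#' Filters taxa at `params$theta_min`, evaluates every ordered triplet of the
#' remaining taxa, and assembles accepted triplets into a directed signed
#' network: each accepted triplet contributes a cooperative edge
#' cooperator -> target and a competitive edge competitor -> target.  Parallel
#' edges of the same sign are merged; the merged weight is the maximum
#' conformity score among contributing triplets and `n_triplets` counts them.
#' By construction, every node with an incoming cooperative edge also has at
#' least one incoming competitive edge.
#'
#' @param x An [abundance_matrix()].
#' @param params An [rmn_params()] object.
#' @param region_of Optional sample -> region mapping (exactly two regions)
#'   used to annotate nodes via [annotate_site_category()]; defaults to the
#'   mapping stored in `x`, if any.
#' @return An [rmn_network()] object.  The full triplet table is attached as
#'   attribute `"triplets"`.
#' @export
infer_network <- function(x, params = rmn_params(), region_of = x$region_of) {
  stopifnot(inherits(x, "abund_matrix"))
  xf <- filter_taxa(x, params$theta_min)
  if (nrow(xf$values) < 3)
    stop("fewer than 3 taxa remain after abundance filtering")
  if (ncol(xf$values) < 2) stop("need at least 2 samples")

  trip <- evaluate_all_triplets(xf, params)
  acc <- trip[trip$accepted, , drop = FALSE]

  if (nrow(acc) == 0) {
    edges <- empty_edge_frame()
  } else {
    long <- rbind(
      data.frame(source = acc$cooperator, target = acc$target,
                 sign = "cooperative", score = acc$score),
      data.frame(source = acc$competitor, target = acc$target,
                 sign = "competitive", score = acc$score))
    key <- paste(long$source, long$target, long$sign, sep = "\r")
    weight <- tapply(long$score, key, max)
    n_triplets <- tapply(long$score, key, length)
    parts <- do.call(rbind, strsplit(names(weight), "\r", fixed = TRUE))
    edges <- data.frame(source = parts[, 1], target = parts[, 2],
                        sign = parts[, 3],
                        weight = as.numeric(weight),
                        n_triplets = as.integer(n_triplets))
    edges <- edges[order(edges$source, edges$target, edges$sign), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }

  node_ids <- sort(unique(c(edges$source, edges$target)))
  max_ab <- if (length(node_ids))
    apply(x$values[node_ids, , drop = FALSE], 1, max) else numeric(0)
  category <- if (!is.null(region_of) && length(node_ids)) {
    unname(annotate_site_category(x, region_of, params$theta_min)[node_ids])
  } else rep(NA_character_, length(node_ids))
  nodes <- data.frame(taxon = node_ids, category = category,
                      max_abundance = unname(max_ab))

  net <- rmn_network(nodes, edges)
  attr(net, "triplets") <- trip
  net
}

#' Categorise taxa by site presence
#'
#' A taxon is "present" in a region when its maximum relative abundance over
#' that region's samples reaches `theta_min`.  With exactly two regions
#' (regionA = lexicographically smaller label), each taxon is assigned one of
#' `both`, `<regionA>_only`, `<regionB>_only` or `below_threshold`.
#'
#' @param x An [abundance_matrix()].
#' @param region_of Named character vector mapping every sample of `x` to one
#'   of exactly two region labels.
#' @param theta_min Presence threshold (fraction).
#' @return Named character vector over the taxa of `x`.
#' @export
annotate_site_category <- function(x, region_of = x$region_of,
                                   theta_min = 0.001) {
  stopifnot(inherits(x, "abund_matrix"))
  if (is.null(region_of)) stop("region_of is required")
  region_of <- check_region_map(region_of, samples(x))
  missing <- setdiff(samples(x), names(region_of))
  if (length(missing)) stop("sample without region label: ", missing[1])
  regions <- sort(unique(region_of))
  if (length(regions) != 2)
    stop("exactly 2 regions are required, got ", length(regions))

  in_a <- apply(x$values[, names(region_of)[region_of == regions[1]],
                         drop = FALSE], 1, max) >= theta_min
  in_b <- apply(x$values[, names(region_of)[region_of == regions[2]],
                         drop = FALSE], 1, max) >= theta_min
  out <- rep("below_threshold", nrow(x$values))
  out[in_a & in_b] <- "both"
  out[in_a & !in_b] <- paste0(regions[1], "_only")
  out[!in_a & in_b] <- paste0(regions[2], "_only")
  names(out) <- taxa(x)
  out
}
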