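#' Specification of a synthetic community with planted interactions
#'
#' Describes a simulated multi-sample relative-abundance matrix in which one or
#' more (target, cooperator, competitor) triplets are planted: the target's
#' abundance is a linear response to its regulators, all other taxa form a
#' random background community.  Used to benchmark [infer_network()] against a
#' known truth.
#'
#' The background community is drawn per sample from a symmetric Dirichlet
#' distribution (independent gamma draws renormalised) over the non-target
#' taxa.  Each planted target is then set to
#' `baseline + beta_coop * cooperator - beta_comp * competitor + noise`,
#' floored at `1e-6`, and the sample is renormalised to sum to one (real
#' relative-abundance data are compositional, so the closure is deliberate).
#'
#' @param n_taxa Total number of taxa (>= 3).
#' @param n_samples Number of samples (>= 2).
#' @param planted List of integer triples `c(target, cooperator, competitor)`
#'   (1-based taxon indices, distinct within each triple).  Regulators must not
#'   themselves be targets.  Default: one triplet, taxa 1-3.
#' @param beta_coop,beta_comp Response strengths (positive).
#' @param noise_sd Standard deviation of Gaussian noise added to each planted
#'   target's raw abundance (fraction units); 0 for a noiseless community.
#' @param baseline Constant baseline (raw units) of each planted target.  The
#'   default 0.5 keeps the response positive for any regulator draw, so the
#'   floor is never active in noiseless data.
#' @param baseline_concentration Dirichlet concentration of the background
#'   community; 1 gives a flat Dirichlet, smaller values give sparser, more
#'   uneven communities.
#' @param n_regions Number of region labels to assign (samples are split into
#'   contiguous blocks); default 2, labels `siteA`, `siteB`, ...
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_taxa = 8, n_samples = 40,
                           planted = list(c(1L, 2L, 3L)),
                           beta_coop = 0.5, beta_comp = 0.5,
                           noise_sd = 0, baseline = 0.5,
                           baseline_concentration = 1,
                           n_regions = 2, seed = 1) {
  stopifnot(n_taxa >= 3, n_samples >= 2, beta_coop > 0, beta_comp > 0,
            noise_sd >= 0, baseline >= 0, baseline_concentration > 0,
            n_regions >= 1)
  planted <- lapply(planted, function(p) as.integer(p))
  for (p in planted) {
    if (length(p) != 3) stop("each planted triple must have 3 indices")
    if (anyDuplicated(p)) stop("planted triple has duplicate indices")
    if (any(p < 1 | p > n_taxa)) stop("planted index out of range")
  }
  targets <- vapply(planted, `[`, 0L, 1)
  if (anyDuplicated(targets)) stop("two planted triples share a target")
  regs <- unlist(lapply(planted, `[`, 2:3))
  if (any(regs %in% targets))
    stop("a planted regulator may not itself be a planted target")
  structure(list(n_taxa = as.integer(n_taxa), n_samples = as.integer(n_samples),
                 planted = planted, beta_coop = beta_coop,
                 beta_comp = beta_comp, noise_sd = noise_sd,
                 baseline = baseline,
                 baseline_concentration = baseline_concentration,
                 n_regions = as.integer(n_regions), seed = as.integer(seed)),
            class = "synthetic_spec")
}

synth_taxa_names <- function(n) sprintf("taxon%02d", seq_len(n))
synth_sample_names <- function(n) sprintf("sample%02d", seq_len(n))

#' Simulate a structureless background community
#'
#' Each sample is an independent draw from a symmetric Dirichlet distribution
#' (gamma draws renormalised to sum to one); there are no planted
#' interactions.
#'
#' @param n_taxa,n_samples Matrix dimensions.
#' @param seed Integer seed (deterministic output).
#' @param concentration Dirichlet concentration parameter.
#' @return An [abundance_matrix()] whose columns each sum to one.
#' @export
generate_null <- function(n_taxa, n_samples, seed = 1, concentration = 1) {
  stopifnot(n_taxa >= 1, n_samples >= 1, concentration > 0)
  vals <- with_seed(seed, matrix(stats::rgamma(n_taxa * n_samples,
                                               shape = concentration),
                                 nrow = n_taxa))
  vals <- sweep(vals, 2, colSums(vals), "/")
  dimnames(vals) <- list(synth_taxa_names(n_taxa), synth_sample_names(n_samples))
  abundance_matrix(vals)
}

#' Simulate a community with planted cooperator/competitor triplets
#'
#' See [synthetic_spec()] for the generative model.  Region labels split the
#' samples into contiguous equal blocks (`siteA` first).
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `matrix` (an [abundance_matrix()] with
#'   `region_of` set) and `truth` (an [rmn_network()]).  For every planted
#'   triple `(t, c, k)` the truth network holds the planted edges
#'   `c -> t` (cooperative) and `k -> t` (competitive) together with their
#'   closure-implied mirror `c -> k` (cooperative) and `t -> k` (competitive):
#'   because samples are renormalised, a deterministic linear response makes
#'   the competitor an exact rule-model target as well (see source for the
#'   identity), and a correct inference recovers both triplets.  In
#'   particular, each planted triple yields one mutual-negative pair
#'   `{t, k}` in the truth network.
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_taxa <- spec$n_taxa
  n_samples <- spec$n_samples
  targets <- vapply(spec$planted, `[`, 0L, 1)
  background <- setdiff(seq_len(n_taxa), targets)
  if (length(background) < 2 && length(spec$planted))
    stop("need at least 2 non-target taxa as background")

  raw <- with_seed(spec$seed, {
    g <- matrix(stats::rgamma(length(background) * n_samples,
                              shape = spec$baseline_concentration),
                nrow = length(background))
    g <- sweep(g, 2, colSums(g), "/")
    raw <- matrix(0, n_taxa, n_samples)
    raw[background, ] <- g
    for (p in spec$planted) {
      noise <- if (spec$noise_sd > 0)
        stats::rnorm(n_samples, 0, spec$noise_sd) else 0
      raw[p[1], ] <- pmax(1e-6, spec$baseline +
                            spec$beta_coop * raw[p[2], ] -
                            spec$beta_comp * raw[p[3], ] + noise)
    }
    raw
  })
  vals <- sweep(raw, 2, colSums(raw), "/")
  dimnames(vals) <- list(synth_taxa_names(n_taxa),
                         synth_sample_names(n_samples))

  region_of <- NULL
  if (spec$n_regions >= 1) {
    labels <- paste0("site", LETTERS[seq_len(spec$n_regions)])
    blocks <- sort(rep_len(seq_len(spec$n_regions), n_samples))
    region_of <- stats::setNames(labels[blocks], colnames(vals))
  }

  ## Truth holds the planted edges plus the closure-implied mirror of each
  ## triple.  Relative abundances are compositional: with background fractions
  ## summing to one and a deterministic response t = b + bc*C - bk*K, the
  ## identity K_obs = (b/S + bc*C_obs - t_obs)/bk (S = sample sum) makes the
  ## competitor itself an exact target of cooperator C and competitor t, so
  ## (K; C; t) conforms to the rule model wherever (t; C; K) does.  Those
  ## dependencies are real features of the simulated data, not false
  ## positives, and belong in the ground truth.
  tx <- rownames(vals)
  truth_edges <- do.call(rbind, lapply(spec$planted, function(p) {
    data.frame(source = tx[c(p[2], p[3], p[2], p[1])],
               target = tx[c(p[1], p[1], p[3], p[3])],
               sign = c("cooperative", "competitive",
                        "cooperative", "competitive"),
               weight = 1, n_triplets = 1L)
  }))
  if (is.null(truth_edges)) truth_edges <- empty_edge_frame()
  truth_edges <- unique(truth_edges)
  truth <- rmn_network(edges = truth_edges)

  list(matrix = abundance_matrix(vals, region_of = region_of), truth = truth)
}

#' Score recovery of planted edges
#'
#' Compares inferred and true networks as sets of signed directed edges
#' `(source, target, sign)`.
#'
#' @param inferred,truth [rmn_network()] objects.
#' @return List with `precision`, `recall` and `f1`.  Empty sets follow the
#'   usual conventions: precision is 1 when nothing was inferred, recall is 1
#'   when nothing was planted, and f1 is 0 when precision + recall is 0.
#' @export
score_recovery <- function(inferred, truth) {
  stopifnot(inherits(inferred, "rmn_network"), inherits(truth, "rmn_network"))
  key <- function(net) paste(net$edges$source, net$edges$target,
                             net$edges$sign, sep = "\r")
  ik <- key(inferred)
  tk <- key(truth)
  tp <- length(intersect(ik, tk))
  precision <- if (length(ik)) tp / length(ik) else 1
  recall <- if (length(tk)) tp / length(tk) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}
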