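# Shared fixtures and an independent brute-force oracle for the triplet rule.

# Worked three-taxon example: X responds positively to cooperator Y and
# negatively to competitor Z over four samples (consecutive pairs).
toy_matrix <- function() {
  vals <- rbind(
    X = c(0.10, 0.30, 0.05, 0.33),
    Y = c(0.10, 0.20, 0.05, 0.25),
    Z = c(0.20, 0.05, 0.25, 0.10))
  colnames(vals) <- paste0("s", 1:4)
  abundance_matrix(vals)
}

random_abundance <- function(n_taxa, n_samples, seed) {
  set.seed(seed)
  vals <- matrix(runif(n_taxa * n_samples), n_taxa)
  vals <- sweep(vals, 2, colSums(vals), "/")
  dimnames(vals) <- list(paste0("t", seq_len(n_taxa)),
                         paste0("s", seq_len(n_samples)))
  abundance_matrix(vals)
}

# Brute-force re-implementation of the rule model: scalar comparisons in
# explicit loops, sharing no code with the package internals.
oracle_triplet <- function(x, target, coop, comp, epsilon, pair_mode) {
  vals <- x$values
  n <- ncol(vals)
  pairs <- list()
  if (pair_mode == "consecutive") {
    for (i in seq_len(n - 1)) pairs[[i]] <- c(i, i + 1)
  } else {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n))
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  one <- function(b, a) {
    if (a - b > epsilon) "UP" else if (b - a > epsilon) "DOWN" else "STEADY"
  }
  support <- 0L
  contradiction <- 0L
  for (p in pairs) {
    dc <- one(vals[coop, p[1]], vals[coop, p[2]])
    dk <- one(vals[comp, p[1]], vals[comp, p[2]])
    dt <- one(vals[target, p[1]], vals[target, p[2]])
    pred <- if (dc == "UP" && dk == "DOWN") "UP"
            else if (dc == "DOWN" && dk == "UP") "DOWN"
            else NA_character_
    if (!is.na(pred)) {
      if (dt == pred) support <- support + 1L
      else contradiction <- contradiction + 1L
    }
  }
  list(support = support, contradiction = contradiction)
}

expect_matches_oracle <- function(x, target, coop, comp, params) {
  got <- evaluate_triplet(x, target, coop, comp, params)
  want <- oracle_triplet(x, target, coop, comp, params$epsilon,
                         params$pair_mode)
  expect_identical(c(got$support, got$contradiction),
                   c(want$support, want$contradiction),
                   label = sprintf("triplet (%s;%s;%s)", target, coop, comp))
}
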