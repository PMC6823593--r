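test_that("change classification respects the steady band", {
  expect_identical(classify_change(0.10, 0.10, 0.01), "STEADY")
  expect_identical(classify_change(0.10, 0.16, 0.01), "UP")
  expect_identical(classify_change(0.10, 0.095, 0.01), "STEADY")
  expect_identical(classify_change(0.16, 0.10, 0.01), "DOWN")
  expect_identical(classify_change(c(0, 0.5), c(0.5, 0), 0.1), c("UP", "DOWN"))
})

test_that("sample pair enumeration covers both modes", {
  s <- paste0("s", 1:4)
  expect_equal(nrow(sample_pairs(s, "consecutive")), 3)
  expect_equal(nrow(sample_pairs(s, "all_pairs")), 6)
  expect_equal(nrow(sample_pairs(s[1], "all_pairs")), 0)
  ap <- sample_pairs(s, "all_pairs")
  expect_true(all(match(ap[, "before"], s) < match(ap[, "after"], s)))
})

test_that("abundance filtering keeps taxa by their maximum", {
  vals <- rbind(lo = c(0.0005, 0.0004), hi = c(0.002, 0.001))
  colnames(vals) <- c("a", "b")
  m <- abundance_matrix(vals)
  expect_identical(taxa(filter_taxa(m, 0.001)), "hi")
  expect_identical(taxa(filter_taxa(m, 0)), c("lo", "hi"))
  counts <- vapply(c(0, 5e-4, 1e-3, 3e-3), function(th)
    length(taxa(filter_taxa(m, th))), 0L)
  expect_true(all(diff(counts) <= 0))  # raising theta never adds taxa
})

test_that("the worked triplet example scores as derived by hand", {
  m <- toy_matrix()
  p <- rmn_params(epsilon = 0.01, pair_mode = "consecutive")
  r <- evaluate_triplet(m, "X", "Y", "Z", p)
  expect_equal(r$support, 3)
  expect_equal(r$contradiction, 0)
  expect_equal(r$score, 1.0)
  expect_true(r$accepted)

  # anti-correlated target: same pairs, every prediction contradicted
  m2 <- m
  m2$values["X", ] <- 1 - m$values["X", ]
  r2 <- evaluate_triplet(m2, "X", "Y", "Z", p)
  expect_equal(r2$support, 0)
  expect_equal(r2$contradiction, 3)
  expect_equal(r2$score, -1)
  expect_false(r2$accepted)
})

test_that("a constant matrix is uninformative", {
  vals <- matrix(0.25, 3, 4,
                 dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  r <- evaluate_triplet(abundance_matrix(vals), "A", "B", "C", rmn_params())
  expect_equal(r$informative, 0)
  expect_equal(r$score, 0)
  expect_false(r$accepted)
})

test_that("triplet evaluation validates its inputs", {
  m <- toy_matrix()
  expect_error(evaluate_triplet(m, "X", "X", "Z", rmn_params()), "distinct")
  expect_error(evaluate_triplet(m, "X", "Y", "Q", rmn_params()),
               "not in matrix")
})

test_that("support and contradiction match the brute-force oracle", {
  for (seed in 1:30) {
    set.seed(seed + 500)
    nt <- sample(3:6, 1)
    ns <- sample(3:8, 1)
    m <- random_abundance(nt, ns, seed)
    p <- rmn_params(epsilon = sample(c(0, 0.001, 0.05), 1),
                    pair_mode = sample(c("all_pairs", "consecutive"), 1))
    trio <- sample(taxa(m), 3)
    expect_matches_oracle(m, trio[1], trio[2], trio[3], p)
  }
})

test_that("the worked network example yields the hand-enumerated edges", {
  p <- rmn_params(theta_min = 0, epsilon = 0.01, pair_mode = "consecutive")
  net <- infer_network(toy_matrix(), p)
  trip <- attr(net, "triplets")
  acc <- trip[trip$accepted, c("target", "cooperator", "competitor")]
  expect_equal(nrow(acc), 2)
  expect_true(any(acc$target == "X" & acc$cooperator == "Y" &
                    acc$competitor == "Z"))
  expect_true(any(acc$target == "Y" & acc$cooperator == "X" &
                    acc$competitor == "Z"))

  got <- net$edges[, c("source", "target", "sign")]
  want <- data.frame(source = c("Y", "Z", "X", "Z"),
                     target = c("X", "X", "Y", "Y"),
                     sign = c("cooperative", "competitive",
                              "cooperative", "competitive"))
  key <- function(d) sort(paste(d$source, d$target, d$sign))
  expect_identical(key(got), key(want))
  expect_true(all(net$edges$weight == 1))
  expect_equal(nrow(mutual_negative_pairs(net)), 0)
})

test_that("network inference rejects degenerate inputs", {
  two <- abundance_matrix(matrix(runif(4) / 4, 2, 2,
                                 dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(infer_network(two), "fewer than 3 taxa")
  one_sample <- abundance_matrix(matrix(c(0.2, 0.3, 0.5), 3, 1,
                                        dimnames = list(c("a", "b", "c"), "s1")))
  expect_error(infer_network(one_sample), "2 samples")
})

test_that("every cooperative in-edge is accompanied by a competitive one", {
  for (seed in 1:25) {
    m <- random_abundance(sample(4:7, 1), sample(4:8, 1), seed + 900)
    net <- infer_network(m, rmn_params(epsilon = 0.02, s_min = 0.5))
    coop_targets <- unique(net$edges$target[net$edges$sign == "cooperative"])
    comp_targets <- unique(net$edges$target[net$edges$sign == "competitive"])
    expect_true(all(coop_targets %in% comp_targets))
  }
})

test_that("scores are invariant to reversing every sample pair", {
  # flipping the column order reverses the orientation of every pair in
  # all_pairs mode; UP/DOWN predictions map onto each other
  for (seed in 1:10) {
    m <- random_abundance(4, 6, seed + 40)
    rev <- m
    rev$values <- m$values[, rev(seq_len(ncol(m$values)))]
    p <- rmn_params(epsilon = 0.01)
    trio <- taxa(m)[1:3]
    a <- evaluate_triplet(m, trio[1], trio[2], trio[3], p)
    b <- evaluate_triplet(rev, trio[1], trio[2], trio[3], p)
    expect_equal(a[c("support", "contradiction", "score")],
                 b[c("support", "contradiction", "score")])
  }
})

test_that("accepted triplets ignore sample order in all_pairs mode", {
  for (seed in 1:10) {
    set.seed(seed + 77)
    m <- random_abundance(5, 6, seed + 13)
    perm <- m
    perm$values <- m$values[, sample(ncol(m$values))]
    p <- rmn_params(epsilon = 0.01, s_min = 0.5)
    key <- function(x) {
      tr <- evaluate_all_triplets(x, p)
      sort(paste(tr$target, tr$cooperator, tr$competitor)[tr$accepted])
    }
    expect_identical(key(m), key(perm))
  }
})

test_that("tightening acceptance thresholds never adds edges", {
  m <- random_abundance(6, 8, 321)
  edge_keys <- function(p) {
    net <- infer_network(m, p)
    paste(net$edges$source, net$edges$target, net$edges$sign)
  }
  loose <- edge_keys(rmn_params(epsilon = 0.01, s_min = 0, m_min = 1))
  mid <- edge_keys(rmn_params(epsilon = 0.01, s_min = 0.5, m_min = 2))
  strict <- edge_keys(rmn_params(epsilon = 0.01, s_min = 1, m_min = 3))
  expect_true(all(mid %in% loose))
  expect_true(all(strict %in% mid))
})

test_that("site categories follow regional presence at the threshold", {
  vals <- rbind(both = c(0.05, 0.05), a_only = c(0.002, 0.0002),
                nowhere = c(0.0004, 0.0002))
  colnames(vals) <- c("s1", "s2")
  m <- abundance_matrix(vals)
  reg <- c(s1 = "Loihi", s2 = "Mariana")
  cat <- annotate_site_category(m, reg, 0.001)
  expect_identical(unname(cat["both"]), "both")
  expect_identical(unname(cat["a_only"]), "Loihi_only")
  expect_identical(unname(cat["nowhere"]), "below_threshold")

  expect_error(annotate_site_category(m, c(s1 = "A", s2 = "A"), 0.001),
               "exactly 2 regions")
  expect_error(annotate_site_category(m, c(s1 = "A"), 0.001),
               "without region")
})
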