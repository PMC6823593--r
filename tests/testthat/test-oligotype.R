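test_that("column entropy matches closed forms", {
  expect_equal(column_entropy(rep("A", 10)), 0)
  expect_equal(column_entropy(c(rep("A", 5), rep("C", 5))), 1)
  expect_equal(column_entropy(c(A = 3, C = 1)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(column_entropy(c(A = 3, C = 1)), 0.8113, tolerance = 1e-4)
  expect_error(column_entropy(character(0)), "empty")
  expect_error(column_entropy(c(A = 0)), "empty")
})

test_that("entropy profiles have one value per column and detect ragged input", {
  aln <- c(r1_1 = "ACGT", r1_2 = "ACGT")
  prof <- entropy_profile(aln)
  expect_equal(prof$alignment_length, 4)
  expect_equal(prof$entropy, rep(0, 4))  # identical sequences
  expect_error(entropy_profile(c(a_1 = "ACGT", b_1 = "ACG")),
               "ragged.*b_1")
  # relabeling characters leaves entropy unchanged
  e1 <- entropy_profile(c(x_1 = "AC", x_2 = "AA"))$entropy
  e2 <- entropy_profile(c(x_1 = "TG", x_2 = "TT"))$entropy
  expect_equal(e1, e2)
})

test_that("entropy is permutation-invariant and maximal for uniform columns", {
  aln <- c(a_1 = "AG", a_2 = "CG", a_3 = "GG", a_4 = "TG")
  prof <- entropy_profile(aln)
  expect_equal(prof$entropy[1], log2(4))  # uniform over 4 characters
  shuffled <- aln[c(3, 1, 4, 2)]
  expect_equal(entropy_profile(shuffled)$entropy, prof$entropy)
})

test_that("component selection takes the k largest entropies, ties leftmost", {
  prof <- structure(list(alignment_length = 4,
                         entropy = c(0, 1.0, 0.5, 1.0), counts = NULL),
                    class = "entropy_profile")
  expect_identical(select_components(prof, 2), c(2L, 4L))
  expect_identical(select_components(structure(
    list(alignment_length = 2, entropy = c(0.2, 0.9), counts = NULL),
    class = "entropy_profile"), 1), 2L)
  expect_identical(select_components(prof, 4), 1:4)
  expect_error(select_components(prof, 0), "positive")
  expect_error(select_components(prof, 5), "exceeds")
})

test_that("decompose tabulates oligotypes per sample", {
  aln <- c(S1_1 = "AC", S1_2 = "AC", S1_3 = "GT")
  tab <- decompose(aln, c(1, 2))
  expect_identical(rownames(tab$counts), c("AC", "GT"))  # by total, desc
  expect_equal(unname(tab$counts[, "S1"]), c(2L, 1L))
  expect_equal(unname(tab$percents[, "S1"]), c(200, 100) / 3)
  expect_equal(sum(tab$percents[, "S1"]), 100, tolerance = 1e-6)

  single <- decompose(c(S1_1 = "ACGT"), 2)
  expect_equal(unname(single$percents[, 1]), 100)

  expect_error(decompose(aln, c(1, 2), sample_of = c(S1_1 = "S1")),
               "absent from sample_of")
})

test_that("decompose conserves reads per sample", {
  set.seed(42)
  for (rep in 1:10) {
    n_reads <- sample(5:30, 1)
    smp <- sample(paste0("S", 1:3), n_reads, replace = TRUE)
    seqs <- vapply(seq_len(n_reads), function(i)
      paste(sample(c("A", "C", "G", "T", "-"), 6, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- paste0(smp, "_", seq_len(n_reads))
    tab <- decompose(seqs, sample(1:6, 2))
    expect_equal(colSums(tab$counts)[sort(unique(smp))],
                 table(smp)[sort(unique(smp))],
                 ignore_attr = TRUE)
  }
})

test_that("selecting every column reproduces full-sequence deduplication", {
  set.seed(7)
  for (rep in 1:5) {
    seqs <- vapply(1:12, function(i)
      paste(sample(c("A", "C"), 4, replace = TRUE), collapse = ""), "")
    names(seqs) <- paste0("S1_", 1:12)
    tab <- decompose(seqs, 1:4)
    expect_setequal(rownames(tab$counts), unique(unname(seqs)))
    expect_equal(sum(tab$counts), 12)
  }
})

test_that("oligotype tables round-trip through matrix_percents within 1e-6", {
  aln <- c(S1_1 = "AC", S1_2 = "AC", S1_3 = "GT", S2_1 = "GT")
  tab <- decompose(aln, c(1, 2))
  p <- withr::local_tempfile()
  write_matrix_percent(tab, p)
  expect_match(readLines(p)[2], "66\\.666667")
  back <- read_oligotyping_matrix_percent(p)
  expect_equal(back$values[rownames(tab$percents), colnames(tab$percents)] * 100,
               tab$percents, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("gap characters are ordinary residues in entropy and labels", {
  aln <- c(S1_1 = "A-", S1_2 = "AC")
  expect_equal(entropy_profile(aln)$entropy, c(0, 1))
  tab <- decompose(aln, 1:2)
  expect_setequal(rownames(tab$counts), c("A-", "AC"))
})

test_that("the full pipeline reads FASTA and selects high-entropy loci", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">S1_1 extra description", "ACGT", ">S1_2", "ACGT",
               ">S1_3", "GCTT", ">S2_1", "GCGT"), fa)
  aln <- read_alignment_fasta(fa)
  expect_identical(names(aln)[1], "S1_1")  # description stripped
  tab <- oligotype(aln, k = 2)
  expect_identical(tab$positions, c(1L, 3L))
  expect_equal(sum(tab$counts), 4)
})
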