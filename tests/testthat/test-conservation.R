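# Alignment reading, per-column identity, scaffold windows and
# fingerprint positions.

mini_fasta <- function(seqs) paste0(">", names(seqs), "\n", seqs,
                                    collapse = "\n")

test_that("alignment and group map load and validate", {
  fa <- mini_fasta(c(s1 = "ACDEF", s2 = "ACDEF", s3 = "ACDE-", s4 = "ACDEF"))
  groups <- c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2")
  ga <- read_alignment(fa, groups)
  expect_equal(ncol(ga$seq), 5L)
  expect_equal(nrow(ga$seq), 4L)

  expect_error(read_alignment(mini_fasta(c(a = "ACDEF", b = "ACDE")),
                              c(a = "g", b = "g")), "unequal lengths")
  expect_error(read_alignment(fa, groups[1:3]), "s4")
  fa_dup <- mini_fasta(c(s1 = "AC", s1 = "AC"))
  expect_error(read_alignment(fa_dup, c(s1 = "g")), "duplicate")
})

test_that("per-column identity follows the gap-inclusive convention", {
  fa <- mini_fasta(c(s1 = "AAAT", s2 = "AAA-", s3 = "AAA-", s4 = "ATAA"))
  # columns: AAAA | AAAT(transposed)... build explicitly instead:
  seqs <- c(s1 = "AAA", s2 = "AAA", s3 = "AAA", s4 = "TA-")
  ga <- read_alignment(mini_fasta(seqs), c(s1 = "g", s2 = "g", s3 = "g",
                                           s4 = "g"))
  p <- column_identity(ga, "g")
  # col1 "AAAT" -> A 75; col2 "AAAA" -> A 100; col3 "AA A-" -> A 75
  expect_equal(p$modal_residue, c("A", "A", "A"))
  expect_equal(p$identity_percent, c(75, 100, 75))
  expect_equal(p$n_nongap, c(4L, 4L, 3L))
})

test_that("gapped sequences stay in the identity denominator", {
  seqs <- c(s1 = "A", s2 = "A", s3 = "-", s4 = "-")
  ga <- read_alignment(mini_fasta(seqs), setNames(rep("g", 4), names(seqs)))
  p <- column_identity(ga, "g")
  expect_equal(p$identity_percent, 50)   # "AA--" -> 2/4
  expect_equal(p$n_nongap, 2L)
})

test_that("modal ties break to the lexicographically smallest residue", {
  seqs <- c(s1 = "T", s2 = "A", s3 = "T", s4 = "A")
  ga <- read_alignment(mini_fasta(seqs), setNames(rep("g", 4), names(seqs)))
  expect_message(p <- column_identity(ga, "g"), "tie")
  expect_identical(p$modal_residue, "A")
})

test_that("all-gap columns have no modal residue and zero identity", {
  seqs <- c(s1 = "-A", s2 = "-A")
  ga <- read_alignment(mini_fasta(seqs), c(s1 = "g", s2 = "g"))
  p <- column_identity(ga, "g")
  expect_true(is.na(p$modal_residue[1]))
  expect_equal(p$identity_percent[1], 0)
})

test_that("profiles are invariant to sequence order", {
  plan <- replicate(6, list(g = list(residue = "D", identity = 75)),
                    simplify = FALSE)
  aln <- gen_alignment(c(g = 8L), plan, seed = 3)
  ga <- aln$alignment
  perm <- ga
  set.seed(1)
  ord <- sample(nrow(ga$seq))
  perm$seq <- perm$seq[ord, , drop = FALSE]
  perm$ids <- perm$ids[ord]
  perm$groups <- perm$groups[ord]
  expect_equal(column_identity(perm, "g"), column_identity(ga, "g"),
               ignore_attr = TRUE)
})

test_that("scaffold windows are maximal runs above threshold", {
  p <- data.frame(column = 1:5, modal_residue = "A",
                  identity_percent = c(80, 80, 80, 40, 90), n_nongap = 4L)
  expect_equal(scaffold_windows(p, threshold = 70, min_len = 3),
               data.frame(start = 1L, end = 4L, length = 3L))
  low <- transform(p, identity_percent = 10)
  expect_equal(nrow(scaffold_windows(low)), 0L)
  hi <- data.frame(column = 1:10, modal_residue = "A",
                   identity_percent = 90, n_nongap = 4L)
  expect_equal(scaffold_windows(hi),
               data.frame(start = 1L, end = 11L, length = 10L))
})

test_that("fingerprint detection needs a conserved focal column that the
           contrast group lost or replaced", {
  mk_prof <- function(modal, ident) data.frame(
    column = seq_along(modal), modal_residue = modal,
    identity_percent = ident, n_nongap = 4L)
  focal <- mk_prof(c("T", "D", "L"), c(100, 100, 60))
  contrast <- mk_prof(c("R", "D", "K"), c(90, 100, 100))
  hits <- fingerprint_positions(focal, contrast)
  expect_equal(hits$column, 1L)   # col2 same residue, col3 focal below t_high
  # poorly conserved contrast also counts, even with the same modal residue
  contrast2 <- mk_prof(c("T", "D", "K"), c(40, 100, 100))
  expect_equal(fingerprint_positions(focal, contrast2)$column, 1L)
  expect_error(fingerprint_positions(focal, contrast[1:2, ]), "different")
})

test_that("a profile against itself yields no fingerprints", {
  plan <- scenario_plan_for_tests()
  aln <- gen_alignment(c(mammalia_v6 = 6L, sauropsida = 6L, amphibia = 4L,
                         fish = 4L), plan, seed = 5)
  pa <- column_identity(aln$alignment, "mammalia_v6")
  expect_equal(nrow(fingerprint_positions(pa, pa)), 0L)
})

test_that("planted fingerprint columns are recovered exactly", {
  plan <- scenario_plan_for_tests()
  aln <- gen_alignment(c(mammalia_v6 = 6L, sauropsida = 6L, amphibia = 4L,
                         fish = 4L), plan, seed = 6)
  pa <- column_identity(aln$alignment, "mammalia_v6")
  pf <- column_identity(aln$alignment, "fish")
  hits <- fingerprint_positions(pa, pf)
  expect_identical(hits$column, attr(plan, "fingerprints"))
})

test_that("generated alignments have exact planted counts and sizes", {
  plan <- replicate(40, list(g1 = list(residue = "D", identity = 100),
                             g2 = list(residue = "D", identity = 50)),
                    simplify = FALSE)
  aln <- gen_alignment(c(g1 = 6L, g2 = 4L), plan, seed = 9)
  expect_equal(dim(aln$alignment$seq), c(10L, 40L))
  p1 <- column_identity(aln$alignment, "g1")
  p2 <- column_identity(aln$alignment, "g2")
  expect_true(all(p1$identity_percent == 100))
  expect_true(all(p2$identity_percent == 50))
  # per-column counts sum to the group size
  col <- aln$alignment$seq[aln$alignment$groups == "g2", 1]
  expect_equal(length(col), 4L)
  expect_equal(sum(col == "D") + sum(col != "D"), 4L)
  # unreachable identity is rejected
  bad <- replicate(2, list(g1 = list(residue = "A", identity = 33)),
                   simplify = FALSE)
  expect_error(gen_alignment(c(g1 = 6L), bad, seed = 1), "not an exact count")
})
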