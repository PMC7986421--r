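test_that("global protein alignment is optimal and matches the DP oracle", {
  same <- global_protein_align("MKVLA", "MKVLA")
  expect_identical(same$a, "MKVLA")
  expect_identical(same$b, "MKVLA")
  expect_equal(pairwise_identity(c(same$a, same$b)), 100)

  gap <- global_protein_align("ACD", "AD")
  expect_identical(gap$a, "ACD")
  expect_identical(gap$b, "A-D")

  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(19)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:8) {
    a <- paste(sample(aas, 20, replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(15:25, 1), replace = TRUE), collapse = "")
    al <- global_protein_align(a, b, gap_open = 10, gap_extend = 1)
    expect_equal(al$score,
                 nw_oracle_affine(a, b, BLOSUM62, open = 10, ext = 1))
  }
  expect_error(global_protein_align("", "AD"), "non-empty")
})

test_that("codon back-translation mirrors the protein alignment", {
  cds_a <- "ATGAAAGTG"           # MKV
  cds_b <- "ATGGTG"              # MV
  pa <- global_protein_align("MKV", "MV")
  ca <- codon_backtranslate(pa, cds_a, cds_b)
  expect_identical(ca$seqs[1], "ATGAAAGTG")
  expect_identical(ca$seqs[2], "ATG---GTG")
  # gap-free alignment concatenates the codons
  pa2 <- global_protein_align("MKV", "MKV")
  ca2 <- codon_backtranslate(pa2, cds_a, "ATGAAGGTG")
  expect_equal(nchar(ca2$seqs[1]), 3 * 3)
  expect_false(grepl("-", ca2$seqs[1], fixed = TRUE))

  # round trip: translating the de-gapped alignment returns the proteins
  degap <- gsub("-", "", ca$seqs, fixed = TRUE)
  expect_identical(vapply(degap, translate_cds, character(1),
                          USE.NAMES = FALSE), c("MKV", "MV"))

  # trailing stop codons are tolerated, translation mismatches are not
  ca3 <- codon_align("ATGAAAGTGTAA", "ATGGTGTGA")
  expect_identical(ca3$seqs[2], "ATG---GTG")
  expect_error(codon_backtranslate(pa, cds_a, "ATGCCC"), "translate")
})

test_that("pairwise identity counts columns per convention", {
  expect_equal(pairwise_identity(c(strrep("ACGT", 150), strrep("ACGT", 150))),
               100)
  # 9 mismatches in 600 ungapped columns
  a <- strrep("A", 600)
  b <- paste0(strrep("A", 591), strrep("C", 9))
  expect_equal(pairwise_identity(c(a, b)), 98.5)

  # gap columns excluded by default, counted on request
  a2 <- "AC-GT"
  b2 <- "ACCGA"
  expect_equal(pairwise_identity(c(a2, b2)), 100 * 3 / 4)
  expect_equal(pairwise_identity(c(a2, b2), include_gaps = TRUE), 100 * 3 / 5)

  # seeded simulated pair agrees with a column-counting oracle
  set.seed(20)
  fam <- generate_paralogue_family(2, 300, identity = 96, seed = 20)
  s <- as.character(fam)
  oracle <- 100 * mean(strsplit(s[1], "")[[1]] == strsplit(s[2], "")[[1]])
  expect_equal(pairwise_identity(s), oracle)

  expect_error(pairwise_identity(c("----", "AC--")), "comparable")
})

test_that("Nei-Gojobori reproduces the hand-computed worked example", {
  r <- nei_gojobori(c("TTTGGGCCCAAA", "TTCGGGCCCAAA"))
  expect_equal(r$S, 8 / 3, tolerance = 1e-12)
  expect_equal(r$N, 12 - 8 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.375, tolerance = 1e-12)
  expect_equal(r$dS, -0.75 * log(0.5), tolerance = 1e-12)
  expect_equal(r$dS, 0.5199, tolerance = 1e-4)
  expect_equal(r$dN, 0)
  expect_equal(r$omega, 0)
})

test_that("degenerate dN/dS cases are flagged rather than silent", {
  same <- nei_gojobori(c("ATGAAA", "ATGAAA"))
  expect_equal(same$Sd + same$Nd, 0)
  expect_true(is.na(same$omega))
  expect_true("undefined_omega" %in% same$flags)

  # nonsynonymous-only divergence: dS = 0, dN > 0, omega undefined
  fam <- generate_paralogue_family(2, 300, identity = 95, syn_weight = 0,
                                   nonsyn_weight = 1, seed = 23)
  r <- nei_gojobori(as.character(fam))
  expect_equal(r$dS, 0)
  expect_gt(r$dN, 0)
  expect_true("undefined_omega" %in% r$flags)
})

test_that("Nei-Gojobori is symmetric and concatenation-invariant", {
  fam <- generate_paralogue_family(2, 300, identity = 92, seed = 24)
  s <- as.character(fam)
  r12 <- nei_gojobori(s)
  r21 <- nei_gojobori(rev(s))
  for (f in c("S", "N", "Sd", "Nd", "dS", "dN")) {
    expect_equal(r12[[f]], r21[[f]], tolerance = 1e-12)
  }
  # self-concatenation doubles counts, leaves proportions and rates alone
  dbl <- nei_gojobori(paste0(s, s))
  expect_equal(dbl$S, 2 * r12$S, tolerance = 1e-12)
  expect_equal(dbl$Sd, 2 * r12$Sd, tolerance = 1e-12)
  expect_equal(dbl$pS, r12$pS, tolerance = 1e-12)
  expect_equal(dbl$dN, r12$dN, tolerance = 1e-12)
  expect_equal(dbl$omega, r12$omega, tolerance = 1e-12)
  # sites split as S + N = 3 x codons
  expect_equal(r12$S + r12$N, 3 * r12$n_codons)
})

test_that("NJ recovers additive trees exactly", {
  # two taxa: one branch of total length d
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 3)

  # four taxa satisfying the four-point condition
  taxa <- c("A", "B", "C", "D")
  d4 <- matrix(c(0, 5, 7, 8,
                 5, 0, 8, 9,
                 7, 8, 0, 9,
                 8, 9, 9, 0), 4, dimnames = list(taxa, taxa))
  t4 <- nj_tree(d4)
  coph <- ape::cophenetic.phylo(t4)[taxa, taxa]
  expect_equal(coph, d4, tolerance = 1e-10)
  expect_false(attr(t4, "clamped"))

  # five taxa from a known tree: path lengths reproduce the input
  ref <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2,e:2);")
  d5 <- ape::cophenetic.phylo(ref)
  t5 <- nj_tree(d5)
  expect_equal(ape::cophenetic.phylo(t5)[rownames(d5), colnames(d5)],
               d5, tolerance = 1e-10)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("bootstrap support finds an overwhelming bipartition", {
  # two clades differing at half of all codon columns
  block_a <- strrep("ATG", 50)
  block_b <- paste(rep(c("ATG", "CCC"), 25), collapse = "")
  seqs <- c(t1 = block_a, t2 = block_a, t3 = block_b, t4 = block_b)
  bs <- bootstrap_support(seqs, n_replicates = 100, seed = 1)
  expect_true(any(bs$support >= 99.9))
  expect_length(bs$support, bs$tree$Nnode)

  # determinism per seed
  bs2 <- bootstrap_support(seqs, n_replicates = 100, seed = 1)
  expect_identical(bs$support, bs2$support)

  # no informative columns: supports still reported, topology flagged
  flat <- c(t1 = block_a, t2 = block_a, t3 = block_a, t4 = block_a)
  bs3 <- bootstrap_support(flat, n_replicates = 10, seed = 2)
  expect_true("arbitrary_topology" %in% bs3$flags)

  expect_error(bootstrap_support(seqs, n_replicates = 0), "replicates")
  expect_error(bootstrap_support(seqs[1:3], 10), "4 taxa")
})
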