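test_that("noiseless generation reproduces the decay means exactly", {
  p <- "BnaFLC.A02"
  arch <- archetype("one", "spring", a = setNames(100, p),
                    b = setNames(-0.1, p))
  ns <- noise_spec(sigma_log = 0, timepoints = c(0, 7, 14), replicates = 3)
  panel <- generate_panel(list(arch), ns, seed = 1)
  at7 <- panel$records$tpm[panel$records$day == 7]
  expect_equal(at7, rep(100 * exp(-0.7), 3), tolerance = 1e-12)
  expect_equal(unique(at7), 49.659, tolerance = 1e-4)

  # floor-only gene: constant at c regardless of b
  arch2 <- archetype("two", "spring", a = setNames(0, p),
                     b = setNames(-0.3, p), c = setNames(50, p))
  panel2 <- generate_panel(list(arch2), ns, seed = 1)
  expect_true(all(panel2$records$tpm == 50))
})

test_that("replicate noise follows the stated lognormal model", {
  p <- "BnaFLC.A02"
  arch <- archetype("mc", "spring", a = setNames(100, p),
                    b = setNames(-0.1, p))
  ns <- noise_spec(sigma_log = 0.3, detection_floor = 0, replicates = 2000,
                   timepoints = 0)
  panel <- generate_panel(list(arch), ns, seed = 42)
  obs <- panel$records$tpm
  se <- 0.3 / sqrt(2000)
  expect_lt(abs(mean(log(obs)) - log(100)), 3 * se)
  expect_lt(abs(sd(log(obs)) - 0.3), 3 * se)
})

test_that("generation is deterministic per seed and validates inputs", {
  p1 <- generate_panel(default_archetypes(), noise_spec(), seed = 7)
  p2 <- generate_panel(default_archetypes(), noise_spec(), seed = 7)
  expect_identical(p1$records, p2$records)
  p3 <- generate_panel(default_archetypes(), noise_spec(), seed = 8)
  expect_false(identical(p1$records, p3$records))

  expect_error(generate_panel(list(), noise_spec()), "non-empty")
  expect_error(noise_spec(timepoints = c(0, 7, 7)), "strictly increasing")
  expect_error(noise_spec(timepoints = c(7, 14)), "day 0")
  expect_error(noise_spec(sigma_log = -1), "sigma_log")
})

test_that("default archetypes satisfy the documented composition structure", {
  archs <- default_archetypes()
  expect_gte(length(archs), 6L)
  types <- vapply(archs, `[[`, character(1), "crop_type")
  expect_setequal(unique(types), crop_types())
  strategies <- vapply(archs, `[[`, character(1), "strategy")
  expect_setequal(strategies[types == "winter"], c("A", "B", "C"))

  totals <- vapply(archs, function(a) sum(a$a + a$c), numeric(1))
  # exactly one spring archetype sits at the default competence threshold
  expect_equal(sum(types == "spring" & abs(totals - 75) < 1e-9), 1L)
  expect_true(all(totals[types == "spring"] <= 75 + 1e-9))

  # the semi-winter archetype loads >= 40% of day-0 total on its
  # fastest-decaying paralogue
  sw <- archs[[which(types == "semi_winter")[1]]]
  fast <- names(which.max(abs(sw$b)))
  expect_gte((sw$a + sw$c)[[fast]] / sum(sw$a + sw$c), 0.4)

  # winter strategies A and C have higher totals than B
  wt <- function(s) totals[types == "winter" & strategies == s]
  expect_gt(wt("A"), wt("B"))
  expect_gt(wt("C"), wt("B"))
})

test_that("paralogue families hit identity targets with in-frame sequences", {
  fam <- generate_paralogue_family(2, length = 600, identity = 100, seed = 1)
  expect_identical(as.character(fam[[1]]), as.character(fam[[2]]))

  fam <- generate_paralogue_family(2, length = 600, identity = 98.5, seed = 3)
  d <- str_mismatches(as.character(fam[[1]]), as.character(fam[[2]]))
  expect_true(abs(d - 9) <= 3)
  # realized identity within +-1% of target
  expect_lt(abs(100 * (1 - d / 600) - 98.5), 1)

  # same seed => identical family
  fam2 <- generate_paralogue_family(2, length = 600, identity = 98.5, seed = 3)
  expect_identical(as.character(fam), as.character(fam2))

  # synonymous-only evolution leaves the proteins identical
  for (s in 5:8) {
    fam3 <- generate_paralogue_family(3, length = 300, identity = 95,
                                      syn_weight = 1, nonsyn_weight = 0,
                                      seed = s)
    prots <- vapply(as.character(fam3), translate_cds, character(1))
    expect_length(unique(prots), 1L)
    # and no internal stops anywhere
    expect_false(any(grepl("*", prots, fixed = TRUE)))
  }

  expect_error(generate_paralogue_family(2, 600, identity = 101), "identity")
  expect_error(generate_paralogue_family(2, 601), "multiple of 3")
})

test_that("simulated reads match their origins and error model", {
  fam <- generate_paralogue_family(2, 600, 98.5, seed = 1)
  refs <- as.character(fam)

  # error-free reads are exact substrings of their origin
  rr <- generate_reads(fam, read_length = 100, error_rate = 0, depth = 30,
                       seed = 2)
  for (k in seq_along(rr$reads)) {
    tr <- rr$truth[k, ]
    window <- substring(refs[[tr$origin]], tr$start, tr$start + 99)
    obs <- rr$reads[[k]]
    if (tr$strand == "-") {
      obs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(obs)))
    }
    expect_identical(obs, window)
  }

  # substitution errors are i.i.d. at the nominal rate (binomial check)
  rr <- generate_reads(refs[1], read_length = 100, error_rate = 0.01,
                       depth = 1000, paired = FALSE, seed = 3)
  mism <- sum(vapply(seq_along(rr$reads), function(k) {
    tr <- rr$truth[k, ]
    window <- substring(refs[[tr$origin]], tr$start, tr$start + 99)
    obs <- rr$reads[[k]]
    if (tr$strand == "-") {
      obs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(obs)))
    }
    str_mismatches(obs, window)
  }, numeric(1)))
  n_bases <- 1000 * 100
  expect_lt(abs(mism - n_bases * 0.01), 3 * sqrt(n_bases * 0.01 * 0.99))

  # paired mode: mate offset equals insert - read_length
  rp <- generate_reads(fam, read_length = 150, error_rate = 0, depth = 10,
                       paired = TRUE, insert = 300, seed = 4)
  for (k in seq_along(rp$reads)) {
    tr <- rp$truth[k, ]
    mate_start <- tr$start + 300 - 150
    window <- substring(refs[[tr$origin]], mate_start, mate_start + 149)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rp$mates[[k]])))
    expect_identical(rc, window)
  }

  expect_error(generate_reads(fam, read_length = 150, depth = 0), "depth")
  expect_error(generate_reads(fam, read_length = 700), "read_length")
})

test_that("FASTQ and truth-table output round-trips", {
  fam <- generate_paralogue_family(2, 300, 98, seed = 1)
  rr <- generate_reads(fam, read_length = 80, error_rate = 0, depth = 5,
                       paired = TRUE, insert = 200, seed = 2)
  fq1 <- tempfile(fileext = ".fastq"); fq2 <- tempfile(fileext = ".fastq")
  tt <- tempfile(fileext = ".tsv")
  write_reads(rr, fq1, fq2, tt)
  back <- Biostrings::readDNAStringSet(fq1, format = "fastq")
  expect_identical(unname(as.character(back)), unname(rr$reads))
  expect_identical(names(back), names(rr$reads))
  truth <- read.delim(tt, stringsAsFactors = FALSE)
  expect_identical(truth$read_id, rr$truth$read_id)
  expect_identical(truth$start, rr$truth$start)
  unlink(c(fq1, fq2, tt))
})
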