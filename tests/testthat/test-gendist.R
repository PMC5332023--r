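test_that("p-distances handle mismatches and pairwise deletion as defined", {
  aln <- Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGA", c = "AC-T"))
  dm <- pairwisePDistance(aln, minSites = 0)
  d <- distances(dm)
  expect_equal(d["a", "b"], 0.25)
  expect_identical(comparedSites(dm)["a", "b"], 4L)
  expect_equal(d["a", "c"], 0)  # gap site excluded from the pair
  expect_identical(comparedSites(dm)["a", "c"], 3L)
  expect_identical(diag(d), c(a = 0, b = 0, c = 0))
  expect_identical(d, t(d))
})

test_that("pairs with no comparable sites are flagged missing, never zero", {
  aln <- Biostrings::DNAStringSet(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_warning(dm <- pairwisePDistance(aln, minSites = 0),
                 "no comparable sites")
  expect_true(is.na(distances(dm)["a", "b"]))
  expect_false(is.na(distances(dm)["a", "c"]))
})

test_that("short compared fragments trigger a warning", {
  aln <- Biostrings::DNAStringSet(c(a = strrep("A", 150),
                                    b = strrep("A", 150)))
  expect_warning(pairwisePDistance(aln, minSites = 200), "fewer than 200")
  expect_silent(pairwisePDistance(aln, minSites = 100))
})

test_that("p-distances agree with a brute-force per-site oracle", {
  set.seed(42)
  for (rep in seq_len(100)) {
    aln <- randomAlignment(nSeq = 4, nSites = 60)
    d <- suppressWarnings(distances(pairwisePDistance(aln, minSites = 0)))
    s <- as.character(aln)
    for (i in 1:3) {
      for (j in (i + 1):4) {
        expect_identical(d[i, j], bruteForceP(s[[i]], s[[j]]))
      }
    }
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("clade-pair summaries aggregate the right sequence pairs", {
  d <- matrix(0.06, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0
  d["c", "d"] <- d["d", "c"] <- 0
  dm <- new("DistanceMatrix", d = d,
            sites = matrix(500L, 4, 4, dimnames = dimnames(d)))
  clades <- c(a = "X", b = "X", c = "Y", d = "Y")
  s <- cladePairSummary(dm, clades)
  cross <- s[s$cladeA == "X" & s$cladeB == "Y", ]
  expect_equal(cross$mean, 0.06)
  expect_equal(cross$sd, 0)
  expect_identical(cross$nComparisons, 4L)
  intraX <- s[s$cladeA == "X" & s$cladeB == "X", ]
  expect_equal(intraX$mean, 0)
  expect_equal(c(intraX$min, intraX$max), c(0, 0))
  # singleton clades get no intra row; unmapped ids are an error
  s2 <- cladePairSummary(dm, c(a = "X", b = "X", c = "Y", d = "Z"))
  expect_false(any(s2$cladeA == "Z" & s2$cladeB == "Z"))
  expect_error(cladePairSummary(dm, clades[1:3]), "d")
})

test_that("a calibrated 9-clade simulation recovers the target means", {
  cal <- calibratedCladeSpecs(nTips = 3L)
  L <- 2000L
  sim <- simulateAlignment(cal$specs, L, seed = 3)
  dm <- pairwisePDistance(sim$alignment, minSites = 0)
  s <- cladePairSummary(dm, sim$clades)
  m <- merge(s[s$cladeA != s$cladeB, ], cal$expected,
             by = c("cladeA", "cladeB"))
  expect_identical(nrow(m), 36L)
  se <- sqrt(m$expectedP * (1 - m$expectedP) / L)
  expect_true(all(abs(m$mean - m$expectedP) < 3 * se))
})

test_that("divergence categories form a total monotone step function", {
  expect_identical(as.character(classifyDivergence(0.025)), "low")
  expect_identical(as.character(classifyDivergence(0.03)), "moderate")
  expect_identical(as.character(classifyDivergence(0.05)), "moderate")
  expect_identical(as.character(classifyDivergence(0.057)), "high")
  expect_identical(as.character(classifyDivergence(0.07)), "high")
  expect_identical(as.character(classifyDivergence(0.12)), "very_high")
  p <- seq(0, 1, by = 0.0005)
  codes <- as.integer(classifyDivergence(p))
  expect_false(anyNA(codes))          # total on [0, 1]
  expect_true(all(diff(codes) >= 0))  # monotone
  expect_error(classifyDivergence(-0.01), "\\[0, 1\\]")
  expect_error(classifyDivergence(1.01), "\\[0, 1\\]")
})

test_that("p-distances match an independent phylogenetics implementation", {
  set.seed(9)
  for (rep in 1:5) {
    aln <- randomAlignment(nSeq = 6, nSites = 300)
    ours <- suppressWarnings(distances(pairwisePDistance(aln, minSites = 0)))
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(as.matrix(aln))),
                                   model = "raw", pairwise.deletion = TRUE))
    expect_equal(ours, ref[rownames(ours), colnames(ours)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})
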