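publishedSummary <- function() {
  s <- referenceTable("distances")
  s[, c("cladeA", "cladeB", "mean")]
}

test_that("threshold clustering on the published clade means merges only F and H", {
  part <- clusterLineages(publishedSummary(), threshold = 0.03)
  expect_length(part$groups, 8L)
  expect_true(any(vapply(part$groups, identical, logical(1), c("F", "H"))))
  # the minimum inter-clade mean is the F-H 2.5% cell
  inter <- publishedSummary()
  inter <- inter[inter$cladeA != inter$cladeB, ]
  expect_equal(min(inter$mean), 0.025)
  expect_identical(
    sort(unlist(inter[which.min(inter$mean), c("cladeA", "cladeB")],
                use.names = FALSE)), c("F", "H"))
})

test_that("clustering respects trivial thresholds and missing-pair errors", {
  expect_length(clusterLineages(publishedSummary(), threshold = 0)$groups, 9L)
  expect_length(clusterLineages(publishedSummary(), threshold = 1)$groups, 1L)
  broken <- publishedSummary()
  broken <- broken[!(broken$cladeA == "F" & broken$cladeB == "H"), ]
  expect_error(clusterLineages(broken, 0.03), "F-H")
})

test_that("clustering is permutation-invariant and monotone in the threshold", {
  s <- publishedSummary()
  base <- clusterLineages(s, 0.04)$groups
  set.seed(5)
  for (rep in 1:10) {
    perm <- s[sample(nrow(s)), ]
    # also swap the clade-pair orientation of half the rows
    flip <- sample(c(TRUE, FALSE), nrow(perm), replace = TRUE)
    tmp <- perm$cladeA[flip]
    perm$cladeA[flip] <- perm$cladeB[flip]
    perm$cladeB[flip] <- tmp
    expect_identical(clusterLineages(perm, 0.04)$groups, base)
  }
  sizes <- vapply(c(0, 0.02, 0.03, 0.05, 0.08, 0.2, 1), function(th)
    length(clusterLineages(s, th)$groups), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("analyst overrides split, merge, log, and police their inputs", {
  part <- clusterLineages(publishedSummary(), 0.03)
  ov <- data.frame(lineage = "F", action = "split_out",
                   rationale = "short 16S fragment deflates the F-H mean")
  part9 <- applyOverrides(part, ov)
  expect_length(part9$groups, 9L)
  expect_true(any(vapply(part9$groups, identical, logical(1), "F")))
  expect_identical(part9$overrides$rationale, ov$rationale)

  expect_identical(applyOverrides(part, part$overrides[0, ])$groups,
                   part$groups)
  expect_warning(
    applyOverrides(part9, data.frame(lineage = "F", action = "split_out",
                                     rationale = "again")),
    "no-op")
  expect_error(
    applyOverrides(part, data.frame(lineage = "Z", action = "split_out",
                                    rationale = "")),
    "unknown lineage")
  merged <- applyOverrides(part9, data.frame(
    lineage = "F", action = "merge_into:H", rationale = "undo"))
  expect_true(any(vapply(merged$groups, identical, logical(1), c("F", "H"))))
})

test_that("evidence integration reproduces the published verdict counts", {
  part <- applyOverrides(
    clusterLineages(publishedSummary(), 0.03),
    data.frame(lineage = "F", action = "split_out",
               rationale = "short-fragment artifact"))
  res <- integrateEvidence(part, referenceTable("evidence"))
  counts <- table(res$groupStatus$status)
  expect_identical(counts[["CCS"]], 5L)
  expect_identical(counts[["UCS"]], 4L)
  expect_false("DCL" %in% names(counts))
  expect_identical(unname(res$lineageStatus[c("A", "B", "C", "H", "I")]),
                   rep("CCS", 5))
  expect_identical(unname(res$lineageStatus[c("D", "E", "F", "G")]),
                   rep("UCS", 4))
})

test_that("the CCS/UCS/DCL rules are forced by evidence availability", {
  onePer <- function(ac, mo) {
    part <- structure(list(groups = list("X"),
                           overrides = data.frame()), class = "lineagePartition")
    ev <- data.frame(lineage = "X", acoustic_status = ac, morpho_status = mo)
    integrateEvidence(part, ev)$groupStatus$status
  }
  expect_identical(onePer("unavailable", "not_distinct"), "DCL")
  expect_identical(onePer("unavailable", "unavailable"), "UCS")
  expect_identical(onePer("distinct", "unavailable"), "CCS")
  expect_identical(onePer("not_distinct", "distinct"), "CCS")
  # property: CCS never appears without at least one distinct character set
  set.seed(8)
  states <- c("distinct", "not_distinct", "unavailable")
  for (rep in 1:50) {
    ac <- sample(states, 1)
    mo <- sample(states, 1)
    v <- onePer(ac, mo)
    if (v == "CCS") expect_true("distinct" %in% c(ac, mo))
    if (!"distinct" %in% c(ac, mo)) expect_false(v == "CCS")
  }
  part <- structure(list(groups = list("X"), overrides = data.frame()),
                    class = "lineagePartition")
  expect_error(
    integrateEvidence(part, data.frame(lineage = "Y",
                                       acoustic_status = "distinct",
                                       morpho_status = "distinct")),
    "missing from the evidence")
})
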