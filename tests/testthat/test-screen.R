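test_that("confidence membership needs co-detection at the same timepoint", {
  mk <- function(v) countsExperiment(matrix(v, nrow = 1))
  # detected in both libraries at t0
  ce <- mk(c(3, 0, 0, 2, 0, 0))
  expect_identical(nrow(buildConfidenceSet(ce)), 1L)
  expect_identical(buildConfidenceSet(ce)$member_timepoints, "t0")
  # detected in different timepoints of the two libraries: not a member
  expect_identical(nrow(buildConfidenceSet(mk(c(3, 0, 0, 0, 5, 0)))), 0L)
  # threshold is >= 2 junction reads, per sample
  expect_identical(nrow(buildConfidenceSet(mk(c(1, 0, 0, 9, 0, 0)))), 0L)
  expect_identical(nrow(buildConfidenceSet(mk(c(2, 0, 0, 2, 0, 0)))), 1L)
  # incomplete grids are refused with the missing cells named
  bad <- mk(c(3, 0, 0, 2, 0, 0))[, 1:5]
  expect_error(buildConfidenceSet(bad), "rnaser t48")
})

test_that("known-catalog annotation is an exact coordinate match", {
  set <- data.frame(circ_id = c("a", "b", "c"), contig = "c1",
                    start = c(10L, 50L, 90L), end = c(40L, 80L, 120L),
                    strand = c("+", "-", "+"))
  known <- data.frame(contig = "c1", start = c(10L, 50L), end = c(40L, 81L),
                      name = ".", score = 0L, strand = c("+", "-"))
  ann <- annotateKnown(set, known)
  # exact match annotated; off-by-one end is novel; absent is novel
  expect_identical(ann$annotation_status, c("annotated", "novel", "novel"))
  # empty catalog: everything novel
  expect_identical(annotateKnown(set, known[0, ])$annotation_status,
                   rep("novel", 3))
})

test_that("fold changes use same-library baselines with symmetric pseudocounts", {
  ce <- countsExperiment(matrix(c(10, 20, 5, 8, 16, 4), nrow = 1),
                         total_mapped = 1e6)
  fc <- foldChangeGrid(ce, pseudocount = FALSE)
  expect_equal(unname(fc[1, ]), c(2, 0.5, 2, 0.5))
  # zero baseline with pseudocount stays finite
  ce0 <- countsExperiment(matrix(c(0, 6, 0, 0, 6, 0), nrow = 1))
  fc0 <- foldChangeGrid(ce0)
  expect_true(all(is.finite(fc0)))
  expect_equal(unname(fc0[1, c(1, 3)]), c(7, 7))  # (6+1)/(0+1)
  # rescaling one sample's depth together with its counts is a no-op on
  # the normalized scale (exact in the pseudocount-free limit; the
  # pseudocount itself is deliberately depth-aware)
  counts <- matrix(c(10, 20, 5, 8, 16, 4), nrow = 1)
  tot <- rep(1e6, 6)
  grid <- sampleGrid(); grid$total_mapped_reads <- tot
  ceA <- CircExperiment(data.frame(contig = "c", start = 0L, end = 100L,
                                   strand = "+"), counts, grid)
  counts2 <- counts; counts2[1, 2] <- counts[1, 2] * 4L
  grid2 <- grid; grid2$total_mapped_reads[2] <- tot[2] * 4
  ceB <- CircExperiment(data.frame(contig = "c", start = 0L, end = 100L,
                                   strand = "+"), counts2, grid2)
  expect_equal(foldChangeGrid(ceA, pseudocount = FALSE),
               foldChangeGrid(ceB, pseudocount = FALSE))
})

test_that("direction classification applies the literal consensus thresholds", {
  expect_identical(classifyDirection(c(1.6, 1.7, 2.0, 1.2)), "up")
  expect_identical(classifyDirection(c(1.6, 1.7, 2.0, 0.8)), "unchanged")
  expect_identical(classifyDirection(c(0.5, 0.6, 0.62, 0.66)), "down")
  expect_identical(classifyDirection(c(0.5, 0.6, 0.62, 0.99)), "down")
  expect_identical(classifyDirection(c(0.5, 0.6, 0.62, 1.0)), "unchanged")
  # a value equal to 1.5 does not count toward the three, but as the
  # remaining fourth it only needs to clear 1.0 strictly
  expect_identical(classifyDirection(c(1.5, 1.6, 1.7, 1.8)), "up")
  expect_identical(classifyDirection(c(0.67, 0.5, 0.5, 0.5)), "down")
  expect_identical(classifyDirection(c(1.0, 1.6, 1.7, 1.8)), "unchanged")
  expect_identical(classifyDirection(c(1.0, 0.5, 0.55, 0.6)), "unchanged")
  expect_identical(classifyDirection(c(1.5, 1.5, 1.6, 1.7)), "unchanged")
  expect_error(classifyDirection(c(1, 2, NaN, 1)), "finite")
  # matrix form classifies row-wise
  m <- rbind(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_identical(unname(classifyDirection(m)), c("up", "unchanged"))
})

test_that("support filter requires junction reads in both libraries", {
  j <- c(rminus_t0 = 2, rminus_t24 = 4, rminus_t48 = 1,
         rnaser_t0 = 2, rnaser_t24 = 1, rnaser_t48 = 3)
  expect_true(supportFilter("up", j))
  j2 <- j; j2["rnaser_t24"] <- 1; j2["rnaser_t48"] <- 2
  expect_false(supportFilter("up", j2))
  jd <- c(rminus_t0 = 3, rminus_t24 = 0, rminus_t48 = 0,
          rnaser_t0 = 3, rnaser_t24 = 0, rnaser_t48 = 0)
  expect_true(supportFilter("down", jd))
  jd2 <- jd; jd2["rnaser_t0"] <- 2
  expect_false(supportFilter("down", jd2))
  expect_error(supportFilter("unchanged", j), "up or down")
})

test_that("direction rule is reciprocal-symmetric away from the 0.67 edge", {
  # 0.67 is not exactly 1/1.5; values in (1/0.67, 1.5]... i.e. fold
  # changes in (1.4925, 1.5] classify asymmetrically by construction:
  expect_identical(classifyDirection(rep(1.495, 4)), "unchanged")
  expect_identical(classifyDirection(1 / rep(1.495, 4)), "down")
  # away from that sliver the rule is symmetric
  set.seed(42)
  for (i in 1:200) {
    fc <- exp(runif(4, -1.2, 1.2))
    fc[fc > 1.4925 & fc <= 1.5] <- 1.6
    fc[fc >= 1 / 1.5 & fc < 0.67] <- 0.6
    d1 <- classifyDirection(fc)
    d2 <- classifyDirection(1 / fc)
    expect_identical(d1 == "up", d2 == "down")
  }
})

test_that("raising any fold change never demotes an up call", {
  rank <- c(down = 1, unchanged = 2, up = 3)
  set.seed(7)
  for (i in 1:200) {
    fc <- exp(runif(4, -1.5, 1.5))
    d0 <- classifyDirection(fc)
    k <- sample(4, 1)
    fc2 <- fc; fc2[k] <- fc2[k] * exp(runif(1, 0, 1))
    expect_gte(rank[classifyDirection(fc2)], rank[d0])
  }
})

test_that("the differential screen demotes unsupported calls and stays inside the set", {
  counts <- rbind(
    c(4, 10, 12, 5, 14, 15),   # up, supported
    c(2, 6, 7, 0, 2, 2),       # up by FC, unsupported in rnaser
    c(9, 3, 3, 8, 3, 3),       # down, supported
    c(5, 5, 5, 5, 5, 5),       # null
    c(0, 9, 9, 1, 9, 9))       # detected nowhere at t0 in rnaser
  ce <- countsExperiment(counts)
  cs <- buildConfidenceSet(ce)
  res <- screenDifferential(cs, ce)
  expect_true(all(res$circ_id %in% cs$circ_id))
  byId <- setNames(res$direction, res$circ_id)
  ids <- rownames(ce)
  expect_identical(unname(byId[ids[1]]), "up")
  expect_identical(unname(byId[ids[2]]), "unchanged")
  expect_false(res$support_pass[res$circ_id == ids[2]])
  expect_identical(unname(byId[ids[3]]), "down")
  expect_identical(unname(byId[ids[4]]), "unchanged")
  # row 5 is not in the confidence set (rnaser_t0 = 1 < 2 and no
  # co-detected timepoint at t0; t24/t48 co-detected, so it is a member)
  expect_true(ids[5] %in% cs$circ_id)
})

test_that("screen matches the one-expression rule on random count grids", {
  set.seed(11)
  n <- 300
  counts <- matrix(rpois(6 * n, lambda = rep(c(8, 12, 10, 25, 30, 28),
                                             each = n)), ncol = 6)
  ce <- countsExperiment(counts)
  cs <- buildConfidenceSet(ce)
  res <- screenDifferential(cs, ce)
  fc <- foldChangeGrid(ce)
  jr <- junctionReads(ce)
  for (i in seq_len(nrow(res))) {
    id <- res$circ_id[i]
    expect_identical(res$direction[i],
                     oracleScreenRule(fc[id, ], jr[id, ]))
  }
})
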