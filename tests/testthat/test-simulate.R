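test_that("generator is deterministic and respects its configuration", {
  cfg <- simConfig(seed = 3L, n_genes = 6L, n_circ = 6L,
                   exons_per_gene = c(4L, 8L), depth_per_sample = 500L)
  b1 <- buildToyGenome(cfg)
  b2 <- buildToyGenome(cfg)
  expect_identical(genomeSeqs(b1), genomeSeqs(b2))
  expect_identical(exonTable(b1), exonTable(b2))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeFastaDna(genomeSeqs(b1), file.path(d1, "g.fa"))
  writeFastaDna(genomeSeqs(b2), file.path(d2, "g.fa"))
  expect_identical(tools::md5sum(file.path(d1, "g.fa"))[[1]],
                   tools::md5sum(file.path(d2, "g.fa"))[[1]])

  # exon count bounds per gene (lncRNA gene deliberately small)
  ex <- exonTable(b1); tx <- transcriptTable(b1); g <- geneTable(b1)
  perTx <- table(ex$transcript_id)
  pc <- tx$transcript_id[tx$gene_id %in% g$gene_id[g$biotype == "protein_coding"]]
  expect_true(all(perTx[pc] >= 4 & perTx[pc] <= 8))

  # reads are reproducible too
  truth <- assignAbundances(chooseCircTemplates(b1, cfg), cfg)
  s1 <- simulateReads(b1, truth, cfg)
  s2 <- simulateReads(b1, truth, cfg)
  expect_identical(s1$samples$rminus_t0$mate1, s2$samples$rminus_t0$mate1)
  expect_identical(s1$junction_truth, s2$junction_truth)
})

test_that("every intron carries canonical splice flanks in transcript orientation", {
  fx <- smallSimFixture()
  seqs <- genomeSeqs(fx$bundle)
  ex <- exonTable(fx$bundle); tx <- transcriptTable(fx$bundle)
  g <- geneTable(fx$bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  for (tid in tx$transcript_id) {
    e <- ex[ex$transcript_id == tid, ]
    if (nrow(e) < 2) next
    strand <- g$strand[g$gene_id == tx2g[[tid]]]
    ctg <- seqs[[g$contig[g$gene_id == tx2g[[tid]]]]]
    for (i in seq_len(nrow(e) - 1)) {
      don <- substr(ctg, e$end[i] + 1, e$end[i] + 2)
      acc <- substr(ctg, e$start[i + 1] - 1, e$start[i + 1])
      if (strand == "+") {
        expect_identical(don, "GT"); expect_identical(acc, "AG")
      } else {
        expect_identical(don, "CT"); expect_identical(acc, "AC")
      }
    }
  }
})

test_that("template exon counts follow the configured distribution", {
  cfg <- simConfig(seed = 9L, n_genes = 140L, exons_per_gene = c(7L, 10L),
                   n_circ = 1000L,
                   circ_exon_count_dist = c(`2` = 0.5, `3` = 0.5))
  bundle <- buildToyGenome(cfg)
  truth <- chooseCircTemplates(bundle, cfg)
  k <- truth$templates$n_exons
  # binomial sampling oracle: mean 2.5, sd of the mean = 0.5/sqrt(n)
  expect_equal(mean(k), 2.5, tolerance = 0.1 / 2.5)
  expect_true(all(k %in% c(2L, 3L)) || mean(!k %in% c(2L, 3L)) < 0.05)
  # templates are contiguous interior exon runs of their transcript
  ex <- exonTable(bundle)
  i <- sample(nrow(truth$templates), 50)
  for (r in i) {
    tplr <- truth$templates[r, ]
    e <- ex[ex$transcript_id == tplr$transcript_id, ]
    a <- match(tplr$start, e$start); b <- match(tplr$end, e$end)
    expect_false(is.na(a) || is.na(b))
    expect_gt(a, 1); expect_lt(b, nrow(e))
    expect_identical(b - a + 1L, tplr$n_exons)
    expect_identical(sum(e$end[a:b] - e$start[a:b]), tplr$circ_len)
  }
  # requesting more templates than exist is an error
  cfgBig <- simConfig(seed = 9L, n_genes = 3L, n_circ = 500L)
  bSmall <- buildToyGenome(cfgBig)
  expect_error(chooseCircTemplates(bSmall, cfgBig), "exceeds")
})

test_that("abundance models behave as configured", {
  cfg0 <- simConfig(seed = 21L, n_genes = 30L, n_circ = 40L,
                    n_de_up = 2L, n_de_down = 2L, de_effect_up = 2,
                    circ_fraction_model = "constant", circ_fraction = 0.1)
  bundle <- buildToyGenome(cfg0)
  truth <- assignAbundances(chooseCircTemplates(bundle, cfg0), cfg0)
  # constant model: circ/linear ratio equals the planted fraction at t0
  lin <- truth$linear[truth$templates$gene_id, "rminus_t0"]
  ratio <- truth$circ[, "rminus_t0"] / lin
  expect_equal(unname(ratio), rep(0.1, nrow(truth$templates)))
  # planted up x2 doubles the expectation at t24 relative to t0
  up <- truth$de$circ_id[truth$de$direction == "up"]
  expect_equal(truth$circ[up, "rminus_t24"], 2 * truth$circ[up, "rminus_t0"])
  dn <- truth$de$circ_id[truth$de$direction == "down"]
  expect_equal(truth$circ[dn, "rminus_t48"],
               cfg0$de_effect_down * truth$circ[dn, "rminus_t0"])
  # RNase R thinning: survival factors applied per library
  expect_equal(truth$circ[, "rnaser_t0"],
               truth$circ[, "rminus_t0"] * cfg0$p_survive_circ)
  expect_equal(truth$linear[, "rnaser_t0"],
               truth$linear[, "rminus_t0"] * cfg0$p_survive_linear)
  # saturating model: ratio decreases with host expression over the truth
  cfg1 <- simConfig(seed = 21L, n_genes = 30L, n_circ = 40L,
                    circ_fraction_model = "saturating")
  t1 <- assignAbundances(chooseCircTemplates(bundle, cfg1), cfg1)
  lin1 <- t1$linear[t1$templates$gene_id, "rminus_t0"]
  r1 <- t1$circ[, "rminus_t0"] / lin1
  expect_lt(suppressWarnings(cor(r1, lin1, method = "spearman")), 0)
  # invalid survival ordering is rejected
  expect_error(simConfig(p_survive_circ = 0.01, p_survive_linear = 0.5),
               "p_survive_circ")
})

test_that("read simulation honours depth, read length and rolling circles", {
  fx <- smallSimFixture()
  cfg <- fx$cfg
  for (sid in names(fx$sim$samples)) {
    rs <- fx$sim$samples[[sid]]
    expect_length(rs$ids, cfg$depth_per_sample)
    expect_true(all(nchar(rs$mate1) == cfg$read_len))
    expect_true(all(nchar(rs$mate2) == cfg$read_len))
  }
  # error-free reconstruction of a wrapping circle fragment
  cfg0 <- simConfig(seed = 31L, n_genes = 6L, n_circ = 6L,
                    depth_per_sample = 2000L, error_rate = 0,
                    circ_fraction = 0.4)
  b <- buildToyGenome(cfg0)
  tr <- assignAbundances(chooseCircTemplates(b, cfg0), cfg0)
  sim <- simulateReads(b, tr, cfg0)
  fr <- sim$samples$rminus_t0$frags
  circFr <- which(fr$unit_type == "circ")
  tpl <- tr$templates
  checked <- 0L
  for (i in circFr) {
    t <- tpl[tpl$circ_id == fr$unit_id[i], ]
    cs <- templateCircSeq(b, t)
    C <- nchar(cs)
    u <- fr$start[i]
    if (u + cfg0$read_len <= C) next   # want a wrapping mate1
    expected <- paste0(substr(cs, u + 1, C),
                       substr(strrep(cs, 3), 1, cfg0$read_len - (C - u)))
    expect_identical(sim$samples$rminus_t0$mate1[i], expected)
    checked <- checked + 1L
    if (checked >= 5L) break
  }
  expect_gt(checked, 0L)
})

test_that("junction-spanning read counts match the fragment-model expectation", {
  fx <- smallSimFixture()
  lambda <- expectedJunctionReads(fx$bundle, fx$truth, fx$cfg)
  emp <- fx$sim$junction_truth
  # per circ and sample, empirical count within 3 sigma (Poisson) of the
  # enumeration-based expectation
  ok <- abs(emp - lambda) <= 3 * sqrt(pmax(lambda, 1))
  expect_gt(mean(ok), 0.98)
  # pooled counts agree tightly
  expect_lt(abs(sum(emp) - sum(lambda)) / sum(lambda), 0.1)
})

test_that("RNase R survival model produces the expected enrichment", {
  fx <- smallSimFixture()
  lambda <- expectedJunctionReads(fx$bundle, fx$truth, fx$cfg)
  emp <- fx$sim$junction_truth
  eligible <- lambda[, "rminus_t0"] >= 20
  expect_gt(sum(eligible), 0)
  expRatio <- lambda[eligible, "rnaser_t0"] / lambda[eligible, "rminus_t0"]
  empRatio <- emp[eligible, "rnaser_t0"] / pmax(emp[eligible, "rminus_t0"], 1)
  expect_true(all(abs(empRatio / expRatio - 1) < 0.5))
  # enrichment direction: treated library strongly enriches circles
  expect_true(all(expRatio > 1))
})

test_that("trimming truncates reads and qualities from the 3' end", {
  rs <- list(mate1 = c(strrep("A", 125)), mate2 = c(strrep("C", 125)),
             qual1 = strrep("I", 125), qual2 = strrep("I", 125))
  tr <- trimReads(rs, 80L)
  expect_identical(nchar(tr$mate1), 80L)
  expect_identical(nchar(tr$qual2), 80L)
  expect_identical(tr$mate1, strrep("A", 80))
  expect_identical(trimReads(tr, 80L)$mate1, tr$mate1)  # identity at 80
  expect_error(trimReads(tr, 100L), "exceeds")
})
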