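test_that("anchor extraction splits terminal segments and skips short reads", {
  r <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")  # 100 nt
  an <- extractAnchors(r, 20L)
  expect_identical(an$left, substr(r, 1, 20))
  expect_identical(an$right, substr(r, 81, 100))
  expect_null(extractAnchors(substr(r, 1, 39), 20L))
})

test_that("linear alignment maps exonic and spliced reads, forwards junction reads", {
  fx <- smallSimFixture()
  bundle <- fx$bundle; index <- fx$index
  seqs <- genomeSeqs(bundle)
  ex <- exonTable(bundle)
  # read equal to an exonic substring maps with 0 mismatches
  e <- ex[ex$end - ex$start >= 160, ][1, ]
  exonic <- substr(seqs[[1]], e$start + 10, e$start + 134)
  # read spanning a linear splice junction maps via the transcript sequence
  tid <- ex$transcript_id[1]
  ts <- transcriptSeq(bundle, tid)
  spliced <- substr(ts, 150, 274)
  # back-splice junction read has no end-to-end linear placement
  tpl <- fx$truth$templates[1, ]
  cs <- templateCircSeq(bundle, tpl)
  C <- nchar(cs)
  junc <- paste0(substr(cs, C - 59, C), substr(cs, 1, 65))
  reads <- list(ids = c("exonic", "spliced", "junction"),
                mate1 = c(exonic, spliced, junc),
                mate2 = oRevcomp(c(exonic, spliced, junc)))
  al <- alignReads(reads, index)
  a1 <- al$aln[al$aln$read_id == "exonic" & al$aln$mate == 1]
  expect_identical(nrow(a1), 1L)
  expect_identical(a1$mm, 0L)
  expect_identical(a1$ref_type, "contig")
  a2 <- al$aln[al$aln$read_id == "spliced" & al$aln$mate == 1]
  expect_identical(a2$ref_type, "transcript")
  expect_true(all(al$unmapped$read_id == "junction"))
  # brute-force confirmation: no linear end-to-end placement exists
  pl <- oLinearPlacements(junc, c(genomeSeqs(bundle),
                                  setNames(ts, tid)),
                          setNames(c(rep("contig", length(seqs)), "transcript"),
                                   c(names(seqs), tid)))
  expect_null(pl)
})

test_that("breakpoint resolution accepts the true junction and rejects mutants", {
  g <- junctionFixture()
  s <- 100L; e <- 200L; L <- 125L
  read <- makeJunctionRead(g, s, e, b = 60L, L = L)
  # anchors: left 20 of read sits at e-60; right 20 at s+(L-60)-20
  leftPos <- e - 60L
  rightPos <- s + (L - 60L) - 20L
  res <- resolveBreakpoint(read, g, leftPos, rightPos)
  expect_identical(res$status, "ok")
  expect_identical(res$start, s)
  expect_identical(res$end, e)
  expect_identical(res$strand, "+")
  expect_identical(res$offset, 60L)
  expect_identical(res$mm, 0L)

  # GT -> GC at the donor kills the call
  g2 <- g; substr(g2, 202, 202) <- "C"
  expect_identical(resolveBreakpoint(read, g2, leftPos, rightPos)$status,
                   "no_gtag")

  # span above the ceiling is rejected before scoring
  expect_identical(
    resolveBreakpoint(read, g, leftPos, rightPos, max_circ_len = 50L)$status,
    "span_exceeded")

  # three mismatches near the breakpoint exceed the allowance
  read3 <- read
  substr(read3, 58, 58) <- if (substr(read3, 58, 58) == "A") "C" else "A"
  substr(read3, 60, 60) <- if (substr(read3, 60, 60) == "A") "C" else "A"
  substr(read3, 62, 62) <- if (substr(read3, 62, 62) == "A") "C" else "A"
  expect_identical(resolveBreakpoint(read3, g, leftPos, rightPos)$status,
                   "too_many_mm")
})

test_that("equal-scoring duplicated junction contexts are discarded as ambiguous", {
  # two concentric rings share the read: ring 1 = [100, 200) and ring 2 =
  # [96, 196), both with valid AG|circle|GT flanks, with the four bases
  # [96,100) identical to [196,200) so the breakpoint offsets b = 60 and
  # b = 56 score identically (0 mismatches each)
  g <- junctionFixture(seed = 13L)
  substr(g, 95, 96) <- "AG"    # acceptor for ring-2 start 96
  substr(g, 97, 98) <- "GT"    # [96,98)  == [196,198)
  substr(g, 99, 100) <- "AG"   # acceptor for ring-1 start 100; == [198,200)
  substr(g, 197, 198) <- "GT"  # donor for ring-2 end 196
  substr(g, 199, 200) <- "AG"  # circle-end bases mirror [98,100)
  substr(g, 201, 202) <- "GT"  # donor for ring-1 end 200
  read <- makeJunctionRead(g, 100L, 200L, b = 60L)
  res <- resolveBreakpoint(read, g, 140L, 145L)
  expect_identical(res$status, "ambiguous")
  # removing the inner ring's acceptor restores a unique breakpoint
  g2 <- g; substr(g2, 95, 96) <- "CC"
  res2 <- resolveBreakpoint(read, g2, 140L, 145L)
  expect_identical(res2$status, "ok")
  expect_identical(res2$start, 100L)
  expect_identical(res2$end, 200L)
})

test_that("repeat filtering drops duplicated junction context and multi-hit anchors", {
  fx <- smallSimFixture()
  bundle <- fx$bundle
  tpl <- fx$truth$templates[1, ]
  cand <- data.frame(contig = tpl$contig, start = tpl$start, end = tpl$end,
                     strand = tpl$strand, max_anchor_hits = 1L)
  expect_true(filterRepetitive(cand, bundle))
  # anchor multi-mapping flag
  cand2 <- cand; cand2$max_anchor_hits <- 2L
  expect_false(filterRepetitive(cand2, bundle))
  # plant an exact copy of the junction sequence elsewhere in the genome
  seqs <- genomeSeqs(bundle)
  ctg <- seqs[[tpl$contig]]
  jseq <- paste0(substr(ctg, tpl$end - 19L, tpl$end),
                 substr(ctg, tpl$start + 1L, tpl$start + 20L))
  dupSeqs <- c(seqs, dup = paste0(strrep("A", 30), jseq, strrep("C", 30)))
  dupBundle <- GenomeBundle(dupSeqs, geneTable(bundle),
                            transcriptTable(bundle), exonTable(bundle))
  expect_false(filterRepetitive(cand, dupBundle))
})

test_that("a circle inside a two-copy segmental duplication is dropped", {
  # toy genome whose circle-bearing segment appears twice
  set.seed(17)
  seg <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
  substr(seg, 99, 100) <- "AG"; substr(seg, 201, 202) <- "GT"
  g <- paste0(seg, strrep("T", 50), seg)
  genes <- data.frame(gene_id = "gd", contig = "cd", strand = "+",
                      biotype = "other")
  txs <- data.frame(transcript_id = "gd.t1", gene_id = "gd",
                    cds_start = NA_integer_, cds_end = NA_integer_)
  exons <- data.frame(transcript_id = "gd.t1", start = 100L, end = 200L)
  bundle <- GenomeBundle(c(cd = g), genes, txs, exons)
  index <- buildAlignmentIndex(bundle)
  read <- makeJunctionRead(g, 100L, 200L, b = 60L)
  unm <- data.table::data.table(read_id = "r1", mate = 1L, seq = read)
  jr <- findJunctionReads(unm, bundle, index)
  # both anchors hit two loci: discarded as repetitive before resolution
  expect_identical(nrow(jr$calls), 0L)
  expect_identical(unname(jr$rejects["repetitive"]), 1L)
  # a candidate carrying the multi-locus anchor flag is dropped too
  cand <- data.frame(contig = "cd", start = 100L, end = 200L, strand = "+",
                     max_anchor_hits = 2L)
  expect_false(filterRepetitive(cand, bundle))
})

test_that("mate consistency distinguishes inside, outside and junction mates", {
  fx <- smallSimFixture()
  index <- fx$index
  call <- data.frame(read_id = "p1", mate = 1L, contig = "c1",
                     start = 1000L, end = 1600L, strand = "+")
  mkAln <- function(pos, strand = "+", ref = "c1", ref_type = "contig") {
    a <- data.table::data.table(read_id = "p1", mate = 2L, ref = ref,
                                ref_type = ref_type, pos = pos,
                                strand = strand, mm = 0L, n_best = 1L)
    attr(a, "read_len") <- 125L
    a
  }
  # mate inside the circle interval, antisense orientation: consistent
  expect_true(checkMateConsistency(call, mkAln(1200L, "-"), NULL, index))
  # mate far downstream: inconsistent
  expect_false(checkMateConsistency(call, mkAln(11600L, "-"), NULL, index))
  # wrong orientation: inconsistent
  expect_false(checkMateConsistency(call, mkAln(1200L, "+"), NULL, index))
  # unmapped mate that spans the same back-splice: consistent
  mateCall <- data.frame(read_id = "p1", mate = 2L, contig = "c1",
                         start = 1000L, end = 1600L, strand = "+")
  expect_true(checkMateConsistency(call, NULL, mateCall, index))
  # unmapped mate with no junction call: inconsistent
  expect_false(checkMateConsistency(call, NULL, NULL, index))
})

test_that("both mates wrapping a short circle still count as one fragment", {
  # short circle (~150 nt) with fragment longer than the circumference:
  # both mates span the back-splice; support must count one fragment
  cfg <- simConfig(seed = 19L, n_genes = 5L, exon_len = c(140L, 160L),
                   n_circ = 4L,
                   circ_exon_count_dist = c(`1` = 1),
                   depth_per_sample = 3000L, error_rate = 0,
                   circ_fraction = 0.5, frag_len_mean = 200,
                   frag_len_sd = 20)
  b <- buildToyGenome(cfg)
  tr <- assignAbundances(chooseCircTemplates(b, cfg), cfg)
  sim <- simulateReads(b, tr, cfg)
  det <- detectCircRNAs(b, sim$samples["rminus_t0"],
                        data.frame(sample_id = "rminus_t0",
                                   library = "rminus", timepoint = "t0"))
  jr <- junctionReads(det$circ)[, "rminus_t0"]
  truthJr <- sim$junction_truth[, "rminus_t0"]
  cc <- circCoords(det$circ)
  key <- paste(cc$contig, cc$start, cc$end, cc$strand)
  tpl <- tr$templates
  tkey <- paste(tpl$contig, tpl$start, tpl$end, tpl$strand)
  m <- match(key, tkey)
  expect_false(anyNA(m))
  # no double counting: called support never exceeds simulated spanning pairs
  expect_true(all(jr <= truthJr[m]))
  expect_gt(sum(jr), 0)
})

test_that("cross-sample merging keeps counts but applies the detection threshold", {
  calls <- list(
    s1 = data.frame(read_id = c("a", "b", "c"), mate = 1L, contig = "cT",
                    start = 100L, end = 650L, strand = "+",
                    max_anchor_hits = 1L),
    s2 = data.frame(read_id = "d", mate = 1L, contig = "cT",
                    start = 100L, end = 650L, strand = "+",
                    max_anchor_hits = 1L),
    s3 = data.frame(read_id = c("e", "e"), mate = c(1L, 2L), contig = "cT",
                    start = 100L, end = 650L, strand = "+",
                    max_anchor_hits = 1L))
  st <- data.frame(sample_id = c("s1", "s2", "s3"),
                   library = "rminus", timepoint = c("t0", "t24", "t48"),
                   total_mapped_reads = 1000L)
  bundle <- tinyBundle()
  ce <- callCircRNAs(calls, st, bundle)
  expect_identical(nrow(ce), 1L)
  jr <- junctionReads(ce)
  # same junction in 3 samples: one candidate, three count entries
  expect_identical(unname(jr[1, ]), c(3L, 1L, 1L))
  # pair with both mates spanning counts once (s3)
  det <- detectedMatrix(ce)
  expect_identical(unname(det[1, ]), c(TRUE, FALSE, FALSE))
})

test_that("accepted calls re-satisfy the GT-AG invariant and span limit", {
  fx <- smallSimFixture()
  cc <- circCoords(fx$det$circ)
  seqs <- genomeSeqs(fx$bundle)
  for (i in seq_len(nrow(cc))) {
    ctg <- seqs[[cc$contig[i]]]
    don <- substr(ctg, cc$end[i] + 1, cc$end[i] + 2)
    acc <- substr(ctg, cc$start[i] - 1, cc$start[i])
    if (cc$strand[i] == "+") {
      expect_identical(don, "GT"); expect_identical(acc, "AG")
    } else {
      expect_identical(don, "CT"); expect_identical(acc, "AC")
    }
    expect_lte(cc$end[i] - cc$start[i], 100000L)
  }
  # junction support conservation against simulated spanning pairs
  tpl <- fx$truth$templates
  tkey <- paste(tpl$contig, tpl$start, tpl$end, tpl$strand)
  key <- paste(cc$contig, cc$start, cc$end, cc$strand)
  m <- match(key, tkey)
  jr <- junctionReads(fx$det$circ)
  for (i in which(!is.na(m)))
    expect_true(all(jr[i, ] <= fx$sim$junction_truth[m[i], ]))
})
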