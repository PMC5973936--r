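# Shared fixtures, built in code and memoized for the session.

.fixtureCache <- new.env(parent = emptyenv())

# small full simulate->detect fixture shared across detect/quantify tests
smallSimFixture <- function() {
  if (!is.null(.fixtureCache$small)) return(.fixtureCache$small)
  cfg <- simConfig(seed = 7L, n_genes = 8L, n_circ = 10L,
                   depth_per_sample = 3000L, intron_len = c(300L, 600L),
                   circ_fraction = 0.3)
  bundle <- buildToyGenome(cfg)
  truth <- assignAbundances(chooseCircTemplates(bundle, cfg), cfg)
  sim <- simulateReads(bundle, truth, cfg)
  index <- buildAlignmentIndex(bundle)
  det <- detectCircRNAs(bundle, sim$samples, sampleGrid(), index = index)
  .fixtureCache$small <- list(cfg = cfg, bundle = bundle, truth = truth,
                              sim = sim, det = det, index = index)
  .fixtureCache$small
}

# hand-built contig with one plus-strand circle [100, 200) flanked by
# canonical splice sites, for breakpoint-resolution unit tests
junctionFixture <- function(seed = 11L, clen = 400L) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
             collapse = "")
  substr(g, 99, 100) <- "AG"   # acceptor upstream of start 100 (0-based)
  substr(g, 201, 202) <- "GT"  # donor at end 200 (0-based)
  g
}

# read of length L crossing the [s, e) back-splice with b bases from the
# circle-end side (genome-forward frame)
makeJunctionRead <- function(genome, s, e, b, L = 125L) {
  left <- substr(genome, e - b + 1L, e)          # [e-b, e)
  right <- substr(genome, s + 1L, s + (L - b))   # [s, s+L-b)
  paste0(left, right)
}

# tiny GenomeBundle written out by hand for io/characterize edge cases:
# one plus-strand coding gene (4 exons), one minus-strand coding gene
# (3 exons), a 2-exon lncRNA, and a single-exon antisense gene nested in
# the first gene's intron 1
tinyBundle <- function() {
  if (!is.null(.fixtureCache$tiny)) return(.fixtureCache$tiny)
  set.seed(5)
  seqchars <- sample(c("A", "C", "G", "T"), 6000, replace = TRUE)
  g <- paste(seqchars, collapse = "")
  fixIntron <- function(g, s, e, strand) {
    # intron [s, e) with canonical flanks in transcript orientation
    if (strand == "+") {
      substr(g, s + 1L, s + 2L) <- "GT"; substr(g, e - 1L, e) <- "AG"
    } else {
      substr(g, s + 1L, s + 2L) <- "CT"; substr(g, e - 1L, e) <- "AC"
    }
    g
  }
  # gene gp (+): exons [100,250) [500,650) [900,1050) [1300,1450)
  gpEx <- data.frame(transcript_id = "gp.t1",
                     start = c(100L, 500L, 900L, 1300L),
                     end = c(250L, 650L, 1050L, 1450L))
  for (i in 1:3) g <- fixIntron(g, gpEx$end[i], gpEx$start[i + 1], "+")
  # gene gm (-): exons [2000,2150) [2400,2550) [2800,2950)
  gmEx <- data.frame(transcript_id = "gm.t1",
                     start = c(2000L, 2400L, 2800L),
                     end = c(2150L, 2550L, 2950L))
  for (i in 1:2) g <- fixIntron(g, gmEx$end[i], gmEx$start[i + 1], "-")
  # lncRNA gl (+): exons [3500,3650) [3900,4050)
  glEx <- data.frame(transcript_id = "gl.t1",
                     start = c(3500L, 3900L), end = c(3650L, 4050L))
  g <- fixIntron(g, glEx$end[1], glEx$start[2], "+")
  # antisense single-exon gene ga (-) inside gp's intron 1
  gaEx <- data.frame(transcript_id = "ga.t1", start = 300L, end = 420L)
  genes <- data.frame(
    gene_id = c("gp", "gm", "gl", "ga"),
    contig = "cT", strand = c("+", "-", "+", "-"),
    biotype = c("protein_coding", "protein_coding", "lncRNA", "other"))
  txs <- data.frame(
    transcript_id = c("gp.t1", "gm.t1", "gl.t1", "ga.t1"),
    gene_id = c("gp", "gm", "gl", "ga"),
    cds_start = c(575L, 2100L, NA, NA),   # gp: mid exon2 .. mid exon3
    cds_end = c(975L, 2500L, NA, NA))     # gm: mid exon1 .. mid exon2
  exons <- rbind(gpEx, gmEx, glEx, gaEx)
  .fixtureCache$tiny <- GenomeBundle(c(cT = g), genes, txs, exons)
  .fixtureCache$tiny
}

# the default study-condition simulation (full grid, seed 42) + detection
defaultSimFixture <- function() {
  if (!is.null(.fixtureCache$default)) return(.fixtureCache$default)
  cfg <- simConfig(seed = 42L)
  bundle <- buildToyGenome(cfg)
  truth <- assignAbundances(chooseCircTemplates(bundle, cfg), cfg)
  sim <- simulateReads(bundle, truth, cfg)
  index <- buildAlignmentIndex(bundle)
  det <- detectCircRNAs(bundle, sim$samples, sampleGrid(), index = index)
  .fixtureCache$default <- list(cfg = cfg, bundle = bundle, truth = truth,
                                sim = sim, det = det, index = index)
  .fixtureCache$default
}

circRow <- function(contig, start, end, strand) {
  data.frame(circ_id = circId(contig, start, end), contig = contig,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

# CircExperiment from a bare count matrix over the standard grid
countsExperiment <- function(counts, total_mapped = 4e6) {
  grid <- sampleGrid()
  grid$total_mapped_reads <- total_mapped
  n <- nrow(counts)
  cand <- data.frame(contig = "cX", start = (seq_len(n) - 1L) * 500L,
                     end = (seq_len(n) - 1L) * 500L + 200L, strand = "+")
  colnames(counts) <- grid$sample_id
  CircExperiment(cand, counts, grid)
}
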