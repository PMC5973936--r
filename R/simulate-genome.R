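# Synthetic-data generator, part 1: configuration and toy genome.
#
# The generator emulates the study design the pipeline targets: stranded
# total-RNA paired-end libraries over a 2 (RNase R-untreated "rminus" /
# -treated "rnaser") x 3 (t0/t24/t48) sample grid, with multi-exon genes,
# exon-derived circRNAs at varying circular:linear proportions, back-splice
# junction coverage, and preferential RNase R survival of circles.

#' Simulation configuration
#'
#' Defaults define the study conditions of the package's simulated
#' experiments (see the methods vignette for rationale): 20 multi-exon
#' genes on a ~100 kb contig, 30 exon-derived circRNAs whose exon-count
#' distribution peaks at 2-3 exons, 2 x 125 bp paired-end reads, fragment
#' length ~N(250, 30), RNase R modeled as per-molecule Bernoulli survival
#' (circular 0.9, linear 0.05), and 1e4 read pairs per sample.
#'
#' @param seed integer RNG seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param n_genes number of genes placed on the contig.
#' @param exons_per_gene integer range (lo, hi) of exons per gene.
#' @param exon_len,intron_len,intergenic_len integer ranges (bp).
#' @param read_len read length (bp); mates have equal length.
#' @param frag_len_mean,frag_len_sd fragment (insert) length distribution,
#'   truncated normal, lower bound `read_len`.
#' @param n_circ number of circRNA templates to plant.
#' @param circ_exon_count_dist named probability vector over exon counts.
#' @param circ_fraction_model `"saturating"` (circ/linear ratio decreases
#'   with host expression), `"constant"` (by-product null: fixed ratio), or
#'   `"independent"` (ratio drawn independently of host expression).
#' @param circ_fraction base circular:linear proportion.
#' @param p_survive_linear,p_survive_circ per-molecule RNase R survival
#'   probabilities; circular must be >= linear.
#' @param depth_per_sample read pairs per sample (the untreated libraries
#'   always sequence exactly this many pairs).
#' @param depth_model `"fixed"`: every sample sequences `depth_per_sample`
#'   pairs (equal-depth protocol; the treated library's surviving pool is
#'   renormalized, so circular junction counts are strongly enriched, as
#'   observed in real equal-depth RNase R libraries). `"proportional"`:
#'   treated samples are sequenced at the untreated library's per-molecule
#'   sampling rate (pairs scale with surviving material), isolating the
#'   per-molecule survival model — linear read counts drop by
#'   `1/p_survive_linear` and circular junction counts by `p_survive_circ`.
#' @param circ_max_per_gene cap on circRNA templates per host gene
#'   (default unlimited; set 1 to forbid nested/overlapping circles, whose
#'   internal splice reads contaminate the flanking-exon linear estimate).
#' @param de_spec optional data.frame (`circ_id`, `direction`, `effect`)
#'   of planted differential regulation applied at t24 and t48; if NULL,
#'   `n_de_up`/`n_de_down` circs are chosen with effects
#'   `de_effect_up`/`de_effect_down`.
#' @param n_de_up,n_de_down,de_effect_up,de_effect_down planted DE defaults.
#'   Up effects must exceed 1.5 and down effects be below 0.67 so planted
#'   truths are detectable by the screen.
#' @param error_rate per-base substitution sequencing error rate.
#' @param unspliced_fraction fraction of linear molecules sampled from
#'   unspliced pre-mRNA (provides exon-intron boundary reads).
#' @param linear_meanlog,linear_sdlog log-normal host-gene abundance.
#' @param min_anchor minimum bases a junction-spanning read keeps on each
#'   side of the back-splice (matches the detector's anchor length).
#' @param contig contig name.
#' @param contig_len optional fixed contig length; an error if the gene
#'   layout does not fit.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(seed = 42L,
                      n_genes = 20L,
                      exons_per_gene = c(4L, 8L),
                      exon_len = c(120L, 300L),
                      intron_len = c(400L, 900L),
                      intergenic_len = c(300L, 800L),
                      read_len = 125L,
                      frag_len_mean = 250,
                      frag_len_sd = 30,
                      n_circ = 30L,
                      circ_exon_count_dist = c(`1` = 0.15, `2` = 0.35,
                                               `3` = 0.30, `4` = 0.15,
                                               `5` = 0.05),
                      circ_fraction_model = c("saturating", "constant",
                                              "independent"),
                      circ_fraction = 0.25,
                      p_survive_linear = 0.05,
                      p_survive_circ = 0.9,
                      depth_per_sample = 10000L,
                      depth_model = c("fixed", "proportional"),
                      circ_max_per_gene = Inf,
                      de_spec = NULL,
                      n_de_up = 5L, n_de_down = 5L,
                      de_effect_up = 2.5, de_effect_down = 0.4,
                      error_rate = 0.001,
                      unspliced_fraction = 0.05,
                      linear_meanlog = log(10), linear_sdlog = 1,
                      min_anchor = 20L,
                      contig = "c1",
                      contig_len = NULL) {
  circ_fraction_model <- match.arg(circ_fraction_model)
  depth_model <- match.arg(depth_model)
  if (p_survive_circ < p_survive_linear)
    stopf("p_survive_circ must be >= p_survive_linear (RNase R degrades linear RNA preferentially)")
  if (abs(sum(circ_exon_count_dist) - 1) > 1e-8)
    stopf("circ_exon_count_dist must sum to 1")
  if (de_effect_up <= 1.5 || de_effect_down >= 0.67)
    stopf("planted effects must be detectable: up > 1.5, down < 0.67")
  if (!is.null(de_spec)) {
    if (any(de_spec$direction == "up" & de_spec$effect <= 1.5) ||
        any(de_spec$direction == "down" & de_spec$effect >= 0.67))
      stopf("de_spec effects must be > 1.5 (up) or < 0.67 (down)")
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              intergenic_len = as.integer(intergenic_len),
              read_len = as.integer(read_len),
              frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
              n_circ = as.integer(n_circ),
              circ_exon_count_dist = circ_exon_count_dist,
              circ_fraction_model = circ_fraction_model,
              circ_fraction = circ_fraction,
              p_survive_linear = p_survive_linear,
              p_survive_circ = p_survive_circ,
              depth_per_sample = as.integer(depth_per_sample),
              depth_model = depth_model,
              circ_max_per_gene = circ_max_per_gene,
              de_spec = de_spec,
              n_de_up = as.integer(n_de_up), n_de_down = as.integer(n_de_down),
              de_effect_up = de_effect_up, de_effect_down = de_effect_down,
              error_rate = error_rate,
              unspliced_fraction = unspliced_fraction,
              linear_meanlog = linear_meanlog, linear_sdlog = linear_sdlog,
              min_anchor = as.integer(min_anchor),
              contig = contig, contig_len = contig_len)
  class(cfg) <- "simConfig"
  cfg
}

#' The 2 x 3 sample grid
#'
#' @return data.frame with `sample_id`, `library`, `timepoint` for the six
#'   samples rminus/rnaser x t0/t24/t48.
#' @export
sampleGrid <- function() {
  g <- expand.grid(timepoint = c("t0", "t24", "t48"),
                   library = c("rminus", "rnaser"),
                   stringsAsFactors = FALSE)[, 2:1]
  g$sample_id <- paste(g$library, g$timepoint, sep = "_")
  g[, c("sample_id", "library", "timepoint")]
}

# one gene: exon/intron lengths and strand-aware canonical splice flanks.
# On "+", introns begin GT and end AG in genomic forward orientation; on
# "-" the transcript reads right-to-left so the genomic forward intron
# begins CT (acceptor, rc of AG) and ends AC (donor, rc of GT).
.makeGeneSeq <- function(nEx, exLens, inLens, strand) {
  pieces <- character(0)
  rel <- integer(0); cursor <- 0L
  exStart <- integer(nEx); exEnd <- integer(nEx)
  for (i in seq_len(nEx)) {
    exStart[i] <- cursor
    pieces <- c(pieces, randomDna(exLens[i]))
    cursor <- cursor + exLens[i]
    exEnd[i] <- cursor
    if (i < nEx) {
      intr <- randomDna(inLens[i])
      if (strand == "+") {
        substr(intr, 1L, 2L) <- "GT"
        substr(intr, inLens[i] - 1L, inLens[i]) <- "AG"
      } else {
        substr(intr, 1L, 2L) <- "CT"
        substr(intr, inLens[i] - 1L, inLens[i]) <- "AC"
      }
      pieces <- c(pieces, intr)
      cursor <- cursor + inLens[i]
    }
  }
  list(seq = paste(pieces, collapse = ""), exStart = exStart, exEnd = exEnd,
       len = cursor)
}

#' Build a toy genome with canonical gene models
#'
#' Places `n_genes` non-overlapping (per strand) multi-exon genes on one
#' contig with alternating strands. Every intron carries canonical splice
#' flanks (GT..AG in transcript orientation), so both linear splice borders
#' and back-splice borders of exon-run circles validate the GT-AG rule by
#' construction. The layout includes one multi-exon lncRNA gene and one
#' single-exon antisense gene nested in the first sufficiently large intron
#' of a protein-coding gene. Deterministic given `config$seed`.
#'
#' @param config a [simConfig()].
#' @param outdir optional directory; if given, writes `genome.fa` and
#'   `genes.gtf` there.
#' @return a [GenomeBundle-class].
#' @export
buildToyGenome <- function(config, outdir = NULL) {
  set.seed(subSeed(config$seed, 0L))
  nG <- config$n_genes
  strands <- rep(c("+", "-"), length.out = nG)
  lncIdx <- nG  # last gene is the lncRNA
  genes <- vector("list", nG)
  cursor <- sample(config$intergenic_len[1]:config$intergenic_len[2], 1)
  grows <- list(); txrows <- list(); exrows <- list(); seqs <- character(0)
  gaps <- character(0)
  antisensePlaced <- FALSE; anti <- NULL
  for (i in seq_len(nG)) {
    nEx <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
    if (i == lncIdx) nEx <- max(3L, min(nEx, 4L))
    exLens <- sample(config$exon_len[1]:config$exon_len[2], nEx, replace = TRUE)
    inLens <- if (nEx > 1)
      sample(config$intron_len[1]:config$intron_len[2], nEx - 1L, replace = TRUE)
    else integer(0)
    gs <- .makeGeneSeq(nEx, exLens, inLens, strands[i])
    gid <- sprintf("g%02d", i)
    tid <- paste0(gid, ".t1")
    biotype <- if (i == lncIdx) "lncRNA" else "protein_coding"
    exS <- gs$exStart + cursor; exE <- gs$exEnd + cursor
    cdsS <- NA_integer_; cdsE <- NA_integer_
    if (biotype == "protein_coding") {
      # CDS starts mid exon 2 (every 4th gene: mid exon 3, leaving exon-2
      # circles in the UTR) and ends mid second-to-last exon
      j1 <- if (i %% 4L == 0L && nEx >= 5L) 3L else 2L
      j2 <- max(j1, nEx - 1L)
      cdsS <- as.integer(floor((exS[j1] + exE[j1]) / 2))
      cdsE <- as.integer(floor((exS[j2] + exE[j2]) / 2))
      if (cdsE <= cdsS) cdsE <- cdsS + 1L
    }
    # nest the antisense single-exon gene in the first roomy intron
    if (!antisensePlaced && biotype == "protein_coding" && nEx >= 2) {
      intrLen <- if (nEx > 1) inLens[1] else 0L
      aLen <- 150L
      if (intrLen >= aLen + 60L) {
        aStart <- exE[1] - cursor + 30L  # relative to gene, inside intron 1
        aStrand <- if (strands[i] == "+") "-" else "+"
        anti <- list(gene_id = "gAS", tid = "gAS.t1",
                     start = cursor + aStart, end = cursor + aStart + aLen,
                     strand = aStrand)
        antisensePlaced <- TRUE
      }
    }
    grows[[i]] <- data.frame(gene_id = gid, contig = config$contig,
                             strand = strands[i], biotype = biotype)
    txrows[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                              cds_start = cdsS, cds_end = cdsE)
    exrows[[i]] <- data.frame(transcript_id = tid, start = exS, end = exE)
    seqs <- c(seqs, gs$seq)
    cursor <- cursor + gs$len
    gap <- sample(config$intergenic_len[1]:config$intergenic_len[2], 1)
    gaps <- c(gaps, randomDna(gap))
    cursor <- cursor + gap
  }
  # assemble contig
  firstGap <- exrows[[1]]$start[1]
  contigSeq <- paste0(randomDna(firstGap),
                      paste(mapply(function(s, g) paste0(s, g), seqs, gaps),
                            collapse = ""))
  if (!is.null(config$contig_len)) {
    if (nchar(contigSeq) > config$contig_len)
      stopf("gene layout (%d bp) does not fit contig_len %d",
            nchar(contigSeq), config$contig_len)
    contigSeq <- paste0(contigSeq,
                        randomDna(config$contig_len - nchar(contigSeq)))
  }
  genesDf <- do.call(rbind, grows)
  txDf <- do.call(rbind, txrows)
  exDf <- do.call(rbind, exrows)
  if (!is.null(anti)) {
    genesDf <- rbind(genesDf, data.frame(gene_id = anti$gene_id,
                                         contig = config$contig,
                                         strand = anti$strand,
                                         biotype = "other"))
    txDf <- rbind(txDf, data.frame(transcript_id = anti$tid,
                                   gene_id = anti$gene_id,
                                   cds_start = NA_integer_,
                                   cds_end = NA_integer_))
    exDf <- rbind(exDf, data.frame(transcript_id = anti$tid,
                                   start = anti$start, end = anti$end))
  }
  bundle <- GenomeBundle(setNames(contigSeq, config$contig),
                         genesDf, txDf, exDf)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeFastaDna(genomeSeqs(bundle), file.path(outdir, "genome.fa"))
    writeGeneModels(bundle, file.path(outdir, "genes.gtf"))
  }
  bundle
}

#' Spliced transcript sequence (transcript orientation)
#'
#' @param bundle a [GenomeBundle-class].
#' @param transcript_id transcript id.
#' @return character scalar; exons concatenated 5'->3' (reverse-complemented
#'   for minus-strand genes).
#' @export
transcriptSeq <- function(bundle, transcript_id) {
  ex <- exonTable(bundle)
  e <- ex[ex$transcript_id == transcript_id, ]
  if (!nrow(e)) stopf("unknown transcript %s", transcript_id)
  tx <- transcriptTable(bundle)
  g <- geneTable(bundle)
  gi <- g[g$gene_id == tx$gene_id[tx$transcript_id == transcript_id], ]
  seq <- genomeSeqs(bundle)[[gi$contig]]
  s <- paste(substr(rep(seq, nrow(e)), e$start + 1L, e$end), collapse = "")
  if (gi$strand == "-") revcompChr(s) else s
}

# pre-mRNA (gene span) sequence in transcript orientation
preMrnaSeq <- function(bundle, transcript_id) {
  ex <- exonTable(bundle)
  e <- ex[ex$transcript_id == transcript_id, ]
  tx <- transcriptTable(bundle)
  g <- geneTable(bundle)
  gi <- g[g$gene_id == tx$gene_id[tx$transcript_id == transcript_id], ]
  seq <- genomeSeqs(bundle)[[gi$contig]]
  s <- subseq0(seq, min(e$start), max(e$end))
  if (gi$strand == "-") revcompChr(s) else s
}
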