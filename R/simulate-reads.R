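# Synthetic-data generator, part 3: read simulation.

# apply uniform substitution errors in place; returns modified reads
.addSubstitutions <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  L <- nchar(reads)
  nerr <- rbinom(length(reads), L, rate)
  hit <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample(L[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  reads
}

# does a mate crossing window [lo, hi] (absolute coordinates along the
# unrolled circle) contain a positive multiple of C?
.crossesBoundary <- function(lo, hi, C) {
  hiM <- floor(hi / C); loM <- ceiling(lo / C)
  hiM >= loM & hiM >= 1
}

#' Simulate stranded paired-end reads for the sample grid
#'
#' Fragments are sampled per sample in proportion to molecule count x
#' template length; circle fragments start uniformly on the circumference
#' and wrap (rolling circle), so reads can span the back-splice point.
#' Libraries are strand-specific with mate 1 on the transcript sense
#' strand; a configurable fraction of linear molecules is sampled from
#' unspliced pre-mRNA so exon-intron boundary reads exist. Substitution
#' errors at `config$error_rate`; no indels. Deterministic given
#' `config$seed`.
#'
#' @param bundle a [GenomeBundle-class].
#' @param truth abundance-annotated truth from [assignAbundances()].
#' @param config a [simConfig()].
#' @return list with one entry per sample (`ids`, `mate1`, `mate2`,
#'   `qual1`, `qual2`, `frags` truth table) plus `junction_truth`
#'   (circ x sample matrix of simulated junction-spanning pairs; a pair
#'   counts once even if both mates span) and `grid`.
#' @export
simulateReads <- function(bundle, truth, config) {
  tpl <- truth$templates
  grid <- truth$grid
  Lr <- config$read_len
  A <- config$min_anchor
  tx <- transcriptTable(bundle)
  txSeqs <- setNames(lapply(tx$transcript_id, transcriptSeq, bundle = bundle),
                     tx$transcript_id)
  preSeqs <- setNames(lapply(tx$transcript_id, preMrnaSeq, bundle = bundle),
                      tx$transcript_id)
  circSeqs <- setNames(
    lapply(seq_len(nrow(tpl)), function(i) templateCircSeq(bundle, tpl[i, ])),
    tpl$circ_id)
  junctionTruth <- matrix(0L, nrow(tpl), nrow(grid),
                          dimnames = list(tpl$circ_id, grid$sample_id))
  out <- list()
  for (j in seq_len(nrow(grid))) {
    sid <- grid$sample_id[j]
    set.seed(subSeed(config$seed, 10L + j))
    units <- .sampleUnits(bundle, truth, config, sid)
    uSeq <- character(nrow(units))
    for (i in seq_len(nrow(units))) {
      uSeq[i] <- switch(units$unit_type[i],
                        linear = txSeqs[[units$unit_id[i]]],
                        premrna = preSeqs[[units$unit_id[i]]],
                        circ = circSeqs[[units$unit_id[i]]])
    }
    uLen <- nchar(uSeq)
    w <- units$count * uLen
    n <- config$depth_per_sample
    if ((config$depth_model %||% "fixed") == "proportional" &&
        grid$library[j] == "rnaser") {
      # sequence the treated library at the untreated library's
      # per-molecule sampling rate: pairs scale with surviving material
      refUnits <- .sampleUnits(bundle, truth, config,
                               paste0("rminus_", grid$timepoint[j]))
      n <- max(1L, as.integer(round(config$depth_per_sample * sum(w) /
                                    sum(refUnits$count * uLen))))
    }
    drawn <- sample.int(nrow(units), n, replace = TRUE, prob = w)
    isCirc <- units$unit_type[drawn] == "circ"
    flen <- integer(n)
    # linear fragments bounded by template length (resampling rule);
    # circle fragments unbounded (rolling circle)
    if (any(!isCirc))
      flen[!isCirc] <- rtruncnormInt(sum(!isCirc), config$frag_len_mean,
                                     config$frag_len_sd, lo = Lr,
                                     hi = uLen[drawn[!isCirc]])
    if (any(isCirc))
      flen[isCirc] <- rtruncnormInt(sum(isCirc), config$frag_len_mean,
                                    config$frag_len_sd, lo = Lr)
    u <- integer(n)
    u[!isCirc] <- floor(runif(sum(!isCirc)) *
                        (uLen[drawn[!isCirc]] - flen[!isCirc] + 1L))
    u[isCirc] <- floor(runif(sum(isCirc)) * uLen[drawn[isCirc]])
    frag <- character(n)
    if (any(!isCirc)) {
      k <- which(!isCirc)
      frag[k] <- substr(uSeq[drawn[k]], u[k] + 1L, u[k] + flen[k])
    }
    if (any(isCirc)) {
      k <- which(isCirc)
      reps <- ceiling((u[k] + flen[k]) / uLen[drawn[k]])
      frag[k] <- substr(strrep(uSeq[drawn[k]], reps), u[k] + 1L,
                        u[k] + flen[k])
    }
    mate1 <- substr(frag, 1L, Lr)
    mate2 <- revcompChr(substr(frag, flen - Lr + 1L, flen))
    mate1 <- .addSubstitutions(mate1, config$error_rate)
    mate2 <- .addSubstitutions(mate2, config$error_rate)
    # junction truth: either mate crosses the back-splice with >= A bases
    # on both sides; a pair counts once
    spans <- rep(FALSE, n)
    if (any(isCirc)) {
      k <- which(isCirc)
      C <- uLen[drawn[k]]
      m1 <- .crossesBoundary(u[k] + A, u[k] + Lr - A, C)
      m2 <- .crossesBoundary(u[k] + flen[k] - Lr + A, u[k] + flen[k] - A, C)
      spans[k] <- m1 | m2
    }
    frags <- data.frame(
      read_id = sprintf("%s_f%06d", sid, seq_len(n)),
      unit_type = units$unit_type[drawn], unit_id = units$unit_id[drawn],
      gene_id = units$gene_id[drawn],
      start = u, frag_len = flen, spans_junction = spans,
      stringsAsFactors = FALSE)
    junctionTruth[, j] <- as.integer(
      table(factor(units$unit_id[drawn[spans]], levels = tpl$circ_id)))
    out[[sid]] <- list(ids = frags$read_id, mate1 = mate1, mate2 = mate2,
                       qual1 = rep(strrep("I", Lr), n),
                       qual2 = rep(strrep("I", Lr), n),
                       frags = frags)
  }
  list(samples = out, junction_truth = junctionTruth, grid = grid)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.gtf`, per-sample FASTQ pairs
#' (`<sample>_1.fastq`, `<sample>_2.fastq`), `truth_circ.tsv` (templates +
#' per-sample expected abundances and simulated junction-spanning pairs)
#' and `truth_expression.tsv` (per-gene linear abundances).
#'
#' @param bundle,truth,sim,config generator state ([buildToyGenome()],
#'   [assignAbundances()], [simulateReads()], [simConfig()]).
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
writeSimulatedDataset <- function(bundle, truth, sim, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeFastaDna(genomeSeqs(bundle), file.path(outdir, "genome.fa"))
  writeGeneModels(bundle, file.path(outdir, "genes.gtf"))
  for (sid in names(sim$samples)) {
    writeFastqPair(sim$samples[[sid]],
                   file.path(outdir, paste0(sid, "_1.fastq")),
                   file.path(outdir, paste0(sid, "_2.fastq")))
  }
  tpl <- truth$templates
  tcirc <- data.frame(tpl[, c("circ_id", "gene_id", "transcript_id", "contig",
                              "strand", "start", "end", "n_exons",
                              "circ_len")],
                      truth$circ,
                      setNames(as.data.frame(sim$junction_truth),
                               paste0("jr_", colnames(sim$junction_truth))),
                      check.names = FALSE)
  write.table(tcirc, file.path(outdir, "truth_circ.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  texp <- data.frame(gene_id = rownames(truth$linear), truth$linear,
                     check.names = FALSE)
  write.table(texp, file.path(outdir, "truth_expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Trim reads to a fixed length (3' truncation)
#'
#' Keeps the first `target_len` bases of every read and quality string.
#'
#' @param reads a per-sample read set (list with `mate1`, `mate2`,
#'   `qual1`, `qual2`).
#' @param target_len target read length; must not exceed the current
#'   read length.
#' @return the read set with truncated sequences and qualities.
#' @export
trimReads <- function(reads, target_len) {
  L <- unique(nchar(c(reads$mate1, reads$mate2)))
  if (any(target_len > L))
    stopf("target_len %d exceeds read length %d", target_len, min(L))
  reads$mate1 <- substr(reads$mate1, 1L, target_len)
  reads$mate2 <- substr(reads$mate2, 1L, target_len)
  reads$qual1 <- substr(reads$qual1, 1L, target_len)
  reads$qual2 <- substr(reads$qual2, 1L, target_len)
  reads
}
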