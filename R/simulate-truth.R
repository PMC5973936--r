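# Synthetic-data generator, part 2: circRNA truth set and abundances.

#' Choose circRNA templates from annotated exons
#'
#' Each template is a contiguous run of k exons of one transcript taken
#' from the interior exons (never the terminal ones, whose outer borders
#' lack splice flanks); the circle sequence is the concatenation of the
#' run's exons and the back-splice joins the last exon's 3' end to the
#' first exon's 5' start. Exon counts are sampled from
#' `config$circ_exon_count_dist` (mode at 2-3 by default, the typical
#' exon-derived circRNA size). Deterministic given `config$seed`.
#'
#' @param bundle a [GenomeBundle-class].
#' @param config a [simConfig()].
#' @return ground-truth list (class `circTruth`) with a `templates`
#'   data.frame: `circ_id`, `gene_id`, `transcript_id`, `contig`, `strand`,
#'   `start`, `end`, `n_exons`, `circ_len` plus list-columns `exon_starts`,
#'   `exon_ends`.
#' @export
chooseCircTemplates <- function(bundle, config) {
  set.seed(subSeed(config$seed, 1L))
  ex <- exonTable(bundle); tx <- transcriptTable(bundle); g <- geneTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  cands <- list()
  for (tid in tx$transcript_id) {
    e <- ex[ex$transcript_id == tid, ]
    nEx <- nrow(e)
    if (nEx < 3) next  # no interior run possible
    for (k in seq_len(nEx - 2L)) {
      for (a in 2:(nEx - k)) {
        cands[[length(cands) + 1L]] <- data.frame(
          transcript_id = tid, a = a, k = k)
      }
    }
  }
  if (!length(cands)) stopf("no circ templates available in this annotation")
  cands <- do.call(rbind, cands)
  if (config$n_circ > nrow(cands))
    stopf("requested n_circ=%d exceeds the %d available templates",
          config$n_circ, nrow(cands))
  dist <- config$circ_exon_count_dist
  ks <- sample(as.integer(names(dist)), config$n_circ, replace = TRUE,
               prob = dist)
  cap <- config$circ_max_per_gene %||% Inf
  candGene <- tx2g[cands$transcript_id]
  geneCount <- setNames(integer(length(unique(candGene))),
                        unique(candGene))
  used <- rep(FALSE, nrow(cands))
  pick <- integer(config$n_circ)
  for (i in seq_len(config$n_circ)) {
    open <- which(!used & geneCount[candGene] < cap)
    if (!length(open))
      stopf("requested n_circ=%d infeasible under circ_max_per_gene=%s",
            config$n_circ, format(cap))
    avail <- open[cands$k[open] == ks[i]]
    if (!length(avail)) {
      # fall back to the nearest available run length
      avail <- open[abs(cands$k[open] - ks[i]) ==
                    min(abs(cands$k[open] - ks[i]))]
    }
    pick[i] <- if (length(avail) == 1L) avail else sample(avail, 1L)
    used[pick[i]] <- TRUE
    pickedGene <- candGene[[pick[i]]]
    geneCount[pickedGene] <- geneCount[pickedGene] + 1L
  }
  sel <- cands[pick, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    tid <- sel$transcript_id[i]
    e <- ex[ex$transcript_id == tid, ]
    idx <- sel$a[i]:(sel$a[i] + sel$k[i] - 1L)
    gid <- tx2g[[tid]]
    gi <- g[g$gene_id == gid, ]
    data.frame(circ_id = circId(gi$contig, e$start[idx[1]], e$end[idx[length(idx)]]),
               gene_id = gid, transcript_id = tid, contig = gi$contig,
               strand = gi$strand, start = e$start[idx[1]],
               end = e$end[idx[length(idx)]], n_exons = sel$k[i],
               circ_len = sum(e$end[idx] - e$start[idx]),
               exon_starts = I(list(e$start[idx])),
               exon_ends = I(list(e$end[idx])))
  })
  templates <- do.call(rbind, rows)
  rownames(templates) <- NULL
  structure(list(templates = templates), class = "circTruth")
}

#' Circle sequence of a truth template (transcript orientation)
#' @param bundle a [GenomeBundle-class].
#' @param template one row of the truth `templates` data.frame.
#' @return character scalar.
#' @export
templateCircSeq <- function(bundle, template) {
  seq <- genomeSeqs(bundle)[[template$contig]]
  s <- paste(substr(rep(seq, length(template$exon_starts[[1]])),
                    template$exon_starts[[1]] + 1L,
                    template$exon_ends[[1]]), collapse = "")
  if (template$strand == "-") revcompChr(s) else s
}

#' Assign per-sample expected molecule counts
#'
#' Linear abundance per gene is log-normal and constant over time (the
#' linear-unchanged null); circular abundance is `fraction(model, linear) x
#' linear`; planted DE effects multiply the circular abundance at t24 and
#' t48 in both libraries; RNase R-treated samples are thinned by the
#' survival probabilities. Deterministic given `config$seed`.
#'
#' @param truth result of [chooseCircTemplates()].
#' @param config a [simConfig()].
#' @return `truth` extended with `linear` (gene x sample expected
#'   molecules), `circ` (circ x sample), `fraction` (per circ), `de`
#'   (planted regulation), and the sample grid.
#' @export
assignAbundances <- function(truth, config) {
  set.seed(subSeed(config$seed, 2L))
  tpl <- truth$templates
  grid <- sampleGrid()
  genes <- unique(tpl$gene_id)
  L <- setNames(rlnorm(length(genes), config$linear_meanlog,
                       config$linear_sdlog), genes)
  L0 <- exp(config$linear_meanlog)
  frac <- switch(config$circ_fraction_model,
    constant = rep(config$circ_fraction, nrow(tpl)),
    saturating = config$circ_fraction * 2 * L0 /
      (L0 + L[tpl$gene_id]),
    independent = runif(nrow(tpl), 0.05, 0.5))
  frac <- unname(frac)
  c0 <- frac * L[tpl$gene_id]
  de <- config$de_spec
  if (is.null(de)) {
    nde <- config$n_de_up + config$n_de_down
    de <- data.frame(circ_id = character(0), direction = character(0),
                     effect = numeric(0))
    if (nde > 0 && nrow(tpl) > 0) {
      idx <- sample(nrow(tpl), min(nde, nrow(tpl)))
      dirs <- rep(c("up", "down"),
                  c(config$n_de_up, config$n_de_down))[seq_along(idx)]
      de <- data.frame(circ_id = tpl$circ_id[idx], direction = dirs,
                       effect = ifelse(dirs == "up", config$de_effect_up,
                                       config$de_effect_down))
    }
  }
  eff <- setNames(rep(1, nrow(tpl)), tpl$circ_id)
  eff[de$circ_id] <- de$effect
  circ <- matrix(0, nrow(tpl), nrow(grid),
                 dimnames = list(tpl$circ_id, grid$sample_id))
  linear <- matrix(0, length(genes), nrow(grid),
                   dimnames = list(genes, grid$sample_id))
  for (j in seq_len(nrow(grid))) {
    survC <- if (grid$library[j] == "rnaser") config$p_survive_circ else 1
    survL <- if (grid$library[j] == "rnaser") config$p_survive_linear else 1
    tEff <- if (grid$timepoint[j] == "t0") rep(1, nrow(tpl)) else unname(eff)
    circ[, j] <- c0 * tEff * survC
    linear[, j] <- L * survL
  }
  truth$linear <- linear
  truth$circ <- circ
  truth$fraction <- setNames(frac, tpl$circ_id)
  truth$de <- de
  truth$grid <- grid
  truth
}

# probability that a fragment from a circle of circumference C produces a
# junction-spanning read pair (either mate crosses the back-splice with at
# least `minAnchor` bases on both sides), by enumeration over uniform start
# positions and the discretized truncated-normal fragment length law
pSpanCirc <- function(C, readLen, minAnchor, fragMean, fragSd) {
  fmax <- max(readLen, ceiling(fragMean + 6 * fragSd))
  f <- readLen:fmax
  pf <- stats::pnorm(f + 0.5, fragMean, fragSd) -
    stats::pnorm(f - 0.5, fragMean, fragSd)
  pf <- pf / sum(pf)
  u <- 0:(C - 1L)
  crosses <- function(lo, hi) {
    # any positive multiple of C in [lo, hi]
    hiM <- floor(hi / C); loM <- ceiling(lo / C)
    hiM >= loM & hiM >= 1
  }
  p <- vapply(f, function(fl) {
    m1 <- crosses(u + minAnchor, u + readLen - minAnchor)
    m2 <- crosses(u + fl - readLen + minAnchor, u + fl - minAnchor)
    mean(m1 | m2)
  }, numeric(1))
  sum(pf * p)
}

# per-sample sampling-unit table: spliced + unspliced linear and circles,
# with expected molecule counts and lengths; weight = count x length
.sampleUnits <- function(bundle, truth, config, sample_id) {
  tx <- transcriptTable(bundle)
  tpl <- truth$templates
  genes <- rownames(truth$linear)
  txOf <- setNames(tx$transcript_id, tx$gene_id)
  sp <- data.frame(unit_type = "linear", unit_id = txOf[genes],
                   gene_id = genes,
                   count = truth$linear[, sample_id] *
                     (1 - config$unspliced_fraction))
  un <- data.frame(unit_type = "premrna", unit_id = txOf[genes],
                   gene_id = genes,
                   count = truth$linear[, sample_id] *
                     config$unspliced_fraction)
  ci <- data.frame(unit_type = "circ", unit_id = tpl$circ_id,
                   gene_id = tpl$gene_id,
                   count = truth$circ[, sample_id])
  units <- rbind(sp, un, ci)
  rownames(units) <- NULL
  units
}

#' Expected junction-spanning read pairs per circRNA and sample
#'
#' Under the generator's fragment model: fragments are sampled in
#' proportion to molecule count x template length; a circle fragment
#' yields a junction read when either mate crosses the back-splice with at
#' least `min_anchor` bases on each side.
#'
#' @param bundle,truth,config generator state (truth must carry abundances).
#' @return matrix circ x sample of expected junction read pairs.
#' @export
expectedJunctionReads <- function(bundle, truth, config) {
  tpl <- truth$templates
  seqsLen <- list()
  txLen <- setNames(
    vapply(transcriptTable(bundle)$transcript_id,
           function(t) nchar(transcriptSeq(bundle, t)), numeric(1)),
    transcriptTable(bundle)$transcript_id)
  preLen <- setNames(
    vapply(transcriptTable(bundle)$transcript_id,
           function(t) nchar(preMrnaSeq(bundle, t)), numeric(1)),
    transcriptTable(bundle)$transcript_id)
  pspan <- vapply(tpl$circ_len, pSpanCirc,
                  numeric(1), readLen = config$read_len,
                  minAnchor = config$min_anchor,
                  fragMean = config$frag_len_mean, fragSd = config$frag_len_sd)
  out <- matrix(0, nrow(tpl), nrow(truth$grid),
                dimnames = list(tpl$circ_id, truth$grid$sample_id))
  unitLen <- function(units) {
    ifelse(units$unit_type == "linear", txLen[units$unit_id],
    ifelse(units$unit_type == "premrna", preLen[units$unit_id],
           tpl$circ_len[match(units$unit_id, tpl$circ_id)]))
  }
  for (s in truth$grid$sample_id) {
    units <- .sampleUnits(bundle, truth, config, s)
    w <- units$count * unitLen(units)
    W <- sum(w)
    n <- config$depth_per_sample
    if ((config$depth_model %||% "fixed") == "proportional" &&
        truth$grid$library[truth$grid$sample_id == s] == "rnaser") {
      tp <- truth$grid$timepoint[truth$grid$sample_id == s]
      refUnits <- .sampleUnits(bundle, truth, config,
                               paste0("rminus_", tp))
      n <- max(1L, as.integer(round(config$depth_per_sample * W /
                                    sum(refUnits$count * unitLen(refUnits)))))
    }
    ci <- units$unit_type == "circ"
    out[, s] <- n * (w[ci] / W) * pspan[match(units$unit_id[ci], tpl$circ_id)]
  }
  out
}

#' Count-level junction-read simulation
#'
#' Draws Poisson junction-read counts around [expectedJunctionReads()]
#' expectations — the count-level view of the generator used when an
#' experiment consumes junction counts only (e.g. screen-scale planted-DE
#' studies, where read-level simulation at the required junction coverage
#' would be needlessly large).
#'
#' @param bundle,truth,config generator state.
#' @return a [CircExperiment-class] whose `total_mapped_reads` is
#'   `2 x depth_per_sample` per sample.
#' @export
simulateJunctionCounts <- function(bundle, truth, config) {
  set.seed(subSeed(config$seed, 3L))
  lambda <- expectedJunctionReads(bundle, truth, config)
  counts <- matrix(rpois(length(lambda), lambda), nrow(lambda),
                   dimnames = dimnames(lambda))
  grid <- truth$grid
  grid$total_mapped_reads <- 2L * config$depth_per_sample
  tpl <- truth$templates
  CircExperiment(tpl[, c("contig", "start", "end", "strand")], counts, grid)
}

#' Abstract screen-scale planted-DE experiment
#'
#' Generates junction-read counts for a large set of abstract circRNAs
#' (coordinates synthetic, no genome needed) across the 2 x 3 grid:
#' baseline Poisson rates uniform in `lambda_range`, planted up/down
#' effects applied at t24 and t48 in both libraries, RNase R enrichment as
#' a constant library factor.
#'
#' @param n_up,n_down,n_null planted regulation class sizes.
#' @param lambda_range baseline junction-read rate range (t0, rminus).
#' @param effect_up,effect_down fold-change ranges for planted effects.
#' @param rnaser_enrichment junction-rate multiplier in the treated library.
#' @param total_mapped total mapped reads per sample (normalization).
#' @param seed RNG seed.
#' @return list: `circ` ([CircExperiment-class]) and `truth`
#'   (`circ_id`, `direction`).
#' @export
simulateScreenCounts <- function(n_up = 50L, n_down = 50L, n_null = 400L,
                                 lambda_range = c(10, 50),
                                 effect_up = c(2, 4),
                                 effect_down = c(0.25, 0.5),
                                 rnaser_enrichment = 5,
                                 total_mapped = 4e6, seed = 1L) {
  set.seed(subSeed(seed, 4L))
  n <- n_up + n_down + n_null
  dir <- rep(c("up", "down", "unchanged"), c(n_up, n_down, n_null))
  lam0 <- runif(n, lambda_range[1], lambda_range[2])
  eff <- rep(1, n)
  eff[dir == "up"] <- runif(n_up, effect_up[1], effect_up[2])
  eff[dir == "down"] <- runif(n_down, effect_down[1], effect_down[2])
  grid <- sampleGrid()
  counts <- matrix(0L, n, nrow(grid))
  for (j in seq_len(nrow(grid))) {
    lam <- lam0 *
      (if (grid$library[j] == "rnaser") rnaser_enrichment else 1) *
      (if (grid$timepoint[j] == "t0") 1 else eff)
    counts[, j] <- rpois(n, lam)
  }
  cand <- data.frame(contig = "s1", start = (seq_len(n) - 1L) * 1000L,
                     end = (seq_len(n) - 1L) * 1000L + 300L, strand = "+")
  grid$total_mapped_reads <- total_mapped
  ce <- CircExperiment(cand, counts, grid)
  list(circ = ce,
       truth = data.frame(circ_id = rownames(ce), direction = dir))
}
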