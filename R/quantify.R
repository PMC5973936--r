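# Expression computation: normalized circular abundance, flanking-exon
# linear abundance, host-gene FPKM and circular:linear ratios.

#' Normalize junction reads to sequencing depth
#'
#' `junction_reads / total_mapped * 1e8` — junction reads per 1e8 mapped
#' reads.
#'
#' @param junction_reads non-negative count(s).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return numeric, same length as `junction_reads`.
#' @export
normalizeCirc <- function(junction_reads, total_mapped) {
  if (any(total_mapped <= 0)) stopf("total_mapped must be positive")
  junction_reads / total_mapped * 1e8
}

#' FPKM from its components
#'
#' Fragments per kilobase of exon model per million mapped fragments.
#'
#' @param fragments exonic fragment count of the gene.
#' @param exonic_len_bp exonic model length in bp (> 0).
#' @param total_fragments total mapped fragments in the sample.
#' @return numeric FPKM.
#' @export
fpkmValue <- function(fragments, exonic_len_bp, total_fragments) {
  if (any(exonic_len_bp <= 0)) stopf("zero-length gene model")
  fragments / (exonic_len_bp / 1000) / (total_fragments / 1e6)
}

#' Circular to linear ratio with a pseudocount
#'
#' `circ_norm / (linear_norm + eps)`. With `eps = 0` and a zero linear
#' value the ratio is undefined and returned as NA (the undefined flag).
#' The recommended `eps` is the normalized equivalent of one raw read in
#' the same sample ([normalizeCirc()] of 1), applied symmetrically by the
#' callers that build fold changes.
#'
#' @param circ_norm,linear_norm normalized abundances.
#' @param eps pseudocount on the normalized scale.
#' @return numeric ratio(s); NA where undefined.
#' @export
circLinearRatio <- function(circ_norm, linear_norm, eps = 0) {
  den <- linear_norm + eps
  out <- ifelse(den > 0, circ_norm / den, NA_real_)
  out
}

# transcript whose exon borders match the circle's breakpoints, if any
matchCircTranscript <- function(circ, bundle) {
  ex <- exonTable(bundle); tx <- transcriptTable(bundle); g <- geneTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  for (tid in unique(ex$transcript_id)) {
    gi <- g[g$gene_id == tx2g[[tid]], ]
    if (gi$contig != circ$contig || gi$strand != circ$strand) next
    e <- ex[ex$transcript_id == tid, ]
    a <- which(e$start == circ$start)
    b <- which(e$end == circ$end)
    if (length(a) == 1L && length(b) == 1L && b >= a)
      return(list(transcript_id = tid, gene_id = gi$gene_id,
                  strand = gi$strand, exons = e, a = a, b = b))
  }
  NULL
}

# fragments (unique read pairs) whose mate crosses a transcript-coordinate
# boundary with >= ov bases on each side
.crossingTx <- function(aln, tid, boundary, read_len, ov) {
  sel <- aln[aln$ref_type == "transcript" & aln$ref == tid &
             aln$pos <= boundary - ov &
             aln$pos + read_len >= boundary + ov, ]
  unique(sel$read_id)
}

# fragments whose mate crosses a genomic coordinate with >= ov bases each side
.crossingContig <- function(aln, contig, coord, read_len, ov) {
  sel <- aln[aln$ref_type == "contig" & aln$ref == contig &
             aln$pos <= coord - ov &
             aln$pos + read_len >= coord + ov, ]
  unique(sel$read_id)
}

#' Linear abundance at a circRNA's flanking exons
#'
#' Implements the flanking-exon linear estimate: at the circle's first
#' exon, fragments spanning the linear splice from the upstream
#' neighboring exon into it plus fragments crossing its upstream
#' exon-intron boundary; symmetric counts at the last exon; the per-flank
#' totals are averaged. Terminal-exon circles with no neighbor on one side
#' use the available side only (`one_sided`). Circles whose boundaries do
#' not match annotated exon borders are counted via exon-intron boundary
#' fragments only and flagged (`boundary_matched = FALSE`). Fragments
#' (read pairs), not mates, are the counting unit.
#'
#' @param circ one-row data.frame (`contig`, `start`, `end`, `strand`).
#' @param aln alignment table of one sample ([alignReads()] `$aln`).
#' @param bundle a [GenomeBundle-class].
#' @param index from [buildAlignmentIndex()] (transcript maps).
#' @param read_len read length of the library.
#' @param min_overhang minimum bases on each side of a boundary for a
#'   fragment to count as crossing it; the default equals the detector's
#'   anchor length so circular (junction) and linear (boundary) fragment
#'   counts share the same effective crossing window and their ratio is
#'   directly interpretable.
#' @return data.frame: `raw` (mean per-flank fragment count), `n_flanks`,
#'   `boundary_matched`, `one_sided`.
#' @export
quantifyLinearFlanking <- function(circ, aln, bundle, index,
                                   read_len = 125L, min_overhang = 20L) {
  m <- matchCircTranscript(circ, bundle)
  ov <- min_overhang
  if (is.null(m)) {
    up <- length(.crossingContig(aln, circ$contig, circ$start, read_len, ov))
    dn <- length(.crossingContig(aln, circ$contig, circ$end, read_len, ov))
    return(data.frame(raw = mean(c(up, dn)), n_flanks = 2L,
                      boundary_matched = FALSE, one_sided = FALSE))
  }
  map <- index$txMap[[m$transcript_id]]
  txs <- map$tx_start
  flanks <- numeric(0)
  oneSided <- FALSE
  # upstream (genomic) flank: neighbor exon a-1
  if (m$a > 1L) {
    boundary <- max(txs[m$a - 1L], txs[m$a])
    spl <- .crossingTx(aln, m$transcript_id, boundary, read_len, ov)
    ei <- .crossingContig(aln, circ$contig, circ$start, read_len, ov)
    flanks <- c(flanks, length(unique(c(spl, ei))))
  } else oneSided <- TRUE
  # downstream (genomic) flank: neighbor exon b+1
  if (m$b < nrow(m$exons)) {
    boundary <- max(txs[m$b], txs[m$b + 1L])
    spl <- .crossingTx(aln, m$transcript_id, boundary, read_len, ov)
    ei <- .crossingContig(aln, circ$contig, circ$end, read_len, ov)
    flanks <- c(flanks, length(unique(c(spl, ei))))
  } else oneSided <- TRUE
  if (!length(flanks)) {
    # single-exon gene hosting the circle: no neighbors at all
    return(data.frame(raw = 0, n_flanks = 0L, boundary_matched = TRUE,
                      one_sided = TRUE))
  }
  data.frame(raw = mean(flanks), n_flanks = length(flanks),
             boundary_matched = TRUE, one_sided = oneSided)
}

#' Host-gene FPKM from alignments
#'
#' Fragments (pairs) with at least one mapped mate are assigned to genes
#' by exon overlap in the fragment's sense orientation (mate 1 carries the
#' transcript strand); fragments overlapping the exon models of several
#' genes are split fractionally (1/n). FPKM = exonic fragments / (exonic
#' length in kb x total mapped fragments in millions).
#'
#' @param bundle a [GenomeBundle-class].
#' @param aln alignment table of one sample.
#' @param index from [buildAlignmentIndex()].
#' @param read_len read length.
#' @param total_fragments total mapped fragments; default: number of
#'   distinct read pairs with a mapped mate.
#' @return data.frame: `gene_id`, `fragments` (fractional), `exonic_bp`,
#'   `fpkm`.
#' @export
computeFpkm <- function(bundle, aln, index, read_len = 125L,
                        total_fragments = NULL) {
  g <- geneTable(bundle); ex <- exonTable(bundle)
  tx <- transcriptTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  # exonic union per gene
  exg <- ex; exg$gene_id <- tx2g[exg$transcript_id]
  exonicBp <- vapply(split(exg, exg$gene_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    sum(IRanges::width(ir))
  }, numeric(1))
  if (is.null(total_fragments))
    total_fragments <- length(unique(aln$read_id))
  if (!nrow(aln) || total_fragments == 0) {
    return(data.frame(gene_id = g$gene_id, fragments = 0,
                      exonic_bp = exonicBp[g$gene_id],
                      fpkm = 0, row.names = NULL))
  }
  # candidate genes per mate
  a <- as.data.frame(aln)
  a$sense <- ifelse(a$mate == 1L, a$strand,
                    ifelse(a$strand == "+", "-", "+"))
  pairs <- list()
  txHits <- a[a$ref_type == "transcript", ]
  if (nrow(txHits))
    pairs[[1]] <- data.frame(read_id = txHits$read_id,
                             gene_id = tx2g[txHits$ref])
  ctgHits <- a[a$ref_type == "contig", ]
  if (nrow(ctgHits)) {
    gcontig <- setNames(g$contig, g$gene_id)
    gstrand <- setNames(g$strand, g$gene_id)
    geneOf <- setNames(exg$gene_id, NULL)
    exIr <- IRanges::IRanges(exg$start + 1L, exg$end)
    rdIr <- IRanges::IRanges(ctgHits$pos + 1L, ctgHits$pos + read_len)
    hits <- IRanges::findOverlaps(rdIr, exIr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- gcontig[geneOf[sh]] == ctgHits$ref[qh] &
      gstrand[geneOf[sh]] == ctgHits$sense[qh]
    if (any(keep))
      pairs[[length(pairs) + 1L]] <- data.frame(
        read_id = ctgHits$read_id[qh[keep]], gene_id = geneOf[sh[keep]])
  }
  frags <- setNames(numeric(nrow(g)), g$gene_id)
  if (length(pairs)) {
    pg <- unique(do.call(rbind, pairs))
    nGenes <- table(pg$read_id)
    wt <- 1 / as.numeric(nGenes[pg$read_id])
    agg <- tapply(wt, pg$gene_id, sum)
    frags[names(agg)] <- agg
  }
  data.frame(gene_id = g$gene_id, fragments = unname(frags[g$gene_id]),
             exonic_bp = unname(exonicBp[g$gene_id]),
             fpkm = fpkmValue(unname(frags[g$gene_id]),
                              unname(exonicBp[g$gene_id]), total_fragments),
             row.names = NULL)
}

#' Long-format expression table for a detection result
#'
#' For every sample: normalized circular abundance per candidate
#' (`feature_kind = "circ"`), the flanking-exon linear estimate per
#' candidate (`"linear_flank"`), and host-gene FPKM (`"gene_fpkm"`; its
#' `normalized` column is the FPKM itself). Circular and linear_flank
#' `normalized` values are reads per 1e8 mapped reads.
#'
#' @param detection result of [detectCircRNAs()].
#' @param bundle a [GenomeBundle-class].
#' @param index from [buildAlignmentIndex()]; rebuilt if NULL.
#' @param read_len read length.
#' @param min_overhang boundary-crossing overhang, see
#'   [quantifyLinearFlanking()].
#' @return data.frame: `feature_id`, `feature_kind`, `sample_id`, `raw`,
#'   `normalized`, `boundary_matched`, `one_sided`.
#' @export
quantifyExpression <- function(detection, bundle, index = NULL,
                               read_len = 125L, min_overhang = 20L) {
  if (is.null(index)) index <- buildAlignmentIndex(bundle)
  circ <- detection$circ
  st <- sampleInfo(circ)
  coords <- circCoords(circ)
  jr <- junctionReads(circ)
  out <- list()
  for (si in seq_len(nrow(st))) {
    sid <- st$sample_id[si]
    tot <- st$total_mapped_reads[si]
    aln <- detection$alignments[[sid]]$aln
    if (nrow(coords)) {
      out[[length(out) + 1L]] <- data.frame(
        feature_id = coords$circ_id, feature_kind = "circ", sample_id = sid,
        raw = jr[, sid], normalized = normalizeCirc(jr[, sid], tot),
        boundary_matched = NA, one_sided = NA, row.names = NULL)
      lin <- do.call(rbind, lapply(seq_len(nrow(coords)), function(i)
        quantifyLinearFlanking(coords[i, ], aln, bundle, index,
                               read_len = read_len,
                               min_overhang = min_overhang)))
      out[[length(out) + 1L]] <- data.frame(
        feature_id = coords$circ_id, feature_kind = "linear_flank",
        sample_id = sid, raw = lin$raw,
        normalized = normalizeCirc(lin$raw, tot),
        boundary_matched = lin$boundary_matched, one_sided = lin$one_sided,
        row.names = NULL)
    }
    fp <- computeFpkm(bundle, aln, index, read_len = read_len)
    out[[length(out) + 1L]] <- data.frame(
      feature_id = fp$gene_id, feature_kind = "gene_fpkm", sample_id = sid,
      raw = fp$fragments, normalized = fp$fpkm,
      boundary_matched = NA, one_sided = NA, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
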