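# Linear alignment: an internal seed-and-extend aligner over the genome and
# the annotated spliced transcripts. Seeds are exact k-mers (k = anchor
# length); with max_mm+1 evenly spaced seeds per read, any end-to-end
# placement with <= max_mm mismatches has at least one exact seed
# (pigeonhole), so the aligner is complete at the configured mismatch
# allowance. Designed for toy-genome scale.

#' Build the seed index for alignment and anchor lookup
#'
#' Indexes every k-mer of the contigs and of the annotated spliced
#' transcript sequences (k-mers containing N are skipped, so anchors
#' overlapping N never match and the corresponding reads are discarded as
#' ambiguous input).
#'
#' @param bundle a [GenomeBundle-class].
#' @param k seed length (the detector's anchor length).
#' @return an opaque index list used by [alignReads()] and
#'   [findJunctionReads()].
#' @export
buildAlignmentIndex <- function(bundle, k = 20L) {
  contigs <- genomeSeqs(bundle)
  if (!length(contigs) || !sum(nchar(contigs)))
    stopf("empty genome")
  tx <- transcriptTable(bundle)
  txSeqs <- setNames(
    vapply(tx$transcript_id, transcriptSeq, character(1), bundle = bundle),
    tx$transcript_id)
  refs <- c(contigs, txSeqs)
  refType <- setNames(rep(c("contig", "transcript"),
                          c(length(contigs), length(txSeqs))), names(refs))
  tabs <- lapply(seq_along(refs), function(i) {
    s <- refs[[i]]; n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                           ref = names(refs)[i], pos = starts - 1L)
  })
  idx <- data.table::rbindlist(tabs)
  idx <- idx[!grepl("N", idx$kmer, fixed = TRUE)]
  data.table::setkey(idx, kmer)
  gidx <- idx[idx$ref %in% names(contigs)]
  data.table::setkey(gidx, kmer)
  # transcript -> genomic projection tables
  ex <- exonTable(bundle)
  g <- geneTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  txMap <- lapply(tx$transcript_id, function(tid) {
    e <- ex[ex$transcript_id == tid, ]
    gi <- g[g$gene_id == tx2g[[tid]], ]
    w <- e$end - e$start
    if (gi$strand == "+") {
      txs <- cumsum(c(0L, w))[seq_len(nrow(e))]
    } else {
      # transcript coordinate 0 is the genomically last exon's right edge
      txs <- rev(cumsum(c(0L, rev(w)))[seq_len(nrow(e))])
    }
    list(contig = gi$contig, strand = gi$strand, gene_id = gi$gene_id,
         exon_start = e$start, exon_end = e$end, tx_start = txs,
         tx_len = sum(w))
  })
  names(txMap) <- tx$transcript_id
  list(index = idx, genome_index = gidx, refs = refs, refType = refType,
       refLen = setNames(nchar(refs), names(refs)), k = as.integer(k),
       contigs = contigs, txMap = txMap)
}

# genomic interval(s) covered by transcript interval [s, e) (0-based)
projectTxInterval <- function(map, s, e) {
  out <- list()
  for (i in seq_along(map$exon_start)) {
    w <- map$exon_end[i] - map$exon_start[i]
    ts <- map$tx_start[i]; te <- ts + w
    ov_s <- max(s, ts); ov_e <- min(e, te)
    if (ov_s >= ov_e) next
    if (map$strand == "+") {
      gs <- map$exon_start[i] + (ov_s - ts)
      ge <- map$exon_start[i] + (ov_e - ts)
    } else {
      ge <- map$exon_end[i] - (ov_s - ts)
      gs <- map$exon_end[i] - (ov_e - ts)
    }
    out[[length(out) + 1L]] <- c(gs, ge)
  }
  out
}

#' Align reads end-to-end to genome and spliced transcripts
#'
#' A mate is mapped if it aligns end-to-end with at most `max_mm`
#' mismatches to a contig (either orientation) or to an annotated spliced
#' transcript. `total_mapped_reads` counts mapped mates, each mate
#' separately. Ties prefer genomic placements (transcript placements add
#' information only when a read crosses a linear splice junction).
#'
#' @param reads read set: list with `ids`, `mate1`, `mate2`.
#' @param index from [buildAlignmentIndex()].
#' @param max_mm maximum mismatches per mate.
#' @return list: `aln` (data.table: read_id, mate, ref, ref_type, pos,
#'   strand, mm, n_best — best placement per mapped mate), `unmapped`
#'   (data.table: read_id, mate, seq), `total_mapped`.
#' @export
alignReads <- function(reads, index, max_mm = 2L) {
  k <- index$k
  qdt <- data.table::data.table(
    read_id = rep(reads$ids, 2L),
    mate = rep(c(1L, 2L), each = length(reads$ids)),
    seq = c(reads$mate1, reads$mate2))
  qdt$qi <- seq_len(nrow(qdt))
  cands <- list()
  for (ori in c("+", "-")) {
    q <- if (ori == "+") qdt$seq else revcompChr(qdt$seq)
    Ls <- nchar(q)
    for (L in unique(Ls)) {
      sel <- which(Ls == L)
      if (L < k) next
      offs <- unique(as.integer(floor(seq(0L, L - k, length.out = max_mm + 1L))))
      seedDt <- data.table::data.table(
        qi = rep(qdt$qi[sel], each = length(offs)),
        off = rep(offs, length(sel)))
      seedDt$kmer <- substring(q[seedDt$qi], seedDt$off + 1L,
                               seedDt$off + k)
      hits <- index$index[seedDt, on = "kmer", nomatch = NULL,
                          allow.cartesian = TRUE]
      if (!nrow(hits)) next
      hits$pos0 <- hits$pos - hits$off
      hits <- hits[hits$pos0 >= 0 &
                   hits$pos0 + L <= index$refLen[hits$ref]]
      hits <- unique(hits[, c("qi", "ref", "pos0")])
      if (!nrow(hits)) next
      refSub <- substring(index$refs[hits$ref], hits$pos0 + 1L,
                          hits$pos0 + L)
      hits$mm <- hamming_count(q[hits$qi], refSub, cap = max_mm)
      hits <- hits[hits$mm <= max_mm]
      if (!nrow(hits)) next
      hits$strand <- ori
      cands[[length(cands) + 1L]] <- hits
    }
  }
  if (length(cands)) {
    cands <- data.table::rbindlist(cands)
    cands$ref_type <- index$refType[cands$ref]
    cands$prio <- ifelse(cands$ref_type == "contig", 0L, 1L)
    data.table::setorderv(cands, c("qi", "mm", "prio", "ref", "pos0", "strand"))
    bestMm <- cands[, list(best = min(mm)), by = "qi"]
    cands <- cands[bestMm, on = "qi"]
    atBest <- cands[cands$mm == cands$best]
    nb <- atBest[, list(n_best = .N), by = c("qi", "ref_type")]
    best <- atBest[!duplicated(atBest$qi)]
    best <- nb[best, on = c("qi", "ref_type")]
  } else {
    best <- data.table::data.table(qi = integer(0), n_best = integer(0),
                                   ref = character(0), pos0 = integer(0),
                                   mm = integer(0), strand = character(0),
                                   ref_type = character(0))
  }
  aln <- data.table::data.table(
    read_id = qdt$read_id[best$qi], mate = qdt$mate[best$qi],
    ref = best$ref, ref_type = best$ref_type, pos = best$pos0,
    strand = best$strand, mm = best$mm, n_best = best$n_best)
  unm <- qdt[!qdt$qi %in% best$qi]
  list(aln = aln,
       unmapped = unm[, c("read_id", "mate", "seq")],
       total_mapped = nrow(aln))
}

#' Split a read into terminal anchors
#'
#' @param read read sequence.
#' @param anchor_len anchor length.
#' @return list with `left` (first `anchor_len` bases) and `right` (last
#'   `anchor_len` bases), or NULL when the read is shorter than two
#'   anchors (skipped upstream with a log record).
#' @export
extractAnchors <- function(read, anchor_len = 20L) {
  L <- nchar(read)
  if (L < 2L * anchor_len) return(NULL)
  list(left = substr(read, 1L, anchor_len),
       right = substr(read, L - anchor_len + 1L, L))
}
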