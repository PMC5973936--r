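# Back-spliced junction discovery: anchor splitting of unaligned reads,
# head-to-tail breakpoint resolution with GT-AG enforcement, ambiguity and
# repeat filtering, mate-consistency checking, and cross-sample merging.

REJECT_CATEGORIES <- c("short_read", "no_anchor", "span_exceeded", "no_gtag",
                       "too_many_mm", "ambiguous", "strand_conflict",
                       "mate_inconsistent", "repetitive")

#' Resolve the back-splice breakpoint of a head-to-tail anchored read
#'
#' The query (a read, or its reverse complement, oriented so that it
#' aligns forward to the genome) has its left anchor at `left_pos` and its
#' right anchor at `right_pos < left_pos` (reversed orientation). Both
#' anchors are extended toward the read interior; every breakpoint offset
#' `b` (bases taken from the left, circle-end, side) is scored as the total
#' mismatch count of the two segments, and is admissible only when the
#' genome flanks the implied circle as `AG | circle | GT` on the plus
#' strand (reverse-complement rule, `CT | circle | AC` read forward, on
#' minus). The unique best-scoring admissible offset is accepted; ties are
#' discarded as ambiguous.
#'
#' @param query read sequence in genome-forward orientation.
#' @param contig_seq contig sequence.
#' @param left_pos,right_pos 0-based genomic start positions of the exact
#'   left/right anchor matches.
#' @param anchor_len anchor length.
#' @param max_mm maximum total mismatches.
#' @param max_circ_len maximum circle span.
#' @return list with `status` (`"ok"` or a rejection category) and, when
#'   ok: `start`, `end` (0-based half-open circle), `strand`, `offset`
#'   (breakpoint offset in the query), `mm`.
#' @export
resolveBreakpoint <- function(query, contig_seq, left_pos, right_pos,
                              anchor_len = 20L, max_mm = 2L,
                              max_circ_len = 100000L) {
  L <- nchar(query); k <- anchor_len
  clen <- nchar(contig_seq)
  span <- left_pos - right_pos + L - k
  if (span <= 0 || span > max_circ_len)
    return(list(status = "span_exceeded"))
  # b range from geometry and contig bounds
  rstart <- right_pos + k - L                       # genome pos of query[0]
  bmin <- max(k, 2L - rstart)                       # s = rstart + b >= 2
  bmax <- min(L - k, clen - left_pos - 2L)          # e + 2 <= clen
  if (bmin > bmax) return(list(status = "no_gtag"))
  # mismatch profiles in the two anchor frames
  leftRef <- substr(contig_seq, left_pos + 1L, left_pos + bmax)
  m1 <- cumsum(mismatch_profile(substr(query, 1L, bmax), leftRef))
  rightRef <- substr(contig_seq, rstart + bmin + 1L, rstart + L)
  m2i <- mismatch_profile(substr(query, bmin + 1L, L), rightRef)
  # suffix sums over b..L-1 for each b in bmin..bmax
  sufAll <- rev(cumsum(rev(m2i)))                   # index 1 == b=bmin
  bs <- bmin:bmax
  mmTot <- m1[bs] + sufAll[bs - bmin + 1L]
  e <- left_pos + bs
  s <- rstart + bs
  donor <- substring(contig_seq, e + 1L, e + 2L)
  acceptor <- substring(contig_seq, s - 1L, s)
  strandOf <- ifelse(donor == "GT" & acceptor == "AG", "+",
              ifelse(donor == "CT" & acceptor == "AC", "-", NA))
  ok <- !is.na(strandOf)
  if (!any(ok)) return(list(status = "no_gtag"))
  mmOk <- mmTot[ok]
  best <- min(mmOk)
  if (best > max_mm) return(list(status = "too_many_mm"))
  if (sum(mmOk == best) > 1L) return(list(status = "ambiguous"))
  i <- which(ok)[which.min(mmOk)]
  list(status = "ok", start = s[i], end = e[i], strand = strandOf[i],
       offset = bs[i], mm = mmTot[i])
}

# hashed lookup table (kmer -> data.frame(ref, pos)) for a batch of
# anchor k-mers against the genome index
.anchorLookup <- function(index, kmers) {
  kmers <- unique(kmers)
  h <- index$genome_index[list(kmers), on = "kmer", nomatch = NULL]
  env <- new.env(hash = TRUE, size = max(16L, length(kmers)))
  if (nrow(h)) {
    sp <- split(seq_len(nrow(h)), h$kmer)
    for (km in names(sp))
      assign(km, h[sp[[km]], c("ref", "pos")], envir = env)
  }
  env
}

.anchorHits <- function(lookup, kmer) {
  h <- get0(kmer, envir = lookup, inherits = FALSE)
  if (is.null(h)) data.frame(ref = character(0), pos = integer(0)) else h
}

#' Scan unmapped reads for back-spliced junction evidence
#'
#' For each unmapped read (and its reverse complement), the terminal
#' anchors are looked up exactly in the genome; head-to-tail anchor pairs
#' (right-anchor locus upstream of left-anchor locus, same contig) are
#' passed to [resolveBreakpoint()]. The junction strand implied by the
#' GT-AG rule is cross-checked against library strandedness (mate 1 is
#' transcript-sense); conflicts are rejected.
#'
#' @param unmapped data.table from [alignReads()] (`read_id`, `mate`,
#'   `seq`).
#' @param bundle a [GenomeBundle-class].
#' @param index from [buildAlignmentIndex()].
#' @param max_mm,max_circ_len detection parameters.
#' @return list: `calls` (data.frame: read_id, mate, contig, start, end,
#'   strand, offset, mm, max_anchor_hits) and `rejects` (named integer
#'   vector of category counts).
#' @export
findJunctionReads <- function(unmapped, bundle, index, max_mm = 2L,
                              max_circ_len = 100000L) {
  k <- index$k
  contigs <- index$contigs
  rejects <- setNames(integer(length(REJECT_CATEGORIES)), REJECT_CATEGORIES)
  calls <- list()
  if (!nrow(unmapped)) {
    return(list(calls = .emptyCallDf(), rejects = rejects))
  }
  seqs <- unmapped$seq
  rcs <- revcompChr(seqs)
  # one batched genome lookup for all anchors of all reads
  Lall <- nchar(seqs)
  longEnough <- Lall >= 2L * k
  allAnchors <- c(substr(seqs[longEnough], 1L, k),
                  substr(seqs[longEnough], Lall[longEnough] - k + 1L,
                         Lall[longEnough]),
                  substr(rcs[longEnough], 1L, k),
                  substr(rcs[longEnough], Lall[longEnough] - k + 1L,
                         Lall[longEnough]))
  lookup <- .anchorLookup(index, allAnchors)
  for (r in seq_len(nrow(unmapped))) {
    L <- Lall[r]
    if (L < 2L * k) { rejects["short_read"] <- rejects["short_read"] + 1L; next }
    cat <- "no_anchor"
    hadPair <- FALSE
    accepted <- list()
    for (ori in c("+", "-")) {
      q <- if (ori == "+") seqs[r] else rcs[r]
      an <- extractAnchors(q, k)
      hl <- .anchorHits(lookup, an$left)
      hr <- .anchorHits(lookup, an$right)
      if (!nrow(hl) || !nrow(hr)) next
      if (nrow(hl) > 1L || nrow(hr) > 1L) {
        # anchors from repetitive/homologous regions: discard outright
        hadPair <- TRUE; cat <- "repetitive"; next
      }
      for (i in seq_len(nrow(hl))) for (j in seq_len(nrow(hr))) {
        if (hl$ref[i] != hr$ref[j]) next
        g0 <- hl$pos[i]; r0 <- hr$pos[j]
        # head-to-tail geometry: implied span e - s = g0 - r0 + L - k
        if (g0 - r0 + L - k <= 0L) next
        hadPair <- TRUE
        res <- resolveBreakpoint(q, contigs[[hl$ref[i]]], g0, r0,
                                 anchor_len = k, max_mm = max_mm,
                                 max_circ_len = max_circ_len)
        if (res$status != "ok") { cat <- res$status; next }
        # library strandedness: mate1 sense, mate2 antisense
        expStrand <- if (unmapped$mate[r] == 1L) ori else
          (if (ori == "+") "-" else "+")
        if (res$strand != expStrand) { cat <- "strand_conflict"; next }
        accepted[[length(accepted) + 1L]] <- data.frame(
          read_id = unmapped$read_id[r], mate = unmapped$mate[r],
          contig = hl$ref[i], start = res$start, end = res$end,
          strand = res$strand, offset = res$offset, mm = res$mm,
          max_anchor_hits = max(nrow(hl), nrow(hr)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(accepted) > 1L) {
      acc <- do.call(rbind, accepted)
      acc <- unique(acc)
      if (nrow(acc) > 1L) {
        best <- acc[acc$mm == min(acc$mm), , drop = FALSE]
        if (nrow(best) > 1L) {
          rejects["ambiguous"] <- rejects["ambiguous"] + 1L
          next
        }
        acc <- best
      }
      calls[[length(calls) + 1L]] <- acc
    } else if (length(accepted) == 1L) {
      calls[[length(calls) + 1L]] <- accepted[[1L]]
    } else if (hadPair) {
      rejects[cat] <- rejects[cat] + 1L
    } else {
      rejects["no_anchor"] <- rejects["no_anchor"] + 1L
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else .emptyCallDf()
  list(calls = calls, rejects = rejects)
}

.emptyCallDf <- function() {
  data.frame(read_id = character(0), mate = integer(0), contig = character(0),
              start = integer(0), end = integer(0), strand = character(0),
              offset = integer(0), mm = integer(0),
              max_anchor_hits = integer(0), stringsAsFactors = FALSE)
}

#' Check that a junction read's mate is consistent with a circular template
#'
#' TRUE iff the mate maps inside the circle interval `[start, end)` on the
#' circle's strand (sense-consistent with library strandedness) or itself
#' spans the same back-splice junction. Reads failing this do not count as
#' junction support.
#'
#' @param call one junction call row (as from [findJunctionReads()]).
#' @param mate_aln the mate's alignment row from [alignReads()] (or NULL).
#' @param mate_call the mate's junction call row (or NULL).
#' @param index from [buildAlignmentIndex()].
#' @return logical.
#' @export
checkMateConsistency <- function(call, mate_aln, mate_call, index) {
  # expected alignment orientation of the mate (mate1 sense, mate2 rc)
  mateNo <- if (call$mate == 1L) 2L else 1L
  expOri <- if (call$strand == "+") {
    if (mateNo == 1L) "+" else "-"
  } else {
    if (mateNo == 1L) "-" else "+"
  }
  if (!is.null(mate_call) && nrow(mate_call)) {
    same <- mate_call$contig == call$contig &
      mate_call$start == call$start & mate_call$end == call$end &
      mate_call$strand == call$strand
    if (any(same)) return(TRUE)
  }
  if (is.null(mate_aln) || !nrow(mate_aln)) return(FALSE)
  a <- mate_aln[1, ]
  if (a$ref_type == "contig") {
    mlen <- attr(mate_aln, "read_len") %||% 0L
    gs <- a$pos; ge <- a$pos + mlen
    return(a$ref == call$contig && a$strand == expOri &&
           gs >= call$start && ge <= call$end)
  }
  # transcript placement: project to genome
  map <- index$txMap[[a$ref]]
  if (is.null(map)) return(FALSE)
  if (map$contig != call$contig || map$strand != call$strand) return(FALSE)
  # on the transcript (sense) the expected orientation is + for mate1 and
  # - for mate2, independent of gene strand
  expTxOri <- if (mateNo == 1L) "+" else "-"
  if (a$strand != expTxOri) return(FALSE)
  mlen <- attr(mate_aln, "read_len") %||% 0L
  iv <- projectTxInterval(map, a$pos, a$pos + mlen)
  if (!length(iv)) return(FALSE)
  all(vapply(iv, function(x) x[1] >= call$start && x[2] <= call$end,
             logical(1)))
}

#' Drop candidates from repetitive or homologous regions
#'
#' A merged candidate is discarded when any supporting read's anchor had
#' more than one best genomic locus, or when the back-splice junction
#' sequence (anchor_len bases each side of the joint) occurs anywhere in
#' the genome as an exact match on either strand — a genuine junction
#' sequence is absent from the linear genome.
#'
#' @param candidates data.frame with `contig`, `start`, `end`, `strand`,
#'   `max_anchor_hits`.
#' @param bundle a [GenomeBundle-class].
#' @param anchor_len anchor length used for the junction sequence.
#' @return logical vector, TRUE = keep.
#' @export
filterRepetitive <- function(candidates, bundle, anchor_len = 20L) {
  if (!nrow(candidates)) return(logical(0))
  seqs <- genomeSeqs(bundle)
  ss <- Biostrings::DNAStringSet(seqs)
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (!is.null(candidates$max_anchor_hits) &&
        candidates$max_anchor_hits[i] > 1L) { keep[i] <- FALSE; next }
    ctg <- seqs[[candidates$contig[i]]]
    s <- candidates$start[i]; e <- candidates$end[i]
    jseq <- paste0(subseq0(ctg, max(e - anchor_len, s), e),
                   subseq0(ctg, s, min(s + anchor_len, e)))
    pat <- Biostrings::DNAString(jseq)
    n <- sum(Biostrings::vcountPattern(pat, ss)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), ss))
    if (n > 0L) keep[i] <- FALSE
  }
  keep
}

#' Merge per-sample junction evidence into circRNA candidates
#'
#' Junction support is counted in fragments: a read pair contributes at
#' most one junction read to a candidate even when both mates span the
#' back-splice. Candidates are merged by (contig, start, end, strand)
#' across samples; per-sample presence in downstream detected sets
#' requires `min_junction_reads` (the counts themselves are retained).
#'
#' @param sampleCalls named list (per sample) of consistency-checked call
#'   data.frames.
#' @param sampleTable data.frame with `sample_id`, `library`, `timepoint`,
#'   `total_mapped_reads`.
#' @param bundle a [GenomeBundle-class] (for junction flank annotation).
#' @return a [CircExperiment-class]; `metadata()$min_junction_reads`
#'   records the detection threshold.
#' @export
callCircRNAs <- function(sampleCalls, sampleTable, bundle,
                         min_junction_reads = 2L) {
  seqs <- genomeSeqs(bundle)
  allCalls <- data.table::rbindlist(
    lapply(names(sampleCalls), function(s) {
      d <- sampleCalls[[s]]
      if (!nrow(d)) return(NULL)
      d$sample_id <- s
      d
    }), fill = TRUE)
  if (is.null(allCalls) || !nrow(allCalls)) {
    cand <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), strand = character(0))
    counts <- matrix(0L, 0L, nrow(sampleTable))
    ce <- CircExperiment(cand, counts, sampleTable)
    S4Vectors::metadata(ce)$min_junction_reads <- min_junction_reads
    return(ce)
  }
  # fragment rule: one junction read per (pair, junction)
  allCalls <- unique(allCalls[, c("sample_id", "read_id", "contig", "start",
                                  "end", "strand", "max_anchor_hits")],
                     by = c("sample_id", "read_id", "contig", "start", "end",
                            "strand"))
  agg <- allCalls[, list(n = .N, max_anchor_hits = max(max_anchor_hits)),
                  by = c("contig", "start", "end", "strand", "sample_id")]
  cand <- unique(agg[, c("contig", "start", "end", "strand")])
  data.table::setorderv(cand, c("contig", "start", "end", "strand"))
  candKey <- paste(cand$contig, cand$start, cand$end, cand$strand)
  counts <- matrix(0L, nrow(cand), nrow(sampleTable),
                   dimnames = list(NULL, sampleTable$sample_id))
  for (r in seq_len(nrow(agg))) {
    i <- match(paste(agg$contig[r], agg$start[r], agg$end[r], agg$strand[r]),
               candKey)
    counts[i, agg$sample_id[r]] <- agg$n[r]
  }
  cand <- as.data.frame(cand)
  anchorHitsMax <- agg[, list(m = max(max_anchor_hits)),
                       by = c("contig", "start", "end", "strand")]
  cand$max_anchor_hits <- anchorHitsMax$m[
    match(candKey, paste(anchorHitsMax$contig, anchorHitsMax$start,
                         anchorHitsMax$end, anchorHitsMax$strand))]
  cand$flank_donor <- vapply(seq_len(nrow(cand)), function(i)
    subseq0(seqs[[cand$contig[i]]], cand$end[i], cand$end[i] + 2L),
    character(1))
  cand$flank_acceptor <- vapply(seq_len(nrow(cand)), function(i)
    subseq0(seqs[[cand$contig[i]]], cand$start[i] - 2L, cand$start[i]),
    character(1))
  ce <- CircExperiment(cand[, c("contig", "start", "end", "strand",
                                "flank_donor", "flank_acceptor",
                                "max_anchor_hits")],
                       counts, sampleTable)
  S4Vectors::metadata(ce)$min_junction_reads <- min_junction_reads
  ce
}

#' Per-sample detected indicator
#'
#' A circRNA is detected in a sample iff its junction-read count reaches
#' `min_reads`.
#'
#' @param circ a [CircExperiment-class].
#' @param min_reads detection threshold (default 2).
#' @return logical matrix, circ x sample.
#' @export
detectedMatrix <- function(circ, min_reads = 2L) {
  junctionReads(circ) >= min_reads
}

#' Full back-splice detection across a sample grid
#'
#' Orchestrates [alignReads()], [findJunctionReads()],
#' [checkMateConsistency()], [callCircRNAs()] and [filterRepetitive()] for
#' every sample.
#'
#' @param bundle a [GenomeBundle-class].
#' @param readSets named list of per-sample read sets (`ids`, `mate1`,
#'   `mate2`).
#' @param sampleTable data.frame with `sample_id`, `library`, `timepoint`
#'   matching `names(readSets)`; `total_mapped_reads` is filled in from
#'   the alignment.
#' @param anchor_len,max_mm,max_circ_len,min_junction_reads detection
#'   parameters.
#' @param index optionally a prebuilt [buildAlignmentIndex()].
#' @return list: `circ` ([CircExperiment-class], repeat-filtered),
#'   `alignments` (per-sample [alignReads()] results), `rejections`
#'   (sample x category counts).
#' @export
detectCircRNAs <- function(bundle, readSets, sampleTable,
                           anchor_len = 20L, max_mm = 2L,
                           max_circ_len = 100000L, min_junction_reads = 2L,
                           index = NULL) {
  missing <- setdiff(sampleTable$sample_id, names(readSets))
  if (length(missing))
    stopf("missing read sets for sample(s): %s", paste(missing, collapse = ", "))
  if (is.null(index)) index <- buildAlignmentIndex(bundle, k = anchor_len)
  alignments <- list()
  sampleCalls <- list()
  rejections <- matrix(0L, nrow(sampleTable), length(REJECT_CATEGORIES),
                       dimnames = list(sampleTable$sample_id,
                                       REJECT_CATEGORIES))
  totalMapped <- integer(nrow(sampleTable))
  for (si in seq_len(nrow(sampleTable))) {
    sid <- sampleTable$sample_id[si]
    reads <- readSets[[sid]]
    al <- alignReads(reads, index, max_mm = max_mm)
    alignments[[sid]] <- al
    totalMapped[si] <- al$total_mapped
    jr <- findJunctionReads(al$unmapped, bundle, index, max_mm = max_mm,
                            max_circ_len = max_circ_len)
    rejections[sid, names(jr$rejects)] <- jr$rejects
    calls <- jr$calls
    if (nrow(calls)) {
      readLen <- nchar(reads$mate1[1])
      ok <- logical(nrow(calls))
      alnDt <- data.table::as.data.table(al$aln)
      data.table::setkey(alnDt, read_id, mate)
      callsByRead <- split(seq_len(nrow(calls)),
                           paste(calls$read_id, calls$mate))
      for (i in seq_len(nrow(calls))) {
        mateNo <- if (calls$mate[i] == 1L) 2L else 1L
        ma <- alnDt[list(calls$read_id[i], mateNo), nomatch = NULL]
        if (nrow(ma)) attr(ma, "read_len") <- readLen
        mcIdx <- callsByRead[[paste(calls$read_id[i], mateNo)]]
        mc <- if (is.null(mcIdx)) NULL else calls[mcIdx, , drop = FALSE]
        ok[i] <- checkMateConsistency(calls[i, ], ma, mc, index)
      }
      rejections[sid, "mate_inconsistent"] <-
        rejections[sid, "mate_inconsistent"] + sum(!ok)
      calls <- calls[ok, , drop = FALSE]
    }
    sampleCalls[[sid]] <- calls
  }
  st <- sampleTable
  st$total_mapped_reads <- pmax(totalMapped, 1L)
  circ <- callCircRNAs(sampleCalls, st, bundle,
                       min_junction_reads = min_junction_reads)
  if (nrow(circ)) {
    keep <- filterRepetitive(circCoords(circ), bundle, anchor_len = anchor_len)
    nDropped <- sum(!keep)
    if (nDropped) {
      rejections[, "repetitive"] <- rejections[, "repetitive"] +
        as.integer(colSums(junctionReads(circ)[!keep, , drop = FALSE]) > 0)
    }
    circ <- circ[keep, ]
  }
  list(circ = circ, alignments = alignments, rejections = rejections)
}
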