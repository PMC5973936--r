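# Independent oracles, written against the rules rather than the
# implementation: brute-force junction-template detection (Biostrings
# matching), a one-expression transcription of the screen rule, a naive
# doubled-sequence seed scan, and a memoized-recursion pairing DP.

oRevcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

oHamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# all end-to-end linear placements of a read (genome + spliced
# transcripts, both orientations) with <= max_mm mismatches.
# `subjects` may be a prebuilt list of DNAString objects (same names as
# refs) to avoid repeated construction; `first_only` stops at the first
# placement found (mapped/unmapped determination).
oLinearPlacements <- function(seq, refs, refType, max_mm = 2L,
                              subjects = NULL, first_only = FALSE) {
  if (is.null(subjects))
    subjects <- lapply(refs, Biostrings::DNAString)
  out <- list()
  for (ori in c("+", "-")) {
    q <- if (ori == "+") seq else oRevcomp(seq)
    qd <- Biostrings::DNAString(q)
    for (rn in names(refs)) {
      m <- Biostrings::matchPattern(qd, subjects[[rn]],
                                    max.mismatch = max_mm)
      if (length(m)) {
        out[[length(out) + 1L]] <- data.frame(
          ref = rn, ref_type = refType[[rn]],
          pos = Biostrings::start(m) - 1L, strand = ori,
          mm = vapply(as.character(m), oHamming, numeric(1), a = q),
          stringsAsFactors = FALSE)
        if (first_only) return(do.call(rbind, out))
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# enumerate every contiguous exon-run circular template of the annotation
oTemplates <- function(bundle) {
  ex <- exonTable(bundle); tx <- transcriptTable(bundle); g <- geneTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  seqs <- genomeSeqs(bundle)
  rows <- list()
  for (tid in tx$transcript_id) {
    e <- ex[ex$transcript_id == tid, ]
    gi <- g[g$gene_id == tx2g[[tid]], ]
    for (i in seq_len(nrow(e))) for (j in i:nrow(e)) {
      cs <- paste(substr(rep(seqs[[gi$contig]], j - i + 1L),
                         e$start[i:j] + 1L, e$end[i:j]), collapse = "")
      if (gi$strand == "-") cs <- oRevcomp(cs)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = gi$contig, start = e$start[i], end = e$end[j],
        strand = gi$strand, gene_id = gi$gene_id, seq = cs,
        stringsAsFactors = FALSE)
    }
  }
  tpl <- do.call(rbind, rows)
  tpl[!duplicated(paste(tpl$contig, tpl$start, tpl$end, tpl$strand)), ]
}

# junction placements of a circle-sense query against one template:
# positions in the junction context where the query matches <= max_mm and
# crosses the back-splice with >= A bases on each side
oJunctionMatches <- function(q, circSeq, A = 20L, max_mm = 2L) {
  L <- nchar(q); C <- nchar(circSeq)
  if (C < L - A) return(integer(0))   # context would wrap; not supported
  J <- paste0(substr(circSeq, C - (L - A) + 1L, C), substr(circSeq, 1L, L - A))
  hits <- integer(0); mms <- integer(0)
  for (p in 0:(L - 2L * A)) {
    mm <- oHamming(q, substr(J, p + 1L, p + L))
    if (mm <= max_mm) { hits <- c(hits, p); mms <- c(mms, mm) }
  }
  attr(hits, "mm") <- mms
  hits
}

# brute-force circRNA caller over annotated exon-run templates
oracleDetect <- function(bundle, readSets, sampleTable, A = 20L,
                         max_mm = 2L, min_reads = 2L) {
  tpl <- oTemplates(bundle)
  contigs <- genomeSeqs(bundle)
  tx <- transcriptTable(bundle)
  txSeqs <- setNames(vapply(tx$transcript_id, transcriptSeq, character(1),
                            bundle = bundle), tx$transcript_id)
  refs <- c(contigs, txSeqs)
  refType <- setNames(rep(c("contig", "transcript"),
                          c(length(contigs), length(txSeqs))), names(refs))
  ex <- exonTable(bundle); g <- geneTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  txInfo <- lapply(tx$transcript_id, function(tid) {
    e <- ex[ex$transcript_id == tid, ]
    gi <- g[g$gene_id == tx2g[[tid]], ]
    list(exons = e, contig = gi$contig, strand = gi$strand)
  })
  names(txInfo) <- tx$transcript_id

  projTx <- function(tid, s, e) {
    info <- txInfo[[tid]]
    w <- info$exons$end - info$exons$start
    if (info$strand == "+") txs <- cumsum(c(0L, w))[seq_along(w)]
    else txs <- rev(cumsum(c(0L, rev(w)))[seq_along(w)])
    lo <- Inf; hi <- -Inf
    for (i in seq_along(w)) {
      os <- max(s, txs[i]); oe <- min(e, txs[i] + w[i])
      if (os >= oe) next
      if (info$strand == "+") {
        lo <- min(lo, info$exons$start[i] + (os - txs[i]))
        hi <- max(hi, info$exons$start[i] + (oe - txs[i]))
      } else {
        lo <- min(lo, info$exons$end[i] - (oe - txs[i]))
        hi <- max(hi, info$exons$end[i] - (os - txs[i]))
      }
    }
    c(lo, hi)
  }

  tuples <- paste(tpl$contig, tpl$start, tpl$end, tpl$strand)
  counts <- matrix(0L, nrow(tpl), nrow(sampleTable),
                   dimnames = list(tuples, sampleTable$sample_id))
  subjects <- lapply(refs, Biostrings::DNAString)
  for (sid in sampleTable$sample_id) {
    rs <- readSets[[sid]]
    n <- length(rs$ids)
    placements <- vector("list", 2L * n)
    mapped <- matrix(FALSE, n, 2L)
    for (m in 1:2) {
      seqsm <- if (m == 1) rs$mate1 else rs$mate2
      for (i in seq_len(n)) {
        pl <- oLinearPlacements(seqsm[i], refs, refType, max_mm,
                                subjects = subjects, first_only = TRUE)
        mapped[i, m] <- !is.null(pl)
      }
    }
    # junction candidates for every unmapped mate: unique best across the
    # template set, ties dropped as ambiguous
    juncOf <- vector("list", 2L * n)
    for (m in 1:2) {
      seqsm <- if (m == 1) rs$mate1 else rs$mate2
      for (i in seq_len(n)) {
        if (mapped[i, m]) next
        q <- if (m == 1) seqsm[i] else oRevcomp(seqsm[i])
        cand <- list()
        for (t in seq_len(nrow(tpl))) {
          hits <- oJunctionMatches(q, tpl$seq[t], A, max_mm)
          if (length(hits))
            cand[[length(cand) + 1L]] <- data.frame(
              t = t, p = hits, mm = attr(hits, "mm"))
        }
        if (!length(cand)) next
        cand <- do.call(rbind, cand)
        cand$tuple <- tuples[cand$t]
        cand <- cand[!duplicated(paste(cand$tuple, cand$p)), ]
        best <- cand[cand$mm == min(cand$mm), ]
        if (nrow(best) == 1L) juncOf[[(m - 1L) * n + i]] <- best
      }
    }
    # mate consistency + fragment-level counting
    for (i in seq_len(n)) {
      seen <- character(0)
      for (m in 1:2) {
        jc <- juncOf[[(m - 1L) * n + i]]
        if (is.null(jc)) next
        t <- jc$t
        s0 <- tpl$start[t]; e0 <- tpl$end[t]; st <- tpl$strand[t]
        other <- if (m == 1L) 2L else 1L
        expOri <- if (st == "+") (if (other == 1L) "+" else "-")
                  else (if (other == 1L) "-" else "+")
        consistent <- FALSE
        oj <- juncOf[[(other - 1L) * n + i]]
        if (!is.null(oj) && tuples[oj$t] == jc$tuple) consistent <- TRUE
        if (!consistent) {
          pl <- if (mapped[i, other]) {
            oLinearPlacements(if (other == 1L) rs$mate1[i] else rs$mate2[i],
                              refs, refType, max_mm, subjects = subjects)
          } else NULL
          if (!is.null(pl)) {
            pl$prio <- ifelse(pl$ref_type == "contig", 0L, 1L)
            pl <- pl[order(pl$mm, pl$prio, pl$ref, pl$pos, pl$strand), ]
            bestPl <- pl[1, ]
            mlen <- nchar(if (other == 1L) rs$mate1[i] else rs$mate2[i])
            if (bestPl$ref_type == "contig") {
              consistent <- bestPl$ref == tpl$contig[t] &&
                bestPl$strand == expOri &&
                bestPl$pos >= s0 && bestPl$pos + mlen <= e0
            } else {
              info <- txInfo[[bestPl$ref]]
              expTxOri <- if (other == 1L) "+" else "-"
              if (info$contig == tpl$contig[t] && info$strand == st &&
                  bestPl$strand == expTxOri) {
                gv <- projTx(bestPl$ref, bestPl$pos, bestPl$pos + mlen)
                consistent <- is.finite(gv[1]) && gv[1] >= s0 && gv[2] <= e0
              }
            }
          }
        }
        if (consistent && !(jc$tuple %in% seen)) {
          counts[jc$tuple, sid] <- counts[jc$tuple, sid] + 1L
          seen <- c(seen, jc$tuple)
        }
      }
    }
  }
  keep <- apply(counts >= min_reads, 1, any)
  out <- tpl[keep, c("contig", "start", "end", "strand")]
  out <- cbind(out, counts[keep, , drop = FALSE])
  rownames(out) <- NULL
  out[order(out$contig, out$start, out$end), ]
}

# one-expression transcription of the differential screen rule
# fc: numeric(4) = (rminus t24/t0, rminus t48/t0, rnaser t24/t0, rnaser
# t48/t0); j: named junction counts over the 6-sample grid
oracleScreenRule <- function(fc, j, min_support = 3) {
  isUp <- (sum(fc > 1.5) >= 3) && (all(fc[fc <= 1.5] > 1.0)) &&
    (max(j["rminus_t24"], j["rminus_t48"]) >= min_support) &&
    (max(j["rnaser_t24"], j["rnaser_t48"]) >= min_support)
  isDown <- (sum(fc < 0.67) >= 3) && (all(fc[fc >= 0.67] < 1.0)) &&
    (j["rminus_t0"] >= min_support) && (j["rnaser_t0"] >= min_support)
  if (isUp) "up" else if (isDown) "down" else "unchanged"
}

# naive doubled-sequence seed-site scan (RNA space)
oracleSeedScan <- function(circ_seq, mirna_seq) {
  toRna <- function(x) chartr("Tt", "Uu", toupper(x))
  rcRna <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
  tgt <- toRna(circ_seq); mir <- toRna(mirna_seq)
  L <- nchar(tgt)
  dbl <- paste0(tgt, tgt)
  m7 <- rcRna(substr(mir, 2, 8)); m6 <- rcRna(substr(mir, 2, 7))
  res <- list()
  for (p in 0:(L - 1)) {
    w8 <- substr(dbl, p + 1, p + 8)
    has7 <- substr(w8, 1, 7) == m7
    has6 <- substr(w8, 1, 6) == m6
    if (!has6 && !has7) next
    cls <- if (has7 && substr(w8, 8, 8) == "A") "8mer"
      else if (has7) "7mer-m8"
      else if (has6 && substr(w8, 7, 7) == "A") "7mer-A1"
      else "6mer"
    res[[length(res) + 1]] <- data.frame(site_start = p, seed_class = cls)
  }
  if (!length(res)) return(data.frame(site_start = integer(0),
                                      seed_class = character(0)))
  do.call(rbind, res)
}

# memoized-recursion local duplex alignment with the same scoring scheme
# and seed gap-free constraint as the package's iterative Gotoh
oraclePairingScore <- function(site_region, mirna_seq, match = 5,
                               wobble = 1, mismatch = -3, gap_open = -8,
                               gap_extend = -2) {
  toRna <- function(x) chartr("Tt", "Uu", toupper(x))
  tgt <- strsplit(toRna(site_region), "")[[1]]
  mir <- strsplit(toRna(mirna_seq), "")[[1]]
  n <- length(mir); nt <- length(tgt)
  q <- rev(mir); qpos <- rev(seq_len(n))
  ps <- function(t, m) {
    wc <- (t == "A" && m == "U") || (t == "U" && m == "A") ||
      (t == "G" && m == "C") || (t == "C" && m == "G")
    if (wc) return(match)
    if ((t == "G" && m == "U") || (t == "U" && m == "G")) return(wobble)
    mismatch
  }
  NEG <- -1e9
  memo <- new.env(parent = emptyenv())
  sc <- function(state, i, j) {
    key <- paste(state, i, j)
    v <- get0(key, envir = memo)
    if (!is.null(v)) return(v)
    v <- if (state == "M") {
      if (i == 0 || j == 0) 0
      else {
        s <- ps(tgt[i], q[j])
        max(0, sc("M", i - 1, j - 1) + s, sc("X", i - 1, j - 1) + s,
            sc("Y", i - 1, j - 1) + s)
      }
    } else if (state == "X") {   # gap in miRNA, consumes target
      if (i == 0 || j == 0 || (qpos[j] >= 3 && qpos[j] <= 8)) NEG
      else max(sc("M", i - 1, j) + gap_open, sc("X", i - 1, j) + gap_extend)
    } else {                     # gap in target, consumes miRNA
      if (i == 0 || j == 0 || (qpos[j] >= 2 && qpos[j] <= 8)) NEG
      else max(sc("M", i, j - 1) + gap_open, sc("Y", i, j - 1) + gap_extend)
    }
    assign(key, v, envir = memo)
    v
  }
  best <- 0
  for (i in seq_len(nt)) for (j in seq_len(n))
    best <- max(best, sc("M", i, j))
  best
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")
randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
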