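# miRNA response-element prediction on circRNA sequences: canonical seed
# matching on the circularized sequence (so back-splice-spanning sites are
# found), a simplified miRanda-like duplex pairing score, and the
# three-way intersection with CLIP support.

#' Spliced circular sequence of a circRNA
#'
#' Concatenation of the constituent exon sequences of the border-matched
#' transcript in transcript order, sense strand. Non-exonic circles fall
#' back to the genomic span (attribute `exonic = FALSE`).
#'
#' @param circ one-row data.frame (`contig`, `start`, `end`, `strand`).
#' @param bundle a [GenomeBundle-class].
#' @return character scalar with attribute `exonic`.
#' @export
circSequence <- function(circ, bundle) {
  seqs <- genomeSeqs(bundle)
  m <- matchCircTranscript(circ, bundle)
  if (is.null(m)) {
    s <- subseq0(seqs[[circ$contig]], circ$start, circ$end)
    if (circ$strand == "-") s <- revcompChr(s)
    attr(s, "exonic") <- FALSE
    return(s)
  }
  e <- m$exons[m$a:m$b, , drop = FALSE]
  s <- paste(substr(rep(seqs[[circ$contig]], nrow(e)), e$start + 1L, e$end),
             collapse = "")
  if (circ$strand == "-") s <- revcompChr(s)
  attr(s, "exonic") <- TRUE
  s
}

SEED_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Seed-match sites of a miRNA on a circular sequence
#'
#' Scans the circularized target (the sequence with its first 7 bases
#' appended, so sites spanning the back-splice are found once, reported at
#' positions modulo the circle length). Site classes follow the canonical
#' definitions: `6mer` = Watson-Crick complement of miRNA positions 2-7;
#' `7mer-m8` = positions 2-8; `7mer-A1` = positions 2-7 plus an A opposite
#' position 1; `8mer` = positions 2-8 plus the A1. The maximal class is
#' reported per site start; duplicates (wrap-around) are removed.
#' DNA input is normalized to RNA (T to U).
#'
#' @param circ_seq circular target sequence (DNA or RNA alphabet).
#' @param mirna_seq mature miRNA sequence, 5' to 3', >= 8 nt.
#' @param circ_id,mirna_id identifiers carried into the output.
#' @return data.frame: `circ_id`, `mirna_id`, `site_start` (0-based on the
#'   circle), `seed_class`, `spans_junction`.
#' @export
seedMatchSites <- function(circ_seq, mirna_seq, circ_id = NA, mirna_id = NA) {
  mir <- rnaify(mirna_seq)
  if (nchar(mir) < 8) stopf("miRNA shorter than 8 nt")
  tgt <- rnaify(as.character(circ_seq))
  L <- nchar(tgt)
  ext <- paste0(tgt, substr(tgt, 1L, min(7L, L)))
  m7 <- revcompRna(substr(mir, 2L, 8L))   # target-sense match of pos 2-8
  m6 <- revcompRna(substr(mir, 2L, 7L))   # target-sense match of pos 2-7
  rows <- list()
  for (p0 in 0:(L - 1L)) {
    has7 <- substr(ext, p0 + 1L, p0 + 7L) == m7
    has6 <- substr(ext, p0 + 1L, p0 + 6L) == m6
    if (!has6 && !has7) next
    a1_8 <- substr(ext, p0 + 8L, p0 + 8L) == "A"
    a1_7 <- substr(ext, p0 + 7L, p0 + 7L) == "A"
    cls <- if (has7 && a1_8) "8mer"
           else if (has7) "7mer-m8"
           else if (has6 && a1_7) "7mer-A1"
           else "6mer"
    span <- switch(cls, `8mer` = 8L, `7mer-m8` = 7L, `7mer-A1` = 7L,
                   `6mer` = 6L)
    if (p0 + span > 2L * L) next  # degenerate tiny circles
    rows[[length(rows) + 1L]] <- data.frame(
      circ_id = circ_id, mirna_id = mirna_id, site_start = p0,
      seed_class = cls, spans_junction = (p0 + span) > L,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(circ_id = character(0), mirna_id = character(0),
               site_start = integer(0), seed_class = character(0),
               spans_junction = logical(0))
  out[!duplicated(out$site_start), , drop = FALSE]
}

#' Duplex pairing score of a miRNA against a target region
#'
#' Best local alignment of the miRNA (read 3' to 5') against the target
#' region (5' to 3') under a simplified miRanda-like scheme:
#' Watson-Crick pair +5, G:U wobble +1, mismatch -3, gap open -8 (first
#' gapped base) and gap extension -2, with the seed region (miRNA
#' positions 2-8) required to be gap-free. Affine-gap (Gotoh) dynamic
#' programming; alphabet normalized to RNA.
#'
#' @param site_region target sequence (site plus upstream context).
#' @param mirna_seq mature miRNA, 5' to 3'.
#' @param match,wobble,mismatch,gap_open,gap_extend scoring parameters.
#' @return best local alignment score (numeric).
#' @export
pairingScore <- function(site_region, mirna_seq, match = 5, wobble = 1,
                         mismatch = -3, gap_open = -8, gap_extend = -2) {
  tgt <- strsplit(rnaify(site_region), "")[[1]]
  mir <- strsplit(rnaify(mirna_seq), "")[[1]]
  n <- length(mir)
  q <- rev(mir)                 # miRNA 3' -> 5'
  qpos <- rev(seq_len(n))       # original miRNA position of each q char
  nt <- length(tgt)
  pairScore <- function(t, m) {
    if ((t == "A" && m == "U") || (t == "U" && m == "A") ||
        (t == "G" && m == "C") || (t == "C" && m == "G")) return(match)
    if ((t == "G" && m == "U") || (t == "U" && m == "G")) return(wobble)
    mismatch
  }
  NEG <- -1e9
  M <- matrix(0, nt + 1L, n + 1L)
  Ix <- matrix(NEG, nt + 1L, n + 1L)  # gap in miRNA (consumes target)
  Iy <- matrix(NEG, nt + 1L, n + 1L)  # gap in target (consumes miRNA)
  best <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(n)) {
      pj <- qpos[j]                 # miRNA position consumed at column j
      inSeed <- pj >= 2L && pj <= 8L
      s <- pairScore(tgt[i], q[j])
      M[i + 1L, j + 1L] <- max(0,
                               M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      # target insertions between adjacent seed positions (between pj and
      # pj-1, both in 2..8, i.e. pj in 3..8) are forbidden
      ixAllowed <- !(pj >= 3L && pj <= 8L)
      if (ixAllowed) {
        Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open,
                                  Ix[i, j + 1L] + gap_extend)
      }
      if (!inSeed) {
        Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open,
                                  Iy[i + 1L, j] + gap_extend)
      }
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

#' Extract a site's region with upstream context from a circular sequence
#'
#' The miRNA 3' supplementary region pairs upstream (5') of the seed
#' match, so the region is `[site_start - context, site_start + 8)` on the
#' circle, wrapping across the back-splice as needed.
#'
#' @param circ_seq circular sequence.
#' @param site_start 0-based site start.
#' @param context upstream context length (default 30).
#' @return character scalar.
#' @export
siteRegion <- function(circ_seq, site_start, context = 30L) {
  tgt <- rnaify(as.character(circ_seq))
  L <- nchar(tgt)
  startIdx <- ((site_start - context) %% L)
  reps <- ceiling((startIdx + context + 8L) / L) + 1L
  big <- strrep(tgt, reps)
  substr(big, startIdx + 1L, startIdx + context + 8L)
}

#' Three-way sponge verdicts
#'
#' Per miRNA: `passes_seed` iff at least one site of class 7mer or better;
#' `passes_pairing` iff at least one site's pairing score reaches the
#' threshold; `passes_clip` iff the (circRNA, miRNA) pair is listed in the
#' CLIP table; `final` is the conjunction — the prediction kept by all
#' three lines of evidence.
#'
#' @param seed_hits data.frame from [seedMatchSites()] (one circRNA, all
#'   miRNAs).
#' @param pairing_hits data.frame with `mirna_id`, `score` per site.
#' @param clip_table data.frame with columns `mirna_id`, `target_id` (or a
#'   TSV path); may be empty (warning; all `passes_clip` FALSE).
#' @param circ_id the circRNA id used to filter `clip_table`.
#' @param mirna_ids universe of miRNAs to report.
#' @param score_threshold pairing-score threshold (default 80).
#' @return data.frame: `mirna_id`, `passes_seed`, `passes_pairing`,
#'   `passes_clip`, `final`.
#' @export
intersectPredictions <- function(seed_hits, pairing_hits, clip_table,
                                 circ_id, mirna_ids,
                                 score_threshold = 80) {
  if (is.character(clip_table))
    clip_table <- read.delim(clip_table, stringsAsFactors = FALSE)
  if (!nrow(clip_table)) {
    warning("empty CLIP table: all passes_clip are FALSE")
    clip_table <- data.frame(mirna_id = character(0),
                             target_id = character(0))
  }
  strong <- seed_hits$seed_class %in% c("7mer-A1", "7mer-m8", "8mer")
  clipMirs <- clip_table$mirna_id[clip_table$target_id == circ_id]
  out <- data.frame(
    mirna_id = mirna_ids,
    passes_seed = vapply(mirna_ids, function(m)
      any(strong & seed_hits$mirna_id == m), logical(1)),
    passes_pairing = vapply(mirna_ids, function(m)
      any(pairing_hits$mirna_id == m &
          pairing_hits$score >= score_threshold), logical(1)),
    passes_clip = mirna_ids %in% clipMirs,
    row.names = NULL)
  out$final <- out$passes_seed & out$passes_pairing & out$passes_clip
  out
}

#' Predict miRNA sponge interactions for a set of circRNAs
#'
#' Runs [seedMatchSites()], [pairingScore()] on every site (with upstream
#' circular context) and [intersectPredictions()] per circRNA.
#'
#' @param circs data.frame of circRNA coordinates (with `circ_id`).
#' @param bundle a [GenomeBundle-class].
#' @param mirnas named character vector of mature miRNA sequences.
#' @param clip_table CLIP support table (`mirna_id`, `target_id`) or TSV
#'   path.
#' @param score_threshold pairing threshold (default 80).
#' @param context upstream context for the pairing score.
#' @return data.frame per (circ, miRNA): `circ_id`, `mirna_id`, `n_sites`,
#'   `best_class`, `best_score`, `passes_seed`, `passes_pairing`,
#'   `passes_clip`, `final`.
#' @export
predictSponges <- function(circs, bundle, mirnas, clip_table,
                           score_threshold = 80, context = 30L) {
  if (is.character(clip_table))
    clip_table <- read.delim(clip_table, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(circs))) {
    cs <- circSequence(circs[i, ], bundle)
    cid <- circs$circ_id[i]
    seedAll <- list(); pairAll <- list()
    for (mid in names(mirnas)) {
      sites <- seedMatchSites(cs, mirnas[[mid]], circ_id = cid,
                              mirna_id = mid)
      seedAll[[mid]] <- sites
      if (nrow(sites)) {
        sc <- vapply(sites$site_start, function(p)
          pairingScore(siteRegion(cs, p, context), mirnas[[mid]]),
          numeric(1))
        pairAll[[mid]] <- data.frame(mirna_id = mid,
                                     site_start = sites$site_start,
                                     score = sc)
      }
    }
    seedDf <- do.call(rbind, seedAll)
    if (is.null(seedDf)) seedDf <- seedMatchSites("ACGUACGU", "ACGUACGU")[0, ]
    pairDf <- if (length(pairAll)) do.call(rbind, pairAll) else
      data.frame(mirna_id = character(0), site_start = integer(0),
                 score = numeric(0))
    verdict <- intersectPredictions(seedDf, pairDf, clip_table, cid,
                                    names(mirnas),
                                    score_threshold = score_threshold)
    verdict$n_sites <- vapply(verdict$mirna_id, function(m)
      sum(seedDf$mirna_id == m), numeric(1))
    verdict$best_class <- vapply(verdict$mirna_id, function(m) {
      cl <- seedDf$seed_class[seedDf$mirna_id == m]
      if (!length(cl)) NA_character_ else
        SEED_CLASSES[max(match(cl, SEED_CLASSES))]
    }, character(1))
    verdict$best_score <- vapply(verdict$mirna_id, function(m) {
      s <- pairDf$score[pairDf$mirna_id == m]
      if (!length(s)) NA_real_ else max(s)
    }, numeric(1))
    verdict <- cbind(circ_id = cid, verdict)
    out[[length(out) + 1L]] <-
      verdict[, c("circ_id", "mirna_id", "n_sites", "best_class",
                  "best_score", "passes_seed", "passes_pairing",
                  "passes_clip", "final")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
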