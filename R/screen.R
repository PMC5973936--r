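# High-confidence set construction and the differential-regulation
# consensus screen over the 2 (library) x 3 (timepoint) grid.
#
# The screen is deliberately the rule-based procedure it reimplements —
# literal fold-change constants (1.5 / 0.67 / 1.0), junction-read support
# minima, no count-model statistics and no multiple-testing correction.

.checkGrid <- function(st) {
  need <- sampleGrid()
  key <- paste(st$library, st$timepoint)
  absent <- setdiff(paste(need$library, need$timepoint), key)
  if (length(absent))
    stopf("sample grid incomplete; missing cell(s): %s",
          paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Build the high-confidence circRNA set
#'
#' A circRNA is detected in a sample iff it has at least `min_reads`
#' junction reads there; it is a member of the confidence set iff it is
#' detected in BOTH library types at the SAME timepoint for at least one
#' of the three timepoints.
#'
#' @param circ a [CircExperiment-class] covering the full 2 x 3 grid.
#' @param min_reads detection threshold (default 2 junction reads).
#' @return data.frame: candidate coordinates plus `circ_id`,
#'   `member_timepoints` (comma-separated co-detected timepoints) for the
#'   members only.
#' @export
buildConfidenceSet <- function(circ, min_reads = 2L) {
  st <- sampleInfo(circ)
  .checkGrid(st)
  det <- detectedMatrix(circ, min_reads)
  tps <- c("t0", "t24", "t48")
  co <- sapply(tps, function(tp) {
    rm <- st$sample_id[st$library == "rminus" & st$timepoint == tp]
    rn <- st$sample_id[st$library == "rnaser" & st$timepoint == tp]
    det[, rm, drop = TRUE] & det[, rn, drop = TRUE]
  })
  if (!is.matrix(co)) co <- matrix(co, nrow = nrow(circ),
                                   dimnames = list(rownames(circ), tps))
  member <- rowSums(co) > 0
  out <- circCoords(circ)[member, , drop = FALSE]
  out$member_timepoints <- apply(co[member, , drop = FALSE], 1, function(z)
    paste(tps[z], collapse = ","))
  rownames(out) <- NULL
  out
}

#' Annotate circRNAs against a known catalog
#'
#' `annotated` iff the exact tuple (contig, start, end, strand) appears in
#' the catalog; otherwise `novel`.
#'
#' @param set confidence-set data.frame ([buildConfidenceSet()]).
#' @param known_bed path to a BED6 catalog, or a data.frame from
#'   [readCircBed()].
#' @return `set` with an `annotation_status` column.
#' @export
annotateKnown <- function(set, known_bed) {
  known <- if (is.character(known_bed)) readCircBed(known_bed) else known_bed
  key <- paste(known$contig, known$start, known$end, known$strand)
  mine <- paste(set$contig, set$start, set$end, set$strand)
  set$annotation_status <- ifelse(mine %in% key, "annotated", "novel")
  set
}

#' Fold changes over the four treated timepoints
#'
#' For each circRNA the 4-vector (rminus t24/t0, rminus t48/t0, rnaser
#' t24/t0, rnaser t48/t0) computed on depth-normalized junction reads with
#' a symmetric pseudocount: each sample contributes `normalized + eps_s`,
#' where `eps_s` is one raw read normalized in that sample
#' ([normalizeCirc()] of 1). With `pseudocount = FALSE`, zero baselines
#' give Inf/NaN.
#'
#' @param circ a [CircExperiment-class] covering the 2 x 3 grid.
#' @param pseudocount logical.
#' @return numeric matrix circ x 4, columns `fc_rminus_t24`,
#'   `fc_rminus_t48`, `fc_rnaser_t24`, `fc_rnaser_t48`.
#' @export
foldChangeGrid <- function(circ, pseudocount = TRUE) {
  st <- sampleInfo(circ)
  .checkGrid(st)
  jr <- junctionReads(circ)
  norm <- sweep(jr, 2, st$total_mapped_reads, "/") * 1e8
  eps <- if (pseudocount) 1e8 / st$total_mapped_reads else rep(0, nrow(st))
  names(eps) <- st$sample_id
  cols <- c(fc_rminus_t24 = NA, fc_rminus_t48 = NA,
            fc_rnaser_t24 = NA, fc_rnaser_t48 = NA)
  out <- matrix(NA_real_, nrow(circ), 4,
                dimnames = list(rownames(circ), names(cols)))
  for (lib in c("rminus", "rnaser")) {
    s0 <- st$sample_id[st$library == lib & st$timepoint == "t0"]
    for (tp in c("t24", "t48")) {
      s1 <- st$sample_id[st$library == lib & st$timepoint == tp]
      out[, sprintf("fc_%s_%s", lib, tp)] <-
        (norm[, s1] + eps[s1]) / (norm[, s0] + eps[s0])
    }
  }
  out
}

#' Classify a fold-change 4-vector
#'
#' `up` iff at least three of the four values exceed 1.5 and any remaining
#' value exceeds 1.0; `down` iff at least three are below 0.67 and any
#' remaining value is below 1.0; otherwise `unchanged`. Values equal to a
#' threshold do not pass (strict inequalities).
#'
#' @param fc4 numeric vector of 4 finite fold changes, or a matrix with 4
#'   columns (row-wise classification).
#' @return character: `up`, `down` or `unchanged`.
#' @export
classifyDirection <- function(fc4) {
  if (is.matrix(fc4)) {
    stopifnot(ncol(fc4) == 4)
    return(apply(fc4, 1, classifyDirection))
  }
  if (length(fc4) != 4 || any(is.na(fc4)) || any(is.nan(fc4)))
    stopf("classifyDirection needs 4 finite fold changes")
  nUp <- sum(fc4 > 1.5)
  if (nUp == 4L || (nUp == 3L && fc4[fc4 <= 1.5] > 1.0)) return("up")
  nDn <- sum(fc4 < 0.67)
  if (nDn == 4L || (nDn == 3L && fc4[fc4 >= 0.67] < 1.0)) return("down")
  "unchanged"
}

#' Junction-read support filter for a regulation call
#'
#' Upregulated calls require at least `min` junction reads in the 24 h or
#' 48 h timepoint of BOTH libraries; downregulated calls require at least
#' `min` junction reads in the untreated (t0) sample of BOTH libraries.
#'
#' @param direction `"up"` or `"down"`.
#' @param counts named numeric vector of the circRNA's junction reads with
#'   names `<library>_<timepoint>` (as [sampleGrid()] sample ids).
#' @param min support threshold (default 3).
#' @return logical.
#' @export
supportFilter <- function(direction, counts, min = 3L) {
  if (direction == "up") {
    max(counts["rminus_t24"], counts["rminus_t48"]) >= min &&
      max(counts["rnaser_t24"], counts["rnaser_t48"]) >= min
  } else if (direction == "down") {
    counts["rminus_t0"] >= min && counts["rnaser_t0"] >= min
  } else {
    stopf("supportFilter expects direction up or down")
  }
}

#' Screen for dynamically regulated circRNAs
#'
#' Pipeline: [foldChangeGrid()] then [classifyDirection()] then
#' [supportFilter()]; a direction whose support fails is demoted to
#' `unchanged` (with `support_pass = FALSE` retained for audit). Only
#' confidence-set members are screened.
#'
#' @param confidence_set data.frame from [buildConfidenceSet()] (optionally
#'   [annotateKnown()]-ed).
#' @param circ the [CircExperiment-class] the set was built from.
#' @param min_support junction-read support threshold (default 3).
#' @param pseudocount passed to [foldChangeGrid()].
#' @return data.frame: `circ_id`, `annotation_status` (if present), the
#'   four fold changes, `raw_direction`, `support_pass`, `direction`.
#' @export
screenDifferential <- function(confidence_set, circ, min_support = 3L,
                               pseudocount = TRUE) {
  ids <- confidence_set$circ_id
  fc <- foldChangeGrid(circ, pseudocount = pseudocount)[ids, , drop = FALSE]
  jr <- junctionReads(circ)[ids, , drop = FALSE]
  raw <- classifyDirection(fc)
  support <- vapply(seq_along(ids), function(i) {
    if (raw[i] == "unchanged") return(NA)
    supportFilter(raw[i], jr[i, ], min = min_support)
  }, logical(1))
  final <- ifelse(raw != "unchanged" & !is.na(support) & support,
                  raw, "unchanged")
  out <- data.frame(circ_id = ids, fc, raw_direction = unname(raw),
                    support_pass = support, direction = unname(final),
                    row.names = NULL)
  if (!is.null(confidence_set$annotation_status))
    out <- cbind(out[1],
                 annotation_status = confidence_set$annotation_status,
                 out[-1])
  out
}
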