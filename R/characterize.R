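# Descriptive analytics of the high-confidence set: genomic origin, exon
# counts, circRNAs per gene, ratio-vs-expression correlation, host-linear
# relationship classes, and cross-cell-type specificity.

#' Genomic origin of a circRNA
#'
#' Category precedence: if both breakpoints coincide with exon borders of
#' a sense-strand protein-coding transcript, the circle is `CDS` when any
#' constituent exon overlaps the CDS span, else `5UTR`/`3UTR` by position
#' relative to the CDS (strand-aware); else `lncRNA` when contained in a
#' sense lncRNA's exons; else `antisense` when overlapping any gene on the
#' opposite strand; else `unannotated`.
#'
#' @param circ one-row data.frame (`contig`, `start`, `end`, `strand`).
#' @param bundle a [GenomeBundle-class].
#' @return character scalar category.
#' @export
classifyGenomicOrigin <- function(circ, bundle) {
  g <- geneTable(bundle); tx <- transcriptTable(bundle); ex <- exonTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  m <- matchCircTranscript(circ, bundle)
  if (!is.null(m)) {
    gi <- g[g$gene_id == m$gene_id, ]
    if (gi$biotype == "protein_coding") {
      ti <- tx[tx$transcript_id == m$transcript_id, ]
      e <- m$exons[m$a:m$b, , drop = FALSE]
      overlapsCds <- any(e$start < ti$cds_end & e$end > ti$cds_start)
      if (overlapsCds) return("CDS")
      beforeCds <- circ$end <= ti$cds_start
      if (gi$strand == "+") return(if (beforeCds) "5UTR" else "3UTR")
      return(if (beforeCds) "3UTR" else "5UTR")
    }
    if (gi$biotype == "lncRNA") return("lncRNA")
  }
  # containment in a sense lncRNA's exons (border match not required)
  lnc <- g[g$biotype == "lncRNA" & g$contig == circ$contig &
           g$strand == circ$strand, ]
  for (gid in lnc$gene_id) {
    tids <- tx$transcript_id[tx$gene_id == gid]
    e <- ex[ex$transcript_id %in% tids, ]
    if (circ$start >= min(e$start) && circ$end <= max(e$end))
      return("lncRNA")
  }
  # antisense: overlap with any opposite-strand gene span
  opp <- g[g$contig == circ$contig & g$strand != circ$strand, ]
  for (gid in opp$gene_id) {
    tids <- tx$transcript_id[tx$gene_id == gid]
    e <- ex[ex$transcript_id %in% tids, ]
    if (circ$start < max(e$end) && circ$end > min(e$start))
      return("antisense")
  }
  "unannotated"
}

#' Number of annotated exons inside a circRNA
#'
#' Exons of the border-matched transcript falling inside `[start, end)`.
#' Non-exonic circles return NA (undefined).
#'
#' @param circ one-row data.frame.
#' @param bundle a [GenomeBundle-class].
#' @return integer or NA.
#' @export
exonCount <- function(circ, bundle) {
  m <- matchCircTranscript(circ, bundle)
  if (is.null(m)) return(NA_integer_)
  as.integer(m$b - m$a + 1L)
}

#' circRNAs per host gene
#'
#' Assigns each confidence-set circRNA to the gene of its border-matched
#' transcript; circles matching no transcript are excluded (logged via the
#' `unassigned` attribute).
#'
#' @param set confidence-set data.frame.
#' @param bundle a [GenomeBundle-class].
#' @return list: `per_gene` (data.frame gene_id, n_circ), `histogram`
#'   (table of n_circ), `fraction_single`, `unassigned` (circ ids).
#' @export
circPerGene <- function(set, bundle) {
  if (!nrow(set))
    return(list(per_gene = data.frame(gene_id = character(0),
                                      n_circ = integer(0)),
                histogram = table(integer(0)), fraction_single = NaN,
                unassigned = character(0)))
  gene <- vapply(seq_len(nrow(set)), function(i) {
    m <- matchCircTranscript(set[i, ], bundle)
    if (is.null(m)) NA_character_ else m$gene_id
  }, character(1))
  unassigned <- set$circ_id[is.na(gene)]
  tab <- table(gene[!is.na(gene)])
  perGene <- data.frame(gene_id = names(tab), n_circ = as.integer(tab),
                        row.names = NULL)
  list(per_gene = perGene, histogram = table(perGene$n_circ),
       fraction_single = mean(perGene$n_circ == 1L),
       unassigned = unassigned)
}

#' Representative circRNA of a host gene
#'
#' Among a gene's circRNAs, the one with maximal normalized expression
#' summed over the three RNase R-untreated timepoints; ties resolve to the
#' lexicographically smallest id (deterministic).
#'
#' @param circ_ids the gene's circRNA ids.
#' @param circ a [CircExperiment-class].
#' @return a single circ_id.
#' @export
hostRepresentative <- function(circ_ids, circ) {
  st <- sampleInfo(circ)
  rm <- st$sample_id[st$library == "rminus"]
  jr <- junctionReads(circ)[circ_ids, rm, drop = FALSE]
  norm <- sweep(jr, 2, st$total_mapped_reads[match(rm, st$sample_id)], "/") * 1e8
  tot <- rowSums(norm)
  best <- circ_ids[tot == max(tot)]
  sort(best)[1]
}

#' Correlation between circ:linear ratio and host expression
#'
#' Spearman rank correlation across genes of the circular:linear ratio of
#' each gene's representative circRNA against host-gene expression.
#'
#' @param ratio,host_expr numeric vectors, one entry per gene.
#' @return list with `rho` and `p`.
#' @export
ratioExpressionCorrelation <- function(ratio, host_expr) {
  keep <- is.finite(ratio) & is.finite(host_expr)
  if (sum(keep) < 10)
    stopf("need at least 10 gene pairs for the ratio/expression correlation (have %d)",
          sum(keep))
  ct <- suppressWarnings(cor.test(ratio[keep], host_expr[keep],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Direction of the host linear transcript
#'
#' Two-timepoint analog of the circular rule using the RNase R-untreated
#' library only: both fold changes above 1.5 is `up`, both below 0.67 is
#' `down`, else `unchanged`.
#'
#' @param fc2 numeric vector (t24/t0, t48/t0), or a 2-column matrix.
#' @return character.
#' @export
linearDirection <- function(fc2) {
  if (is.matrix(fc2)) return(apply(fc2, 1, linearDirection))
  if (length(fc2) != 2 || any(is.na(fc2)))
    stopf("linearDirection needs 2 finite fold changes")
  if (all(fc2 > 1.5)) return("up")
  if (all(fc2 < 0.67)) return("down")
  "unchanged"
}

#' Host-linear relationship class
#'
#' Partition of (circ direction, linear direction) pairs: a changed circle
#' with an unchanged host is `independent`; same non-null directions are
#' `concordant`; opposite non-null directions are `reciprocal`; an
#' unchanged circle is `both_unchanged`.
#'
#' @param circ_direction,linear_direction character vectors in
#'   up/down/unchanged.
#' @return character vector of classes.
#' @export
classifyHostRelation <- function(circ_direction, linear_direction) {
  mapply(function(cd, ld) {
    if (cd == "unchanged") return("both_unchanged")
    if (ld == "unchanged") return("independent")
    if (cd == ld) return("concordant")
    "reciprocal"
  }, circ_direction, linear_direction, USE.NAMES = FALSE)
}

#' Venn partition and per-set specificity of named circRNA sets
#'
#' Computes all 2^n - 1 Venn region cardinalities over n named sets and
#' each set's specific fraction |set minus union of others| / |set|.
#'
#' @param named_sets named list (>= 2) of circ id character vectors.
#' @return list: `regions` (data.frame `region` such as `"A&B"`, `count`),
#'   `specific` (data.frame `set`, `specific`, `size`, `fraction`).
#' @export
cellSpecificSets <- function(named_sets) {
  if (length(named_sets) < 2 || is.null(names(named_sets)))
    stopf("need >= 2 named sets")
  nm <- names(named_sets)
  ids <- unique(unlist(named_sets))
  memb <- vapply(named_sets, function(s) ids %in% s, logical(length(ids)))
  if (!is.matrix(memb)) memb <- matrix(memb, nrow = length(ids))
  profile <- apply(memb, 1, function(z) paste(nm[z], collapse = "&"))
  regions <- list()
  for (k in seq_along(nm)) {
    for (combo in as.data.frame(combn(nm, k), stringsAsFactors = FALSE)) {
      lab <- paste(combo, collapse = "&")
      regions[[lab]] <- sum(profile == lab)
    }
  }
  specific <- data.frame(
    set = nm,
    specific = vapply(nm, function(s)
      sum(memb[, s] & rowSums(memb[, setdiff(nm, s), drop = FALSE]) == 0),
      numeric(1)),
    size = vapply(named_sets, function(s) length(unique(s)), numeric(1)),
    row.names = NULL)
  specific$fraction <- ifelse(specific$size > 0,
                              specific$specific / specific$size, NaN)
  list(regions = data.frame(region = names(regions),
                            count = unlist(regions), row.names = NULL),
       specific = specific)
}
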