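#' GenomeBundle: genome sequence plus gene models
#'
#' The coordinate authority for all pipeline stages. Holds contig sequences
#' (uppercase DNA) and Ensembl-style gene models flattened into three tables.
#' All coordinates are 0-based half-open.
#'
#' @slot sequences [Biostrings::DNAStringSet] of contigs.
#' @slot genes data.frame: `gene_id`, `contig`, `strand` (+/-), `biotype`
#'   (`protein_coding`, `lncRNA`, `other`).
#' @slot transcripts data.frame: `transcript_id`, `gene_id`, `cds_start`,
#'   `cds_end` (NA unless protein_coding; endpoints fall inside exons).
#' @slot exons data.frame: `transcript_id`, `start`, `end`; within a
#'   transcript exons are non-overlapping and sorted by start.
#'
#' @export
setClass("GenomeBundle",
  representation(
    sequences = "DNAStringSet",
    genes = "data.frame",
    transcripts = "data.frame",
    exons = "data.frame"
  )
)

validGenomeBundle <- function(object) {
  msgs <- character(0)
  g <- object@genes; tx <- object@transcripts; ex <- object@exons
  lens <- setNames(Biostrings::width(object@sequences), names(object@sequences))
  if (anyDuplicated(names(object@sequences)))
    msgs <- c(msgs, "duplicate contig names")
  if (nrow(g)) {
    if (!all(g$strand %in% c("+", "-")))
      msgs <- c(msgs, "gene strand must be + or -")
    if (!all(g$biotype %in% c("protein_coding", "lncRNA", "other")))
      msgs <- c(msgs, "unknown biotype")
  }
  if (nrow(ex)) {
    tx2gene <- setNames(tx$gene_id, tx$transcript_id)
    ctg <- setNames(g$contig, g$gene_id)[tx2gene[ex$transcript_id]]
    if (anyNA(ctg)) msgs <- c(msgs, "exon references unknown transcript/gene")
    else {
      bad <- ex$start < 0 | ex$end > lens[ctg] | ex$end <= ex$start
      if (any(bad))
        msgs <- c(msgs, sprintf("%d exon(s) outside contig bounds or empty", sum(bad)))
      for (tid in unique(ex$transcript_id)) {
        e <- ex[ex$transcript_id == tid, ]
        if (is.unsorted(e$start, strictly = TRUE) && nrow(e) > 1)
          msgs <- c(msgs, sprintf("exons of %s not sorted by start", tid))
        if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
          msgs <- c(msgs, sprintf("overlapping exons in %s", tid))
      }
    }
  }
  if (nrow(tx)) {
    bt <- setNames(g$biotype, g$gene_id)[tx$gene_id]
    hasCds <- !is.na(tx$cds_start)
    if (any(hasCds & bt != "protein_coding"))
      msgs <- c(msgs, "cds_span present on non-protein_coding transcript")
    if (any(!hasCds & bt == "protein_coding"))
      msgs <- c(msgs, "protein_coding transcript lacks cds_span")
    for (i in which(hasCds)) {
      e <- ex[ex$transcript_id == tx$transcript_id[i], ]
      inExon <- function(p, endpoint = FALSE)
        any(p >= e$start & p <= if (endpoint) e$end else e$end - 1L)
      if (!inExon(tx$cds_start[i]) || !inExon(tx$cds_end[i], endpoint = TRUE))
        msgs <- c(msgs, sprintf("cds_span of %s not inside exons", tx$transcript_id[i]))
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("GenomeBundle", validGenomeBundle)

#' Construct a GenomeBundle
#'
#' @param sequences named character vector or DNAStringSet of contigs
#'   (uppercased on entry).
#' @param genes,transcripts,exons annotation tables, see
#'   [GenomeBundle-class].
#' @return a validated `GenomeBundle`.
#' @export
GenomeBundle <- function(sequences, genes, transcripts, exons) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  ex <- exons[order(match(exons$transcript_id, transcripts$transcript_id), exons$start), ,
              drop = FALSE]
  rownames(ex) <- NULL
  ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
  new("GenomeBundle", sequences = sequences,
      genes = as.data.frame(genes), transcripts = as.data.frame(transcripts),
      exons = as.data.frame(ex))
}

#' @describeIn GenomeBundle-class contig sequences as a named character vector
#' @param x a GenomeBundle
#' @export
genomeSeqs <- function(x) setNames(as.character(x@sequences), names(x@sequences))

#' @describeIn GenomeBundle-class gene table
#' @export
geneTable <- function(x) x@genes

#' @describeIn GenomeBundle-class transcript table
#' @export
transcriptTable <- function(x) x@transcripts

#' @describeIn GenomeBundle-class exon table (0-based half-open)
#' @export
exonTable <- function(x) x@exons

setMethod("show", "GenomeBundle", function(object) {
  cat(sprintf("GenomeBundle: %d contig(s), %.1f kb; %d gene(s), %d transcript(s), %d exon(s)\n",
              length(object@sequences),
              sum(Biostrings::width(object@sequences)) / 1000,
              nrow(object@genes), nrow(object@transcripts), nrow(object@exons)))
  bt <- table(object@genes$biotype)
  if (length(bt)) cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
})

#' CircExperiment: back-splice junction counts across a sample grid
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. Rows are circRNA
#' candidates (rowData: `contig`, `start`, `end`, `strand`, `flank_donor`,
#' `flank_acceptor`; coordinates 0-based half-open, `start` = first base of
#' the circle, `end` one past the last). Columns are samples (colData:
#' `sample_id`, `library` in rminus/rnaser, `timepoint` in t0/t24/t48,
#' `total_mapped_reads`). The single assay `junction_reads` holds per-sample
#' back-spliced junction fragment counts.
#'
#' @export
setClass("CircExperiment", contains = "SummarizedExperiment")

validCircExperiment <- function(object) {
  msgs <- character(0)
  if (!"junction_reads" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'junction_reads' missing")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("contig", "start", "end", "strand")
  if (!all(need %in% colnames(rd))) {
    msgs <- c(msgs, "rowData needs contig/start/end/strand")
  } else if (nrow(rd)) {
    if (any(rd$end <= rd$start)) msgs <- c(msgs, "end must exceed start")
    if (!all(rd$strand %in% c("+", "-"))) msgs <- c(msgs, "strand must be + or -")
  }
  cd <- SummarizedExperiment::colData(object)
  needc <- c("sample_id", "library", "timepoint", "total_mapped_reads")
  if (!all(needc %in% colnames(cd))) {
    msgs <- c(msgs, "colData needs sample_id/library/timepoint/total_mapped_reads")
  } else if (nrow(cd)) {
    if (!all(cd$library %in% c("rminus", "rnaser")))
      msgs <- c(msgs, "library must be rminus or rnaser")
    if (!all(cd$timepoint %in% c("t0", "t24", "t48")))
      msgs <- c(msgs, "timepoint must be t0/t24/t48")
    if (any(cd$total_mapped_reads <= 0))
      msgs <- c(msgs, "total_mapped_reads must be positive")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("CircExperiment", validCircExperiment)

#' Construct a CircExperiment
#'
#' @param candidates data.frame with `contig`, `start`, `end`, `strand` and
#'   optionally `flank_donor`, `flank_acceptor`.
#' @param counts integer matrix, candidates x samples.
#' @param samples data.frame with `sample_id`, `library`, `timepoint`,
#'   `total_mapped_reads`.
#' @return a validated `CircExperiment`.
#' @export
CircExperiment <- function(candidates, counts, samples) {
  candidates <- as.data.frame(candidates)
  if (is.null(candidates$flank_donor)) candidates$flank_donor <- NA_character_
  if (is.null(candidates$flank_acceptor)) candidates$flank_acceptor <- NA_character_
  counts <- as.matrix(counts)
  rownames(counts) <- circId(candidates$contig, candidates$start, candidates$end)
  colnames(counts) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(junction_reads = counts),
    rowData = S4Vectors::DataFrame(candidates),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  )
  new("CircExperiment", se)
}

#' @describeIn CircExperiment-class candidate coordinate table (with circ_id)
#' @param x a CircExperiment
#' @export
circCoords <- function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(circ_id = rownames(x), rd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @describeIn CircExperiment-class junction-read count matrix
#' @export
junctionReads <- function(x) SummarizedExperiment::assay(x, "junction_reads")

#' @describeIn CircExperiment-class sample table
#' @export
sampleInfo <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x), row.names = NULL)
}

setMethod("show", "CircExperiment", function(object) {
  cat(sprintf("CircExperiment: %d circRNA candidate(s) x %d sample(s)\n",
              nrow(object), ncol(object)))
  if (ncol(object)) {
    cd <- SummarizedExperiment::colData(object)
    cat("  grid:", paste(sprintf("%s(%s,%s)", cd$sample_id, cd$library,
                                 cd$timepoint), collapse = " "), "\n")
  }
  if (nrow(object)) {
    jr <- SummarizedExperiment::assay(object, "junction_reads")
    cat(sprintf("  junction reads: total %d, median per circ %.1f\n",
                sum(jr), median(rowSums(jr))))
  }
})
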