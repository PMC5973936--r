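# Readers/writers for the plain-text formats the pipeline touches.
# FASTA/FASTQ go through Biostrings; GTF through rtracklayer; BED6 is
# written directly because internal coordinates are already BED-native
# (0-based half-open).

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased; record order is preserved. Duplicate record
#' names and characters outside ACGTN are errors.
#'
#' @param path FASTA file.
#' @return named character vector, name -> sequence.
#' @export
readFastaDna <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stopf("duplicate FASTA record name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("non-ACGTN characters in record(s): %s",
          paste(nm[bad], collapse = ", "))
  setNames(seqs, nm)
}

#' Write DNA sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
writeFastaDna <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read Ensembl-style GTF gene models
#'
#' GTF is 1-based inclusive; exon `[s, e]` becomes `[s-1, e)` internally.
#' Exons within a transcript are stored sorted by start regardless of
#' strand. A CDS feature under a non-protein_coding biotype, or a feature
#' without `gene_id`, is an error.
#'
#' @param path GTF file.
#' @return list with `genes`, `transcripts`, `exons` tables ready for
#'   [GenomeBundle()].
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]; type <- type[keep]
  if (!length(gr)) stopf("no exon features in %s", path)
  gid <- as.character(md$gene_id)
  tid <- as.character(md$transcript_id)
  if (any(is.na(gid) | gid == ""))
    stopf("feature without gene_id in %s", path)
  if (any(is.na(tid) | tid == ""))
    stopf("exon/CDS feature without transcript_id in %s", path)
  biotype <- if ("gene_biotype" %in% colnames(md))
    as.character(md$gene_biotype) else rep("protein_coding", length(gr))
  biotype[is.na(biotype)] <- "other"
  biotype[!biotype %in% c("protein_coding", "lncRNA", "other")] <- "other"

  df <- data.frame(
    type = type, contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid, transcript_id = tid, biotype = biotype,
    stringsAsFactors = FALSE
  )
  exdf <- df[df$type == "exon", ]
  cdsdf <- df[df$type == "CDS", ]
  genes <- unique(exdf[, c("gene_id", "contig", "strand", "biotype")])
  if (anyDuplicated(genes$gene_id))
    stopf("gene %s has inconsistent contig/strand/biotype",
          genes$gene_id[duplicated(genes$gene_id)][1])
  txs <- unique(exdf[, c("transcript_id", "gene_id")])
  txs$cds_start <- NA_integer_; txs$cds_end <- NA_integer_
  if (nrow(cdsdf)) {
    bt <- setNames(genes$biotype, genes$gene_id)
    badbt <- bt[cdsdf$gene_id] != "protein_coding"
    if (any(badbt))
      stopf("CDS feature under non-protein_coding gene %s",
            cdsdf$gene_id[badbt][1])
    agg <- do.call(rbind, lapply(split(cdsdf, cdsdf$transcript_id), function(d)
      data.frame(transcript_id = d$transcript_id[1],
                 cds_start = min(d$start), cds_end = max(d$end))))
    m <- match(txs$transcript_id, agg$transcript_id)
    txs$cds_start <- agg$cds_start[m]
    txs$cds_end <- agg$cds_end[m]
  }
  exons <- exdf[order(match(exdf$transcript_id, txs$transcript_id), exdf$start),
                c("transcript_id", "start", "end")]
  rownames(exons) <- rownames(txs) <- rownames(genes) <- NULL
  list(genes = genes, transcripts = txs, exons = exons)
}

#' Write a GenomeBundle's annotation as GTF
#'
#' Inverse of [readGeneModels()]: internal `[start, end)` becomes 1-based
#' inclusive `[start+1, end]`.
#'
#' @param bundle a [GenomeBundle-class].
#' @param path output GTF.
#' @export
writeGeneModels <- function(bundle, path) {
  g <- geneTable(bundle); tx <- transcriptTable(bundle); ex <- exonTable(bundle)
  tx2g <- setNames(tx$gene_id, tx$transcript_id)
  ginfo <- g[match(tx2g[ex$transcript_id], g$gene_id), ]
  rows <- data.frame(
    contig = ginfo$contig, start = ex$start, end = ex$end,
    strand = ginfo$strand, type = "exon",
    gene_id = ginfo$gene_id, transcript_id = ex$transcript_id,
    biotype = ginfo$biotype, stringsAsFactors = FALSE
  )
  hasCds <- !is.na(tx$cds_start)
  if (any(hasCds)) {
    ct <- tx[hasCds, ]
    cg <- g[match(ct$gene_id, g$gene_id), ]
    # emit CDS as per-exon pieces clipped to the cds span
    cdsRows <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
      e <- ex[ex$transcript_id == ct$transcript_id[i], ]
      s <- pmax(e$start, ct$cds_start[i]); en <- pmin(e$end, ct$cds_end[i])
      k <- s < en
      if (!any(k)) return(NULL)
      data.frame(contig = cg$contig[i], start = s[k], end = en[k],
                 strand = cg$strand[i], type = "CDS",
                 gene_id = ct$gene_id[i], transcript_id = ct$transcript_id[i],
                 biotype = cg$biotype[i], stringsAsFactors = FALSE)
    }))
    rows <- rbind(rows, cdsRows)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$contig,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$phase <- ifelse(rows$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$source <- "circDynamics"
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  S4Vectors::mcols(gr)$gene_biotype <- rows$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write circRNA candidates as BED6
#'
#' One line per circRNA: contig, start, end, `circ_<contig>_<start>_<end>`,
#' score = total junction reads across samples, strand. Output sorted by
#' (contig, start).
#'
#' @param x a [CircExperiment-class] or a data.frame with `contig`, `start`,
#'   `end`, `strand` and optionally `score`.
#' @param path output BED.
#' @export
writeCircBed <- function(x, path) {
  if (is(x, "CircExperiment")) {
    df <- circCoords(x)
    df$score <- if (ncol(x)) rowSums(junctionReads(x)) else 0L
  } else {
    df <- as.data.frame(x)
    if (is.null(df$score)) df$score <- 0L
  }
  df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
  out <- data.frame(df$contig, as.integer(df$start), as.integer(df$end),
                    circId(df$contig, df$start, df$end),
                    as.integer(df$score), df$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 circRNA catalog
#'
#' @param path BED file (>= 6 columns).
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open, as BED).
#' @export
readCircBed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stopf("malformed BED (need 6 columns): %s", path)
  df <- df[, 1:6]
  names(df) <- c("contig", "start", "end", "name", "score", "strand")
  if (!is.numeric(df$start) || !is.numeric(df$end) ||
      !all(df$strand %in% c("+", "-")))
    stopf("malformed BED: %s", path)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

stripMateSuffix <- function(ids) {
  ids <- sub("\\s.*$", "", ids)
  sub("/[12]$", "", ids)
}

#' Read a pair of matched FASTQ files
#'
#' Mate files must have equal record counts and matching read ids
#' (a trailing `/1` / `/2` or anything after whitespace is ignored).
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ (phred+33).
#' @return list with `ids`, `mate1`, `mate2`, `qual1`, `qual2`
#'   (character vectors in file order).
#' @export
readFastqPair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stopf("unequal record counts: %d vs %d", length(r1), length(r2))
  id1 <- stripMateSuffix(names(r1)); id2 <- stripMateSuffix(names(r2))
  if (!identical(id1, id2)) {
    i <- which(id1 != id2)[1]
    stopf("mismatched read ids at record %d: '%s' vs '%s'", i, id1[i], id2[i])
  }
  list(ids = id1,
       mate1 = unname(as.character(r1)), mate2 = unname(as.character(r2)),
       qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
       qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}

#' Write a pair of FASTQ files
#'
#' @param reads list as returned by [readFastqPair()].
#' @param path1,path2 output files.
#' @export
writeFastqPair <- function(reads, path1, path2) {
  wr <- function(seqs, quals, ids, suffix, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- paste0(ids, suffix)
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(reads$mate1, reads$qual1, reads$ids, "/1", path1)
  wr(reads$mate2, reads$qual2, reads$ids, "/2", path2)
  invisible(c(path1, path2))
}
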