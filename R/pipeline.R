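# Orchestration: run the full simulate -> detect -> quantify -> screen ->
# characterize chain into a run directory with a provenance manifest.
# Each stage writes its outputs to files, so any stage can be re-run from
# the preceding stage's files with the corresponding exported function.

#' Run the full pipeline on a simulated dataset
#'
#' Stages run in dependency order: the synthetic dataset is generated and
#' written (`genome.fa`, `genes.gtf`, FASTQ pairs, truth tables), circRNAs
#' are detected (`circ_calls.tsv`, `circ_calls.bed`, rejection log),
#' expression is quantified (`expression.tsv`), the confidence set is
#' built and screened (`confidence_set.tsv`, `regulation.tsv`), and the
#' set is characterized (`categories.tsv`, `circ_per_gene.tsv`,
#' `host_relation.tsv`). A `manifest.json` records the package version,
#' seed, effective configuration and md5 checksums of every output, so a
#' rerun with the same config is verifiably byte-identical.
#'
#' @param config a [simConfig()].
#' @param outdir run directory (created).
#' @param known_bed optional BED6 catalog of known circRNAs for
#'   annotation.
#' @param anchor_len,max_mm,max_circ_len,min_junction_reads,min_support
#'   detection/screen parameters.
#' @return invisible list with the in-memory stage results (`bundle`,
#'   `truth`, `sim`, `detection`, `expression`, `confidence`, `screen`,
#'   `characterization`).
#' @export
runPipeline <- function(config, outdir, known_bed = NULL,
                        anchor_len = 20L, max_mm = 2L,
                        max_circ_len = 100000L, min_junction_reads = 2L,
                        min_support = 3L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # stage: simulate
  bundle <- buildToyGenome(config)
  truth <- chooseCircTemplates(bundle, config)
  truth <- assignAbundances(truth, config)
  sim <- simulateReads(bundle, truth, config)
  writeSimulatedDataset(bundle, truth, sim, config, outdir)
  # stage: detect
  st <- sampleGrid()
  detection <- detectCircRNAs(bundle, sim$samples, st,
                              anchor_len = anchor_len, max_mm = max_mm,
                              max_circ_len = max_circ_len,
                              min_junction_reads = min_junction_reads)
  circ <- detection$circ
  writeCircBed(circ, file.path(outdir, "circ_calls.bed"))
  calls <- cbind(circCoords(circ), junctionReads(circ))
  write.table(calls, file.path(outdir, "circ_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = rownames(detection$rejections),
                         detection$rejections, row.names = NULL),
              file.path(outdir, "rejections.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # stage: quantify
  index <- buildAlignmentIndex(bundle, k = anchor_len)
  expression <- quantifyExpression(detection, bundle, index,
                                   read_len = config$read_len)
  write.table(expression, file.path(outdir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # stage: screen
  confidence <- buildConfidenceSet(circ, min_reads = min_junction_reads)
  if (!is.null(known_bed)) confidence <- annotateKnown(confidence, known_bed)
  write.table(confidence, file.path(outdir, "confidence_set.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  screenRes <- screenDifferential(confidence, circ,
                                  min_support = min_support)
  write.table(screenRes, file.path(outdir, "regulation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # stage: characterize
  categories <- vapply(seq_len(nrow(confidence)), function(i)
    classifyGenomicOrigin(confidence[i, ], bundle), character(1))
  exCounts <- vapply(seq_len(nrow(confidence)), function(i)
    exonCount(confidence[i, ], bundle), integer(1))
  catDf <- data.frame(circ_id = confidence$circ_id, category = categories,
                      exon_count = exCounts)
  write.table(catDf, file.path(outdir, "categories.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cpg <- circPerGene(confidence, bundle)
  write.table(cpg$per_gene, file.path(outdir, "circ_per_gene.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hostRel <- .hostRelationTable(screenRes, expression, confidence)
  write.table(hostRel, file.path(outdir, "host_relation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  characterization <- list(categories = catDf, circ_per_gene = cpg,
                           host_relation = hostRel)
  # provenance manifest
  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "circDynamics",
    version = as.character(utils::packageVersion("circDynamics")),
    seed = config$seed,
    config = config[setdiff(names(config), "de_spec")],
    de_spec = config$de_spec,
    checksums = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(bundle = bundle, truth = truth, sim = sim,
                 detection = detection, expression = expression,
                 confidence = confidence, screen = screenRes,
                 characterization = characterization))
}

# host-linear relationship table: circ direction from the screen, linear
# direction from the rminus flanking-exon fold changes
.hostRelationTable <- function(screenRes, expression, confidence) {
  lin <- expression[expression$feature_kind == "linear_flank" &
                    grepl("^rminus", expression$sample_id), ]
  if (!nrow(lin) || !nrow(screenRes)) {
    return(data.frame(circ_id = character(0), circ_direction = character(0),
                      linear_direction = character(0),
                      relation = character(0)))
  }
  wide <- stats::reshape(lin[, c("feature_id", "sample_id", "raw")],
                         idvar = "feature_id", timevar = "sample_id",
                         direction = "wide")
  names(wide) <- sub("^raw\\.", "", names(wide))
  m <- match(screenRes$circ_id, wide$feature_id)
  eps <- 1  # one-fragment pseudocount on raw flanking counts
  fc2 <- cbind((wide$rminus_t24[m] + eps) / (wide$rminus_t0[m] + eps),
               (wide$rminus_t48[m] + eps) / (wide$rminus_t0[m] + eps))
  linDir <- rep("unchanged", nrow(screenRes))
  okRows <- which(!is.na(fc2[, 1]) & !is.na(fc2[, 2]))
  if (length(okRows)) linDir[okRows] <- linearDirection(fc2[okRows, , drop = FALSE])
  data.frame(circ_id = screenRes$circ_id,
             circ_direction = screenRes$direction,
             linear_direction = linDir,
             relation = classifyHostRelation(screenRes$direction, linDir))
}
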