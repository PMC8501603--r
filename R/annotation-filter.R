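#' Filter transcripts of an annotation
#'
#' Removes transcripts failing any active criterion and then drops genes left
#' without transcripts. This implements both the RefSeq-Curated style
#' source-class extraction (keep only "BestRefSeq" / "Curated Genomic"
#' records) and the tailored-annotation idea of excluding non-expressed or
#' low-mappability transcripts before differential-expression analysis.
#' The input object is not modified.
#'
#' @param ann a [TxAnnotation-class].
#' @param minMappability keep transcripts with mappability >= this value;
#'   requires `mappability`.
#' @param minAbundanceCpm keep transcripts with CPM >= this value in **every**
#'   sample of `counts`; requires `counts`.
#' @param biotypes character vector of biotype groups to keep
#'   (subset of `"mRNA"`, `"lncRNA"`, `"other"`).
#' @param sourceClasses character vector of source classes to keep (e.g.
#'   `c("BestRefSeq", "Curated Genomic")`).
#' @param mappability a transcript-level [MappabilityResult-class] covering
#'   every transcript of `ann`.
#' @param counts a transcripts-by-samples count matrix (or a
#'   `SummarizedExperiment` with a `counts` assay) whose rownames cover every
#'   transcript of `ann`.
#' @return A new, filtered [TxAnnotation-class].
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "annocomplex")
#' ann <- parseGtf(gtf)
#' filterAnnotation(ann, biotypes = "mRNA")
#' @export
filterAnnotation <- function(ann, minMappability = NULL, minAbundanceCpm = NULL,
                             biotypes = NULL, sourceClasses = NULL,
                             mappability = NULL, counts = NULL) {
  stopifnot(is(ann, "TxAnnotation"))
  td <- txData(ann)
  keep <- rep(TRUE, nrow(td))
  ids <- as.character(td$transcript_id)
  if (!is.null(minMappability)) {
    if (is.null(mappability))
      stop("minMappability requires a MappabilityResult via 'mappability'")
    sc <- mappabilityScores(mappability)
    miss <- setdiff(ids, sc$id)
    if (length(miss))
      stop("mappability lacks transcript(s): ", paste(miss, collapse = ", "))
    keep <- keep & sc$mappability[match(ids, sc$id)] >= minMappability
  }
  if (!is.null(minAbundanceCpm)) {
    if (is.null(counts))
      stop("minAbundanceCpm requires a count matrix via 'counts'")
    if (is(counts, "SummarizedExperiment"))
      counts <- SummarizedExperiment::assay(counts, "counts")
    miss <- setdiff(ids, rownames(counts))
    if (length(miss))
      stop("counts lack transcript(s): ", paste(miss, collapse = ", "))
    cpm <- cpmTransform(counts)
    minCpm <- apply(cpm[match(ids, rownames(cpm)), , drop = FALSE], 1, min)
    keep <- keep & minCpm >= minAbundanceCpm
  }
  if (!is.null(biotypes)) keep <- keep & td$biotype %in% biotypes
  if (!is.null(sourceClasses)) keep <- keep & td$source_class %in% sourceClasses
  TxAnnotation(txExons(ann)[keep], td[keep, , drop = FALSE],
               provenance = ann@provenance)
}
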