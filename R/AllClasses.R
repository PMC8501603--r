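#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList start end strand "strand<-" seqnames width reduce
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet extractAt
NULL

#' Exon-structured gene annotation
#'
#' A `TxAnnotation` holds a set of transcript models: for every transcript an
#' ordered set of exons (as a [GenomicRanges::GRangesList] keyed by transcript
#' id, exons sorted by genomic start), plus a per-transcript table linking each
#' transcript to its gene, biotype group and source class (e.g. "BestRefSeq"
#' for RefSeq-curated records).
#'
#' Invariants enforced by the validity method: at least one exon per
#' transcript; all exons of a transcript on one chromosome and strand;
#' non-overlapping exons within a transcript; unique transcript and gene ids.
#'
#' @slot exons `GRangesList`, one element per transcript, exons sorted by
#'   genomic start.
#' @slot txData `DataFrame` with columns `transcript_id`, `gene_id`,
#'   `biotype` (one of `"mRNA"`, `"lncRNA"`, `"other"`), `source_class`.
#' @slot provenance free-text origin of the annotation (file, release).
#'
#' @seealso [parseGtf()], [filterAnnotation()], [summarizeAnnotation()]
#' @exportClass TxAnnotation
setClass("TxAnnotation",
  representation(
    exons = "GRangesList",
    txData = "DataFrame",
    provenance = "character"
  )
)

setValidity("TxAnnotation", function(object) {
  msg <- character()
  td <- object@txData
  need <- c("transcript_id", "gene_id", "biotype", "source_class")
  if (!all(need %in% colnames(td)))
    return(paste("txData must have columns:", paste(need, collapse = ", ")))
  if (length(object@exons) != nrow(td))
    msg <- c(msg, "exons and txData describe different numbers of transcripts")
  if (anyDuplicated(td$transcript_id))
    msg <- c(msg, "transcript_ids are not unique")
  exNames <- names(object@exons)
  if (is.null(exNames)) exNames <- character(0)
  if (!identical(exNames, as.character(td$transcript_id)))
    msg <- c(msg, "names(exons) must equal txData$transcript_id in order")
  if (length(object@exons)) {
    nex <- lengths(object@exons)
    if (any(nex < 1L)) msg <- c(msg, "every transcript needs >= 1 exon")
    flat <- unlist(object@exons, use.names = FALSE)
    grp <- rep(seq_along(object@exons), nex)
    chrom1 <- !duplicated(grp)
    same_chr <- tapply(as.character(seqnames(flat)), grp,
                       function(x) length(unique(x)) == 1L)
    same_str <- tapply(as.character(strand(flat)), grp,
                       function(x) length(unique(x)) == 1L)
    if (!all(same_chr)) msg <- c(msg, "exons of a transcript must share one chromosome")
    if (!all(same_str)) msg <- c(msg, "exons of a transcript must share one strand")
    if (any(!as.character(strand(flat)) %in% c("+", "-")))
      msg <- c(msg, "exon strand must be '+' or '-'")
    ov <- vapply(seq_along(object@exons), function(i) {
      g <- object@exons[[i]]
      length(g) > 1L && any(start(g)[-1L] <= end(g)[-length(g)])
    }, logical(1))
    if (any(ov))
      msg <- c(msg, paste("overlapping or unsorted exons in transcript(s):",
                          paste(names(object@exons)[ov], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Spliced transcript sequences with a transcript-to-gene map
#'
#' @slot sequences `DNAStringSet` of spliced transcript sequences (uppercase,
#'   alphabet ACGTN), named by transcript id.
#' @slot tx2gene named character vector mapping transcript id to gene id.
#'
#' @seealso [extractTranscriptSequences()], [computeMappability()]
#' @exportClass Transcriptome
setClass("Transcriptome",
  representation(sequences = "DNAStringSet", tx2gene = "character")
)

setValidity("Transcriptome", function(object) {
  msg <- character()
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "sequences must be uniquely named by transcript id")
  if (!identical(names(object@sequences), names(object@tx2gene)))
    msg <- c(msg, "tx2gene must be named by the same transcript ids, in order")
  if (length(object@sequences)) {
    af <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
    # baseOnly 'other' column counts anything outside ACGT; allow N only
    nN <- Biostrings::vcountPattern("N", object@sequences)
    if (any(af[, "other"] != nN))
      msg <- c(msg, "sequences must be over the alphabet {A,C,G,T,N}")
  }
  if (length(msg)) msg else TRUE
})

#' Transcript- or gene-level mappability scores
#'
#' For an entity with sequence S, `n` sliding-window reads are generated from
#' S; each read mapping to N distinct locations contributes 1/N to every
#' location, and `m` is the total fractional mass landing back inside S.
#' Mappability is m/n in (0, 1]; 1 means every read from the entity maps only
#' within it.
#'
#' @slot level `"transcript"` or `"gene"`.
#' @slot windowLength read (window) length in bases.
#' @slot step stride between window starts, in bases.
#' @slot scores `DataFrame` with columns `id`, `n`, `m`, `mappability`,
#'   `short` (TRUE when the entity was shorter than the window and emitted a
#'   single full-length read).
#'
#' @seealso [computeMappability()], [bruteForceMappability()]
#' @exportClass MappabilityResult
setClass("MappabilityResult",
  representation(
    level = "character",
    windowLength = "integer",
    step = "integer",
    scores = "DataFrame"
  )
)

setValidity("MappabilityResult", function(object) {
  msg <- character()
  if (!object@level %in% c("transcript", "gene"))
    msg <- c(msg, "level must be 'transcript' or 'gene'")
  sc <- object@scores
  need <- c("id", "n", "m", "mappability", "short")
  if (!all(need %in% colnames(sc)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  if (nrow(sc)) {
    if (any(sc$n <= 0)) msg <- c(msg, "n must be positive")
    if (any(sc$m < 0 | sc$m > sc$n + 1e-9)) msg <- c(msg, "need 0 <= m <= n")
    if (any(abs(sc$mappability - sc$m / sc$n) > 1e-9))
      msg <- c(msg, "mappability must equal m/n")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TxAnnotation", function(object) {
  cat("TxAnnotation with", nTranscripts(object), "transcripts in",
      nGenes(object), "genes\n")
  if (nzchar(object@provenance)) cat("provenance:", object@provenance, "\n")
  bt <- table(object@txData$biotype)
  if (length(bt))
    cat("biotypes:", paste(names(bt), as.integer(bt), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Transcriptome", function(object) {
  cat("Transcriptome with", length(object@sequences), "transcripts (",
      length(unique(object@tx2gene)), "genes ), total length",
      sum(Biostrings::width(object@sequences)), "nt\n")
})

setMethod("show", "MappabilityResult", function(object) {
  sc <- object@scores
  cat(sprintf("MappabilityResult (%s level, L=%d, step=%d): %d entities\n",
              object@level, object@windowLength, object@step, nrow(sc)))
  if (nrow(sc))
    cat(sprintf("  mean mappability %.4f; %d short (< L) entities\n",
                mean(sc$mappability), sum(sc$short)))
})

#' @describeIn TxAnnotation number of genes
#' @param object,x a `TxAnnotation`
#' @export
nGenes <- function(object) length(unique(object@txData$gene_id))

#' @describeIn TxAnnotation number of transcripts
#' @export
nTranscripts <- function(object) nrow(object@txData)

#' @describeIn TxAnnotation per-transcript metadata (`DataFrame`)
#' @export
txData <- function(object) object@txData

#' @describeIn TxAnnotation exons as a `GRangesList` keyed by transcript id
#' @export
txExons <- function(object) object@exons

#' @describeIn TxAnnotation transcript ids
#' @export
txIds <- function(object) as.character(object@txData$transcript_id)

#' @describeIn TxAnnotation gene ids (unique, in order of first appearance)
#' @export
geneIds <- function(object) unique(as.character(object@txData$gene_id))

#' @describeIn Transcriptome spliced sequences (`DNAStringSet`)
#' @export
txSequences <- function(object) object@sequences

#' @describeIn Transcriptome named transcript-to-gene character map
#' @export
tx2gene <- function(object) object@tx2gene

#' @describeIn MappabilityResult per-entity scores as a plain `data.frame`
#' @export
mappabilityScores <- function(object) as.data.frame(object@scores)

#' Construct a TxAnnotation
#'
#' Low-level constructor; most users obtain annotations from [parseGtf()],
#' [parseGff3()] or [makeFixture()].
#'
#' @param exons `GRangesList` of exons per transcript (exons may be unsorted;
#'   they are sorted by genomic start and deduplicated by
#'   (chrom,start,end,strand) here).
#' @param txData `DataFrame`/`data.frame` with `transcript_id`, `gene_id` and
#'   optionally `biotype`, `source_class`.
#' @param provenance free-text origin string.
#' @return A validated [TxAnnotation-class] object.
#' @export
TxAnnotation <- function(exons, txData, provenance = "") {
  txData <- as(as.data.frame(txData), "DataFrame")
  if (is.null(txData$biotype)) txData$biotype <- "other"
  if (is.null(txData$source_class)) txData$source_class <- ""
  txData$transcript_id <- as.character(txData$transcript_id)
  txData$gene_id <- as.character(txData$gene_id)
  # an unnamed empty GRangesList cannot be subset by character(0)
  exons <- if (nrow(txData)) exons[as.character(txData$transcript_id)]
           else GRangesList()
  exons <- GRangesList(lapply(exons, function(g) {
    g <- g[!duplicated(paste(seqnames(g), start(g), end(g), strand(g)))]
    g[order(start(g))]
  }), compress = TRUE)
  new("TxAnnotation", exons = exons, txData = txData,
      provenance = as.character(provenance))
}

#' Construct a Transcriptome
#'
#' @param sequences named `DNAStringSet` (or named character vector) of
#'   spliced transcript sequences.
#' @param tx2gene named character vector, transcript id to gene id; must cover
#'   every sequence.
#' @return A validated [Transcriptome-class] object.
#' @export
Transcriptome <- function(sequences, tx2gene) {
  if (!is(sequences, "DNAStringSet")) sequences <- DNAStringSet(sequences)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by transcript id")
  missing <- setdiff(ids, names(tx2gene))
  if (length(missing))
    stop("tx2gene lacks entries for: ", paste(missing, collapse = ", "))
  new("Transcriptome", sequences = Biostrings::DNAStringSet(toupper(sequences)),
      tx2gene = tx2gene[ids])
}
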