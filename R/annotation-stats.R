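#' Annotation complexity summary
#'
#' Computes the basic complexity statistics used to compare annotation
#' catalogues: gene and transcript counts, the fraction of genome bases
#' covered by at least one exon (strand-insensitive union of exon intervals
#' over the summed chromosome lengths), the mean number of transcripts per
#' gene, and the mean per-gene percentage of unique exons (see
#' [pctUniqueExons()]).
#'
#' @param ann a [TxAnnotation-class].
#' @param genomeLengths named numeric vector of chromosome lengths covering
#'   every exon chromosome (full sequence lengths, N bases included).
#' @return A one-row `data.frame` with columns `n_genes`, `n_transcripts`,
#'   `exon_genomic_coverage` (fraction), `avg_tx_per_gene`,
#'   `avg_pct_unique_exons`.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "annocomplex")
#' ann <- parseGtf(gtf)
#' summarizeAnnotation(ann, c(chr1 = 1000))
#' @export
summarizeAnnotation <- function(ann, genomeLengths) {
  stopifnot(is(ann, "TxAnnotation"))
  flat <- unlist(txExons(ann), use.names = FALSE)
  bad <- setdiff(unique(as.character(seqnames(flat))), names(genomeLengths))
  if (length(bad))
    stop("no genome length supplied for chromosome(s): ",
         paste(bad, collapse = ", "))
  ng <- nGenes(ann)
  nt <- nTranscripts(ann)
  if (length(flat)) {
    strand(flat) <- "*"
    covered <- sum(width(reduce(flat)))
  } else covered <- 0
  data.frame(
    n_genes = ng,
    n_transcripts = nt,
    exon_genomic_coverage = covered / sum(genomeLengths),
    avg_tx_per_gene = if (ng > 0) nt / ng else NA_real_,
    avg_pct_unique_exons = if (ng > 0) mean(pctUniqueExons(ann)) else NA_real_
  )
}

#' Per-gene percentage of unique exons
#'
#' For each gene, 100 x (number of distinct (chrom,start,end,strand) exon
#' intervals across the gene's transcripts) / (total exon records across the
#' gene's transcripts). A gene whose isoforms share no exon scores 100; heavy
#' exon sharing between isoforms drives the percentage down, making this a
#' within-gene redundancy measure.
#'
#' @param ann a [TxAnnotation-class].
#' @param genes optional character vector of gene ids (default: all genes).
#' @return Named numeric vector of percentages in (0, 100].
#' @export
pctUniqueExons <- function(ann, genes = NULL) {
  stopifnot(is(ann, "TxAnnotation"))
  td <- txData(ann)
  if (is.null(genes)) genes <- unique(as.character(td$gene_id))
  flat <- unlist(txExons(ann), use.names = FALSE)
  gOf <- rep(as.character(td$gene_id), lengths(txExons(ann)))
  key <- paste(seqnames(flat), start(flat), end(flat), strand(flat))
  vapply(genes, function(g) {
    k <- key[gOf == g]
    if (!length(k)) stop("gene has no exon records: ", g)
    100 * length(unique(k)) / length(k)
  }, numeric(1))
}
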