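#' @importFrom rtracklayer import
NULL

# Collapse the zoo of annotation biotype labels into the three groups used
# throughout the package: mRNA, lncRNA, other.
.biotypeGroup <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("other", length(x))
  out[x %in% c("protein_coding", "mrna", "protein-coding")] <- "mRNA"
  out[x %in% c("lncrna", "lincrna", "lnc_rna", "antisense",
               "antisense_rna", "processed_transcript",
               "sense_intronic", "sense_overlapping")] <- "lncRNA"
  out[is.na(x) | !nzchar(x)] <- "other"
  out
}

.firstNonNull <- function(df, keys) {
  for (k in keys) if (!is.null(df[[k]])) return(df[[k]])
  rep(NA_character_, nrow(df))
}

# TRUE when the file holds no feature lines at all (empty or comments only);
# rtracklayer cannot sniff such files, so the parsers short-circuit them.
.noFeatureLines <- function(path) {
  probe <- readLines(path, n = 1000L, warn = FALSE)
  length(probe) < 1000L && !any(nzchar(probe) & !startsWith(probe, "#"))
}

.emptyAnnotation <- function(provenance) {
  TxAnnotation(
    GRangesList(), DataFrame(transcript_id = character(),
                             gene_id = character(),
                             biotype = character(),
                             source_class = character()),
    provenance = provenance)
}

#' Parse a GTF gene annotation
#'
#' Reads exon features from a GTF file and assembles transcript models grouped
#' into genes. Non-exon feature lines (gene, transcript, CDS, ...) are
#' ignored; duplicated exon lines for a transcript are deduplicated by
#' (chrom, start, end, strand). A file with no exon features yields an empty
#' annotation with a warning.
#'
#' The transcript biotype is taken from the first available of
#' `transcript_biotype`, `transcript_type`, `gene_biotype`, `gene_type`,
#' `biotype` attributes and collapsed into `{mRNA, lncRNA, other}`; the GTF
#' source column becomes `source_class` (RefSeq uses it for "BestRefSeq" /
#' "Curated Genomic").
#'
#' @param path path to a GTF file.
#' @return A [TxAnnotation-class].
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "annocomplex")
#' ann <- parseGtf(gtf)
#' ann
#' @export
parseGtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (.noFeatureLines(path)) {
    warning("no exon features found; returning an empty annotation")
    return(.emptyAnnotation(paste0("GTF:", path)))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  .assembleAnnotation(gr, provenance = paste0("GTF:", path),
                      txIdCol = "transcript_id", geneIdCol = "gene_id")
}

.assembleAnnotation <- function(gr, provenance, txIdCol, geneIdCol) {
  m <- mcols(gr)
  ex <- gr[!is.na(m$type) & as.character(m$type) == "exon"]
  if (!length(ex)) {
    warning("no exon features found; returning an empty annotation")
    return(TxAnnotation(
      GRangesList(), DataFrame(transcript_id = character(),
                               gene_id = character(),
                               biotype = character(),
                               source_class = character()),
      provenance = provenance))
  }
  me <- mcols(ex)
  txid <- as.character(me[[txIdCol]])
  gid <- as.character(me[[geneIdCol]])
  if (anyNA(txid) || anyNA(gid))
    stop("exon feature(s) missing ", txIdCol, "/", geneIdCol, " attributes")
  bt <- .biotypeGroup(.firstNonNull(me, c("transcript_biotype",
                                          "transcript_type", "gene_biotype",
                                          "gene_type", "biotype")))
  src <- as.character(me$source)
  src[is.na(src)] <- ""
  ord <- order(match(txid, unique(txid)))
  ex <- ex[ord]; txid <- txid[ord]; gid <- gid[ord]
  bt <- bt[ord]; src <- src[ord]
  first <- !duplicated(txid)
  td <- DataFrame(transcript_id = txid[first], gene_id = gid[first],
                  biotype = bt[first], source_class = src[first])
  mcols(ex) <- NULL
  exl <- S4Vectors::split(ex, factor(txid, levels = td$transcript_id))
  TxAnnotation(exl, td, provenance = provenance)
}

#' Parse a GFF3 gene annotation (RefSeq style)
#'
#' Minimal GFF3 reader: any feature that has exon children (via the exons'
#' `Parent` attribute matching the feature's `ID`) is treated as a transcript,
#' regardless of its type (mRNA, lnc_RNA, tRNA, ...). The transcript's own
#' `Parent` (usually a gene feature) supplies the gene id; transcripts without
#' a parent become single-transcript genes under their own id. The GFF3
#' source column is kept as `source_class`, which for RefSeq distinguishes
#' "BestRefSeq" and "Curated Genomic" records.
#'
#' @param path path to a GFF3 file.
#' @return A [TxAnnotation-class].
#' @export
parseGff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (.noFeatureLines(path)) {
    warning("no exon features found; returning an empty annotation")
    return(.emptyAnnotation(paste0("GFF3:", path)))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  m <- mcols(gr)
  ex <- gr[as.character(m$type) == "exon"]
  if (!length(ex)) {
    warning("no exon features found; returning an empty annotation")
    return(TxAnnotation(
      GRangesList(), DataFrame(transcript_id = character(),
                               gene_id = character(),
                               biotype = character(),
                               source_class = character()),
      provenance = paste0("GFF3:", path)))
  }
  parent <- as.character(S4Vectors::unstrsplit(mcols(ex)$Parent, ","))
  if (any(grepl(",", parent)))
    stop("exons with multiple Parent values are not supported")
  feats <- gr[!is.na(mcols(gr)$ID)]
  fid <- as.character(mcols(feats)$ID)
  idx <- match(parent, fid)
  geneOf <- rep(NA_character_, length(parent))
  btOf <- rep(NA_character_, length(parent))
  hit <- !is.na(idx)
  if (any(hit)) {
    tparent <- mcols(feats)$Parent[idx[hit]]
    gp <- as.character(S4Vectors::unstrsplit(tparent, ","))
    gp[!nzchar(gp)] <- parent[hit][!nzchar(gp)]
    geneOf[hit] <- gp
    btOf[hit] <- as.character(mcols(feats)$type[idx[hit]])
  }
  geneOf[!hit] <- parent[!hit]
  txid <- parent
  src <- as.character(mcols(ex)$source)
  src[is.na(src)] <- ""
  bt <- .biotypeGroup(ifelse(is.na(btOf), "other",
                             ifelse(btOf %in% c("mRNA"), "mRNA",
                                    ifelse(btOf %in% c("lnc_RNA", "lncRNA"),
                                           "lncRNA", "other"))))
  ord <- order(match(txid, unique(txid)))
  ex <- ex[ord]; txid <- txid[ord]
  geneOf <- geneOf[ord]; bt <- bt[ord]; src <- src[ord]
  first <- !duplicated(txid)
  td <- DataFrame(transcript_id = txid[first], gene_id = geneOf[first],
                  biotype = bt[first], source_class = src[first])
  mcols(ex) <- NULL
  exl <- S4Vectors::split(ex, factor(txid, levels = td$transcript_id))
  TxAnnotation(exl, td, provenance = paste0("GFF3:", path))
}

#' Write an annotation as GTF
#'
#' Emits one `exon` feature line per exon with `gene_id`, `transcript_id` and
#' `transcript_biotype` attributes; the `source_class` fills the GTF source
#' column. [parseGtf()] of the written file reproduces exon coordinates,
#' strands and ids exactly (round-trip identity).
#'
#' @param ann a [TxAnnotation-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(ann, path) {
  stopifnot(is(ann, "TxAnnotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#!annocomplex GTF export", con)
  td <- txData(ann)
  if (!nrow(td)) return(invisible(path))
  nex <- lengths(txExons(ann))
  flat <- unlist(txExons(ann), use.names = FALSE)
  i <- rep(seq_len(nrow(td)), nex)
  src <- ifelse(nzchar(td$source_class[i]), td$source_class[i], "annocomplex")
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    as.character(seqnames(flat)), src, start(flat), end(flat),
    as.character(strand(flat)), td$gene_id[i], td$transcript_id[i],
    td$biotype[i])
  writeLines(lines, con)
  invisible(path)
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates each transcript's exon subsequences in genomic order and
#' reverse-complements minus-strand transcripts, yielding the transcriptome
#' implied by the annotation. Output is uppercase.
#'
#' @param ann a [TxAnnotation-class].
#' @param genome a genome as a named `DNAStringSet`, or a path to a FASTA
#'   file (names are truncated at the first whitespace).
#' @return A [Transcriptome-class].
#' @export
extractTranscriptSequences <- function(ann, genome) {
  stopifnot(is(ann, "TxAnnotation"))
  if (is.character(genome)) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  td <- txData(ann)
  if (!nrow(td))
    return(Transcriptome(DNAStringSet(), structure(character(), names = character())))
  flat <- unlist(txExons(ann), use.names = FALSE)
  nex <- lengths(txExons(ann))
  txOf <- rep(td$transcript_id, nex)
  chr <- as.character(seqnames(flat))
  bad <- setdiff(unique(chr), names(genome))
  if (length(bad))
    stop("chromosome(s) absent from genome: ", paste(bad, collapse = ", "))
  over <- end(flat) > Biostrings::width(genome)[match(chr, names(genome))] |
    start(flat) < 1L
  if (any(over))
    stop("exon outside chromosome bounds in transcript(s): ",
         paste(unique(txOf[over]), collapse = ", "))
  pieces <- character(length(flat))
  for (ch in unique(chr)) {
    sel <- chr == ch
    pieces[sel] <- as.character(extractAt(genome[[ch]],
                                          IRanges(start(flat)[sel], end(flat)[sel])))
  }
  seqs <- S4Vectors::unstrsplit(split(pieces, factor(txOf, levels = td$transcript_id)), "")
  seqs <- DNAStringSet(toupper(seqs))
  minus <- vapply(txExons(ann), function(g) as.character(strand(g))[1] == "-",
                  logical(1))
  if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
  Transcriptome(seqs, structure(as.character(td$gene_id),
                                names = as.character(td$transcript_id)))
}
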