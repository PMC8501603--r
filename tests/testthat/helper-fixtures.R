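suppressMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# random nucleotide string
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# reverse complement via plain string ops (independent of Biostrings)
rcStr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# a random transcriptome with engineered redundancy: some transcripts
# duplicated verbatim, some sharing a planted common substring
randomTxome <- function(nTx = 20, lenRange = c(40, 120), dupPairs = 2,
                        sharedCore = 0) {
  lens <- sample(seq(lenRange[1], lenRange[2]), nTx, replace = TRUE)
  seqs <- vapply(lens, randSeq, character(1))
  names(seqs) <- paste0("t", seq_len(nTx))
  if (dupPairs > 0) for (k in seq_len(dupPairs)) {
    i <- 2 * k - 1; j <- 2 * k
    seqs[j] <- seqs[i]
  }
  if (sharedCore > 0) {
    core <- randSeq(sharedCore)
    pick <- sample(seq_len(nTx), min(3, nTx))
    for (i in pick) {
      s <- seqs[i]
      at <- sample.int(max(nchar(s) - sharedCore, 1), 1)
      substr(s, at, at + sharedCore - 1) <- core
      seqs[i] <- s
    }
  }
  Transcriptome(seqs, structure(paste0("g", seq_len(nTx)),
                                names = names(seqs)))
}

# write a toy GTF from a data.frame of exon rows
writeToyGtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
    rows$chrom, ifelse(is.na(rows$source), "toy", rows$source),
    rows$start, rows$end, rows$strand, rows$gene_id, rows$transcript_id,
    ifelse(is.na(rows$biotype), "",
           sprintf(' transcript_biotype "%s";', rows$biotype)))
  writeLines(lines, path)
  path
}

toyExonRow <- function(chrom, start, end, strand, gene, tx,
                       biotype = NA, source = NA) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             gene_id = gene, transcript_id = tx, biotype = biotype,
             source = source, stringsAsFactors = FALSE)
}

# alignment table builder for quantification tests
mkAln <- function(hits, allReads = unique(hits$read_id)) {
  out <- as.data.frame(hits)
  attr(out, "reads") <- allReads
  out
}

# brute-force multinomial likelihood maximisation on the 2-simplex for the
# 3-transcript EM oracle: nested grid refinement
gridSearchAlpha3 <- function(classes, d, levels = 4, width = 1, center = NULL) {
  if (is.null(center)) center <- c(1, 1, 1) / 3
  best <- center; bestLL <- -Inf
  for (lev in seq_len(levels)) {
    gr <- seq(-width / 2, width / 2, length.out = 21)
    for (a1 in center[1] + gr) for (a2 in center[2] + gr) {
      a3 <- 1 - a1 - a2
      if (a1 <= 0 || a2 <= 0 || a3 <= 0) next
      al <- c(a1, a2, a3)
      ll <- sum(d * log(vapply(classes, function(m) sum(al[m]), numeric(1))))
      if (ll > bestLL) { bestLL <- ll; best <- al }
    }
    center <- best
    width <- width / 10
  }
  best
}
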