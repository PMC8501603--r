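#' Synthetic genome + annotation fixture with controlled redundancy
#'
#' Generates a small multi-chromosome genome of i.i.d.-uniform ACGT bases and
#' lays out non-overlapping gene loci on it. Complexity is controlled along
#' the two axes that drive multi-mapping in real annotations:
#' \itemize{
#'   \item \emph{exon sharing between isoforms}: within a gene, every isoform
#'     after the first reuses a per-gene fraction of the first isoform's
#'     exons (identical genomic intervals) and gets fresh exons for the rest,
#'     so sliding-window reads from shared exons multi-map between isoforms;
#'   \item \emph{gene duplication}: a fraction of genes is copied verbatim
#'     (sequence and exon structure) to a new locus under a new gene id, so
#'     every read from a duplicated transcript maps to exactly two places and
#'     its transcript mappability is 0.5 by construction.
#' }
#' The manifest records, per transcript, its share level, duplication partner
#' and sequence-sharing partners, giving analytically known anchors for the
#' mappability statistic without any external aligner. Deterministic given
#' `seed`.
#'
#' @param nGenes number of (non-duplicate) genes.
#' @param nChroms,chromLength chromosomes and their common length in bases.
#' @param maxIsoforms isoforms per gene are drawn uniformly from
#'   `1:maxIsoforms`.
#' @param exonsPerTx range (length-2) of exons per transcript.
#' @param exonLength,intronLength ranges of exon and intron lengths in bases.
#' @param shareLevels per-gene exon-share fraction is drawn uniformly from
#'   this set.
#' @param dupGeneFraction fraction of genes duplicated verbatim elsewhere.
#' @param interGeneGap range of gaps between consecutive loci.
#' @param seed integer seed.
#' @return A list with `genome` (named `DNAStringSet`), `annotation`
#'   ([TxAnnotation-class]) and `manifest` (`data.frame` with
#'   `transcript_id`, `gene_id`, `share_level`, `n_exons`, `is_duplicate`,
#'   `dup_partner`, `partners`).
#' @examples
#' fx <- makeFixture(nGenes = 5, chromLength = 20000, seed = 7)
#' fx$annotation
#' @export
makeFixture <- function(nGenes = 200L, nChroms = 4L, chromLength = 250000L,
                        maxIsoforms = 3L, exonsPerTx = c(2L, 6L),
                        exonLength = c(100L, 300L),
                        intronLength = c(50L, 200L),
                        shareLevels = c(0, 0.25, 0.5, 0.75),
                        dupGeneFraction = 0.15,
                        interGeneGap = c(100L, 500L), seed = 1L) {
  stopifnot(nGenes >= 1, nChroms >= 1, dupGeneFraction >= 0,
            dupGeneFraction <= 1, all(shareLevels >= 0 & shareLevels <= 1))
  set.seed(seed)
  chroms <- paste0("chr", seq_len(nChroms))
  genome <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), chromLength, replace = TRUE),
          collapse = ""), character(1))

  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1L)

  # local (1-based) exon layouts per gene, before placement
  geneLayouts <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    nIso <- sample.int(maxIsoforms, 1L)
    share <- if (length(shareLevels) == 1L) shareLevels else
      sample(shareLevels, 1L)
    strand <- sample(c("+", "-"), 1L)
    n1 <- rint(exonsPerTx)
    pos <- 1L
    iso1 <- matrix(0L, n1, 2L)
    for (e in seq_len(n1)) {
      len <- rint(exonLength)
      iso1[e, ] <- c(pos, pos + len - 1L)
      pos <- pos + len + rint(intronLength)
    }
    isoforms <- list(iso1)
    if (nIso > 1L) for (k in 2:nIso) {
      nShared <- round(share * n1)
      nNew <- max(n1 - nShared, if (nShared == 0L) 1L else 0L)
      ex <- iso1[seq_len(nShared), , drop = FALSE]
      for (e in seq_len(nNew)) {
        len <- rint(exonLength)
        ex <- rbind(ex, c(pos, pos + len - 1L))
        pos <- pos + len + rint(intronLength)
      }
      isoforms[[k]] <- ex
    }
    span <- max(vapply(isoforms, function(x) max(x[, 2]), numeric(1)))
    geneLayouts[[g]] <- list(isoforms = isoforms, span = span,
                             share = share, strand = strand)
  }

  nDup <- round(dupGeneFraction * nGenes)
  dupOf <- if (nDup > 0) sample.int(nGenes, nDup) else integer(0)

  # greedy placement on the chromosome with the most remaining room
  cursor <- structure(rep(1L, nChroms), names = chroms)
  place <- function(span, gap) {
    room <- chromLength - cursor - gap
    ch <- unname(which.max(room))
    if (room[ch] < span)
      stop("genome too short for the requested genes (capacity error)")
    s <- unname(cursor[ch] + gap)
    cursor[ch] <<- s + span
    c(chrom = ch, start = s)
  }

  exRows <- list()
  manifest <- list()
  addGene <- function(gid, layout, at, dupPartnerGene = NA_character_) {
    chrom <- chroms[at[["chrom"]]]
    off <- at[["start"]] - 1L
    isoforms <- layout$isoforms
    hasShare <- length(isoforms) > 1L &&
      round(layout$share * nrow(isoforms[[1]])) > 0L
    txids <- paste0(gid, ".t", seq_along(isoforms))
    for (k in seq_along(isoforms)) {
      ex <- isoforms[[k]]
      exRows[[length(exRows) + 1L]] <<- data.frame(
        chrom = chrom, start = ex[, 1] + off, end = ex[, 2] + off,
        strand = layout$strand, transcript_id = txids[k], gene_id = gid,
        stringsAsFactors = FALSE)
      partners <- if (hasShare) setdiff(txids, txids[k]) else character(0)
      dupTx <- if (!is.na(dupPartnerGene))
        paste0(dupPartnerGene, ".t", k) else NA_character_
      if (!is.na(dupTx)) partners <- c(partners, dupTx)
      manifest[[length(manifest) + 1L]] <<- data.frame(
        transcript_id = txids[k], gene_id = gid, share_level = layout$share,
        n_exons = nrow(ex), is_duplicate = grepl("_dup$", gid),
        dup_partner = dupTx,
        partners = paste(partners, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    invisible(c(at, span = layout$span))
  }

  placements <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    at <- place(geneLayouts[[g]]$span, rint(interGeneGap))
    placements[[g]] <- at
    dupG <- if (g %in% dupOf) paste0("gene", g, "_dup") else NA_character_
    addGene(paste0("gene", g), geneLayouts[[g]], at, dupPartnerGene = dupG)
  }
  for (g in dupOf) {
    at <- place(geneLayouts[[g]]$span, rint(interGeneGap))
    srcAt <- placements[[g]]
    srcCh <- chroms[srcAt[["chrom"]]]
    dstCh <- chroms[at[["chrom"]]]
    span <- geneLayouts[[g]]$span
    piece <- substring(genome[[srcCh]], srcAt[["start"]],
                       srcAt[["start"]] + span - 1L)
    substr(genome[[dstCh]], at[["start"]], at[["start"]] + span - 1L) <- piece
    addGene(paste0("gene", g, "_dup"), geneLayouts[[g]], at,
            dupPartnerGene = paste0("gene", g))
  }

  exTab <- do.call(rbind, exRows)
  gr <- GRanges(exTab$chrom, IRanges(exTab$start, exTab$end),
                strand = exTab$strand)
  exl <- S4Vectors::split(gr, factor(exTab$transcript_id,
                                     levels = unique(exTab$transcript_id)))
  first <- !duplicated(exTab$transcript_id)
  td <- DataFrame(transcript_id = exTab$transcript_id[first],
                  gene_id = exTab$gene_id[first],
                  biotype = "mRNA", source_class = "synthetic")
  ann <- TxAnnotation(exl, td,
                      provenance = sprintf("synthetic fixture (seed %d)", seed))
  list(genome = DNAStringSet(genome),
       annotation = ann,
       manifest = do.call(rbind, manifest))
}

#' Mappability-driven count corruption model
#'
#' Emulates read misassignment between transcripts sharing sequence: returns
#' a function that moves a `(1 - mappability) * strength` share of each
#' transcript's counts to its sequence-sharing partners (from the fixture
#' manifest), split equally among them. Column totals are preserved, so the
#' corruption only redistributes counts within samples. Transcripts with
#' mappability 1 or no partners are untouched.
#'
#' @param map transcript-level [MappabilityResult-class].
#' @param strength corruption strength in `[0, 1]`.
#' @param manifest fixture manifest from [makeFixture()].
#' @return A function taking and returning a transcripts x samples count
#'   matrix (real-valued after corruption).
#' @export
makeNoiseModel <- function(map, strength, manifest) {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  sc <- mappabilityScores(map)
  mapv <- structure(sc$mappability, names = sc$id)
  miss <- setdiff(manifest$transcript_id, names(mapv))
  if (length(miss))
    stop("mappability missing for transcript(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  partners <- strsplit(manifest$partners, ";", fixed = TRUE)
  partners <- lapply(partners, function(p) p[nzchar(p)])
  names(partners) <- manifest$transcript_id
  function(counts) {
    counts <- as.matrix(counts)
    ids <- rownames(counts)
    out <- counts
    for (t in ids) {
      p <- intersect(partners[[t]], ids)
      if (!length(p)) next
      f <- (1 - mapv[[t]]) * strength
      if (f <= 0) next
      moved <- counts[t, ] * f
      out[t, ] <- out[t, ] - moved
      for (q in p) out[q, ] <- out[q, ] + moved / length(p)
    }
    out
  }
}
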