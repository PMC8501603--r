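#' @import data.table
#' @importFrom Biostrings vcountPattern width
NULL

# All length-L substrings of every transcript with length >= L, as a
# data.table(tx, off, kmer); off is 1-based. Transcripts shorter than L are
# absent (handled separately by the callers).
.allWindows <- function(txome, L) {
  seqs <- as.character(txSequences(txome))
  lens <- nchar(seqs)
  keep <- lens >= L
  if (!any(keep))
    return(data.table(tx = character(), off = integer(), kmer = character()))
  seqs <- seqs[keep]; lens <- lens[keep]
  nWin <- lens - L + 1L
  txv <- rep(names(seqs), nWin)
  offv <- unlist(lapply(nWin, seq_len), use.names = FALSE)
  kmer <- substring(rep(seqs, nWin), offv, offv + L - 1L)
  data.table(tx = txv, off = offv, kmer = kmer)
}

#' Sliding-window reads over a transcriptome
#'
#' Generates the read set the mappability statistic is defined on: for a
#' transcript of length `l >= L`, reads of length `L` start at offsets
#' 1, 1+step, 1+2*step, ... up to `l - L + 1` (so `floor((l-L)/step) + 1`
#' reads; `l - L + 1` reads when `step = 1`). Transcripts shorter than `L`
#' emit exactly one full-length read so every transcript is scored.
#'
#' @param txome a [Transcriptome-class].
#' @param L window (read) length in bases; typical values 50, 100, 150.
#' @param step stride between window starts (default 1).
#' @return A `data.frame` with columns `origin_tx`, `origin_offset` (1-based),
#'   `length`, `seq`.
#' @export
generateWindows <- function(txome, L, step = 1L) {
  stopifnot(L > 0, step > 0)
  L <- as.integer(L); step <- as.integer(step)
  seqs <- as.character(txSequences(txome))
  lens <- nchar(seqs)
  if (!length(seqs))
    return(data.frame(origin_tx = character(), origin_offset = integer(),
                      length = integer(), seq = character()))
  nWin <- ifelse(lens >= L, (lens - L) %/% step + 1L, 1L)
  txv <- rep(names(seqs), nWin)
  offv <- unlist(lapply(nWin, function(k) seq(1L, by = step, length.out = k)),
                 use.names = FALSE)
  lenv <- rep(pmin(lens, L), nWin)
  data.frame(origin_tx = txv, origin_offset = offv, length = lenv,
             seq = substring(rep(seqs, nWin), offv, offv + lenv - 1L),
             stringsAsFactors = FALSE)
}

#' Exact-substring location index over a transcriptome
#'
#' A hash-style index of every length-`L` substring of the transcriptome,
#' answering complete occurrence queries (all `(transcript, offset)` pairs)
#' for any query of length `<= L`. Queries of length exactly `L` are resolved
#' by lookup; shorter queries fall back to a full scan. Queries containing
#' `N` never match. This replaces an external read aligner for the
#' mappability computation: every window is an exact substring of the
#' transcriptome, so exact all-occurrence search gives a well-defined
#' multi-mapping count N.
#'
#' @param txome a [Transcriptome-class].
#' @param L index word length.
#' @return An opaque index object for [queryLocations()].
#' @export
buildLocationIndex <- function(txome, L) {
  stopifnot(L > 0)
  L <- as.integer(L)
  dt <- .allWindows(txome, L)
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  setkey(dt, kmer)
  structure(list(table = dt, L = L, txome = txome), class = "LocationIndex")
}

#' Query all exact occurrences of a sequence
#'
#' @param index an index from [buildLocationIndex()].
#' @param query a single nucleotide string of length `<= L`.
#' @return `data.frame` with columns `tx`, `off` (1-based start), one row per
#'   occurrence; zero rows when the query is absent or contains `N`.
#' @export
queryLocations <- function(index, query) {
  stopifnot(inherits(index, "LocationIndex"), length(query) == 1L)
  if (nchar(query) > index$L)
    stop("query longer than index word length")
  if (grepl("N", query, fixed = TRUE))
    return(data.frame(tx = character(), off = integer()))
  if (nchar(query) == index$L) {
    hit <- index$table[.(query), nomatch = NULL]
    return(data.frame(tx = hit$tx, off = hit$off))
  }
  seqs <- txSequences(index$txome)
  ml <- Biostrings::vmatchPattern(query, seqs)
  n <- lengths(ml)
  data.frame(tx = rep(names(seqs), n),
             off = unlist(lapply(ml, IRanges::start), use.names = FALSE))
}

# Occurrence counts c[kmer, tx] over every length-L substring of the
# transcriptome (forward orientation), N-containing kmers dropped.
.occCounts <- function(seqs, L) {
  dt <- .allWindows(Transcriptome(DNAStringSet(seqs),
                                  structure(names(seqs), names = names(seqs))), L)
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  dt[, .(c = .N), by = .(kmer, tx)]
}

#' Transcript or gene mappability by fractional read assignment
#'
#' For every entity (transcript, or gene = union of its transcripts), `n`
#' sliding-window reads are generated from its sequence(s); each read mapping
#' to `N >= 1` distinct `(transcript, offset)` locations contributes `1/N` to
#' every location, and the entity's `m` is the total fractional mass landing
#' at locations inside it, summed over the reads generated from it.
#' Mappability is `m/n`: 1 for fully unique sequence, `1/k` for a sequence
#' duplicated `k` times in different genes. At gene level, reads multi-mapping
#' between isoforms of the same gene are recovered (all those locations lie
#' inside the gene), so gene mappability is at least the count-weighted mean
#' of its transcripts' mappabilities.
#'
#' Mapping is exact substring search over the transcriptome (every window is
#' an exact substring of its origin, so `N` is exactly the number of
#' occurrences). Reads containing `N` bases are generated and counted in `n`
#' but never match. Transcripts shorter than `L` emit one full-length read
#' and are flagged `short` in the result.
#'
#' @param txome a [Transcriptome-class].
#' @param L window (read) length; the published protocol uses 50, 100, 150.
#' @param step stride between window starts (default 1, the densest choice).
#' @param level `"transcript"` or `"gene"`.
#' @param searchRevcomp also count occurrences on the reverse complement of
#'   each transcript (both in `N` and in the entity's own mass). Default
#'   FALSE: transcript space is stranded.
#' @param perReadMaxOne alternative scoring in which a read adds a single
#'   `1/N` to an entity containing at least one of its locations, instead of
#'   `1/N` per contained location. Default FALSE.
#' @return A [MappabilityResult-class].
#' @examples
#' tx <- Transcriptome(
#'   c(t1 = "ACGTACGTTTGCAGGCTTAGCCGATCGAT", t2 = "TTTTGGGGCCCCAAAATTTTGGGGCCCA"),
#'   c(t1 = "g1", t2 = "g2"))
#' computeMappability(tx, L = 10)
#' @export
computeMappability <- function(txome, L, step = 1L,
                               level = c("transcript", "gene"),
                               searchRevcomp = FALSE, perReadMaxOne = FALSE) {
  level <- match.arg(level)
  stopifnot(is(txome, "Transcriptome"), L > 0, step > 0)
  L <- as.integer(L); step <- as.integer(step)
  seqs <- as.character(txSequences(txome))
  g2 <- tx2gene(txome)
  lens <- nchar(seqs)
  ids <- names(seqs)
  if (!length(ids))
    return(new("MappabilityResult", level = level, windowLength = L,
               step = step,
               scores = DataFrame(id = character(), n = numeric(),
                                  m = numeric(), mappability = numeric(),
                                  short = logical())))

  occ <- .occCounts(seqs, L)            # c[kmer, tx], forward
  if (searchRevcomp) {
    rc <- as.character(reverseComplement(DNAStringSet(seqs)))
    names(rc) <- names(seqs)
    occ <- rbind(occ, .occCounts(rc, L))
    occ <- occ[, .(c = sum(c)), by = .(kmer, tx)]
  }
  Nk <- occ[, .(N = sum(c)), by = kmer]

  # reads of length L from long transcripts, grouped by (tx, kmer):
  win <- .allWindows(txome, L)
  if (step > 1L) win <- win[(off - 1L) %% step == 0L]
  reads <- win[, .(r = .N), by = .(tx, kmer)]
  reads[, hasN := grepl("N", kmer, fixed = TRUE)]

  nLong <- ifelse(lens >= L, (lens - L) %/% step + 1L, 0L)

  if (level == "transcript") {
    own <- occ[reads[!(hasN)], on = c("kmer", "tx")]
    own[is.na(c), c := 0L]
    own <- Nk[own, on = "kmer"]
    own[, mass := if (perReadMaxOne) (c > 0) / N else c / N]
    agg <- own[, .(m = sum(mass * r)), by = tx]
    m <- structure(numeric(length(ids)), names = ids)
    m[agg$tx] <- agg$m
    n <- nLong
  } else {
    geneOcc <- occ[, .(cg = sum(c)), by = .(kmer, gene = g2[tx])]
    reads[, gene := g2[tx]]
    own <- geneOcc[reads[!(hasN)], on = c("kmer", "gene")]
    own[is.na(cg), cg := 0L]
    own <- Nk[own, on = "kmer"]
    own[, mass := if (perReadMaxOne) (cg > 0) / N else cg / N]
    agg <- own[, .(m = sum(mass * r)), by = gene]
    genes <- unique(unname(g2))
    m <- structure(numeric(length(genes)), names = genes)
    m[agg$gene] <- agg$m
    n <- vapply(genes, function(g) sum(nLong[g2[ids] == g]), numeric(1))
    ids <- genes
  }

  # short transcripts: one full-length read each, matched by scanning
  shortTx <- names(seqs)[lens < L]
  if (length(shortTx)) {
    dss <- txSequences(txome)
    rcs <- if (searchRevcomp) reverseComplement(dss) else NULL
    for (t in shortTx) {
      pat <- seqs[[t]]
      if (grepl("N", pat, fixed = TRUE)) {
        cv <- integer(length(dss))
      } else {
        cv <- vcountPattern(pat, dss)
        if (searchRevcomp) cv <- cv + vcountPattern(pat, rcs)
      }
      N <- sum(cv)
      if (level == "transcript") {
        inSelf <- cv[match(t, names(dss))]
        m[t] <- m[t] + if (N > 0) {
          if (perReadMaxOne) (inSelf > 0) / N else inSelf / N
        } else 0
        n[match(t, names(seqs))] <- n[match(t, names(seqs))] + 1L
      } else {
        g <- g2[[t]]
        inGene <- sum(cv[g2[names(dss)] == g])
        m[g] <- m[g] + if (N > 0) {
          if (perReadMaxOne) (inGene > 0) / N else inGene / N
        } else 0
        n[match(g, ids)] <- n[match(g, ids)] + 1L
      }
    }
  }

  shortFlag <- if (level == "transcript") lens < L else
    vapply(ids, function(g) any(lens[g2[names(seqs)] == g] < L), logical(1))
  sc <- DataFrame(id = ids, n = as.numeric(n), m = as.numeric(m),
                  mappability = as.numeric(m) / as.numeric(n),
                  short = unname(shortFlag))
  new("MappabilityResult", level = level, windowLength = L, step = step,
      scores = sc)
}

#' Brute-force mappability oracle
#'
#' Same contract as [computeMappability()], realised by scanning every read
#' against every transcript sequence with [Biostrings::vcountPattern()]
#' (which reports all, including overlapping, occurrences). Quadratic; meant
#' for small inputs and as an independent cross-check of the indexed
#' implementation.
#'
#' @inheritParams computeMappability
#' @return A [MappabilityResult-class].
#' @export
bruteForceMappability <- function(txome, L, step = 1L,
                                  level = c("transcript", "gene"),
                                  searchRevcomp = FALSE,
                                  perReadMaxOne = FALSE) {
  level <- match.arg(level)
  stopifnot(sum(Biostrings::width(txSequences(txome))) <= 2e5)
  L <- as.integer(L); step <- as.integer(step)
  dss <- txSequences(txome)
  rcs <- if (searchRevcomp) reverseComplement(dss) else NULL
  g2 <- tx2gene(txome)
  win <- generateWindows(txome, L, step)
  ids <- names(dss)
  m <- structure(numeric(length(ids)), names = ids)
  n <- structure(numeric(length(ids)), names = ids)
  for (k in seq_len(nrow(win))) {
    t <- win$origin_tx[k]
    n[t] <- n[t] + 1
    pat <- win$seq[k]
    if (grepl("N", pat, fixed = TRUE)) next
    cv <- vcountPattern(pat, dss)
    if (searchRevcomp) cv <- cv + vcountPattern(pat, rcs)
    N <- sum(cv)
    if (N == 0) next
    if (level == "transcript") {
      inside <- cv[match(t, ids)]
      m[t] <- m[t] + if (perReadMaxOne) (inside > 0) / N else inside / N
    } else {
      inside <- sum(cv[g2[ids] == g2[[t]]])
      m[t] <- m[t] + if (perReadMaxOne) (inside > 0) / N else inside / N
    }
  }
  if (level == "gene") {
    genes <- unique(unname(g2))
    mG <- vapply(genes, function(g) sum(m[g2[ids] == g]), numeric(1))
    nG <- vapply(genes, function(g) sum(n[g2[ids] == g]), numeric(1))
    shortFlag <- vapply(genes, function(g)
      any(Biostrings::width(dss)[g2[ids] == g] < L), logical(1))
    sc <- DataFrame(id = genes, n = unname(nG), m = unname(mG),
                    mappability = unname(mG / nG), short = unname(shortFlag))
  } else {
    sc <- DataFrame(id = ids, n = unname(n), m = unname(m),
                    mappability = unname(m / n),
                    short = unname(Biostrings::width(dss) < L))
  }
  new("MappabilityResult", level = level, windowLength = L, step = step,
      scores = sc)
}
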