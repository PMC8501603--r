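#' Exact alignment of reads to a transcriptome
#'
#' Maps each read to the set of transcripts containing it as an exact
#' substring, reusing the mappability location index. Reads containing `N`
#' or absent from every transcript get an empty set (unmapped).
#'
#' @param reads named `DNAStringSet` (or named character vector) of reads;
#'   typically from [simulateReads()].
#' @param txome a [Transcriptome-class].
#' @param readLength index word length; defaults to the longest read.
#' @return An alignment table: a `data.frame` with columns `read_id` and
#'   `tx`, one row per (read, transcript) hit, carrying the full universe of
#'   read ids as attribute `"reads"` (reads without rows are unmapped).
#' @export
alignReadsExact <- function(reads, txome, readLength = NULL) {
  seqv <- as.character(reads)
  ids <- names(seqv)
  if (is.null(ids)) stop("reads must be named by read id")
  if (anyDuplicated(ids)) stop("read ids must be unique")
  if (is.null(readLength)) readLength <- if (length(seqv)) max(nchar(seqv)) else 1L
  idx <- buildLocationIndex(txome, as.integer(readLength))
  tab <- idx$table[, .(tx = unique(tx)), by = kmer]
  dt <- data.table(read_id = ids, kmer = seqv, len = nchar(seqv))
  full <- dt[len == readLength]
  hits <- tab[full, on = "kmer", nomatch = NULL,
              allow.cartesian = TRUE][, .(read_id, tx)]
  shrt <- dt[len < readLength]
  if (nrow(shrt)) {
    extra <- lapply(unique(shrt$kmer), function(q) {
      loc <- queryLocations(idx, q)
      if (!nrow(loc)) return(NULL)
      data.table(kmer = q, tx = unique(loc$tx))
    })
    extra <- rbindlist(extra)
    if (nrow(extra))
      hits <- rbind(hits,
                    extra[shrt, on = "kmer", nomatch = NULL][, .(read_id, tx)])
  }
  out <- as.data.frame(hits)
  attr(out, "reads") <- ids
  out
}

# collapse one sample's hits into equivalence classes and run EM
.emOneSample <- function(hits, txIds, tol = 1e-8, maxIter = 1000L) {
  dt <- as.data.table(hits)
  cls <- dt[, .(class = paste(sort(tx), collapse = "\t")), by = read_id]
  cls <- cls[, .(d = .N), by = class]
  members <- strsplit(cls$class, "\t", fixed = TRUE)
  d <- cls$d
  total <- sum(d)
  alpha <- structure(rep(1 / length(txIds), length(txIds)), names = txIds)
  memIdx <- lapply(members, match, table = txIds)
  loglik <- numeric(0)
  for (it in seq_len(maxIter)) {
    mass <- structure(numeric(length(txIds)), names = txIds)
    ll <- 0
    for (k in seq_along(memIdx)) {
      i <- memIdx[[k]]
      s <- sum(alpha[i])
      ll <- ll + d[k] * log(s)
      mass[i] <- mass[i] + d[k] * alpha[i] / s
    }
    loglik <- c(loglik, ll)
    alphaNew <- mass / total
    delta <- max(abs(alphaNew - alpha))
    alpha <- alphaNew
    if (delta < tol) break
  }
  list(est = alpha * total, loglik = loglik, iters = it)
}

#' Equivalence-class EM quantification
#'
#' Collapses each sample's reads into equivalence classes by their mapped
#' transcript set and estimates transcript abundances by
#' expectation-maximisation: abundances start uniform; each class's read
#' count is split across its member transcripts proportionally to the current
#' abundances (E-step), and abundances are re-estimated from the assigned
#' mass (M-step), until the largest abundance change falls below `tol` or
#' `maxIter` iterations. Estimated counts are the final assigned mass scaled
#' to the sample's mapped-read total, so mass is conserved exactly.
#'
#' @param aln alignment table from [alignReadsExact()] (or any `data.frame`
#'   with `read_id`, `tx` and a `"reads"` attribute listing all read ids).
#' @param samples named character vector mapping read id to sample; reads of
#'   different samples are quantified independently. Defaults to parsing the
#'   `transcript|sample|serial` read-id convention.
#' @param txIds transcripts to report (default: every transcript seen in the
#'   alignment); transcripts without reads get estimate 0.
#' @param tol convergence tolerance on `max |delta alpha|`.
#' @param maxIter iteration cap.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `est_counts`, `cpm` and `log2cpm` (prior 1 CPM), one column per sample.
#' @export
emQuantify <- function(aln, samples = NULL, txIds = NULL,
                       tol = 1e-8, maxIter = 1000L) {
  allReads <- attr(aln, "reads")
  if (is.null(allReads)) allReads <- unique(aln$read_id)
  if (!nrow(aln)) stop("all reads are unmapped; nothing to quantify")
  if (is.null(samples)) {
    parts <- strsplit(allReads, "|", fixed = TRUE)
    if (any(lengths(parts) < 3L))
      stop("cannot infer samples from read ids; supply 'samples'")
    samples <- structure(vapply(parts, `[`, "", 2L), names = allReads)
  }
  if (is.null(txIds)) txIds <- sort(unique(aln$tx))
  dt <- as.data.table(aln)
  dt[, sample := samples[read_id]]
  smp <- unique(unname(samples))
  est <- matrix(0, nrow = length(txIds), ncol = length(smp),
                dimnames = list(txIds, smp))
  for (s in smp) {
    sub <- dt[sample == s]
    if (!nrow(sub)) next
    fit <- .emOneSample(sub[, .(read_id, tx)], txIds, tol, maxIter)
    est[, s] <- fit$est
  }
  cpm <- cpmTransform(est)
  SummarizedExperiment(
    assays = list(est_counts = est, cpm = cpm,
                  log2cpm = log2(cpm + 1)),
    colData = DataFrame(sample = smp, row.names = smp))
}

#' Counts-per-million transform
#'
#' `cpm = count / column_sum * 1e6`; with `log2 = TRUE`, returns
#' `log2(cpm + prior)` (default prior 1 CPM, applied identically to
#' estimates and ground truth so rank metrics are comparable).
#'
#' @param counts numeric matrix, features x samples.
#' @param log2 return log2(cpm + prior) instead of cpm.
#' @param prior pseudo-CPM added before the log.
#' @return A matrix of the same shape.
#' @examples
#' cpmTransform(cbind(s1 = c(1, 3)))
#' @export
cpmTransform <- function(counts, log2 = FALSE, prior = 1) {
  counts <- as.matrix(counts)
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero))
    stop("zero column sum in sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  cpm <- sweep(counts, 2, cs, "/") * 1e6
  if (log2) base::log2(cpm + prior) else cpm
}
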