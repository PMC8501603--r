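#' @importFrom stats rnbinom rpois rlnorm runif rbinom
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Per-transcript negative-binomial simulation parameters
#'
#' Holds, for each transcript isoform i, the mean count `mu_i`, the
#' dispersion `phi_i` (variance of the control counts is
#' `mu_i * (1 + phi_i * mu_i)`, the standard NB2 form) and the regulating
#' factor `theta_i`, the multiplicative fold-change applied to the mean in
#' Case samples; `theta_i = 1` exactly for non-DE transcripts.
#'
#' @slot params `DataFrame` with columns `transcript_id`, `mu`, `phi`,
#'   `theta`, `is_de`.
#' @slot nReps replicates per group.
#' @slot seed integer seed recorded for reproducibility.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(params = "DataFrame", nReps = "integer", seed = "integer")
)

setValidity("SimulationParams", function(object) {
  p <- object@params
  msg <- character()
  need <- c("transcript_id", "mu", "phi", "theta", "is_de")
  if (!all(need %in% colnames(p)))
    return(paste("params needs columns:", paste(need, collapse = ", ")))
  if (any(p$mu <= 0)) msg <- c(msg, "mu must be positive")
  if (any(p$phi < 0)) msg <- c(msg, "phi must be non-negative")
  if (any(p$theta <= 0)) msg <- c(msg, "theta must be positive")
  if (any(p$theta[!p$is_de] != 1))
    msg <- c(msg, "theta must be exactly 1 for non-DE transcripts")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationParams", function(object) {
  p <- object@params
  cat(sprintf(paste0("SimulationParams: %d transcripts, %d DE, ",
                     "%d replicates/group, seed %d\n"),
              nrow(p), sum(p$is_de), object@nReps, object@seed))
})

#' @describeIn SimulationParams parameter table as a plain `data.frame`
#' @param object a `SimulationParams`
#' @export
simParams <- function(object) as.data.frame(object@params)

#' Generate simulation parameters
#'
#' Synthesises per-transcript NB parameters: means from a lognormal law,
#' dispersions either constant or following the common mean-dispersion trend
#' `phi = a/mu + b`, and fold-changes `theta = 2^(+/-lfc)` (sign
#' equiprobable) for a `deFraction` share of transcripts (exactly
#' `round(deFraction * n)` of them), `theta = 1` for the rest.
#'
#' @param txIds transcript ids (or a single integer n, yielding ids
#'   `tx1..txn`).
#' @param deFraction fraction of transcripts that are differentially
#'   expressed.
#' @param lfc magnitude of the true log2 fold-change for DE transcripts;
#'   values >= 1 make every DE transcript a "true DE" under the
#'   `|log2 theta| >= 1` rule.
#' @param muMeanlog,muSdlog lognormal parameters of the mean counts.
#' @param phiLaw `"trend"` (`phi = phiA/mu + phiB`) or `"constant"`
#'   (`phi = phiB`).
#' @param phiA,phiB dispersion law coefficients.
#' @param nReps biological replicates per group.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A [SimulationParams-class].
#' @export
makeSimParams <- function(txIds, deFraction = 0.3, lfc = 2,
                          muMeanlog = log(50), muSdlog = 1.5,
                          phiLaw = c("trend", "constant"),
                          phiA = 1, phiB = 0.05,
                          nReps = 3L, seed = 1L) {
  phiLaw <- match.arg(phiLaw)
  stopifnot(deFraction >= 0, deFraction <= 1)
  if (is.numeric(txIds) && length(txIds) == 1L)
    txIds <- paste0("tx", seq_len(txIds))
  n <- length(txIds)
  set.seed(seed)
  mu <- rlnorm(n, meanlog = muMeanlog, sdlog = muSdlog)
  phi <- switch(phiLaw, trend = phiA / mu + phiB, constant = rep(phiB, n))
  nDe <- round(deFraction * n)
  isDe <- rep(FALSE, n)
  isDe[sample.int(n, nDe)] <- TRUE
  theta <- rep(1, n)
  sgn <- ifelse(runif(nDe) < 0.5, -1, 1)
  theta[isDe] <- 2^(sgn * lfc)
  new("SimulationParams",
      params = DataFrame(transcript_id = as.character(txIds), mu = mu,
                         phi = phi, theta = theta, is_de = isDe),
      nReps = as.integer(nReps), seed = as.integer(seed))
}

#' Draw a ground-truth count matrix from the NB model
#'
#' Control replicates are drawn as `Y ~ NB(mean = mu_i,
#' variance = mu_i (1 + phi_i mu_i))` and Case replicates as
#' `Y ~ NB(mean = theta_i mu_i, variance = theta_i mu_i (1 + phi_i theta_i
#' mu_i))`, parameterised as size `r = 1/phi_i` and the corresponding success
#' probability; `phi_i = 0` degenerates to Poisson. Draws are reproducible
#' from the seed stored in `params`.
#'
#' @param params a [SimulationParams-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (transcripts x samples, integer), `colData$group` in
#'   `{Control, Case}` and `rowData` carrying `mu`, `phi`, `theta`.
#' @export
drawCounts <- function(params) {
  stopifnot(is(params, "SimulationParams"))
  p <- params@params
  if (any(p$phi < 0)) stop("negative dispersion")
  nReps <- params@nReps
  set.seed(params@seed + 1L)
  nTx <- nrow(p)
  drawOne <- function(mean, phi) {
    out <- numeric(length(mean))
    pois <- phi == 0
    if (any(pois)) out[pois] <- rpois(sum(pois), mean[pois])
    if (any(!pois)) out[!pois] <- rnbinom(sum(!pois), size = 1 / phi[!pois],
                                          mu = mean[!pois])
    out
  }
  ctl <- vapply(seq_len(nReps), function(j) drawOne(p$mu, p$phi),
                numeric(nTx))
  cse <- vapply(seq_len(nReps), function(j) drawOne(p$theta * p$mu, p$phi),
                numeric(nTx))
  # vapply drops to a vector when nTx == 1; restore the tx-by-rep shape
  counts <- cbind(matrix(ctl, nrow = nTx), matrix(cse, nrow = nTx))
  dimnames(counts) <- list(p$transcript_id,
                           c(paste0("Control_", seq_len(nReps)),
                             paste0("Case_", seq_len(nReps))))
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(
      sample = colnames(counts),
      group = rep(c("Control", "Case"), each = nReps),
      row.names = colnames(counts)),
    rowData = p[, c("mu", "phi", "theta", "is_de")])
}

#' Simulate origin-tracked error-free reads
#'
#' For sample j and transcript i, emits exactly `Y_ij` single-end error-free
#' reads with uniformly random start positions on the spliced transcript
#' sequence (the full transcript when it is shorter than the read length).
#' Read ids encode their origin as `transcript|sample|serial`, and the
#' returned origin table records the same mapping explicitly, so alignment
#' recall/precision can be computed without any guesswork.
#'
#' @param counts count `SummarizedExperiment` from [drawCounts()] (or a plain
#'   integer matrix with dimnames).
#' @param txome a [Transcriptome-class] containing every counted transcript.
#' @param readLength read length in bases (default 100).
#' @param seed integer seed.
#' @return A list with `reads` (named `DNAStringSet`) and `origin`
#'   (`data.frame` with `read_id`, `transcript_id`, `sample`).
#' @export
simulateReads <- function(counts, txome, readLength = 100L, seed = 1L) {
  if (is(counts, "SummarizedExperiment"))
    counts <- assay(counts, "counts")
  seqs <- as.character(txSequences(txome))
  miss <- setdiff(rownames(counts), names(seqs))
  if (length(miss))
    stop("transcript(s) absent from transcriptome: ",
         paste(miss, collapse = ", "))
  set.seed(seed)
  lens <- nchar(seqs)
  nz <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(nz))
    return(list(reads = DNAStringSet(),
                origin = data.frame(read_id = character(),
                                    transcript_id = character(),
                                    sample = character())))
  reps <- counts[nz]
  txv <- rep(rownames(counts)[nz[, 1]], reps)
  smv <- rep(colnames(counts)[nz[, 2]], reps)
  lenv <- pmin(lens[txv], readLength)
  maxStart <- pmax(lens[txv] - readLength + 1L, 1L)
  start <- 1L + floor(runif(length(txv)) * maxStart)
  seqv <- substring(seqs[txv], start, start + lenv - 1L)
  serial <- stats::ave(seq_along(txv), paste(txv, smv), FUN = seq_along)
  ids <- paste(txv, smv, serial, sep = "|")
  reads <- DNAStringSet(seqv)
  names(reads) <- ids
  list(reads = reads,
       origin = data.frame(read_id = ids, transcript_id = unname(txv),
                           sample = unname(smv), stringsAsFactors = FALSE))
}
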