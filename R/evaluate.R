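#' @importFrom stats p.adjust cor pt sd
NULL

#' Alignment-step metrics
#'
#' True positives are reads whose mapped set contains their origin
#' transcript; false positives are mapped reads whose set does not; false
#' negatives are unmapped reads. Recall = TP/(TP+FN),
#' precision = TP/(TP+FP), F1 their harmonic mean. Metrics with a zero
#' denominator are reported as `NA` (undefined), never coerced to 0.
#'
#' @param origin origin table from [simulateReads()] (`read_id`,
#'   `transcript_id`).
#' @param aln alignment table from [alignReadsExact()].
#' @return A list with `recall`, `precision`, `f1`, `TP`, `FP`, `FN`.
#' @export
alignmentMetrics <- function(origin, aln) {
  allReads <- attr(aln, "reads")
  if (is.null(allReads)) allReads <- unique(c(aln$read_id, origin$read_id))
  extra <- setdiff(unique(aln$read_id), origin$read_id)
  if (length(extra))
    stop("aligned read(s) missing from the origin table: ",
         paste(utils::head(extra, 5), collapse = ", "))
  originOf <- structure(origin$transcript_id, names = origin$read_id)
  mapped <- unique(aln$read_id)
  hit <- aln$tx == originOf[aln$read_id]
  TP <- length(unique(aln$read_id[hit]))
  FP <- length(mapped) - TP
  FN <- length(allReads) - length(mapped)
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  list(recall = recall, precision = precision, f1 = f1,
       TP = TP, FP = FP, FN = FN)
}

#' Ground-truth abundance filter
#'
#' Keeps transcripts whose ground-truth CPM is at least `thresholdCpm` in
#' every sample; transcripts under the threshold in any sample are removed
#' before quantification and DE evaluation to avoid metric inflation from
#' unexpressed models. The threshold is strict on the removal side: a
#' transcript sitting exactly at the threshold is kept. At the published
#' library size of 40 million reads, 0.25 CPM corresponds to about 10 raw
#' counts.
#'
#' @param trueCounts ground-truth counts (`SummarizedExperiment` with a
#'   `counts` assay, or a matrix).
#' @param thresholdCpm CPM threshold (default 0.25).
#' @return Character vector of kept transcript ids.
#' @export
groundTruthFilter <- function(trueCounts, thresholdCpm = 0.25) {
  if (is(trueCounts, "SummarizedExperiment"))
    trueCounts <- assay(trueCounts, "counts")
  cpm <- cpmTransform(trueCounts)
  rownames(cpm)[apply(cpm, 1, min) >= thresholdCpm]
}

#' Quantification-step metrics
#'
#' Spearman's rho and the normalised root-mean-squared error
#' (RMSE divided by the range of the true values) of log2 CPM, over all
#' (transcript, sample) pairs of the kept transcripts.
#'
#' @param estLog2cpm,trueLog2cpm matrices of log2 CPM (features x samples)
#'   with shared dimnames.
#' @param kept transcript ids to evaluate (default: all shared rows).
#' @return A list with `spearman_rho`, `nrmse`, `n` (pairs used).
#' @export
# Spearman's rho with the undefined (constant-vector) case mapped to NA
# instead of a zero-sd warning; rho is a rank statistic, so a constant
# side carries no ordering information.
.spearman <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  cor(x, y, method = "spearman")
}

quantMetrics <- function(estLog2cpm, trueLog2cpm, kept = NULL) {
  shared <- intersect(rownames(estLog2cpm), rownames(trueLog2cpm))
  if (!is.null(kept)) shared <- intersect(shared, kept)
  if (length(shared) < 3) stop("need >= 3 kept transcripts")
  e <- as.vector(estLog2cpm[shared, colnames(trueLog2cpm), drop = FALSE])
  t <- as.vector(trueLog2cpm[shared, , drop = FALSE])
  rng <- max(t) - min(t)
  list(spearman_rho = .spearman(e, t),
       nrmse = if (rng > 0) sqrt(mean((e - t)^2)) / rng else NA_real_,
       n = length(t))
}

#' Minimal differential-expression test
#'
#' A reference DE caller so the DE-step metrics can run without external
#' tools: per transcript, the estimated log2 fold-change is the difference
#' of group means of log2 CPM (prior 1), the p-value comes from Welch's
#' unequal-variance t-test on the log2 CPM values, q-values are
#' Benjamini-Hochberg, and the DE call is `|log2FC| >= lfcThreshold` with
#' `q < fdrThreshold`. When both groups are constant, the p-value is 1 for
#' equal means and 0 for unequal means (perfect separation).
#'
#' @param counts transcripts x samples count matrix, or a
#'   `SummarizedExperiment` with a `counts` assay and `colData$group`.
#' @param groups character vector of `"Control"`/`"Case"` per column (taken
#'   from `colData` when `counts` is a `SummarizedExperiment`).
#' @param lfcThreshold,fdrThreshold call thresholds (defaults 1 and 0.05).
#' @return `data.frame` with `transcript_id`, `log2fc` (Case - Control),
#'   `pvalue`, `qvalue`, `call`.
#' @export
simpleDeTest <- function(counts, groups = NULL, lfcThreshold = 1,
                         fdrThreshold = 0.05) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(groups)) groups <- colData(counts)$group
    counts <- assay(counts, 1)
  }
  if (is.null(groups)) stop("groups must be supplied")
  stopifnot(ncol(counts) == length(groups),
            all(groups %in% c("Control", "Case")))
  if (sum(groups == "Control") < 2 || sum(groups == "Case") < 2)
    stop("need >= 2 replicates per group")
  lc <- cpmTransform(counts, log2 = TRUE)
  a <- lc[, groups == "Case", drop = FALSE]
  b <- lc[, groups == "Control", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  q <- p.adjust(p, method = "BH")
  lfc <- ma - mb
  data.frame(transcript_id = rownames(counts), log2fc = lfc, pvalue = p,
             qvalue = q, call = abs(lfc) >= lfcThreshold & q < fdrThreshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' True-DE labels from the regulating factor
#'
#' A transcript is a true DE when its fold-change magnitude is at least 2,
#' i.e. `theta >= 2` or `theta <= 1/2` (equivalently `|log2 theta| >= 1`).
#'
#' @param theta named numeric vector of regulating factors.
#' @return Named logical vector.
#' @export
trueDeLabels <- function(theta) theta >= 2 | theta <= 0.5

# AUC by the rank (Mann-Whitney) formula; score ranking is by ascending
# p-value with |log2fc| breaking ties, remaining ties averaged.
.aucRank <- function(pvalue, absLfc, label) {
  r <- data.table::frank(data.table(p = -pvalue, s = absLfc),
                         ties.method = "average")
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DE-step metrics
#'
#' AUC of the DE ranking (reads are ranked by ascending p-value, ties broken
#' by |log2FC|, remaining ties averaged; computed by the rank/Mann-Whitney
#' formula) against the true-DE labels; Spearman's rho and NRMSE between the
#' estimated log2 fold-change and the true `log2(theta)`; and the confusion
#' counts of the DE calls. AUC is `NA` when only one class is present.
#'
#' @param de result of [simpleDeTest()] (or any table with `transcript_id`,
#'   `log2fc`, `pvalue`, `call`).
#' @param theta named numeric vector of true regulating factors.
#' @param kept transcript ids to evaluate (default: all in `de`).
#' @return A list with `auc`, `spearman_rho_lfc`, `nrmse_lfc`, `TP`, `FP`,
#'   `TN`, `FN`, `n`.
#' @export
deMetrics <- function(de, theta, kept = NULL) {
  ids <- de$transcript_id
  if (!is.null(kept)) {
    de <- de[ids %in% kept, , drop = FALSE]
    ids <- de$transcript_id
  }
  miss <- setdiff(ids, names(theta))
  if (length(miss))
    stop("theta missing for transcript(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  th <- theta[ids]
  truth <- trueDeLabels(th)
  trueLfc <- log2(th)
  rng <- max(trueLfc) - min(trueLfc)
  list(
    auc = .aucRank(de$pvalue, abs(de$log2fc), truth),
    spearman_rho_lfc = if (length(ids) >= 3)
      .spearman(de$log2fc, trueLfc) else NA_real_,
    nrmse_lfc = if (rng > 0) sqrt(mean((de$log2fc - trueLfc)^2)) / rng
      else NA_real_,
    TP = sum(de$call & truth), FP = sum(de$call & !truth),
    TN = sum(!de$call & !truth), FN = sum(!de$call & truth),
    n = length(ids))
}

#' Equal-sized tercile (k-tile) grouping
#'
#' Sorts ids ascending by value (ties broken by id, stable) and splits at
#' positions `ceiling(N/k)`, `ceiling(2N/k)`, ... into groups as equal as
#' possible; with k = 3 the groups are labelled `low`, `middle`, `high`.
#' Reported intervals are `[min, max)` of each group, the last closed.
#'
#' @param values named numeric vector (e.g. per-transcript mappability or
#'   mean true CPM).
#' @param k number of groups (default 3).
#' @return `data.frame` with `id`, `value`, `group` (ordered factor);
#'   attribute `"intervals"` holds each group's value range.
#' @export
tercileGroups <- function(values, k = 3L) {
  ids <- names(values)
  if (is.null(ids)) stop("values must be named")
  N <- length(values)
  if (N < k) stop("need at least k ids")
  ord <- order(values, ids)
  cut <- ceiling(seq_len(k) * N / k)
  sizes <- diff(c(0L, cut))
  labels <- if (k == 3L) c("low", "middle", "high") else paste0("g", seq_len(k))
  grp <- rep(labels, sizes)
  out <- data.frame(id = ids[ord], value = unname(values[ord]),
                    group = factor(grp, levels = labels),
                    stringsAsFactors = FALSE)
  iv <- do.call(rbind, lapply(split(out$value, out$group), range))
  attr(out, "intervals") <- data.frame(group = rownames(iv), min = iv[, 1],
                                       max = iv[, 2], row.names = NULL)
  out
}

#' Stratified performance report
#'
#' Computes the evaluation metrics within cells of mappability tercile x
#' true-abundance tercile, mirroring the faceted benchmark figures:
#' \itemize{
#'   \item DE metrics (AUC, Spearman rho and NRMSE of log2 fold-change)
#'     per cell, faceting transcripts by the tercile of their mean true CPM
#'     over all ground-truth samples;
#'   \item quantification metrics (Spearman rho and NRMSE of log2 CPM) over
#'     (transcript, sample) pairs, faceting pairs by the tercile of the
#'     pair's own true CPM;
#'   \item alignment metrics (recall, precision, F1) per mappability
#'     tercile of the reads' origin transcripts (facet `"all"`).
#' }
#' Cells with fewer than `minCellSize` members are flagged `unreliable`;
#' empty cells are reported with `NA` values, never zero.
#'
#' @param mappability transcript-level [MappabilityResult-class].
#' @param trueCounts ground-truth count `SummarizedExperiment` (with
#'   `rowData$theta`) or matrix plus `theta`.
#' @param quant [emQuantify()] result (`SummarizedExperiment` with a
#'   `log2cpm` assay), or `NULL` to skip quantification metrics.
#' @param de [simpleDeTest()] result, or `NULL` to skip DE metrics.
#' @param origin,aln origin table and alignment table for alignment metrics,
#'   or `NULL` to skip them.
#' @param theta named true regulating factors (defaults to
#'   `rowData(trueCounts)$theta`).
#' @param thresholdCpm ground-truth CPM filter applied before quantification
#'   and DE metrics (default 0.25).
#' @param minCellSize cells smaller than this are flagged (default 10).
#' @return Tidy `data.frame` with columns `step`, `map_group`, `facet`,
#'   `metric`, `value`, `n`, `unreliable`.
#' @export
groupedReport <- function(mappability, trueCounts, quant = NULL, de = NULL,
                          origin = NULL, aln = NULL, theta = NULL,
                          thresholdCpm = 0.25, minCellSize = 10L) {
  sc <- mappabilityScores(mappability)
  mapv <- structure(sc$mappability, names = sc$id)
  if (is(trueCounts, "SummarizedExperiment")) {
    if (is.null(theta)) {
      rd <- rowData(trueCounts)
      theta <- structure(rd$theta, names = rownames(trueCounts))
    }
    trueMat <- assay(trueCounts, "counts")
  } else trueMat <- as.matrix(trueCounts)
  kept <- groundTruthFilter(trueMat, thresholdCpm)
  kept <- intersect(kept, names(mapv))
  trueCpm <- cpmTransform(trueMat)
  trueL2 <- log2(trueCpm + 1)
  rows <- list()
  addRow <- function(step, g, f, metric, value, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      step = step, map_group = g, facet = f, metric = metric,
      value = if (is.null(value)) NA_real_ else as.numeric(value),
      n = n, unreliable = n < minCellSize, stringsAsFactors = FALSE)
  }

  mapTer <- tercileGroups(mapv[kept])
  mapOf <- structure(as.character(mapTer$group), names = mapTer$id)

  if (!is.null(de)) {
    meanCpm <- rowMeans(trueCpm)[kept]
    abTer <- tercileGroups(meanCpm)
    abOf <- structure(as.character(abTer$group), names = abTer$id)
    for (g in levels(mapTer$group)) for (f in levels(abTer$group)) {
      cell <- kept[mapOf[kept] == g & abOf[kept] == f]
      if (!length(cell)) {
        for (met in c("auc", "spearman_rho_lfc", "nrmse_lfc"))
          addRow("de", g, f, met, NA_real_, 0L)
        next
      }
      dm <- deMetrics(de, theta, kept = cell)
      addRow("de", g, f, "auc", dm$auc, dm$n)
      addRow("de", g, f, "spearman_rho_lfc", dm$spearman_rho_lfc, dm$n)
      addRow("de", g, f, "nrmse_lfc", dm$nrmse_lfc, dm$n)
    }
  }

  if (!is.null(quant)) {
    estL2 <- assay(quant, "log2cpm")
    common <- intersect(kept, rownames(estL2))
    pairTrue <- as.vector(trueCpm[common, , drop = FALSE])
    pairIdx <- expand.grid(tx = common, sample = colnames(trueMat),
                           stringsAsFactors = FALSE)
    pTer <- tercileGroups(structure(pairTrue,
                                    names = seq_along(pairTrue)))
    pOf <- character(length(pairTrue))
    pOf[as.integer(pTer$id)] <- as.character(pTer$group)
    eV <- as.vector(estL2[common, colnames(trueMat), drop = FALSE])
    tV <- as.vector(trueL2[common, , drop = FALSE])
    gV <- mapOf[pairIdx$tx]
    for (g in levels(mapTer$group)) for (f in levels(pTer$group)) {
      sel <- gV == g & pOf == f
      n <- sum(sel)
      if (n < 3) {
        addRow("quantification", g, f, "spearman_rho", NA_real_, n)
        addRow("quantification", g, f, "nrmse", NA_real_, n)
        next
      }
      rng <- max(tV[sel]) - min(tV[sel])
      addRow("quantification", g, f, "spearman_rho",
             .spearman(eV[sel], tV[sel]), n)
      addRow("quantification", g, f, "nrmse",
             if (rng > 0) sqrt(mean((eV[sel] - tV[sel])^2)) / rng
             else NA_real_, n)
    }
  }

  if (!is.null(origin) && !is.null(aln)) {
    for (g in levels(mapTer$group)) {
      txg <- names(mapOf)[mapOf == g]
      orr <- origin[origin$transcript_id %in% txg, , drop = FALSE]
      sub <- aln[aln$read_id %in% orr$read_id, , drop = FALSE]
      attr(sub, "reads") <- intersect(attr(aln, "reads"), orr$read_id)
      n <- length(attr(sub, "reads"))
      if (!n) {
        for (met in c("recall", "precision", "f1"))
          addRow("alignment", g, "all", met, NA_real_, 0L)
        next
      }
      am <- alignmentMetrics(orr, sub)
      addRow("alignment", g, "all", "recall", am$recall, n)
      addRow("alignment", g, "all", "precision", am$precision, n)
      addRow("alignment", g, "all", "f1", am$f1, n)
    }
  }

  do.call(rbind, rows)
}
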