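test_that("alignment metrics count origin hits, misses and unmapped reads", {
  origin <- data.frame(read_id = paste0("r", 1:10),
                       transcript_id = rep("t1", 10))
  # 8 reads contain the origin, 1 maps elsewhere only, 1 is unmapped
  hits <- rbind(
    data.frame(read_id = paste0("r", 1:8), tx = "t1"),
    data.frame(read_id = "r1", tx = "t9"),   # extra multi-map is harmless
    data.frame(read_id = "r9", tx = "t2"))
  am <- alignmentMetrics(origin, mkAln(hits, allReads = paste0("r", 1:10)))
  expect_equal(am$TP, 8); expect_equal(am$FP, 1); expect_equal(am$FN, 1)
  expect_equal(am$recall, 8 / 9)
  expect_equal(am$precision, 8 / 9)
  expect_equal(am$f1, 8 / 9)

  # perfect mapping
  perfect <- data.frame(read_id = paste0("r", 1:10), tx = "t1")
  amP <- alignmentMetrics(origin, mkAln(perfect, paste0("r", 1:10)))
  expect_equal(c(amP$recall, amP$precision, amP$f1), c(1, 1, 1))

  # everything unmapped: recall 0, precision undefined (NA, not 0)
  am0 <- alignmentMetrics(origin, mkAln(perfect[0, ], paste0("r", 1:10)))
  expect_equal(am0$recall, 0)
  expect_true(is.na(am0$precision))

  # aligned reads unknown to the origin table are an error
  expect_error(alignmentMetrics(origin[1:2, ],
                                mkAln(perfect, paste0("r", 1:10))), "r3")
})

test_that("the ground-truth CPM filter is strict below threshold only", {
  # library sizes 4e7 per sample so CPM = counts / 40
  base <- 4e7
  cnt <- rbind(
    atT  = c(10, 10),     # exactly 0.25 CPM everywhere -> kept
    below = c(9, 10),     # 0.225 CPM in one sample -> removed
    high = c(1000, 1000),
    zero = c(0, 0),
    mid  = c(50, 11))
  filler <- base - colSums(cnt)
  cnt <- rbind(cnt, filler = filler)
  colnames(cnt) <- c("s1", "s2")
  kept <- groundTruthFilter(cnt, 0.25)
  expect_true(all(c("atT", "high", "mid", "filler") %in% kept))
  expect_false("below" %in% kept)
  expect_false("zero" %in% kept)
  # monotone: raising the threshold never adds transcripts
  kept2 <- groundTruthFilter(cnt, 1)
  expect_true(all(kept2 %in% kept))
})

test_that("quantification metrics match direct formula evaluation", {
  tr <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(paste0("t", 1:4), "s1"))
  expect_equal(quantMetrics(tr, tr)$spearman_rho, 1)
  expect_equal(quantMetrics(tr, tr)$nrmse, 0)
  # a monotone transform keeps rho = 1 but not NRMSE = 0
  est <- tr^2
  qm <- quantMetrics(est, tr)
  expect_equal(qm$spearman_rho, 1)
  expect_gt(qm$nrmse, 0)
  # hand computation on 4 points: est-true = (1,0,0,-1), range(true) = 3
  est2 <- tr + c(1, 0, 0, -1)
  expect_equal(quantMetrics(est2, tr)$nrmse, sqrt(2 / 4) / 3)
  expect_equal(quantMetrics(est2, tr)$spearman_rho,
               cor(est2[, 1], tr[, 1], method = "spearman"))
})

test_that("the reference DE test behaves at its degenerate and clear cases", {
  set.seed(61)
  base <- matrix(rpois(5 * 6, 200), nrow = 5,
                 dimnames = list(paste0("t", 1:5),
                                 c(paste0("Control_", 1:3), paste0("Case_", 1:3))))
  groups <- rep(c("Control", "Case"), each = 3)
  # identical groups: no calls, log2fc 0
  sym <- base
  sym[, 4:6] <- sym[, 1:3]
  deS <- simpleDeTest(sym, groups)
  expect_equal(deS$log2fc, rep(0, 5))
  expect_true(all(!deS$call))
  expect_true(all(deS$pvalue == 1 | deS$pvalue > 0.999 | !is.na(deS$pvalue)))

  # one transcript shifted 4x with tight replicates is called
  set.seed(62)
  m <- matrix(rnbinom(40 * 10, mu = 200, size = 50), nrow = 40)
  m <- cbind(m[, 1:5], m[, 6:10])
  rownames(m) <- paste0("t", 1:40)
  colnames(m) <- c(paste0("Control_", 1:5), paste0("Case_", 1:5))
  m["t1", 6:10] <- rnbinom(5, mu = 800, size = 50)
  de <- simpleDeTest(m, rep(c("Control", "Case"), each = 5))
  expect_true(de$call[de$transcript_id == "t1"])
  expect_lt(sum(de$call), 3)

  # q-values are the BH step-up of the p-values and the call rule is exact
  expect_equal(de$qvalue, p.adjust(de$pvalue, "BH"))
  expect_equal(de$call, abs(de$log2fc) >= 1 & de$qvalue < 0.05)
})

test_that("DE calls are invariant to transcript ordering", {
  set.seed(63)
  m <- matrix(rnbinom(20 * 6, mu = 100, size = 20), nrow = 20,
              dimnames = list(paste0("t", 1:20),
                              c(paste0("Control_", 1:3), paste0("Case_", 1:3))))
  g <- rep(c("Control", "Case"), each = 3)
  de1 <- simpleDeTest(m, g)
  perm <- sample(nrow(m))
  de2 <- simpleDeTest(m[perm, ], g)
  de2 <- de2[match(de1$transcript_id, de2$transcript_id), ]
  expect_equal(de1$qvalue, de2$qvalue)
  expect_equal(de1$call, de2$call)
})

test_that("AUC matches the pairwise-comparison oracle", {
  # hand-enumerable 6-transcript case: 2 true DEs, 8 class pairs, 5 wins
  de <- data.frame(transcript_id = paste0("t", 1:6),
                   log2fc = c(3, 0.1, 0.4, 2, 0.2, 0.3),
                   pvalue = c(0.01, 0.2, 0.03, 0.5, 0.8, 0.04),
                   call = FALSE)
  theta <- c(t1 = 4, t2 = 1, t3 = 1, t4 = 0.25, t5 = 1, t6 = 1)
  dm <- deMetrics(de, theta)
  expect_equal(dm$auc, 5 / 8)

  # random fixtures: rank formula == pairwise oracle (exact)
  pairAuc <- function(p, a, lab) {
    pos <- which(lab); neg <- which(!lab)
    wins <- 0
    for (i in pos) for (j in neg) {
      if (p[i] < p[j] || (p[i] == p[j] && a[i] > a[j])) wins <- wins + 1
      else if (p[i] == p[j] && a[i] == a[j]) wins <- wins + 0.5
    }
    wins / (length(pos) * length(neg))
  }
  set.seed(64)
  for (rep in 1:5) {
    n <- 40
    p <- round(runif(n), 2)          # force ties
    a <- round(runif(n, 0, 3), 1)
    lab <- runif(n) < 0.3
    if (!any(lab) || all(lab)) next
    de <- data.frame(transcript_id = paste0("t", 1:n), log2fc = a,
                     pvalue = p, call = FALSE)
    th <- structure(ifelse(lab, 4, 1), names = de$transcript_id)
    expect_equal(deMetrics(de, th)$auc, pairAuc(p, a, lab))
  }
})

test_that("scores independent of the truth give AUC near one half", {
  set.seed(65)
  n <- 10000
  de <- data.frame(transcript_id = paste0("t", 1:n),
                   log2fc = rnorm(n), pvalue = runif(n), call = FALSE)
  th <- structure(ifelse(runif(n) < 0.3, 4, 1), names = de$transcript_id)
  expect_lt(abs(deMetrics(de, th)$auc - 0.5), 0.02)
})

test_that("true-DE labels follow the fold-change magnitude rule", {
  th <- c(a = 4, b = 2, c = 1.9, d = 1, e = 0.5, f = 0.51, g = 0.25)
  expect_equal(unname(trueDeLabels(th)),
               c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
})

test_that("tercile grouping is equal-sized, stable and interval-reported", {
  v <- structure(1:9, names = paste0("t", 1:9))
  g <- tercileGroups(v)
  expect_equal(split(g$id, g$group),
               list(low = paste0("t", 1:3), middle = paste0("t", 4:6),
                    high = paste0("t", 7:9)))
  # N = 10: ceiling rule gives sizes 4, 3, 3
  v10 <- structure(10:1, names = paste0("t", 1:10))
  g10 <- tercileGroups(v10)
  expect_equal(unname(table(g10$group)), array(c(4L, 3L, 3L)),
               ignore_attr = TRUE)
  # all-equal values fall back to id order with the same sizes
  ve <- structure(rep(5, 10), names = paste0("t", sprintf("%02d", 1:10)))
  ge <- tercileGroups(ve)
  expect_equal(ge$id, sort(names(ve)))
  expect_equal(unname(table(ge$group)), array(c(4L, 3L, 3L)),
               ignore_attr = TRUE)
  expect_error(tercileGroups(c(a = 1, b = 2)), "at least")
})

test_that("the stratified report matches per-cell metrics computed directly", {
  demo <- runDemo(seed = 5, nGenes = 25, chromLength = 60000)
  rep <- demo$report
  expect_true(all(c("step", "map_group", "facet", "metric", "value", "n",
                    "unreliable") %in% colnames(rep)))
  # recompute one DE cell by hand
  sc <- mappabilityScores(demo$mappability)
  mapv <- structure(sc$mappability, names = sc$id)
  kept <- demo$kept
  mt <- tercileGroups(mapv[kept])
  cpm <- cpmTransform(SummarizedExperiment::assay(demo$counts, "counts"))
  at <- tercileGroups(rowMeans(cpm)[kept])
  cell <- intersect(mt$id[mt$group == "low"], at$id[at$group == "low"])
  theta <- structure(SummarizedExperiment::rowData(demo$counts)$theta,
                     names = rownames(demo$counts))
  if (length(cell) >= 2 &&
      length(unique(trueDeLabels(theta[cell]))) == 2) {
    direct <- deMetrics(demo$de, theta, kept = cell)
    got <- rep$value[rep$step == "de" & rep$map_group == "low" &
                     rep$facet == "low" & rep$metric == "auc"]
    expect_equal(got, direct$auc)
  }
  # small cells are flagged unreliable, empty cells are NA not zero
  expect_true(all(rep$unreliable[rep$n < 10]))
  expect_true(all(is.na(rep$value[rep$n == 0])))
})
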