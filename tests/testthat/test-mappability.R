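test_that("sliding-window read counts follow the length rules", {
  set.seed(31)
  txo <- Transcriptome(c(a = randSeq(100), b = randSeq(30), c = randSeq(100)),
                       c(a = "g1", b = "g2", c = "g3"))
  w50 <- generateWindows(txo, L = 50, step = 1)
  expect_equal(sum(w50$origin_tx == "a"), 51)       # l - L + 1
  expect_equal(sum(w50$origin_tx == "b"), 1)        # short rule
  expect_equal(w50$length[w50$origin_tx == "b"], 30)
  w100 <- generateWindows(txo, L = 100, step = 1)
  expect_equal(sum(w100$origin_tx == "a"), 1)
  w7 <- generateWindows(txo, L = 50, step = 7)
  expect_equal(sum(w7$origin_tx == "a"), floor((100 - 50) / 7) + 1)
})

test_that("the location index answers complete occurrence queries", {
  core <- randSeq(12)
  s1 <- paste0(randSeq(20), core, randSeq(15), core, randSeq(10))
  set.seed(32)
  s2 <- randSeq(60)
  txo <- Transcriptome(c(a = s1, b = s2), c(a = "g1", b = "g2"))
  idx <- buildLocationIndex(txo, L = 12)
  # a repeated 12-mer occurs twice in the same transcript
  hits <- queryLocations(idx, core)
  expect_equal(nrow(hits), 2)
  expect_equal(unique(hits$tx), "a")
  expect_equal(sort(hits$off), c(21, 48))
  # a unique 12-mer maps only to itself
  uniq <- substr(s2, 1, 12)
  h2 <- queryLocations(idx, uniq)
  expect_equal(h2, data.frame(tx = "b", off = 1L))
  # absent and N-containing queries return nothing
  expect_equal(nrow(queryLocations(idx, paste(rep("A", 12), collapse = ""))), 0)
  expect_equal(nrow(queryLocations(idx, "ACGTNACGTNAC")), 0)
  # shorter-than-L queries fall back to scanning
  h3 <- queryLocations(idx, substr(core, 1, 8))
  expect_true(all(c(21, 48) %in% h3$off[h3$tx == "a"]))
})

test_that("analytic anchors: unique, duplicated and triplicated sequences", {
  set.seed(33)
  u <- vapply(1:5, function(i) randSeq(80), character(1))
  names(u) <- paste0("u", 1:5)
  txoU <- Transcriptome(u, structure(paste0("gu", 1:5), names = names(u)))
  scU <- mappabilityScores(computeMappability(txoU, L = 25))
  expect_equal(scU$mappability, rep(1, 5))

  dupSeq <- randSeq(90)
  txoD <- Transcriptome(c(d1 = dupSeq, d2 = dupSeq),
                        c(d1 = "gA", d2 = "gB"))
  scD <- mappabilityScores(computeMappability(txoD, L = 25))
  expect_equal(scD$mappability, c(0.5, 0.5))

  txoT <- Transcriptome(c(d1 = dupSeq, d2 = dupSeq, d3 = dupSeq),
                        c(d1 = "gA", d2 = "gB", d3 = "gC"))
  scT <- mappabilityScores(computeMappability(txoT, L = 25))
  expect_equal(scT$mappability, rep(1 / 3, 3))

  # identical transcripts in the SAME gene recover full mass at gene level
  txoG <- Transcriptome(c(d1 = dupSeq, d2 = dupSeq),
                        c(d1 = "gA", d2 = "gA"))
  scG <- mappabilityScores(computeMappability(txoG, L = 25, level = "gene"))
  expect_equal(scG$mappability, 1.0)
  # ... while their transcript-level scores stay 0.5
  scG2 <- mappabilityScores(computeMappability(txoG, L = 25))
  expect_equal(scG2$mappability, c(0.5, 0.5))
})

test_that("reads containing N count toward n but never match", {
  set.seed(34)
  s <- randSeq(60)
  substr(s, 30, 30) <- "N"
  txo <- Transcriptome(c(a = s), c(a = "g1"))
  sc <- mappabilityScores(computeMappability(txo, L = 20))
  # windows overlapping position 30 (offsets 11..30) are dead: 20 of 41
  expect_equal(sc$n, 41)
  expect_equal(sc$m, 21)
  expect_equal(sc$mappability, 21 / 41)
})

test_that("fractional assignment distributes exactly one unit of mass per read", {
  set.seed(35)
  txo <- randomTxome(nTx = 12, dupPairs = 2, sharedCore = 15)
  sc <- mappabilityScores(computeMappability(txo, L = 25))
  # independently redistribute every read's mass over ALL its locations:
  # each location gets 1/N, so each matched read hands out exactly 1 unit,
  # and the share landing in the read's own transcript reproduces m
  idx <- buildLocationIndex(txo, L = 25)
  w <- generateWindows(txo, L = 25)
  received <- 0
  own <- structure(numeric(nrow(sc)), names = sc$id)
  for (i in seq_len(nrow(w))) {
    hits <- queryLocations(idx, w$seq[i])
    if (!nrow(hits)) next
    received <- received + sum(rep(1 / nrow(hits), nrow(hits)))
    own[w$origin_tx[i]] <- own[w$origin_tx[i]] +
      sum(hits$tx == w$origin_tx[i]) / nrow(hits)
  }
  # no N bases here, so every read matches at least itself
  expect_equal(received, sum(sc$n), tolerance = 1e-9)
  expect_equal(unname(own[sc$id]), sc$m, tolerance = 1e-9)
  # mass leaking to duplicate/shared partners leaves its origin, so the
  # own-mass total is strictly below the read total on this fixture ...
  expect_lt(sum(sc$m), sum(sc$n))
  # ... and equals it exactly when nothing is shared
  set.seed(36)
  solo <- randomTxome(nTx = 8, dupPairs = 0, sharedCore = 0)
  scS <- mappabilityScores(computeMappability(solo, L = 25))
  expect_equal(sum(scS$m), sum(scS$n), tolerance = 1e-9)
})

test_that("gene-level mappability dominates the pooled transcript ratio", {
  fx <- makeFixture(nGenes = 12, chromLength = 40000, seed = 36)
  txo <- extractTranscriptSequences(fx$annotation, fx$genome)
  mt <- mappabilityScores(computeMappability(txo, L = 50))
  mg <- mappabilityScores(computeMappability(txo, L = 50, level = "gene"))
  g2 <- tx2gene(txo)
  for (g in mg$id) {
    sub <- mt[g2[mt$id] == g, ]
    expect_gte(mg$mappability[mg$id == g] + 1e-9, sum(sub$m) / sum(sub$n))
  }
})

test_that("indexed and brute-force mappability agree on random fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    txo <- randomTxome(nTx = 15, lenRange = c(35, 90), dupPairs = 1,
                       sharedCore = 12)
    for (lev in c("transcript", "gene")) {
      a <- mappabilityScores(computeMappability(txo, L = 25, level = lev))
      b <- mappabilityScores(bruteForceMappability(txo, L = 25, level = lev))
      expect_equal(a$id, b$id)
      expect_equal(a$n, b$n)
      expect_equal(a$m, b$m, tolerance = 1e-12)
    }
  }
})

test_that("mean mappability is non-decreasing in window length on shared-exon fixtures", {
  fx <- makeFixture(nGenes = 15, chromLength = 50000, seed = 37,
                    shareLevels = c(0.5, 0.75), dupGeneFraction = 0.2)
  txo <- extractTranscriptSequences(fx$annotation, fx$genome)
  means <- vapply(c(50, 100, 150), function(L)
    mean(mappabilityScores(computeMappability(txo, L = L))$mappability),
    numeric(1))
  expect_true(all(diff(means) >= -1e-12))
})

test_that("per-read-max-one scoring differs only for intra-entity repeats", {
  set.seed(38)
  core <- randSeq(25)
  s <- paste0(randSeq(30), core, randSeq(20), core, randSeq(30))
  txo <- Transcriptome(c(a = s), c(a = "g1"))
  scSum <- mappabilityScores(computeMappability(txo, L = 25))
  scOne <- mappabilityScores(computeMappability(txo, L = 25,
                                                perReadMaxOne = TRUE))
  # with the sum rule a self-repeat keeps full mass (2 x 1/2); with the
  # max-one rule each repeat read keeps only 1/2
  expect_equal(scSum$mappability, 1)
  expect_lt(scOne$mappability, 1)
})

test_that("reverse-complement occurrences split mass when enabled", {
  set.seed(39)
  s <- randSeq(70)
  txo <- Transcriptome(c(a = s, b = rcStr(s)), c(a = "g1", b = "g2"))
  fwd <- mappabilityScores(computeMappability(txo, L = 30))
  expect_equal(fwd$mappability, c(1, 1))
  rev <- mappabilityScores(computeMappability(txo, L = 30,
                                              searchRevcomp = TRUE))
  expect_equal(rev$mappability, c(0.5, 0.5))
  # brute force agrees under the flag too
  bf <- mappabilityScores(bruteForceMappability(txo, L = 30,
                                                searchRevcomp = TRUE))
  expect_equal(rev$m, bf$m, tolerance = 1e-12)
})
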