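test_that("grouped splits honor fractions, determinism, and preconditions", {
  ids <- sprintf("c%02d", 1:10)
  sp <- assignSplits(ids, seed = 11L)
  expect_equal(as.integer(table(sp@assignment$split)[c("train",
                                                       "validation",
                                                       "test")]),
               c(6L, 2L, 2L))
  sp2 <- assignSplits(ids, seed = 11L)
  expect_identical(sp@assignment, sp2@assignment)
  expect_error(assignSplits(ids[1:2]), class = "ppiConfigError")
  expect_error(assignSplits(ids, fractions = c(train = 0.5,
                                               validation = 0.2,
                                               test = 0.2)),
               class = "ppiConfigError")
  # rows of one complex can never straddle splits by construction
  tab <- makeFeatureTable(10, seed = 12L)
  d <- featureData(tab)
  rowSplit <- setNames(sp@assignment$split,
                       sp@assignment$complex_id)[d$complex_id]
  expect_silent(assertGroupIntegrity(d$complex_id, rowSplit))
})

test_that("training filter drops only mis-docked actives in training rows", {
  tab <- makeFeatureTable(10, seed = 13L)
  d <- featureData(tab)
  sp <- assignSplits(unique(d$complex_id), seed = 13L)
  # give one active training complex the quoted DockQ profile
  trainActives <- intersect(splitComplexes(sp, "train"),
                            d$complex_id[d$label == "active"])
  cx <- trainActives[1]
  dockqRow <- rep(NA_real_, nrow(d))
  trainIds <- splitComplexes(sp, "train")
  act <- d$label == "active" & d$complex_id %in% trainIds
  dockqRow[act] <- 0.9
  dockqRow[d$complex_id == cx] <- c(0.9, 0.8, 0.1, 0.7, 0.05)
  out <- filterTrainingActives(tab, sp, dockqRow)
  od <- featureData(out)
  expect_equal(sum(od$complex_id == cx), 3L)
  # decoy and non-training rows are untouched
  expect_equal(sum(od$label == "decoy"), sum(d$label == "decoy"))
  testIds <- splitComplexes(sp, "test")
  expect_equal(sum(od$complex_id %in% testIds),
               sum(d$complex_id %in% testIds))
  # all five below threshold: complex contributes nothing
  dockqRow[d$complex_id == cx] <- 0.1
  expect_equal(sum(featureData(filterTrainingActives(tab, sp, dockqRow))$complex_id == cx),
               0L)
  # a missing value for an active training row is a data error
  dockqRow[which(act)[1]] <- NA
  expect_error(filterTrainingActives(tab, sp, dockqRow),
               class = "ppiDataError")
})

test_that("cross-validation separates separable tables and guards groups", {
  tab <- makeFeatureTable(20, effectSize = 8, seed = 14L)
  # a perfectly separable table: the linear backend recovers AUC 1 exactly
  cvLog <- crossvalTrain(tab, folds = 5L, seed = 14L,
                         modelSpec = list(type = "logistic"))
  expect_equal(cvLog$auc, 1)
  # the boosted-tree backend matches on the same data up to the held-out
  # complex-effect extrapolation gap
  cv <- crossvalTrain(tab, folds = 5L, seed = 14L)
  expect_gt(cv$auc, 0.95)
  # group integrity: each complex sits in exactly one fold
  expect_silent(assertGroupIntegrity(cv$predictions$complex_id,
                                     cv$predictions$fold))
  # all rows predicted out-of-fold
  expect_equal(nrow(cv$predictions), nrow(featureData(tab)))
  # one-class folds are a stratification error
  d <- featureData(tab)
  dOne <- d[d$label == "active", ]
  expect_error(crossvalTrain(FeatureTable(dOne), folds = 5L, seed = 1L),
               class = "ppiStratificationError")
})

test_that("backward selection removes a pure-noise feature first", {
  tab <- makeFeatureTable(24, effectSize = 3, seed = 15L,
                          nInformative = 2L)
  feats <- featureNames()
  start <- c(feats[1:2], feats[30])  # two informative + one noise
  sel <- backwardSelect(tab, startFeatures = start, targetSize = 2L,
                        folds = 3L, seed = 15L)
  expect_identical(sel$trace$removed[1], feats[30])
  expect_setequal(sel$features, feats[1:2])
  expect_equal(nrow(sel$trace), 1L)
  # identity subset when target equals start size
  sel0 <- backwardSelect(tab, startFeatures = start, targetSize = 3L,
                         folds = 3L, seed = 15L)
  expect_identical(sel0$features, start)
})

test_that("hyperparameter search prefers capable configurations", {
  tab <- makeFeatureTable(16, effectSize = 3, seed = 16L)
  grid1 <- data.frame(max_depth = 3, n_estimators = 60,
                      learning_rate = 0.2, gamma = 0, lambda = 1,
                      min_child_weight = 1)
  one <- tuneHyperparams(tab, grid1, folds = 3L, seed = 16L)
  expect_equal(one$best$max_depth, 3)
  grid2 <- rbind(grid1,
                 data.frame(max_depth = 1, n_estimators = 1,
                            learning_rate = 0.01, gamma = 10,
                            lambda = 1, min_child_weight = 50))
  two <- tuneHyperparams(tab, grid2, folds = 3L, seed = 16L)
  expect_equal(two$best$n_estimators, 60)
  expect_error(tuneHyperparams(tab, grid1[0, ], folds = 3L),
               class = "ppiConfigError")
  expect_error(tuneHyperparams(tab, grid1[, -1], folds = 3L),
               class = "ppiConfigError")
  # determinism
  again <- tuneHyperparams(tab, grid2, folds = 3L, seed = 16L)
  expect_equal(two$results$auc, again$results$auc)
})

test_that("complex scoring takes the maximum over model scores", {
  tab <- makeFeatureTable(12, effectSize = 3, seed = 17L)
  tm <- trainModel(tab, folds = 3L, seed = 17L)
  d <- featureData(tab)
  one <- d[d$complex_id == d$complex_id[1], ]
  sc <- scoreComplex(tm, one)
  expect_equal(sc$complex_score, max(sc$per_model_scores))
  expect_length(sc$per_model_scores, 5L)
  single <- scoreComplex(tm, one[1, ])
  expect_equal(single$complex_score, single$per_model_scores)
  mixed <- d[1:6, ]
  expect_error(scoreComplex(tm, mixed), class = "ppiGroupingError")
  # scoreTable agrees with per-complex max
  st <- scoreTable(tm, tab)
  expect_equal(st$score[st$complex_id == one$complex_id[1]],
               sc$complex_score)
})

test_that("rank AUC equals the concordant-pair count and handles ties", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T)), 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(18)
  for (rep in 1:10) {
    n <- 50
    s <- round(runif(n), 2)  # rounding forces ties
    l <- runif(n) > 0.5
    if (!any(l) || all(l)) next
    pos <- s[l]; neg <- s[!l]
    oracle <- 0
    for (p in pos) for (q in neg)
      oracle <- oracle + (p > q) + 0.5 * (p == q)
    expect_equal(rocAuc(s, l), oracle / (length(pos) * length(neg)))
  }
  expect_error(rocAuc(1:5, rep(TRUE, 5)), class = "ppiMetricError")
})

test_that("threshold table reproduces the boundary rows and F1 identity", {
  # balanced classes, threshold 0: everything called positive
  s <- c(runif(50, 0.5, 1), runif(50, 0, 0.5))
  l <- rep(c(TRUE, FALSE), each = 50)
  tt <- thresholdTable(s, l)
  row0 <- tt[tt$threshold == 0, ]
  expect_equal(row0$FPR, 1)
  expect_equal(row0$TPR, 1)
  expect_equal(row0$precision, 0.5)
  expect_equal(row0$F1, 2 / 3, tolerance = 1e-9)
  # above all scores: nothing called, precision reported as 1
  hi <- thresholdTable(s, l, thresholds = 2)
  expect_equal(hi$TPR, 0)
  expect_equal(hi$FPR, 0)
  expect_equal(hi$precision, 1)
  # F1 identity on every row
  for (i in seq_len(nrow(tt))) {
    p <- tt$precision[i]; r <- tt$recall[i]
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(tt$F1[i], f)
  }
  expect_equal(nrow(tt), 20L)  # default operating points
})

test_that("confidence baselines: iPTM passthrough and pDockQ behavior", {
  m <- fixDocked()
  conf <- fixConfident()
  im <- findInterface(m)
  b <- baselineScores(conf, m, im)
  expect_equal(unname(b["iptm"]), 0.8)
  # no contacts: closed form at x = 0
  ms <- fixSeparated()
  b0 <- baselineScores(makeConfidence(ms, "uncertain_interface",
                                      seed = 19L),
                       ms, findInterface(ms))
  expect_equal(unname(b0["pdockq"]),
               0.724 / (1 + exp(0.052 * 152.611)) + 0.018)
  # raising interface pLDDT raises pDockQ
  up <- ConfidenceBundle(pmin(plddt(conf) + 5, 100), pae(conf),
                         ptm(conf), iptm(conf))
  expect_gt(baselineScores(up, m, im)["pdockq"], b["pdockq"])
})
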