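test_that("confusion counts agree with a hand tally", {
  cm <- confusionMatrix3(c("I", "I", "D"), c("I", "D", "D"))
  expect_equal(cm["I", "I"], 1L)
  expect_equal(cm["I", "D"], 1L)
  expect_equal(cm["D", "D"], 1L)
  expect_equal(sum(cm), 3L)
  # perfect prediction is diagonal
  lab <- sample(c("I", "N", "D"), 30, TRUE)
  expect_equal(sum(confusionMatrix3(lab, lab)) -
                 sum(diag(confusionMatrix3(lab, lab))), 0L)
  expect_error(confusionMatrix3(c("I"), c("I", "N")), "length mismatch")
})

test_that("per-class metrics match an independent per-snapshot scan", {
  set.seed(8)
  actual <- sample(c("I", "N", "D"), 500, TRUE, prob = c(0.1, 0.2, 0.7))
  pred <- sample(c("I", "N", "D"), 500, TRUE, prob = c(0.2, 0.3, 0.5))
  m <- classMetrics(confusionMatrix3(actual, pred))
  for (cl in c("I", "N", "D")) {
    tp <- sum(actual == cl & pred == cl)
    fp <- sum(actual != cl & pred == cl)
    fn <- sum(actual == cl & pred != cl)
    r <- m[m$class == cl, ]
    expect_equal(r$precision, if (tp + fp) tp / (tp + fp) else 0)
    expect_equal(r$recall, if (tp + fn) tp / (tp + fn) else 0)
  }
  # counting identities
  expect_equal(m$tp + m$fn, as.integer(table(factor(actual, c("I", "N", "D")))),
               ignore_attr = TRUE)
  expect_equal(m$tp + m$fp, as.integer(table(factor(pred, c("I", "N", "D")))),
               ignore_attr = TRUE)
  # harmonic-mean identity and 0/0 convention
  expect_equal(classMetrics(matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 4L),
                                   3, 3))$f1[1], 0.5)
  none <- matrix(0L, 3, 3); none[3, 3] <- 5L
  expect_equal(classMetrics(none)$precision[1], 0)
  expect_equal(classMetrics(none)$f1[1], 0)
})

test_that("fold construction balances classes at the target level", {
  ts <- simulateTrajectories(syntheticConfig(n_targets = 14L,
                                             trajectories_per_target = 2L,
                                             steps_per_trajectory = 80L,
                                             seed = 10L))
  for (seed in c(1L, 7L, 33L)) {
    f <- buildFolds(ts, k = 7L, seed = seed)
    expect_setequal(f$target_id, targetIds(ts))
    expect_equal(sort(unique(f$fold)), 0:6)
    bal <- attr(f, "balance")
    diffs <- abs(as.matrix(bal[, 1:3]) - as.matrix(bal[, 4:6]))
    expect_lte(max(diffs), 6)
    # all trajectories of a target share its fold by construction
    merged <- merge(snapshotData(ts), f, by = "target_id")
    per_traj <- tapply(merged$fold, merged$trajectory_id,
                       function(x) length(unique(x)))
    expect_true(all(per_traj == 1L))
  }
  expect_error(buildFolds(ts, k = 20L), "fewer targets")
})

test_that("learning-curve selection agrees with a brute-force scan", {
  expect_equal(as.numeric(learningCurveSelect(1:40, window = 30L)), 40)
  # alternating curve: every window-2 mean ties at 0.5; the first complete
  # window wins under the first-max tie rule
  alt <- rep(c(0, 1), 10)
  expect_equal(as.numeric(learningCurveSelect(alt, window = 2L)), 2)
  set.seed(12)
  x <- runif(60)
  best <- learningCurveSelect(x, window = 10L)
  brute <- which.max(vapply(10:60, function(i) mean(x[(i - 9):i]),
                            numeric(1))) + 9L
  expect_equal(as.numeric(best), brute)
  expect_error(learningCurveSelect(1:5, window = 30L), "at least")
})

test_that("outcome-restricted CDFs follow the empirical distribution", {
  pred <- data.frame(
    label = c("I", "I", "I", "N"),
    predicted = c("I", "I", "N", "I"),
    delta_gdtts = c(0.02, 0.05, 0.03, 0.001),
    gdtts_ref = c(0.5, 0.6, 0.7, 0.4))
  tp <- cumulativeBy(pred, "delta_gdtts", "TP", "I")
  expect_equal(tp$x, c(0.02, 0.05))
  expect_equal(tp$cdf, c(0.5, 1))
  fn <- cumulativeBy(pred, "delta_gdtts", "FN", "I")
  expect_equal(fn$x, 0.03)
  expect_equal(fn$cdf, 1)
  fp <- cumulativeBy(pred, "delta_gdtts", "FP", "I")
  expect_equal(fp$x, 0.001)
  # CDF axioms
  expect_true(all(diff(tp$cdf) >= 0))
  expect_equal(tp$cdf[length(tp$cdf)], 1)
  expect_warning(out <- cumulativeBy(pred, "delta_gdtts", "FP", "D"), "no FP")
  expect_equal(nrow(out), 0)
})

test_that("assigned-probability histograms count the winning class", {
  pred <- data.frame(predicted = c("I", "I", "D"),
                     prob_I = c(0.52, 0.97, 0.1),
                     prob_N = c(0.3, 0.02, 0.1),
                     prob_D = c(0.18, 0.01, 0.8))
  h <- probabilityDensity(pred, "I")
  expect_equal(sum(h$count), 2L)
  expect_equal(h$count[h$mid == 0.525], 1L)
  expect_equal(h$count[h$mid == 0.975], 1L)
  expect_equal(sum(h$density) * 0.05, 1)
})

test_that("markov estimation matches hand counts and conventions", {
  feat <- matrix(0, 4, 19, dimnames = list(NULL, canonicalFeatures()))
  ts <- makeTrajectorySet(feat, "T1", "T1_r1", c(0L, 2L, 4L, 6L),
                          label = c("I", "I", "D", "D"))
  P <- estimateMarkov(ts)
  expect_equal(P["I", "I"], 0.5)
  expect_equal(P["I", "D"], 0.5)
  expect_equal(P["D", "D"], 1)
  expect_equal(attr(P, "flagged"), "N")
  expect_equal(P["N", ], rep(1 / 3, 3), ignore_attr = TRUE)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  # constant trajectory: identity-like row
  ts2 <- makeTrajectorySet(feat, "T1", "T1_r1", c(0L, 2L, 4L, 6L),
                           label = rep("N", 4))
  expect_equal(estimateMarkov(ts2)["N", "N"], 1)
  # transitions never span trajectory boundaries in the default mode
  ts3 <- makeTrajectorySet(rbind(feat, feat), rep("T1", 8),
                           rep(c("a", "b"), each = 4),
                           rep(c(0L, 2L, 4L, 6L), 2),
                           label = c(rep("I", 4), rep("D", 4)))
  P3 <- estimateMarkov(ts3)
  expect_equal(attr(P3, "counts")["I", "D"], 0L, ignore_attr = TRUE)
  P3c <- estimateMarkov(ts3, mode = "concatenated")
  expect_equal(attr(P3c, "counts")["I", "D"], 1L, ignore_attr = TRUE)
})

test_that("markov estimation recovers a known chain from simulation", {
  # direct simulation from a fixed chain, independent of the trajectory
  # generator's quality walk
  P <- defaultTransitionMatrix()
  set.seed(99)
  n <- 20000L
  s <- integer(n)
  s[1] <- 2L
  for (t in 2:n) s[t] <- sample.int(3L, 1L, prob = P[s[t - 1L], ])
  est <- estimateMarkov(list(stateLevels()[s]))
  counts <- attr(est, "counts")
  for (i in 1:3) {
    ni <- sum(counts[i, ])
    se <- sqrt(P[i, i] * (1 - P[i, i]) / ni)
    expect_lt(abs(est[i, i] - P[i, i]), 3 * se + 1e-12)
  }
})

test_that("segment lengths run-length encode each trajectory", {
  feat <- matrix(0, 5, 19, dimnames = list(NULL, canonicalFeatures()))
  ts <- makeTrajectorySet(feat, "T1", "T1_r1", seq(0L, 8L, 2L),
                          label = c("I", "I", "N", "D", "D"))
  seg <- segmentLengths(ts)
  expect_equal(seg$I, 2L)
  expect_equal(seg$N, 1L)
  expect_equal(seg$D, 2L)
  expect_equal(sum(unlist(seg)), nSnapshots(ts))
  h <- segmentHistogram(seg)
  expect_equal(h$count[h$class == "I" & h$length == 2], 1L)
  # single-label trajectory: one segment of full length
  ts2 <- makeTrajectorySet(feat, "T1", "T1_r1", seq(0L, 8L, 2L),
                          label = rep("D", 5))
  expect_equal(segmentLengths(ts2)$D, 5L)
})
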