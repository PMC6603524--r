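test_that("controller steps follow the start/stop rules", {
  st <- controllerState()
  # off, average below threshold: stay off
  r <- controllerStep(st, value = 0.1, threshold = 0.5)
  expect_equal(r$command, "NONE")
  expect_false(r$state$dbsOn)
  # off, far above threshold: start
  r <- controllerStep(st, value = 5, threshold = 0.5)
  expect_equal(r$command, "START")
  expect_true(r$state$dbsOn)
  # on, classifier says NT: stop (and the trigger disarms)
  r2 <- controllerStep(r$state, value = 5, threshold = 0.5,
                       classifierLabel = "NT")
  expect_equal(r2$command, "STOP")
  expect_false(r2$state$dbsOn)
  expect_false(r2$state$armed)
  # disarmed: the same high value does not re-start...
  r3 <- controllerStep(r2$state, value = 5, threshold = 0.5)
  expect_equal(r3$command, "NONE")
  # ...until the average has returned below the re-arm level
  r4 <- controllerStep(r2$state, value = -10, threshold = 0.5,
                       rearmThreshold = 0)
  expect_true(r4$state$armed)
  # on without a classifier is an error
  expect_error(controllerStep(r$state, 1, 0.5), "classifier")
  # buffer is FIFO with bounded length
  s <- controllerState()
  for (v in 1:7) s <- controllerStep(s, v, threshold = Inf,
                                     memoryWindows = 4)$state
  expect_equal(s$buffer, 4:7)
})

test_that("the closed loop starts in the transition and stops at rest", {
  rec <- generateRecording(scenarioSpec(seed = 42))
  res <- suppressWarnings(analyzeRecording(rec$lfp, NULL, rec$labels))
  tr <- runLoop(res$measures, res$bands$C, oracleClassifier(rec$labels))
  starts <- tr$time[tr$command == "START"]
  stops <- tr$time[tr$command == "STOP"]
  expect_gte(length(starts), 1)
  # commands alternate and START always precedes STOP
  cmds <- tr$command[tr$command != "NONE"]
  expect_true(all(cmds == rep(c("START", "STOP"), length.out = length(cmds))))
  # the first start falls after rest begins to transition (no earlier
  # than TO in this seed) and a stop follows the return to rest
  expect_gte(starts[1], 20)
  expect_lte(starts[1], 30.2)
  expect_true(any(stops >= 45))
  # replay is bit-identical
  tr2 <- runLoop(res$measures, res$bands$C, oracleClassifier(rec$labels))
  expect_identical(tr, tr2)
})

test_that("an always-tremor classifier never stops stimulating", {
  rec <- generateRecording(scenarioSpec(seed = 42))
  res <- suppressWarnings(analyzeRecording(rec$lfp, NULL, rec$labels))
  tr <- runLoop(res$measures, res$bands$C,
                function(f, t) "T")
  expect_gte(sum(tr$command == "START"), 1)
  expect_equal(sum(tr$command == "STOP"), 0)
  expect_true(all(tr$dbsOn[which(tr$command == "START")[1]:nrow(tr)]))
})

test_that("an all-rest recording with a calibrated loop never starts", {
  rec <- generateRecording(scenarioSpec(ntS = 30, toS = 0, tS = 0,
                                        postNtS = 0, seed = 77))
  res <- suppressWarnings(analyzeRecording(rec$lfp, NULL, rec$labels))
  # threshold far above any rest-state fluctuation (calibrated so the
  # trace logic, not chance, is under test)
  b <- res$bands$C
  b@sigma <- b@sigma * 50
  tr <- runLoop(res$measures, b, oracleClassifier(rec$labels))
  expect_equal(sum(tr$command == "START"), 0)
})

test_that("validity arithmetic and identities are exact", {
  r <- validityFromCounts(tp = 9, fn = 1, tn = 8, fp = 2)
  v <- validityTable(r)
  expect_equal(v$Sensitivity, 90)
  expect_equal(v$Specificity, 80)
  expect_equal(v$FPR, 20)
  expect_equal(v$FNR, 10)
  expect_equal(v$ACC, 85)
  # identities hold exactly for arbitrary counts
  set.seed(31)
  for (i in 1:20) {
    cts <- sample(0:50, 4, replace = TRUE) + 1
    r <- validityFromCounts(cts[1], cts[2], cts[3], cts[4])
    v <- validityTable(r)
    expect_identical(v$FPR, 100 - v$Specificity)
    expect_identical(v$FNR, 100 - v$Sensitivity)
  }
})

test_that("well-separated classes give a clean stop classifier", {
  set.seed(61)
  n <- 60
  featNT <- matrix(rnorm(n * 3, mean = 0, sd = 0.3), ncol = 3)
  featT <- matrix(rnorm(n * 3, mean = 5, sd = 0.3), ncol = 3)
  feats <- rbind(featNT, featT)
  colnames(feats) <- c("C", "T", "A")
  labs <- rep(c("NT", "T"), each = n)
  fit <- trainStopClassifier(feats, labs, seed = 2)
  v <- validityTable(fit$report)
  expect_equal(v$Specificity, 100)
  expect_equal(v$FPR, 0)
  expect_gte(v$ACC, 99)
  expect_equal(fit$report@positiveClass, "T")
  # the fitted model predicts fresh points correctly
  expect_equal(fit$predictFn(matrix(c(5, 5, 5), 1)), "T")
  expect_equal(fit$predictFn(matrix(c(0, 0, 0), 1)), "NT")
})

test_that("indistinguishable classes score near chance", {
  set.seed(62)
  feats <- matrix(rnorm(400 * 3), ncol = 3)
  labs <- rep(c("NT", "T"), each = 200)
  fit <- trainStopClassifier(feats, labs, seed = 3)
  expect_lt(abs(validityTable(fit$report)$ACC - 50), 12)
})

test_that("classifier training enforces its preconditions", {
  feats <- matrix(rnorm(40), ncol = 2)
  expect_error(trainStopClassifier(feats, rep("T", 20)), "two classes")
  expect_error(trainStopClassifier(feats, c(rep("NT", 15), rep("T", 5))),
               "10 samples")
  expect_error(trainStopClassifier(feats, rep(c("NT", "TO"), 10)),
               "NT or T")
})

test_that("the onset classifier swaps the class roles", {
  set.seed(63)
  n <- 40
  feats <- rbind(matrix(rnorm(n * 2, 0, 0.4), ncol = 2),
                 matrix(rnorm(n * 2, 3, 0.4), ncol = 2))
  labs <- rep(c("NT", "TO"), each = n)
  fit <- trainOnsetClassifier(feats, labs, seed = 4)
  expect_equal(fit$report@positiveClass, "NT")
  v <- validityTable(fit$report)
  expect_identical(v$FPR, 100 - v$Specificity)
  expect_gte(v$ACC, 95)
})

test_that("block CV keeps folds contiguous", {
  set.seed(64)
  feats <- matrix(rnorm(200 * 2), ncol = 2)
  labs <- rep(c("NT", "T"), each = 100)
  fit <- trainStopClassifier(feats, labs, folds = 5, blockCV = TRUE)
  expect_equal(length(unique(fit$cvFold)), 5L)
  expect_true(all(diff(fit$cvFold) >= 0))   # contiguous blocks in order
})
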