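test_that("subspace distances are Euclidean, symmetric and oracle-exact", {
  x <- matrix(c(0, 3, 1, 0, 4, 1), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  ds <- QsarSet(x, activity = c(1, 2, 3), scaled = TRUE)
  both <- descriptorSubset(1:2)
  expect_equal(pairwiseDistance(ds, 1, 2, both), 5)            # 3-4-5 triangle
  expect_equal(pairwiseDistance(ds, 2, 2, both), 0)
  expect_equal(pairwiseDistance(ds, 1, 2, both),
               pairwiseDistance(ds, 2, 1, both))
  expect_error(pairwiseDistance(ds, 1, 2, descriptorSubset(c(1, 5))),
               "out of range")

  ds6 <- randomQsar(6, 5, seed = 11)
  sub <- descriptorSubset(c(1, 3, 5))
  xm <- descriptorMatrix(ds6)
  for (i in 1:6) for (j in 1:6)
    expect_equal(pairwiseDistance(ds6, i, j, sub),
                 naiveDistance(xm, i, j, c(1, 3, 5)), tolerance = 1e-12)
})

test_that("nearest neighbours are sorted, tie-broken by index, oracle-exact", {
  x <- matrix(c(0, 1, 2), dimnames = list(NULL, "d"))
  ds <- QsarSet(x, activity = c(1, 2, 3), scaled = TRUE)
  s1 <- descriptorSubset(1)
  nn <- nearestNeighbors(ds, 1, s1, 1)
  expect_equal(nn$index, 2L)
  expect_equal(nn$distance, 1)

  # exact tie: compounds 2 and 3 both at distance 1 from compound 1
  xt <- matrix(c(0, 1, -1), dimnames = list(NULL, "d"))
  dst <- QsarSet(xt, activity = c(1, 2, 3), scaled = TRUE)
  tied <- nearestNeighbors(dst, 1, s1, 2)
  expect_equal(tied$index, c(2L, 3L))                           # lower index first

  ds15 <- randomQsar(15, 6, seed = 4)
  sub <- descriptorSubset(c(2, 4, 6))
  xm <- descriptorMatrix(ds15)
  for (target in c(1, 7, 15)) {
    got <- nearestNeighbors(ds15, target, sub, 4)
    pool <- setdiff(1:15, target)
    d <- vapply(pool, function(j) naiveDistance(xm, target, j, c(2, 4, 6)),
                numeric(1))
    ord <- order(d, pool)[1:4]
    expect_equal(got$index, pool[ord])
    expect_equal(got$distance, d[ord], tolerance = 1e-12)
  }
  expect_error(nearestNeighbors(ds15, 1, sub, 15), "pool")
  excl <- nearestNeighbors(ds15, 1, sub, 3, excluded = 2:10)
  expect_true(all(excl$index %in% 11:15))
})

test_that("weighted prediction follows the exp(-distance) softmax contract", {
  expect_equal(weightedPrediction(7, 123), 7)                   # single neighbour
  expect_equal(weightedPrediction(c(2, 4), c(1.3, 1.3)), 3)     # symmetry
  acts <- c(1, 2, 3); dists <- c(0.1, 0.5, 2.0)
  expect_equal(weightedPrediction(acts, dists),
               naiveWeightedPrediction(acts, dists), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(5); d <- runif(5, 0, 3)
    p <- weightedPrediction(a, d)
    expect_equal(p, naiveWeightedPrediction(a, d), tolerance = 1e-12)
    expect_gte(p, min(a)); expect_lte(p, max(a))               # boundedness
  }
  # large distances: stabilized weights must not underflow to 0/0
  expect_equal(weightedPrediction(c(1, 2), c(1000, 1001)),
               naiveWeightedPrediction(c(1, 2), c(0, 1)), tolerance = 1e-12)
  expect_error(weightedPrediction(numeric(0), numeric(0)), "at least one")
  expect_error(weightedPrediction(1:2, 1), "equal length")
  expect_error(weightedPrediction(1:2, c(-1, 1)), "non-negative")
})

test_that("nearer neighbours receive strictly greater weight", {
  # two neighbours with activities 1 and 0: prediction > 0.5 iff the
  # activity-1 neighbour carries the larger weight
  set.seed(31)
  for (i in 1:20) {
    r <- sort(runif(2, 0, 5))
    expect_gt(weightedPrediction(c(1, 0), r), 0.5)
    expect_lt(weightedPrediction(c(0, 1), r), 0.5)
  }
})

test_that("q-squared satisfies its analytic identities", {
  a <- c(1, 2, 3, 4)
  expect_equal(qSquared(a, a), 1)
  expect_equal(qSquared(a, rep(mean(a), 4)), 0)
  expect_equal(qSquared(a, c(1.1, 1.9, 3.2, 3.8)), 0.98, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    act <- rnorm(8); pred <- rnorm(8)
    expect_lte(qSquared(act, pred), 1)
    expect_equal(qSquared(act, pred), naiveQ2(act, pred), tolerance = 1e-12)
  }
  expect_error(qSquared(rep(2, 4), 1:4), "identical")
  expect_error(qSquared(1:3, 1:2), "equal length")
})

test_that("leave-one-out predictions match the naive double-loop oracle", {
  sim <- simulateQsar(nCompounds = 12, nInformative = 3, nNoise = 3,
                      noiseSd = 0.2, seed = 8)
  ds <- rangeScale(sim$dataset)$dataset
  xm <- descriptorMatrix(ds)
  act <- unname(activity(ds))
  for (idx in list(c(1, 2, 3), c(2, 5), 1:6)) {
    res <- looPredict(ds, descriptorSubset(idx), 3)
    expect_equal(unname(res@predictions), naiveLoo(xm, act, idx, 3),
                 tolerance = 1e-12)
    expect_equal(res@residuals, activity(ds) - res@predictions)
    expect_equal(res@q2, naiveQ2(act, unname(res@predictions)),
                 tolerance = 1e-12)
  }
})

test_that("LOO degenerate cases behave analytically", {
  # constant activity: every prediction is the constant; q2 undefined
  ds <- randomQsar(8, 3, seed = 6)
  dsc <- QsarSet(descriptorMatrix(ds), activity = rep(4.2, 8), scaled = TRUE)
  expect_warning(res <- looPredict(dsc, descriptorSubset(1:3), 2),
                 "constant")
  expect_equal(unname(res@predictions), rep(4.2, 8))
  expect_true(is.na(res@q2))

  # duplicated rows: the zero-distance twin makes k = 1 LOO exact
  tw <- makeTwinFixture(nPairs = 4, nDescriptors = 3, seed = 9)
  res1 <- looPredict(tw, descriptorSubset(1:3), 1)
  expect_identical(unname(res1@predictions), unname(activity(tw)))
  expect_identical(res1@q2, 1)
})

test_that("LOO predictions are bounded by the neighbour activity range", {
  ds <- randomQsar(20, 6, seed = 13)
  res <- looPredict(ds, descriptorSubset(c(1, 4, 6)), 4)
  expect_true(all(res@predictions >= min(activity(ds))))
  expect_true(all(res@predictions <= max(activity(ds))))
})

test_that("q-squared is invariant under affine activity maps and row permutation", {
  ds <- randomQsar(18, 5, seed = 17)
  sub <- descriptorSubset(c(2, 3, 5))
  base <- looPredict(ds, sub, 3)
  aff <- QsarSet(descriptorMatrix(ds), activity = -2.5 * activity(ds) + 7,
                 scaled = TRUE)
  resAff <- looPredict(aff, sub, 3)
  expect_equal(resAff@q2, base@q2, tolerance = 1e-12)
  expect_equal(unname(resAff@predictions),
               -2.5 * unname(base@predictions) + 7, tolerance = 1e-12)

  set.seed(18)
  perm <- sample(18)
  per <- QsarSet(descriptorMatrix(ds)[perm, ], activity = activity(ds)[perm],
                 scaled = TRUE)
  resPer <- looPredict(per, sub, 3)
  expect_equal(unname(resPer@predictions), unname(base@predictions)[perm],
               tolerance = 1e-12)
  expect_equal(resPer@q2, base@q2, tolerance = 1e-12)
})

test_that("the k sweep picks the argmax q-squared with ties to smaller k", {
  tw <- makeTwinFixture(nPairs = 5, nDescriptors = 4, seed = 3)
  sw <- sweepK(tw, descriptorSubset(1:4), 5)
  expect_equal(sw$k, 1L)
  expect_identical(sw$result@q2, 1)

  small <- randomQsar(4, 3, seed = 7)
  expect_message(swc <- sweepK(small, descriptorSubset(1:3), 5), "clamped")
  expect_equal(nrow(swc$table), 3L)                             # kMax clamped to 3

  ds <- randomQsar(16, 6, seed = 19)
  sw2 <- sweepK(ds, descriptorSubset(c(1, 2, 6)), 5)
  # recompute every swept q2 independently
  for (k in 1:5) {
    ref <- looPredict(ds, descriptorSubset(c(1, 2, 6)), k)
    expect_equal(sw2$table$q2[k], ref@q2, tolerance = 1e-12)
  }
  expect_equal(sw2$k, sw2$table$k[which.max(sw2$table$q2)])
  expect_equal(sw2$result@q2, max(sw2$table$q2))
})

test_that("fitted models score external compounds against the full reference", {
  sim <- simulateQsar(nCompounds = 14, nInformative = 2, nNoise = 4,
                      noiseSd = 0.1, seed = 23)
  sc <- rangeScale(sim$dataset)
  sub <- descriptorSubset(1:3)
  loo <- looPredict(sc$dataset, sub, 1)
  model <- methods::new("KnnModel", subset = sub, k = 1L,
                        reference = sc$dataset, scaling = sc$params,
                        q2 = loo@q2)

  # a reference compound re-submitted: k = 1 self-match returns its activity
  pred <- predict(model, sim$dataset)
  expect_equal(unname(pred), unname(activity(sc$dataset)), tolerance = 1e-12)

  # empty new data -> empty vector
  empty <- descriptorMatrix(sim$dataset)[0, , drop = FALSE]
  expect_length(predict(model, empty), 0)

  # no-exclusion scoring oracle on a clone of the reference
  model3 <- methods::new("KnnModel", subset = sub, k = 3L,
                         reference = sc$dataset, scaling = sc$params,
                         q2 = loo@q2)
  got <- predict(model3, sim$dataset)
  xm <- descriptorMatrix(sc$dataset)
  act <- unname(activity(sc$dataset))
  for (i in seq_len(nrow(xm))) {
    d <- vapply(seq_len(nrow(xm)),
                function(j) naiveDistance(xm, i, j, 1:3), numeric(1))
    ord <- order(d, seq_along(d))[1:3]
    expect_equal(unname(got[i]), naiveWeightedPrediction(act[ord], d[ord]),
                 tolerance = 1e-12)
  }

  wrongCols <- descriptorMatrix(sim$dataset)[, c(2, 1, 3:6)]
  expect_error(predict(model, wrongCols), "match")
})
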