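dupDb <- function() {
  # every vector duplicated within its class: each left-out point's twin is
  # its nearest neighbor
  base <- rbind(c(0, 0), c(5, 5), c(9, 1))
  raw <- base[rep(1:3, each = 2), ]
  referenceFromMatrix(raw, paste0("p", 1:6),
                      rep(c("A", "B", "C"), each = 2))
}

test_that("leave-one-out on duplicated vectors is perfect at k = 1", {
  db <- dupDb()
  res <- looAccuracy(db, k = 1)
  expect_equal(accuracy(res), 1)
  expect_equal(nrow(perProtein(res)), 6L)
  expect_false(anyDuplicated(perProtein(res)$proteinId) > 0)
})

test_that("a singleton class is necessarily misclassified under LOO", {
  base <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(9, 1))
  db <- referenceFromMatrix(base, paste0("p", 1:5),
                            c("A", "A", "B", "B", "LONER"))
  res <- looAccuracy(db, k = 1)
  expect_equal(accuracy(res), 4 / 5)
  pp <- perProtein(res)
  expect_false(pp$predictedClass[pp$trueClass == "LONER"] == "LONER")
})

test_that("well-separated synthetic clusters classify perfectly", {
  set.seed(21)
  a <- matrix(rnorm(20 * 3, 0, 0.05), 20)
  b <- matrix(rnorm(20 * 3, 10, 0.05), 20)
  db <- referenceFromMatrix(rbind(a, b), paste0("p", 1:40),
                            rep(c("A", "B"), each = 20))
  expect_equal(accuracy(looAccuracy(db, k = 1)), 1)
  # brute-force check of a few scenarios: nearest foreign point is far
  nm <- normMatrix(db)
  for (i in c(1, 25)) {
    d <- rowSums(abs(sweep(nm[-i, ], 2, nm[i, ])))
    expect_equal(unname(classLabels(db)[-i][which.min(d)]),
                 unname(classLabels(db)[i]))
  }
})

test_that("LOO is deterministic across repeated runs", {
  db <- rfeFixture(seed = 5)
  r1 <- looAccuracy(db, k = 2, measure = "braycurtis")
  r2 <- looAccuracy(db, k = 2, measure = "braycurtis")
  expect_identical(perProtein(r1), perProtein(r2))
})

test_that("the sweep covers the full grid with values in [0, 1]", {
  db <- dupDb()
  grid <- accuracySweep(db, ks = 1:3,
                        measures = c("manhattan", "chebyshev", "braycurtis"))
  expect_equal(nrow(grid), 9L)
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  expect_true(all(grid$accuracy[grid$k == 1] == 1))
})

test_that("identical vectors across classes fall to the tie rule uniformly", {
  raw <- matrix(1, 4, 2)
  db <- referenceFromMatrix(raw, paste0("p", 1:4), c("A", "B", "A", "B"))
  # every distance is 0; k = 1 picks the first eligible reference by
  # insertion order: p1 -> p2 (B), and p2, p3, p4 all -> p1 (A), so only
  # p3 is classified correctly
  res <- looAccuracy(db, k = 1)
  expect_equal(perProtein(res)$predictedClass, c("B", "A", "A", "A"))
  expect_equal(accuracy(res), 1 / 4)
  for (m in c("manhattan", "euclidean", "chebyshev"))
    expect_equal(accuracy(looAccuracy(db, k = 1, measure = m)), 1 / 4)
})

test_that("RFE removes a separation-destroying noise attribute first", {
  set.seed(31)
  n <- 20
  cls <- rep(c("A", "B"), each = n / 2)
  informative <- ifelse(cls == "A", 0.2, 0.8) + rnorm(n, 0, 0.02)
  noise <- runif(n)
  db <- referenceFromMatrix(cbind(informative, noise),
                            paste0("p", 1:n), cls)
  res <- rfeRank(db, k = 1)
  expect_equal(eliminationOrder(res), 2L)
  expect_equal(optimalSubset(res), 1L)
  expect_equal(utils::tail(accuracyTrace(res), 1), 1)
  expect_gte(utils::tail(accuracyTrace(res), 1), baselineAccuracy(res))
})

test_that("RFE requires >= 2 attributes and honors the strict stop rule", {
  db <- rfeFixture(seed = 3)
  activeAttributes(db) <- 1L
  expect_error(rfeRank(db), "at least two")

  # copies of one attribute: every removal is accuracy-neutral, so the
  # non-strict rule prunes to a single attribute and the strict rule stops
  # immediately
  raw <- matrix(rep(c(0.1, 0.9), each = 3), 6, 4)
  db2 <- referenceFromMatrix(raw, paste0("p", 1:6),
                             rep(c("A", "B"), each = 3))
  rNon <- rfeRank(db2, k = 1)
  expect_equal(length(optimalSubset(rNon)), 1L)
  expect_true(all(accuracyTrace(rNon) == baselineAccuracy(rNon)))
  rStrict <- rfeRank(db2, k = 1, stopRule = "strict")
  expect_equal(length(eliminationOrder(rStrict)), 0L)
  expect_equal(sort(c(optimalSubset(rStrict), eliminationOrder(rStrict))),
               1:4)
})

test_that("RFE accuracy trace is non-decreasing up to the stop", {
  db <- rfeFixture(seed = 9)
  res <- rfeRank(db, k = 1, measure = "manhattan")
  tr <- c(baselineAccuracy(res), accuracyTrace(res))
  expect_true(all(diff(tr) >= 0))
  expect_equal(sort(c(optimalSubset(res), eliminationOrder(res))),
               sort(activeAttributes(db)))
})

test_that("attribute scores are counts over optimal subsets with min ranks", {
  mk <- function(keep) methods::new("RfeResult",
    eliminationOrder = setdiff(1:18, keep), optimalSubset = as.integer(keep),
    accuracyTrace = numeric(length(setdiff(1:18, keep))),
    baselineAccuracy = 0.5, k = 1L, distanceMeasure = "manhattan")
  res <- list(mk(c(1, 2)), mk(c(1, 3)), mk(c(1, 2)), mk(c(1, 4)))
  sc <- attributeScore(res)
  expect_equal(sc$score[1], 1)
  expect_equal(sc$rank[1], 1)
  expect_equal(sc$score[2], 0.5)
  expect_equal(sc$score[5], 0)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # invariant to the order of the results
  sc2 <- attributeScore(rev(res))
  expect_equal(sc2, sc)
})

test_that("a 126-of-150 retention count scores 0.84", {
  mkKeep <- function(keep) methods::new("RfeResult",
    eliminationOrder = setdiff(1:18, keep), optimalSubset = as.integer(keep),
    accuracyTrace = numeric(length(setdiff(1:18, keep))),
    baselineAccuracy = 0.5, k = 1L, distanceMeasure = "manhattan")
  res <- c(replicate(126, mkKeep(c(15, 1))),
           replicate(24, mkKeep(1)))
  sc <- attributeScore(res)
  expect_equal(sc$score[15], 0.84)
  expect_equal(sc$score[1], 1)
  expect_equal(sc$rank[1], 1)
})
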