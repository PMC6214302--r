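# Ternary matching, prediction arrays, the deterministic action chooser,
# accuracy, generality, insertion, covering, crossover, mutation and the
# rule-set / parameter file formats.

test_that("ternary conditions match states through # wildcards", {
  expect_true(conditionMatches("0101110101", "0101110101"))
  expect_true(conditionMatches("1111##0001", "1111000001"))
  expect_false(conditionMatches("1###", "0111"))
  expect_identical(conditionMatches(c("##", "01", "1#"), "01"),
                   c(TRUE, TRUE, FALSE))
  expect_error(conditionMatches("01", "011"), "length")
})

test_that("the prediction array is the fitness-weighted mean per action", {
  pop <- rbind(classifier("##", 2L, prediction = 100, fitness = 1),
               classifier("##", 3L, prediction = 100, fitness = 0.5),
               classifier("#1", 3L, prediction = 200, fitness = 0.5),
               classifier("1#", 0L, prediction = 0, fitness = 1),
               classifier("11", 0L, prediction = 1000, fitness = 3))
  pa <- predictionArray(pop, seq_len(nrow(pop)))
  expect_equal(pa[["2"]], 100)
  expect_equal(pa[["3"]], 150)
  expect_equal(pa[["0"]], 750)
  # zero total fitness falls back to the unweighted mean
  z <- rbind(classifier("##", 1L, prediction = 10, fitness = 0),
             classifier("##", 1L, prediction = 30, fitness = 0))
  expect_equal(predictionArray(z, 1:2)[["1"]], 20)
  expect_length(predictionArray(pop, integer(0L)), 0L)
})

test_that("the action chooser exploits above 500 and explores at or below", {
  expect_identical(selectAction(c("4" = 600, "1" = 100)), 4L)
  expect_identical(selectAction(c("1" = 700, "2" = 700)), 1L)  # tie-break
  set.seed(12)
  picks <- replicate(200, selectAction(c("0" = 400, "3" = 100, "5" = 250)))
  expect_setequal(unique(picks), c(0L, 3L, 5L))   # explores uniformly
  set.seed(12)
  boundary <- replicate(100, selectAction(c("1" = 500, "2" = 10)))
  expect_true(length(unique(boundary)) > 1L)      # exactly 500 -> explore
  expect_identical(selectAction(c("2" = 100, "5" = 90), greedy = TRUE), 2L)
  expect_error(selectAction(setNames(numeric(0), character(0))), "empty")
})

test_that("classifier accuracy is 1 below eps0 and decays by the power law", {
  p <- xcsParams()
  expect_identical(classifierAccuracy(10, p), 1)
  expect_equal(classifierAccuracy(p$eps0, p), p$alpha)
  expect_equal(classifierAccuracy(37, p), 0.087 * 2^(-0.01), tolerance = 1e-12)
  # non-increasing in the error
  eps <- seq(0, 100, by = 0.5)
  expect_true(all(diff(classifierAccuracy(eps, p)) <= 1e-12))
})

test_that("the payoff target discounts the best current prediction", {
  expect_equal(computeTargetP(0, c("1" = 1000), 0.76), 760)
  expect_equal(computeTargetP(500, numeric(0), 0.76), 500)
})

test_that("strict generality requires more #s, literal agreement and the action", {
  expect_true(isMoreGeneral(list(condition = "##", action = 1),
                            list(condition = "01", action = 1)))
  expect_false(isMoreGeneral(list(condition = "01", action = 1),
                             list(condition = "##", action = 1)))
  expect_false(isMoreGeneral(list(condition = "#1", action = 1),
                             list(condition = "#1", action = 1)))
  expect_false(isMoreGeneral(list(condition = "##", action = 1),
                             list(condition = "01", action = 2)))
  expect_false(isMoreGeneral(list(condition = "#0#", action = 1),
                             list(condition = "011", action = 1)))
})

test_that("insertion merges identical rules and grows the micro count", {
  pop <- classifier("01#", 2L)
  before <- microCount(pop)
  dup <- insertClassifier(pop, classifier("01#", 2L))
  expect_identical(nrow(dup), 1L)
  expect_identical(microCount(dup), before + 1L)
  novel <- insertClassifier(pop, classifier("###", 0L))
  expect_identical(nrow(novel), 2L)
  expect_identical(microCount(novel), before + 1L)
})

test_that("covering copies the state, hashes with P#, and avoids present actions", {
  p0 <- xcsParams(pHash = 0)
  cl <- coverClassifier("10110", c(0L, 2L, 3L), p0)
  expect_identical(cl$condition, "10110")
  expect_true(cl$action %in% c(1L, 4L, 5L))
  expect_identical(cl$prediction, 7.4)
  expect_identical(cl$error, 1.0)
  expect_identical(cl$fitness, 0.03)
  expect_identical(cl$numerosity, 1L)
  expect_identical(cl$experience, 0L)
  p1 <- xcsParams(pHash = 1)
  expect_identical(coverClassifier("10110", 0:4, p1)$condition, "#####")
  expect_error(coverClassifier("101", 0:3, p0), "exhausted")
})

test_that("two-point crossover swaps the characters between the cuts", {
  expect_identical(crossoverTwoPoint("00000", "11111", cuts = c(1, 3)),
                   list("01100", "10011"))
  expect_identical(crossoverTwoPoint("0#1", "1#0", cuts = c(0, 3)),
                   list("1#0", "0#1"))
  expect_identical(crossoverTwoPoint("0101", "1010", cuts = c(2, 2)),
                   list("0101", "1010"))
  set.seed(4)
  for (rep in 1:20) {
    out <- crossoverTwoPoint("00#01", "11#10")
    merged <- paste0(out[[1L]], out[[2L]])
    # children are a permutation of the parents, position by position
    expect_identical(sort(strsplit(merged, "")[[1L]]),
                     sort(strsplit("00#0111#10", "")[[1L]]))
  }
})

test_that("niche mutation toggles against the situation and keeps the match", {
  p0 <- xcsParams(mu = 0)
  expect_identical(mutateClassifier("1#110", 2L, "10110", p0),
                   list(condition = "1#110", action = 2L))
  p1 <- xcsParams(mu = 1)
  set.seed(8)
  m <- mutateClassifier("1#110", 2L, "10110", p1)
  expect_identical(m$condition, "#0###")
  expect_false(m$action == 2L)
  set.seed(9)
  for (rep in 1:25) {
    m <- mutateClassifier("##0#1", 3L, "10011", xcsParams(mu = 0.5))
    expect_true(conditionMatches(m$condition, "10011"))
    expect_true(m$action %in% 0:5)
  }
})

test_that("rule-set files round-trip at 2/4 decimal precision", {
  pop <- rbind(classifier("####1", 2L, prediction = 174.823, fitness = 0.91051),
               classifier("#0#1#", 0L, prediction = 100.4, fitness = 1),
               classifier("11111", 5L, prediction = 7.4, fitness = 0.03))
  path <- withr::local_tempfile(fileext = ".txt")
  writeRuleset(pop, path)
  expect_identical(readLines(path)[1L], "####1 : 2 [174.82/0.9105]")
  back <- readRuleset(path)
  expect_identical(back$condition, pop$condition)
  expect_identical(back$action, pop$action)
  expect_equal(back$prediction, round(pop$prediction, 2L))
  expect_equal(back$fitness, round(pop$fitness, 4L))
  expect_error(readRuleset(textConnection("bad line")))
})

test_that("parameter files round-trip with the ASCII names", {
  p <- xcsParams(popSize = 400, gamma = 0.5, thetaSub = 20)
  path <- withr::local_tempfile(fileext = ".txt")
  writeParams(p, path)
  back <- readParams(path)
  expect_equal(unclass(back), unclass(p))
  expect_error(xcsParams(useNewActionChooser = FALSE), "not implemented")
  expect_error(xcsParams(gamma = 1.5), "gamma")
})
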