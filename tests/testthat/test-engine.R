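# The stateful engine operations: match-set building with covering,
# reinforcement updates, the GA, subsumption and capacity deletion.

pars5 <- function(...) xcsParams(...)

test_that("covering fills the match set up to thetaMna distinct actions", {
  p <- pars5()
  res <- buildMatchSet(newPopulation(5L), "10101", p)
  pop <- res$population
  ms <- pop[res$matchSet, ]
  expect_gte(length(unique(ms$action)), p$thetaMna)
  expect_identical(anyDuplicated(ms$action), 0L)  # never duplicates an action
  expect_true(all(conditionMatches(ms$condition, "10101")))
  expect_true(all(ms$prediction == p$predictionInit))
  expect_true(all(ms$error == p$errorInit))
  expect_true(all(ms$fitness == p$fitnessInit))
})

test_that("no covering occurs when every action is already represented", {
  pop <- do.call(rbind, lapply(0:5, function(a) classifier("#####", a)))
  res <- buildMatchSet(pop, "00000", pars5())
  expect_identical(nrow(res$population), 6L)
  expect_identical(sort(res$matchSet), 1:6)
})

test_that("the match set equals a brute-force filter of the population", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(3:7, 1L)
    pop <- randomPopulation(40L, n)
    state <- paste(sample(c("0", "1"), n, replace = TRUE), collapse = "")
    res <- buildMatchSet(pop, state, pars5(), covering = FALSE)
    expect_identical(res$population$condition, pop$condition)
    expect_identical(sort(res$matchSet),
                     which(conditionMatches(pop$condition, state)))
  }
})

test_that("reinforcement updates follow the two-tier MAM rule", {
  p <- pars5()
  pop <- classifier("#####", 2L, prediction = 7.4, error = 1, fitness = 0.03)
  u1 <- updateActionSet(pop, 1L, 1000, p)
  expect_equal(u1$population$prediction, 1000)       # experience 1 replaces
  expect_equal(u1$population$error, abs(1000 - 7.4)) # error uses old p
  expect_identical(u1$population$experience, 1L)
  u2 <- updateActionSet(u1$population, 1L, 500, p)
  expect_equal(u2$population$prediction, 750)        # averaging at exp 2
  # past 1/beta, a zero-error step leaves the prediction unchanged
  old <- classifier("#####", 2L, prediction = 1000, error = 5,
                    experience = 200L)
  u3 <- updateActionSet(old, 1L, 1000, p)
  expect_equal(u3$population$prediction, 1000)
  expect_equal(u3$population$error, 5 * (1 - p$beta))
})

test_that("the set-size estimate tracks the action set numerosity sum", {
  p <- pars5()
  pop <- rbind(classifier("#####", 2L, numerosity = 3L),
               classifier("##1##", 2L, numerosity = 5L))
  u <- updateActionSet(pop, 1:2, 100, p)
  expect_equal(u$population$actionSetSize, c(8, 8))  # exp 1: replaced by sum
})

test_that("fitness moves towards the numerosity-weighted relative accuracy", {
  p <- pars5(doActionSetSubsumption = FALSE)
  pop <- rbind(classifier("#####", 1L, error = 1, fitness = 0.5,
                          numerosity = 1L, experience = 200L),
               classifier("####1", 1L, error = 100, fitness = 0.5,
                          numerosity = 1L, experience = 200L))
  u <- updateActionSet(pop, 1:2, 100, p)$population
  # accurate classifier gains fitness share, inaccurate one loses it
  expect_gt(u$fitness[1L], u$fitness[2L])
  k2 <- classifierAccuracy(u$error[2L], p)
  k1 <- 1
  expect_equal(u$fitness,
               0.5 + p$beta * (c(k1, k2) / (k1 + k2) - 0.5),
               tolerance = 1e-9)
})

test_that("action-set subsumption absorbs less general rules, conserving micros", {
  p <- pars5()
  pop <- rbind(classifier("##1##", 4L, error = 1, experience = 40L,
                          numerosity = 2L),
               classifier("00100", 4L, numerosity = 3L),
               classifier("0#100", 4L, numerosity = 1L),
               classifier("#####", 3L, numerosity = 1L))
  before <- microCount(pop)
  res <- actionSetSubsumption(pop, 1:3, p)
  out <- res$population
  expect_identical(microCount(out), before)
  expect_false("00100" %in% out$condition)
  expect_false("0#100" %in% out$condition)
  expect_identical(out$numerosity[out$condition == "##1##"], 2L + 3L + 1L)
  expect_identical(sort(out$condition[res$actionSet]), "##1##")
  # no eligible subsumer (inexperienced or inaccurate) -> no-op
  young <- rbind(classifier("##1##", 4L, error = 1, experience = 5L),
                 classifier("00100", 4L))
  res2 <- actionSetSubsumption(young, 1:2, p)
  expect_identical(nrow(res2$population), 2L)
  inaccurate <- rbind(classifier("##1##", 4L, error = 50, experience = 40L),
                      classifier("00100", 4L))
  res3 <- actionSetSubsumption(inaccurate, 1:2, p)
  expect_identical(nrow(res3$population), 2L)
})

test_that("deletion is a no-op under capacity and removes one micro when over", {
  p <- pars5(popSize = 10L)
  pop <- rbind(classifier("#####", 1L, numerosity = 4L),
               classifier("####1", 2L, numerosity = 6L))
  expect_identical(deleteToCapacity(pop, p)$numerosity, c(4L, 6L))
  over <- rbind(classifier("#####", 1L, numerosity = 4L),
                classifier("####1", 2L, numerosity = 7L))
  set.seed(2)
  out <- deleteToCapacity(over, p)
  expect_identical(microCount(out), 10L)
})

test_that("experienced low-fitness classifiers are deleted preferentially", {
  # equal set-size votes; the unfit experienced rule's vote is inflated by
  # meanFitness / (fitness/numerosity), which dwarfs the fit rule's vote
  p <- pars5(popSize = 1L, thetaDel = 20, delta = 0.1)
  pop <- rbind(classifier("#####", 1L, fitness = 1, numerosity = 1L,
                          experience = 50L, actionSetSize = 10),
               classifier("####1", 2L, fitness = 1e-9, numerosity = 1L,
                          experience = 50L, actionSetSize = 10))
  set.seed(6)
  out <- deleteToCapacity(pop, p)
  expect_identical(out$condition, "#####")
})

test_that("the GA respects its activation threshold", {
  p <- pars5()
  pop <- rbind(classifier("10101", 1L, fitness = 0.5, timeStamp = 0L),
               classifier("1010#", 1L, fitness = 0.5, timeStamp = 0L))
  res <- runGA(pop, 1:2, "10101", time = 100L, p)   # gap 100 < thetaGa 260
  expect_false(res$triggered)
  expect_identical(nrow(res$population), 2L)
  set.seed(13)
  res2 <- runGA(pop, 1:2, "10101", time = 300L, p)  # gap 300 > 260
  expect_true(res2$triggered)
  expect_true(all(res2$population$timeStamp[1:2] == 300L))
})

test_that("with chi = mu = 0 the GA clones members and merging absorbs them", {
  p <- pars5(chi = 0, mu = 0)
  pop <- rbind(classifier("10#01", 2L, prediction = 100, error = 1,
                          fitness = 0.4, numerosity = 2L, experience = 50L),
               classifier("1##01", 2L, prediction = 200, error = 2,
                          fitness = 0.6, numerosity = 1L, experience = 50L))
  before <- microCount(pop)
  set.seed(19)
  res <- runGA(pop, 1:2, "10001", time = 1000L, p)
  out <- res$population
  expect_true(res$triggered)
  # children are copies of the parents: no new macroclassifiers appear,
  # total numerosity grows by exactly the two children
  expect_setequal(out$condition, pop$condition)
  expect_identical(microCount(out), before + 2L)
})

test_that("GA children always match the situation they were bred in", {
  p <- pars5()
  set.seed(29)
  for (rep in 1:10) {
    pop <- rbind(classifier("10#0#", 2L, fitness = 0.5, experience = 10L),
                 classifier("1###1", 2L, fitness = 0.5, experience = 10L))
    res <- runGA(pop, 1:2, "10001", time = 1000L, p)
    expect_true(all(conditionMatches(res$population$condition, "10001") |
                      res$population$condition %in% pop$condition))
  }
})

test_that("the population never exceeds capacity after engine operations", {
  p <- pars5(popSize = 25L)
  pop <- newPopulation(5L)
  set.seed(37)
  time <- 0L
  for (i in 1:30) {
    state <- paste(sample(c("0", "1"), 5, replace = TRUE), collapse = "")
    res <- buildMatchSet(pop, state, p, time = time)
    pop <- res$population
    expect_lte(microCount(pop), p$popSize)
    as_idx <- res$matchSet[pop$action[res$matchSet] ==
                             pop$action[res$matchSet][1L]]
    upd <- updateActionSet(pop, as_idx, runif(1, 0, 1000), p)
    pop <- upd$population
    if (length(upd$actionSet)) {
      ga <- runGA(pop, upd$actionSet, state, time = time, p)
      pop <- ga$population
    }
    expect_lte(microCount(pop), p$popSize)
    time <- time + 50L
  }
})
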