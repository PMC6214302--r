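# The control environment: tasks, the reinforcement program, environment
# transitions, trials and whole-state-space evaluation.

xorCycleTask <- function(maxSteps = 100L)
  controlTask(motifNetwork("XOR"), c("011", "110", "101"), maxSteps)

xorPointTask <- function(maxSteps = 100L)
  controlTask(motifNetwork("XOR"), "000", maxSteps)

test_that("control tasks validate the target against the mapped attractors", {
  expect_s3_class(xorPointTask(), "control_task")
  expect_s3_class(xorCycleTask(), "control_task")
  expect_error(controlTask(motifNetwork("XOR"), "010"), "not an attractor")
  expect_error(controlTask(motifNetwork("AND"), c("000", "111")),
               "not an attractor")
})

test_that("the reward is 1000 (steps - interventions) / steps on success, else 0", {
  expect_equal(trialReward(4, 1, TRUE), 750)
  expect_equal(trialReward(17, 0, TRUE), 1000)
  expect_equal(trialReward(50, 12, FALSE), 0)
  set.seed(15)
  for (rep in 1:50) {
    s <- sample(1:100, 1L)
    i <- sample(0:s, 1L)
    r <- trialReward(s, i, TRUE)
    expect_gte(r, 0)
    expect_lte(r, 1000)
    expect_identical(r == 1000, i == 0L)
  }
  expect_error(trialReward(0, 0, TRUE), "at least one step")
  expect_error(trialReward(3, 4, TRUE), "interventions")
})

test_that("environment steps count interventions plus the natural update", {
  task <- xorCycleTask()
  s <- environmentStep(task, "000", 1)
  expect_identical(s$state, "110")
  expect_identical(s$steps, 2L)
  expect_identical(s$interventions, 1L)
  andTask <- controlTask(motifNetwork("AND"), "000")
  s2 <- environmentStep(andTask, "101", 0)
  expect_identical(s2$state, "100")
  expect_identical(s2$steps, 1L)
  expect_identical(s2$interventions, 0L)
})

test_that("a fixed flip-node-1 policy reaches the XOR cycle in one intervention", {
  task <- xorCycleTask()
  pop <- classifier("###", 1L, prediction = 600, error = 0, fitness = 1)
  res <- runTrial(task, pop, xcsParams(thetaMna = 4L), learning = FALSE,
                  start = "000")
  expect_true(res$reached)
  expect_identical(res$steps, 2L)          # intervention + natural update
  expect_identical(res$interventions, 1L)
  # every decision cycle of this trial intervened, so the reinforcement
  # program pays nothing: 1000 * (1 - 1) / 1
  expect_equal(res$reward, 0)
  expect_equal(trialReward(res$steps - res$interventions,
                           res$interventions, res$reached), res$reward)
  expect_identical(res$trajectory, c("000", "110"))
})

test_that("the natural AND trajectory earns the full reward", {
  task <- controlTask(motifNetwork("AND"), "000")
  pop <- classifier("###", 0L, prediction = 600, error = 0, fitness = 1)
  res <- runTrial(task, pop, xcsParams(thetaMna = 4L), learning = FALSE,
                  start = "101")
  expect_true(res$reached)
  expect_identical(res$steps, 2L)
  expect_identical(res$interventions, 0L)
  expect_equal(res$reward, 1000)
  expect_identical(res$trajectory, c("101", "100", "000"))
})

test_that("trials that hit the step cap fail with reward zero", {
  # target {111} of the AND motif has a basin of itself only; never flipping
  # can therefore never reach it from 000
  task <- controlTask(motifNetwork("AND"), "111", maxSteps = 40L)
  pop <- classifier("###", 0L, prediction = 600, error = 0, fitness = 1)
  res <- runTrial(task, pop, xcsParams(thetaMna = 4L), learning = FALSE,
                  start = "000")
  expect_false(res$reached)
  expect_equal(res$reward, 0)
  expect_gte(res$steps, 40L)
})

test_that("start states inside the target cycle are rejected and not sampled", {
  task <- xorPointTask()
  pop <- classifier("###", 0L)
  expect_error(runTrial(task, pop, xcsParams(thetaMna = 4L), start = "000"),
               "inside the target")
  set.seed(44)
  for (rep in 1:10) {
    res <- runTrial(task, pop, xcsParams(thetaMna = 4L), learning = FALSE)
    expect_false(res$trajectory[1L] %in% task$target)
  }
})

test_that("the published six-rule controller covers the cycle-to-point task", {
  task <- xorPointTask()
  rules <- rbind(classifier("110", 3L, 600, 0, 1),
                 classifier("011", 1L, 600, 0, 1),
                 classifier("101", 2L, 600, 0, 1),
                 classifier("001", 3L, 600, 0, 1),
                 classifier("010", 2L, 600, 0, 1),
                 classifier("100", 1L, 600, 0, 1))
  ev <- evaluateAllStates(task, rules)
  expect_true(ev$covered)
  expect_equal(ev$avgInterventions, 6 / 7)
  expect_equal(ev$avgSteps, 13 / 7)
  # 111 reaches 000 naturally (no matching rule -> action 0)
  row111 <- ev$states[ev$states$start == "111", ]
  expect_identical(row111$interventions, 0L)
  expect_identical(row111$steps, 1L)
})

test_that("a single wildcard rule covers the point-to-cycle task", {
  task <- xorCycleTask()
  ev <- evaluateAllStates(task, classifier("###", 1L, 600, 0, 1))
  expect_true(ev$covered)
  # the two cycle-basin states 000 and 111 both need one intervention
  expect_true(all(ev$states$reached))
})

test_that("an unmatched ruleset fails coverage when the target is not global", {
  task <- xorPointTask()
  ev <- evaluateAllStates(task, newPopulation(3L))
  expect_false(ev$covered)
  # states in the fixed point's own basin still arrive naturally
  expect_true(ev$states$reached[ev$states$start == "111"])
})

test_that("greedy evaluation is deterministic and idempotent", {
  task <- xorPointTask()
  set.seed(3)
  pop <- randomPopulation(20L, 3L, actions = 0:3)
  a <- evaluateAllStates(task, pop)
  b <- evaluateAllStates(task, pop)
  expect_identical(a$states, b$states)
})

test_that("evaluation reports serialise as TSV with a summary row", {
  task <- xorPointTask()
  ev <- evaluateAllStates(task, classifier("###", 0L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEvaluationReport(ev, path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(names(tab), c("start", "reached", "steps", "interventions"))
  expect_identical(nrow(tab), nrow(ev$states) + 1L)
  expect_identical(tab$start[nrow(tab)], "AVERAGE")
})
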