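# Coupling the classifier engine to a Boolean network: control tasks,
# the reinforcement program, trials, training and evaluation.

#' Define an attractor-control task
#'
#' A task pairs a network with a target attractor: the controller must steer
#' the network from any start state into the target cycle.  The target is
#' validated against the exhaustively mapped state space.
#'
#' @param net a [booleanNetwork()].
#' @param target character vector: the states of one attractor's cycle.
#' @param maxSteps trial cap; a trial that has not reached the target within
#'   this many counted steps is truncated with reward 0.
#' @return an object of class `control_task`.
#' @examples
#' task <- controlTask(motifNetwork("XOR"), "000")
#' @export
controlTask <- function(net, target, maxSteps = 100L) {
  stopifnot(inherits(net, "boolean_network"))
  target <- as.character(target)
  for (s in target) assertState(s, net$n)
  ss <- mapStateSpace(net)
  ok <- any(vapply(ss$attractors, function(cyc) setequal(cyc, target),
                   logical(1L)))
  if (!ok)
    stop("target is not an attractor of the network: {",
         paste(target, collapse = ", "), "}")
  if (length(target) == 2L^net$n)
    stop("target attractor covers the whole state space; nothing to control")
  structure(list(network = net, target = target,
                 maxSteps = as.integer(maxSteps), n = net$n),
            class = "control_task")
}

#' @export
print.control_task <- function(x, ...) {
  cat(sprintf(
    "Control task: %d-node network, target cycle {%s}, max %d steps/trial\n",
    x$n, paste(x$target, collapse = " -> "), x$maxSteps))
  invisible(x)
}

#' Reward of the reinforcement program
#'
#' On reaching the target attractor the reward is
#' `1000 * (steps - interventions) / steps`; a trial that does not reach the
#' target earns 0.  The reward is 1000 exactly when the target was reached
#' without any intervention.
#'
#' `steps` here is the reinforcement program's own counter, incremented once
#' per reward calculation — i.e. once per decision cycle, equal to the number
#' of natural updates of the trial.  The trial ledger reported by
#' [runTrial()] additionally counts each intervention as a step (that
#' combined count is what the AS statistic reports), so in ledger terms the
#' reward argument is `ledger steps - interventions`.  A trial whose every
#' cycle intervened therefore earns 0.
#'
#' @param steps the reinforcement program's step count (decision cycles).
#' @param interventions number of non-zero actions taken.
#' @param reached whether a target state was reached.
#' @return the reward, in `[0, 1000]`.
#' @examples
#' trialReward(4, 1, TRUE)   # 750
#' trialReward(10, 3, FALSE) # 0
#' @export
trialReward <- function(steps, interventions, reached) {
  if (any(interventions > steps) || any(steps < 0) || any(interventions < 0))
    stop("need 0 <= interventions <= steps")
  if (any(reached & steps == 0))
    stop("a reached trial must have at least one step")
  ifelse(reached, 1000 * (steps - interventions) / steps, 0)
}

#' One environment transition
#'
#' A non-zero action flips the chosen bit and is immediately followed by one
#' natural synchronous update (2 counted steps, 1 intervention); action 0
#' performs the natural update alone (1 counted step, no intervention).
#'
#' @param task a [controlTask()].
#' @param state current bit string.
#' @param action integer in `[0, N]`.
#' @return list with `state` (the post-update state), `steps` and
#'   `interventions` (the counter increments).
#' @examples
#' task <- controlTask(motifNetwork("XOR"), c("011", "110", "101"))
#' environmentStep(task, "000", 1)  # flip -> 100, update -> 110
#' @export
environmentStep <- function(task, state, action) {
  stopifnot(inherits(task, "control_task"))
  assertState(state, task$n)
  action <- as.integer(action)
  intervened <- action != 0L
  state <- flipBit(state, action)
  state <- networkStep(task$network, state)
  list(state = state, steps = if (intervened) 2L else 1L,
       interventions = if (intervened) 1L else 0L)
}

nonTargetStates <- function(task) {
  setdiff(allStates(task$n), task$target)
}

#' Run a single trial
#'
#' One trial of the sense-match-predict-act-reward cycle, from a start state
#' until the target attractor is reached or `maxSteps` is exceeded.  In
#' learning mode the population is updated (covering, reinforcement updates
#' of the previous action set against the discounted current prediction, GA
#' trigger checks, and a final update of the terminal action set with the
#' trial payoff); with `learning = FALSE` the rules are applied greedily and
#' unchanged, and a state matched by no rule takes action 0.
#'
#' @param task a [controlTask()].
#' @param pop an `xcs_population`.
#' @param params an [xcsParams()] object.
#' @param learning update the population?
#' @param start start state; when `NULL`, drawn uniformly from the states
#'   outside the target cycle.
#' @param time global step counter carried across trials (stamps covering and
#'   GA activity).
#' @return list with the updated `population`, the ledger (`steps`,
#'   `interventions`, `reached`, `reward`), the advanced `time` and the
#'   `trajectory` of visited states.
#' @export
runTrial <- function(task, pop, params, learning = TRUE, start = NULL,
                     time = 0L) {
  stopifnot(inherits(task, "control_task"))
  pop <- asPopulation(pop, task$n)
  if (is.null(start)) {
    pool <- nonTargetStates(task)
    start <- pool[sample.int(length(pool), 1L)]
  }
  assertState(start, task$n)
  if (start %in% task$target)
    stop("start state lies inside the target cycle")
  cpp_run_trial(task$network, task$target, pop, params, isTRUE(learning),
                start, task$maxSteps, as.integer(time))
}

#' Train a controller by repeated learning trials
#'
#' Runs learning trials with uniformly random start states outside the
#' target cycle.  After `minTrials` trials, and every `evalInterval` trials
#' thereafter, the population is evaluated greedily from every start state;
#' training stops as soon as an evaluation covers the state space with no
#' failures, or at `hardCeiling` trials (reported as an unsuccessful run,
#' population still returned).
#'
#' @param task a [controlTask()].
#' @param params an [xcsParams()] object.
#' @param minTrials trials before the first evaluation (default 250,000).
#' @param evalInterval trials between subsequent evaluations (default
#'   10,000).
#' @param hardCeiling absolute trial limit.
#' @return an object of class `xcs_training`: list with `population`, `log`
#'   (one row per evaluation checkpoint), `success`, `trials` and `time`.
#' @export
runTraining <- function(task, params = xcsParams(), minTrials = 250000L,
                        evalInterval = 10000L, hardCeiling = 1000000L) {
  stopifnot(inherits(task, "control_task"), inherits(params, "xcs_params"))
  minTrials <- as.integer(minTrials)
  evalInterval <- as.integer(evalInterval)
  hardCeiling <- as.integer(hardCeiling)
  if (minTrials < 1L || evalInterval < 1L || hardCeiling < minTrials)
    stop("need minTrials >= 1, evalInterval >= 1, hardCeiling >= minTrials")
  res <- cpp_run_training(task$network, task$target, params, minTrials,
                          evalInterval, task$maxSteps, hardCeiling)
  structure(res, class = "xcs_training")
}

#' @export
print.xcs_training <- function(x, ...) {
  cat(sprintf("XCS training: %d trials, %s\n", x$trials,
              if (x$success) "state space covered" else "NOT covered"))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf(
      "  last checkpoint: trial %d, avg steps %.3f, avg interventions %.3f\n",
      last$trial, last$avgSteps, last$avgInterventions))
  }
  cat(sprintf("  population: %d macro / %d micro classifiers\n",
              nrow(x$population), microCount(x$population)))
  invisible(x)
}

#' Evaluate a rule set from every start state
#'
#' Runs a greedy, non-learning trial from every state outside the target
#' cycle, restricted to the given rules; a state matched by no rule takes
#' action 0.  The task is covered when every start reaches the target within
#' `maxSteps`; average steps and interventions are taken over the start
#' states outside the target cycle.
#'
#' @param task a [controlTask()].
#' @param pop the rule set to evaluate (an `xcs_population`).
#' @param params an [xcsParams()] object (only the chooser semantics are
#'   used).
#' @param maxSteps per-trial cap; defaults to the task's.
#' @return an object of class `evaluation_report`: list with `states` (one
#'   row per start: `start`, `reached`, `steps`, `interventions`,
#'   `trajectory`), `covered`, `avgSteps` and `avgInterventions`.
#' @export
evaluateAllStates <- function(task, pop, params = xcsParams(),
                              maxSteps = task$maxSteps) {
  stopifnot(inherits(task, "control_task"))
  pop <- asPopulation(pop, task$n)
  df <- cpp_evaluate_all_states(task$network, task$target, pop, params,
                                as.integer(maxSteps))
  structure(list(states = df, covered = all(df$reached),
                 avgSteps = mean(df$steps),
                 avgInterventions = mean(df$interventions)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation over %d start states: %s; avg steps %.3f, avg interventions %.3f\n",
    nrow(x$states), if (x$covered) "covered" else
      sprintf("NOT covered (%d failures)", sum(!x$states$reached)),
    x$avgSteps, x$avgInterventions))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Per-state columns (`start`, `reached`, `steps`, `interventions`) followed
#' by a summary row.
#'
#' @param report an [evaluateAllStates()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- report$states[c("start", "reached", "steps", "interventions")]
  df$start <- as.character(df$start)
  summary <- data.frame(start = "AVERAGE", reached = report$covered,
                        steps = round(report$avgSteps, 3L),
                        interventions = round(report$avgInterventions, 3L),
                        stringsAsFactors = FALSE)
  write.table(rbind(df, summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
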