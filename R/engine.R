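# R surface over the compiled XCS engine.  These wrappers run exactly the
# code the trainer uses, so unit tests exercise the production path.

#' Build the match set for a state, covering as needed
#'
#' Returns all macroclassifiers whose condition matches the state.  With
#' `covering = TRUE`, while the number of DISTINCT actions represented is
#' below `thetaMna`, covering classifiers are created (see
#' [coverClassifier()]), inserted into the population with capacity
#' enforcement, and the match set is rebuilt.  Covering never duplicates an
#' action already present.
#'
#' @param pop an `xcs_population`.
#' @param state bit string.
#' @param params an [xcsParams()] object.
#' @param time current step counter (stamped on covered classifiers).
#' @param covering disable to get a plain match (used in evaluation mode).
#' @return list with the updated `population` and `matchSet` (integer row
#'   indices into it).
#' @export
buildMatchSet <- function(pop, state, params, time = 0L, covering = TRUE) {
  pop <- asPopulation(pop, nchar(state))
  assertState(state, nchar(state))
  stopifnot(inherits(params, "xcs_params"))
  if (covering && params$thetaMna > nchar(state) + 1L)
    stop("thetaMna exceeds the number of available actions (N + 1)")
  cpp_build_match_set(pop, state, params, as.integer(time), covering)
}

#' Reinforcement update of an action set
#'
#' For each member: experience is incremented; prediction error, prediction
#' and action-set-size estimate are updated by the two-tier rule (incremental
#' averaging while experience is below `1/beta`, Widrow-Hoff with rate `beta`
#' afterwards), the error moving towards `|P - prediction|` (computed before
#' the prediction update) and the set-size estimate towards the action set's
#' numerosity sum.  Fitness then receives a plain rate-`beta` update towards
#' the classifier's share of the set's numerosity-weighted accuracy.  When
#' `doActionSetSubsumption` is set, action-set subsumption runs afterwards.
#'
#' @param pop an `xcs_population`.
#' @param actionSet integer row indices of the action set.
#' @param P the payoff target (see [computeTargetP()]).
#' @param params an [xcsParams()] object.
#' @return list with the updated `population` and `actionSet` (indices of the
#'   surviving members).
#' @export
updateActionSet <- function(pop, actionSet, P, params) {
  pop <- asPopulation(pop)
  actionSet <- as.integer(actionSet)
  if (length(actionSet) == 0L) stop("action set is empty")
  stopifnot(all(actionSet >= 1L), all(actionSet <= nrow(pop)))
  cpp_update_action_set(pop, actionSet, P, params)
}

#' Run the genetic algorithm on an action set
#'
#' Fires only when `time` minus the numerosity-weighted mean GA time stamp of
#' the set exceeds `thetaGa`; all members are then stamped with `time`.  Two
#' parents are chosen by fitness-proportionate roulette; the two children
#' (numerosity 1, experience 0) undergo two-point crossover with probability
#' `chi` and niche mutation, and inherit the parents' mean prediction, error
#' and fitness.  With `doGaSubsumption`, an experienced accurate parent that
#' is more general than a child absorbs it (numerosity + 1) instead of the
#' child being inserted; duplicates merge on insertion and roulette deletion
#' restores the capacity bound.
#'
#' @param pop an `xcs_population`.
#' @param actionSet integer row indices of the action set.
#' @param situation the state the action set was formed in.
#' @param time current step counter.
#' @param params an [xcsParams()] object.
#' @return list with the updated `population` and `triggered` (logical).
#' @export
runGA <- function(pop, actionSet, situation, time, params) {
  pop <- asPopulation(pop, nchar(situation))
  assertState(situation, nchar(situation))
  actionSet <- as.integer(actionSet)
  stopifnot(all(actionSet >= 1L), all(actionSet <= nrow(pop)))
  cpp_run_ga(pop, actionSet, situation, as.integer(time), params)
}

#' Action-set subsumption
#'
#' The most general eligible member (experience above `thetaSub`, error below
#' `eps0`; ties by most `#` symbols, then earliest) absorbs every strictly
#' less general member of the set: the victim is removed from the population
#' and its numerosity added to the subsumer, conserving the micro count.
#'
#' @inheritParams updateActionSet
#' @return list with the updated `population` and `actionSet`.
#' @export
actionSetSubsumption <- function(pop, actionSet, params) {
  pop <- asPopulation(pop)
  actionSet <- as.integer(actionSet)
  stopifnot(all(actionSet >= 1L), all(actionSet <= nrow(pop)))
  cpp_action_set_subsumption(pop, actionSet, params)
}

#' Enforce the population capacity by roulette deletion
#'
#' While the micro-classifier count exceeds `popSize`, one micro-classifier
#' is removed by roulette over deletion votes.  A classifier's vote is its
#' action-set-size estimate times its numerosity; experienced classifiers
#' whose per-micro fitness falls below `delta` times the population mean have
#' their vote inflated by the ratio of the mean to their per-micro fitness.
#'
#' @param pop an `xcs_population`.
#' @param params an [xcsParams()] object.
#' @return the updated population (micro count at most `popSize`).
#' @export
deleteToCapacity <- function(pop, params) {
  pop <- asPopulation(pop)
  stopifnot(inherits(params, "xcs_params"))
  cpp_delete_to_capacity(pop, params)
}
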