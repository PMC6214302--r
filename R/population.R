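# Classifier populations: ternary condition-action rules with the XCS
# bookkeeping statistics (prediction, error, fitness, numerosity,
# experience, action-set-size estimate, GA time stamp).
#
# A population is a data.frame of MACROclassifiers: rows are unique
# (condition, action) pairs and `numerosity` counts the identical
# micro-classifiers each row represents.

popCols <- c("condition", "action", "prediction", "error", "fitness",
             "numerosity", "experience", "actionSetSize", "timeStamp")

assertCondition <- function(condition) {
  if (any(grepl("[^01#]", condition)))
    stop("conditions may only contain the characters 0, 1 and #")
  invisible(condition)
}

#' Create an empty classifier population
#'
#' @param conditionLength length N of the ternary conditions (equal to the
#'   number of network nodes).
#' @return an `xcs_population`: a data.frame with columns `condition`,
#'   `action`, `prediction`, `error`, `fitness`, `numerosity`, `experience`,
#'   `actionSetSize` and `timeStamp`.
#' @export
newPopulation <- function(conditionLength) {
  df <- data.frame(condition = character(0L), action = integer(0L),
                   prediction = numeric(0L), error = numeric(0L),
                   fitness = numeric(0L), numerosity = integer(0L),
                   experience = integer(0L), actionSetSize = numeric(0L),
                   timeStamp = integer(0L), stringsAsFactors = FALSE)
  structure(df, class = c("xcs_population", "data.frame"),
            conditionLength = as.integer(conditionLength))
}

#' Construct a single classifier (one-row population)
#'
#' @param condition ternary string over \{0, 1, #\}.
#' @param action integer action (0 = no action, i = flip node i).
#' @param prediction,error,fitness payoff prediction, prediction error and
#'   accuracy-based fitness.
#' @param numerosity,experience,actionSetSize,timeStamp bookkeeping values.
#' @return a one-row `xcs_population`.
#' @export
classifier <- function(condition, action, prediction = 7.4, error = 1.0,
                       fitness = 0.03, numerosity = 1L, experience = 0L,
                       actionSetSize = 1, timeStamp = 0L) {
  assertCondition(condition)
  df <- data.frame(condition = condition, action = as.integer(action),
                   prediction = prediction, error = error, fitness = fitness,
                   numerosity = as.integer(numerosity),
                   experience = as.integer(experience),
                   actionSetSize = as.numeric(actionSetSize),
                   timeStamp = as.integer(timeStamp),
                   stringsAsFactors = FALSE)
  structure(df, class = c("xcs_population", "data.frame"),
            conditionLength = nchar(condition[1L]))
}

# normalise column types before handing a population to the C++ engine
asPopulation <- function(pop, conditionLength = NULL) {
  if (is.null(conditionLength))
    conditionLength <- attr(pop, "conditionLength")
  pop <- as.data.frame(pop, stringsAsFactors = FALSE)
  missing <- setdiff(popCols, names(pop))
  if (length(missing))
    stop("population is missing column(s): ", paste(missing, collapse = ", "))
  pop <- pop[popCols]
  pop$condition <- as.character(pop$condition)
  assertCondition(pop$condition)
  for (cl in c("action", "numerosity", "experience", "timeStamp"))
    pop[[cl]] <- as.integer(pop[[cl]])
  for (cl in c("prediction", "error", "fitness", "actionSetSize"))
    pop[[cl]] <- as.numeric(pop[[cl]])
  if (is.null(conditionLength) && nrow(pop) > 0L)
    conditionLength <- nchar(pop$condition[1L])
  if (nrow(pop) > 0L && any(nchar(pop$condition) != conditionLength))
    stop("all conditions must have the same length")
  rownames(pop) <- NULL
  structure(pop, class = c("xcs_population", "data.frame"),
            conditionLength = as.integer(conditionLength))
}

#' Total micro-classifier count of a population
#'
#' @param pop an `xcs_population`.
#' @return the sum of numerosities.
#' @export
microCount <- function(pop) sum(as.integer(pop$numerosity))

#' Ternary condition matching
#'
#' A condition matches a state when, at every index, the condition character
#' equals the state bit or is the `#` don't-care symbol.
#'
#' @param condition character vector of ternary conditions.
#' @param state a single bit string of the same length.
#' @return logical vector, one entry per condition.
#' @examples
#' conditionMatches(c("1111##0001", "1###"), "1111000001")
#' @export
conditionMatches <- function(condition, state) {
  assertCondition(condition)
  n <- nchar(state)
  if (any(nchar(condition) != n))
    stop("condition and state lengths differ")
  sv <- strsplit(state, "")[[1L]]
  vapply(strsplit(condition, ""), function(cc) all(cc == "#" | cc == sv),
         logical(1L))
}

#' Fitness-weighted prediction array
#'
#' For every action advocated in the match set, the fitness-weighted mean of
#' the advocates' payoff predictions; actions with no supporting classifier
#' are absent.  If all supporting fitnesses are zero the unweighted mean is
#' used.
#'
#' @param pop an `xcs_population`.
#' @param matchSet integer row indices of the match set within `pop`.
#' @return named numeric vector (names are action indices).
#' @export
predictionArray <- function(pop, matchSet) {
  ms <- pop[matchSet, , drop = FALSE]
  if (nrow(ms) == 0L) return(setNames(numeric(0L), character(0L)))
  out <- vapply(split(ms, ms$action), function(g) {
    if (sum(g$fitness) > 0) sum(g$prediction * g$fitness) / sum(g$fitness)
    else mean(g$prediction)
  }, numeric(1L))
  out[order(as.integer(names(out)))]
}

#' Select an action from a prediction array
#'
#' The deterministic chooser: in greedy mode (evaluation) always take the
#' action with the highest predicted payoff; otherwise exploit only when the
#' best prediction exceeds 500 and explore (uniform over the represented
#' actions) when it is 500 or less.  Argmax ties break to the smallest
#' action index.
#'
#' @param pa a named [predictionArray()].
#' @param greedy force exploitation.
#' @return the selected action (integer).
#' @export
selectAction <- function(pa, greedy = FALSE) {
  if (length(pa) == 0L) stop("no action available: empty prediction array")
  acts <- as.integer(names(pa))
  best <- acts[which.max(pa)]  # which.max takes the first (smallest) on ties
  if (greedy || max(pa) > 500) return(best)
  if (length(acts) == 1L) acts else sample(acts, 1L)
}

#' Payoff target for the previous action set
#'
#' `P = prevReward + gamma * max(pa)`; on the terminal step of a trial the
#' target is the current payoff alone (pass an empty array).
#'
#' @param prevReward payoff obtained on the previous step.
#' @param pa the current [predictionArray()] (may be empty).
#' @param gamma discount factor.
#' @return the payoff target `P`.
#' @export
computeTargetP <- function(prevReward, pa, gamma) {
  prevReward + gamma * if (length(pa)) max(pa) else 0
}

#' Classifier accuracy
#'
#' `kappa = 1` while the error is below the threshold `eps0`, and
#' `alpha * (error / eps0)^-nu` beyond it.
#'
#' @param error prediction error(s), non-negative.
#' @param params an [xcsParams()] object.
#' @return accuracy value(s) in (0, 1].
#' @export
classifierAccuracy <- function(error, params) {
  stopifnot(all(error >= 0))
  ifelse(error < params$eps0, 1,
         params$alpha * (error / params$eps0)^(-params$nu))
}

#' Strict generality comparison
#'
#' `general` is more general than `specific` when both advocate the same
#' action, `general` has strictly more `#` symbols, and every literal of
#' `general` equals `specific`'s character at that position.
#'
#' @param general,specific lists (or one-row populations) with elements
#'   `condition` and `action`.
#' @return `TRUE` or `FALSE`.
#' @export
isMoreGeneral <- function(general, specific) {
  g <- as.list(general)
  s <- as.list(specific)
  if (nchar(g$condition) != nchar(s$condition))
    stop("conditions must have the same length")
  if (as.integer(g$action) != as.integer(s$action)) return(FALSE)
  gc <- strsplit(g$condition, "")[[1L]]
  sc <- strsplit(s$condition, "")[[1L]]
  if (sum(gc == "#") <= sum(sc == "#")) return(FALSE)
  all(gc == "#" | gc == sc)
}

#' Insert a classifier into a population
#'
#' If a macroclassifier with the identical (condition, action) pair exists
#' its numerosity is incremented by the inserted numerosity; otherwise the
#' classifier is appended.  The micro-classifier count always grows by the
#' inserted numerosity; capacity is enforced separately by
#' [deleteToCapacity()].
#'
#' @param pop an `xcs_population`.
#' @param cl a one-row population (e.g. from [classifier()]).
#' @return the updated population.
#' @export
insertClassifier <- function(pop, cl) {
  pop <- asPopulation(pop)
  cl <- asPopulation(cl, attr(pop, "conditionLength"))
  stopifnot(nrow(cl) == 1L)
  hit <- which(pop$condition == cl$condition & pop$action == cl$action)
  if (length(hit)) {
    pop$numerosity[hit[1L]] <- pop$numerosity[hit[1L]] + cl$numerosity
    return(pop)
  }
  asPopulation(rbind(as.data.frame(pop), as.data.frame(cl)),
               attr(pop, "conditionLength"))
}

#' Create a covering classifier
#'
#' The condition starts as an exact copy of the state; each character then
#' independently becomes `#` with probability `pHash`.  The action is drawn
#' uniformly from the actions not yet present in the match set, and the
#' statistics are initialised to `predictionInit`, `errorInit` and
#' `fitnessInit`.
#'
#' @param state the current network state (bit string).
#' @param presentActions integer vector of actions already represented.
#' @param params an [xcsParams()] object.
#' @param time current step counter (stored as the GA time stamp).
#' @return a one-row `xcs_population`.
#' @export
coverClassifier <- function(state, presentActions, params, time = 0L) {
  assertState(state, nchar(state))
  stopifnot(inherits(params, "xcs_params"))
  presentActions <- as.integer(presentActions)
  if (length(presentActions) &&
      (min(presentActions) < 0L || max(presentActions) > nchar(state)))
    stop("present actions must lie in [0, N]")
  cpp_cover(state, presentActions, params, as.integer(time))
}

#' Two-point crossover of two conditions
#'
#' Two cut indices `x <= y` are drawn uniformly in `[0, N]` and the
#' characters in `[x, y)` (0-based) are exchanged.
#'
#' @param cond1,cond2 ternary conditions of equal length.
#' @param cuts optional integer vector `c(x, y)` fixing the cut points
#'   (mainly for testing); drawn randomly when `NULL`.
#' @return list of the two recombined conditions.
#' @examples
#' crossoverTwoPoint("00000", "11111", cuts = c(1, 3))
#' @export
crossoverTwoPoint <- function(cond1, cond2, cuts = NULL) {
  assertCondition(c(cond1, cond2))
  if (nchar(cond1) != nchar(cond2)) stop("conditions must have equal length")
  if (!is.null(cuts)) {
    cuts <- as.integer(cuts)
    if (length(cuts) != 2L || any(cuts < 0L) || any(cuts > nchar(cond1)))
      stop("cuts must be two indices in [0, N]")
  }
  cpp_crossover(cond1, cond2, cuts)
}

#' Niche mutation of a classifier
#'
#' At each condition index, with probability `mu`, a `#` becomes the
#' situation's bit and a literal becomes `#`; with probability `mu` the
#' action is replaced by a uniformly chosen different action.  The mutated
#' condition therefore always still matches the situation.
#'
#' @param condition ternary condition.
#' @param action current action.
#' @param situation the state (bit string) the parent was selected in.
#' @param params an [xcsParams()] object.
#' @return list with elements `condition` and `action`.
#' @export
mutateClassifier <- function(condition, action, situation, params) {
  assertCondition(condition)
  assertState(situation, nchar(condition))
  cpp_mutate(condition, as.integer(action), situation, params)
}

#' Read / write a rule-set file
#'
#' One rule per line in the format `<condition> : <action>
#' [<prediction>/<fitness>]`, e.g. `####1 : 2 [174.82/0.9105]`.  Predictions
#' are written with 2 and fitnesses with 4 decimal places; a written file
#' parses back to the same values at that precision.  Statistics not carried
#' by the format (numerosity, experience, error, ...) are initialised to
#' neutral values on read; rule files are intended for greedy evaluation of
#' a finished controller, not for resuming training.
#'
#' @param pop an `xcs_population`.
#' @param path file path.
#' @return `writeRuleset()` returns `path` invisibly; `readRuleset()` an
#'   `xcs_population`.
#' @export
writeRuleset <- function(pop, path) {
  pop <- asPopulation(pop)
  writeLines(sprintf("%s : %d [%.2f/%.4f]", pop$condition, pop$action,
                     pop$prediction, pop$fitness), path)
  invisible(path)
}

#' @rdname writeRuleset
#' @export
readRuleset <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  pat <- "^([01#]+)\\s*:\\s*(\\d+)\\s*\\[([0-9.eE+-]+)/([0-9.eE+-]+)\\]$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, integer(1L)) != 5L
  if (any(bad)) stop("malformed rule line: ", lines[bad][1L])
  df <- data.frame(
    condition = vapply(m, `[`, character(1L), 2L),
    action = as.integer(vapply(m, `[`, character(1L), 3L)),
    prediction = as.numeric(vapply(m, `[`, character(1L), 4L)),
    error = 0, fitness = as.numeric(vapply(m, `[`, character(1L), 5L)),
    numerosity = 1L, experience = 0L, actionSetSize = 1, timeStamp = 0L,
    stringsAsFactors = FALSE)
  asPopulation(df, if (nrow(df)) nchar(df$condition[1L]) else NULL)
}

#' @export
print.xcs_population <- function(x, ...) {
  if (!all(popCols %in% names(x))) {  # column subset: plain table display
    print.data.frame(x)
    return(invisible(x))
  }
  cat(sprintf("XCS population: %d macroclassifiers, %d micro-classifiers\n",
              nrow(x), if (nrow(x)) microCount(x) else 0L))
  if (nrow(x)) {
    ord <- order(-x$numerosity, -x$fitness)
    show <- head(ord, 10L)
    cat("top rules by numerosity:\n")
    for (i in show)
      cat(sprintf("  %s : %d  [%.2f/%.4f]  num=%d exp=%d\n",
                  x$condition[i], x$action[i], x$prediction[i],
                  x$fitness[i], x$numerosity[i], x$experience[i]))
    if (nrow(x) > 10L) cat("  ...\n")
  }
  invisible(x)
}
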