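# Compact-ruleset post-processing: numerosity-ordered prefix search.

#' Compress a trained population into a compact control rule set
#'
#' Wilson-style rule compaction: macroclassifiers are sorted by numerosity
#' (descending; ties broken by fitness, then prediction, then condition,
#' then action) and every prefix of sizes 1..M is evaluated as a standalone
#' greedy controller with [evaluateAllStates()].  Among the prefixes that
#' fully cover the state space, the one with the minimum average number of
#' interventions is returned (ties to the smaller prefix).  Rules are never
#' edited: the result is a verbatim subset of the input population.
#'
#' @param pop the trained `xcs_population`.
#' @param task the [controlTask()] the population was trained on.
#' @param params an [xcsParams()] object (chooser semantics for evaluation).
#' @param maxSteps per-trial cap; defaults to the task's.
#' @return an object of class `compaction_result`: list with `ruleset` (the
#'   chosen prefix), `size`, `covered`, `avgSteps`, `avgInterventions`,
#'   `evaluation` (the chosen prefix's [evaluateAllStates()] report, or the
#'   full-population report when no prefix covers) and `prefixReports`
#'   (a data.frame with one row per prefix size).
#' @export
compactRuleset <- function(pop, task, params = xcsParams(),
                           maxSteps = task$maxSteps) {
  stopifnot(inherits(task, "control_task"))
  pop <- asPopulation(pop, task$n)
  if (nrow(pop) == 0L) stop("population is empty; nothing to compact")
  ord <- order(-pop$numerosity, -pop$fitness, -pop$prediction,
               pop$condition, pop$action)
  sorted <- asPopulation(pop[ord, ], task$n)
  m <- nrow(sorted)
  reports <- vector("list", m)
  rows <- data.frame(size = seq_len(m), covered = logical(m),
                     avgSteps = numeric(m), avgInterventions = numeric(m))
  for (i in seq_len(m)) {
    rep_i <- evaluateAllStates(task, sorted[seq_len(i), , drop = FALSE],
                               params, maxSteps)
    reports[[i]] <- rep_i
    rows$covered[i] <- rep_i$covered
    rows$avgSteps[i] <- rep_i$avgSteps
    rows$avgInterventions[i] <- rep_i$avgInterventions
  }
  covering <- which(rows$covered)
  if (length(covering) == 0L) {
    return(structure(list(ruleset = sorted, size = NA_integer_,
                          covered = FALSE, avgSteps = NA_real_,
                          avgInterventions = NA_real_,
                          evaluation = reports[[m]], prefixReports = rows),
                     class = "compaction_result"))
  }
  best <- covering[which.min(rows$avgInterventions[covering])]
  structure(list(ruleset = asPopulation(sorted[seq_len(best), , drop = FALSE],
                                        task$n),
                 size = best, covered = TRUE,
                 avgSteps = rows$avgSteps[best],
                 avgInterventions = rows$avgInterventions[best],
                 evaluation = reports[[best]], prefixReports = rows),
            class = "compaction_result")
}

#' @export
print.compaction_result <- function(x, ...) {
  if (x$covered)
    cat(sprintf(
      "Compact rule set: %d rules (CR), avg steps %.3f (AS), avg interventions %.3f (AI)\n",
      x$size, x$avgSteps, x$avgInterventions))
  else
    cat("Compaction failed: no numerosity-ordered prefix covers the state space\n")
  invisible(x)
}
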