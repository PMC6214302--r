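# Reproducible experiment runner: generate networks, select targets, train,
# compress, evaluate, and report one results row per run.

#' Select the target attractor of a control experiment
#'
#' @param ss a [mapStateSpace()] result.
#' @param policy `"smallest_basin"` picks the attractor with the smallest
#'   basin of attraction (the hardest target; ties break by canonical state
#'   order); `"explicit"` validates `cycle` against the mapped attractors.
#' @param cycle character vector of states (required for `"explicit"`).
#' @return the target cycle as a character vector in canonical rotation.
#' @examples
#' selectTarget(mapStateSpace(motifNetwork("XOR")))  # "000", basin size 2
#' @export
selectTarget <- function(ss, policy = c("smallest_basin", "explicit"),
                         cycle = NULL) {
  stopifnot(inherits(ss, "state_space"))
  policy <- match.arg(policy)
  if (policy == "explicit") {
    if (is.null(cycle)) stop("policy 'explicit' requires a cycle")
    hit <- which(vapply(ss$attractors, function(a) setequal(a, cycle),
                        logical(1L)))
    if (length(hit) == 0L)
      stop("the given cycle is not an attractor of this network")
    return(ss$attractors[[hit[1L]]])
  }
  sizes <- basinSizes(ss)
  first <- vapply(ss$attractors, `[`, character(1L), 1L)
  ord <- order(sizes, first)
  ss$attractors[[ord[1L]]]
}

#' Configure a control experiment
#'
#' Bundles everything that determines an experiment: the networks (given
#' explicitly or generated from `(n, k)`), the target-selection policy, the
#' XCS parameters and the run protocol (runs per network, trial schedule).
#'
#' @param networks optional list of [booleanNetwork()] objects; when `NULL`,
#'   `nNetworks` networks are generated with [generateRandomNetwork()],
#'   regenerating until each has at least two attractors.
#' @param n,k network dimensions used when generating.
#' @param nNetworks number of networks to generate.
#' @param targetPolicy passed to [selectTarget()].
#' @param targetCycle explicit target cycle (for `targetPolicy =
#'   "explicit"`).
#' @param params an [xcsParams()] object.
#' @param runs independent training runs per network.
#' @param minTrials,evalInterval,hardCeiling training schedule, see
#'   [runTraining()].
#' @param maxSteps per-trial cap.
#' @param outDir optional directory for artifacts (network JSON, state-space
#'   DOT, parameter snapshot, per-run rule sets and evaluation reports,
#'   results TSV).
#' @param seed optional master seed; per-run child seeds are derived from it
#'   deterministically.
#' @return an object of class `experiment_config`.
#' @export
experimentConfig <- function(networks = NULL, n = 5L, k = 2L, nNetworks = 1L,
                             targetPolicy = "smallest_basin",
                             targetCycle = NULL, params = xcsParams(),
                             runs = 5L, minTrials = 250000L,
                             evalInterval = 10000L, hardCeiling = 1000000L,
                             maxSteps = 100L, outDir = NULL, seed = NULL) {
  stopifnot(inherits(params, "xcs_params"))
  structure(list(networks = networks, n = as.integer(n), k = as.integer(k),
                 nNetworks = as.integer(nNetworks),
                 targetPolicy = targetPolicy, targetCycle = targetCycle,
                 params = params, runs = as.integer(runs),
                 minTrials = as.integer(minTrials),
                 evalInterval = as.integer(evalInterval),
                 hardCeiling = as.integer(hardCeiling),
                 maxSteps = as.integer(maxSteps), outDir = outDir,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "experiment_config")
}

generateMultiAttractorNetwork <- function(n, k, maxTries = 1000L) {
  for (i in seq_len(maxTries)) {
    net <- generateRandomNetwork(n, k)
    if (length(mapStateSpace(net)$attractors) >= 2L)
      return(list(network = net, tries = i))
  }
  stop("failed to generate a network with >= 2 attractors in ", maxTries,
       " tries")
}

#' Run a full control experiment
#'
#' For every network and run: train with [runTraining()], compress with
#' [compactRuleset()], and record one results row with the network and run
#' number, the compact rule count (CR), the average steps (AS) and average
#' interventions (AI) of the compact set, and the wall time in seconds
#' (training plus compression).  A run whose compact set does not fully
#' cover the state space is flagged `FAILED`.  With `config$outDir` set, all
#' artifacts are written alongside the results table.  Identical
#' configuration and seed reproduce the results exactly.
#'
#' @param config an [experimentConfig()].
#' @return an object of class `experiment_result`: list with `results` (the
#'   per-run table), `networks`, `targets` and `runs` (per-run details:
#'   training log, compact rule set, evaluation report).
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- config$outDir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  networks <- config$networks
  regenerated <- integer(0L)
  if (is.null(networks)) {
    networks <- vector("list", config$nNetworks)
    for (i in seq_len(config$nNetworks)) {
      g <- generateMultiAttractorNetwork(config$n, config$k)
      networks[[i]] <- g$network
      regenerated[i] <- g$tries
      if (g$tries > 1L)
        message("network ", i, ": regenerated ", g$tries - 1L,
                " time(s) to obtain >= 2 attractors")
    }
  }
  childSeed <- function()
    sample.int(.Machine$integer.max - 1L, 1L)
  results <- NULL
  targets <- list()
  runInfo <- list()
  for (ni in seq_along(networks)) {
    net <- networks[[ni]]
    ss <- mapStateSpace(net)
    target <- selectTarget(ss, config$targetPolicy, config$targetCycle)
    targets[[ni]] <- target
    task <- controlTask(net, target, config$maxSteps)
    if (!is.null(out)) {
      writeNetwork(net, file.path(out, sprintf("network%d.json", ni)))
      writeStateSpaceDot(ss, file.path(out, sprintf("network%d.dot", ni)))
    }
    for (ri in seq_len(config$runs)) {
      seed_ri <- childSeed()
      set.seed(seed_ri)
      t0 <- proc.time()[["elapsed"]]
      training <- runTraining(task, config$params, config$minTrials,
                              config$evalInterval, config$hardCeiling)
      compact <- compactRuleset(training$population, task, config$params)
      elapsed <- proc.time()[["elapsed"]] - t0
      row <- data.frame(Net = ni, Run = ri,
                        CR = if (compact$covered) compact$size else NA_integer_,
                        AS = round(compact$avgSteps, 3L),
                        AI = round(compact$avgInterventions, 3L),
                        Time = round(elapsed, 1L),
                        status = if (compact$covered) "ok" else "FAILED",
                        stringsAsFactors = FALSE)
      results <- rbind(results, row)
      runInfo[[length(runInfo) + 1L]] <-
        list(net = ni, run = ri, seed = seed_ri, training = training,
             compact = compact, evaluation = compact$evaluation)
      if (!is.null(out)) {
        writeRuleset(compact$ruleset,
                     file.path(out, sprintf("net%d_run%d_rules.txt", ni, ri)))
        writeEvaluationReport(compact$evaluation,
                              file.path(out,
                                        sprintf("net%d_run%d_eval.tsv", ni, ri)))
      }
    }
  }
  if (!is.null(out)) {
    writeResultsTable(results, file.path(out, "results.tsv"))
    writeParams(config$params, file.path(out, "params.txt"))
    cfg <- c(sprintf("n = %d", config$n), sprintf("k = %d", config$k),
             sprintf("runs = %d", config$runs),
             sprintf("minTrials = %d", config$minTrials),
             sprintf("evalInterval = %d", config$evalInterval),
             sprintf("hardCeiling = %d", config$hardCeiling),
             sprintf("maxSteps = %d", config$maxSteps),
             sprintf("targetPolicy = %s", config$targetPolicy),
             sprintf("seed = %s",
                     if (is.null(config$seed)) "NULL" else config$seed))
    writeLines(cfg, file.path(out, "config.txt"))
  }
  structure(list(results = results, networks = networks, targets = targets,
                 runs = runInfo, regenerated = regenerated),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Control experiment results (CR = compact rules, AS = avg steps,",
      "AI = avg interventions):\n")
  print.data.frame(x$results, row.names = FALSE)
  invisible(x)
}

#' Write the experiment results table
#'
#' Tab-separated with the columns `Net`, `Run`, `CR`, `AS`, `AI`, `Time`
#' and `status`; AS/AI are rounded to 3 decimals.
#'
#' @param results the `results` data.frame of [runExperiment()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
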