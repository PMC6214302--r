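# XCS parameter ledger with the tuned defaults used throughout.

#' XCS parameter set
#'
#' Collects the full parameter ledger of the classifier system.  The
#' defaults are the tuned values used for the N = 5, K = 2 control
#' experiments; they were obtained by random parameter-space exploration
#' around the standard Butz–Wilson settings and are deliberately tolerant of
#' prediction error (see the package vignette): the multi-step payoff
#' `1000 * (steps - interventions) / steps` fluctuates between action chains
#' of different lengths, so `eps0`, `alpha` and `nu` are set to keep such
#' classifiers reproducible.
#'
#' @param popSize `R`, maximum population size in micro-classifiers; roulette
#'   deletion enforces this bound after every insertion.
#' @param gamma discount factor applied to the next step's best prediction in
#'   the payoff target `P = reward + gamma * max(predictionArray)`.
#' @param thetaMna minimum number of distinct actions required in a match
#'   set before covering stops; must not exceed `N + 1`.
#' @param pHash probability that a covering condition character becomes `#`.
#' @param predictionInit,errorInit,fitnessInit initial prediction, error and
#'   fitness of covered classifiers.
#' @param eps0 error threshold: classifiers with error below it get accuracy
#'   1 and may subsume others.
#' @param thetaGa genetic algorithm activation threshold on the mean
#'   action-set time stamp.
#' @param thetaDel experience threshold above which unfit classifiers are
#'   deleted more aggressively.
#' @param beta learning rate of the Widrow-Hoff updates (and the switch point
#'   `1/beta` of the two-tier moyenne-adaptive-modifiee update).
#' @param alpha,nu accuracy function parameters:
#'   `kappa = alpha * (error/eps0)^-nu` once `error >= eps0`.
#' @param chi crossover probability in the GA.
#' @param mu per-index mutation probability in the GA (niche mutation).
#' @param delta fitness fraction of the population mean below which the
#'   deletion vote of an experienced classifier is inflated.
#' @param thetaSub experience a classifier needs before it may subsume.
#' @param doActionSetSubsumption,doGaSubsumption enable subsumption in the
#'   action set / in the GA.
#' @param useNewActionChooser use the deterministic action chooser (exploit
#'   when the best prediction exceeds 500, otherwise explore).  The
#'   probabilistic `pExplore` chooser is not implemented, so this must be
#'   `TRUE`.
#' @param pExplore recorded for completeness; unused by the deterministic
#'   chooser.
#' @return an object of class `xcs_params`.
#' @examples
#' p <- xcsParams()
#' p$popSize  # 790
#' @export
xcsParams <- function(popSize = 790L,
                      gamma = 0.76,
                      thetaMna = 6L,
                      pHash = 0.4,
                      predictionInit = 7.4,
                      errorInit = 1.0,
                      fitnessInit = 0.03,
                      eps0 = 18.5,
                      thetaGa = 260,
                      thetaDel = 32,
                      beta = 0.01,
                      alpha = 0.087,
                      nu = 0.01,
                      chi = 0.711,
                      mu = 0.263,
                      delta = 0.05,
                      thetaSub = 31.579,
                      doActionSetSubsumption = TRUE,
                      doGaSubsumption = TRUE,
                      useNewActionChooser = TRUE,
                      pExplore = NA_real_) {
  p <- list(popSize = as.integer(popSize), gamma = gamma,
            thetaMna = as.integer(thetaMna), pHash = pHash,
            predictionInit = predictionInit, errorInit = errorInit,
            fitnessInit = fitnessInit, eps0 = eps0, thetaGa = thetaGa,
            thetaDel = thetaDel, beta = beta, alpha = alpha, nu = nu,
            chi = chi, mu = mu, delta = delta, thetaSub = thetaSub,
            doActionSetSubsumption = isTRUE(doActionSetSubsumption),
            doGaSubsumption = isTRUE(doGaSubsumption),
            useNewActionChooser = isTRUE(useNewActionChooser),
            pExplore = as.numeric(pExplore))
  if (p$popSize < 1L) stop("popSize must be positive")
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must lie in [0, 1]")
  if (p$thetaMna < 1L) stop("thetaMna must be positive")
  for (f in c("pHash", "chi", "mu"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (p$beta <= 0 || p$beta > 1) stop("beta must lie in (0, 1]")
  if (p$eps0 < 0 || p$alpha <= 0 || p$nu < 0)
    stop("eps0 must be >= 0 and alpha > 0, nu >= 0")
  if (!p$useNewActionChooser)
    stop("the probabilistic action chooser is not implemented; ",
         "useNewActionChooser must be TRUE")
  structure(p, class = "xcs_params")
}

#' @export
print.xcs_params <- function(x, ...) {
  cat("XCS parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.logical(v)) tolower(as.character(v))
                else format(v)))
  }
  invisible(x)
}

#' Read / write a parameter file
#'
#' Flat `key = value` text format using the ASCII parameter names of
#' [xcsParams()] (`popSize`, `gamma`, `thetaMna`, `pHash`, `predictionInit`,
#' `errorInit`, `fitnessInit`, `eps0`, `thetaGa`, `thetaDel`, `beta`,
#' `alpha`, `nu`, `chi`, `mu`, `delta`, `thetaSub`, ...).
#'
#' @param params an [xcsParams()] object.
#' @param path file path.
#' @return `writeParams()` returns `path` invisibly; `readParams()` returns
#'   an [xcsParams()] object.
#' @export
writeParams <- function(params, path) {
  stopifnot(inherits(params, "xcs_params"))
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15)
  }
  writeLines(sprintf("%s = %s", names(params),
                     vapply(params, fmt, character(1L))), path)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1L)) != 3L
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- vapply(kv, `[`, character(1L), 3L)
  args <- lapply(vals, function(v) {
    if (tolower(v) %in% c("true", "false")) as.logical(toupper(v))
    else if (toupper(v) == "NA") NA_real_
    else as.numeric(v)
  })
  names(args) <- keys
  unknown <- setdiff(keys, names(formals(xcsParams)))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  do.call(xcsParams, args)
}
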