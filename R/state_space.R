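# Exhaustive state-space analysis: successor map, attractors, basins.

allStates <- function(n) {
  ints <- 0:(2L^n - 1L)
  bits <- matrix(0L, length(ints), n)
  for (i in seq_len(n))
    bits[, i] <- bitwAnd(bitwShiftR(ints, n - i), 1L)
  do.call(paste0, as.data.frame(bits))
}

#' Map the full state space of a Boolean network
#'
#' Enumerates all `2^N` states, computes the synchronous successor of each,
#' detects every attractor (state cycle) by trajectory-following with
#' visited-set cycle detection, and assigns each state to the basin of the
#' attractor its trajectory reaches.  Attractor cycles are reported in
#' canonical rotation, starting at the lexicographically smallest state.
#'
#' @param net a [booleanNetwork()] with at most 24 nodes (the analysis is
#'   exhaustive in `2^N`).
#' @return an object of class `state_space`: a list with `states` (all bit
#'   strings, in binary order), `successor` (integer index of each state's
#'   successor), `attractors` (list of character vectors, one cycle each) and
#'   `basin` (integer attractor id per state).
#' @examples
#' ss <- mapStateSpace(motifNetwork("XOR"))
#' ss$attractors          # fixed point {000} and the 3-cycle
#' basinSizes(ss)
#' @export
mapStateSpace <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  if (net$n > 24L)
    stop("state space too large: exhaustive mapping is limited to N <= 24")
  res <- cpp_map_state_space(net)
  states <- allStates(net$n)
  attractors <- lapply(res$attractors, function(idx) states[idx])
  structure(list(n = net$n, states = states, successor = res$successor,
                 attractors = attractors, basin = res$basin),
            class = "state_space")
}

#' Basin sizes of a mapped state space
#'
#' @param ss a [mapStateSpace()] result.
#' @return integer vector, one entry per attractor; entries sum to `2^N`.
#' @export
basinSizes <- function(ss) {
  stopifnot(inherits(ss, "state_space"))
  tabulate(ss$basin, nbins = length(ss$attractors))
}

#' Minimum bit-flip distance between two attractors
#'
#' The smallest number of simultaneous single-bit flips that converts some
#' state of one cycle into some state of the other, i.e. the minimum pairwise
#' Hamming distance across the two state sets.
#'
#' @param a,b character vectors of equal-length bit strings (the states of
#'   one attractor cycle each).
#' @return a non-negative integer; 0 exactly when the cycles share a state.
#' @examples
#' bitFlipDistance("00011", c("01010", "10101"))  # 2
#' @export
bitFlipDistance <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) < 1L || length(b) < 1L) stop("empty attractor")
  n <- nchar(a[1L])
  if (any(nchar(c(a, b)) != n))
    stop("attractors must be defined over the same number of nodes")
  am <- do.call(rbind, strsplit(a, ""))
  bm <- do.call(rbind, strsplit(b, ""))
  min(vapply(seq_len(nrow(am)), function(i)
    min(rowSums(bm != matrix(am[i, ], nrow(bm), n, byrow = TRUE))),
    numeric(1L)))
}

#' Export a state-space graph in DOT format
#'
#' One node per network state, labelled with its bit string, and one directed
#' edge per synchronous successor, suitable for graphviz rendering.
#'
#' @param ss a [mapStateSpace()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStateSpaceDot <- function(ss, path) {
  stopifnot(inherits(ss, "state_space"))
  lines <- c("digraph stateSpace {",
             "  node [shape=box];",
             sprintf("  \"%s\" -> \"%s\";", ss$states,
                     ss$states[ss$successor]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("State space of a %d-node network: %d states, %d attractor(s)\n",
              x$n, length(x$states), length(x$attractors)))
  sizes <- basinSizes(x)
  for (i in seq_along(x$attractors))
    cat(sprintf("  attractor %d: {%s}  basin size %d\n", i,
                paste(x$attractors[[i]], collapse = " -> "), sizes[i]))
  invisible(x)
}
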