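# NK Boolean networks: construction, generation and synchronous simulation.

#' Construct an NK Boolean network
#'
#' An NK Boolean network has `n` binary nodes, each updated synchronously by
#' a fixed Boolean function of `k` input nodes.  The network state is written
#' as a bit string with node 1 as the leftmost character.
#'
#' @param inputs integer matrix (`n` rows, `k` columns) of 1-based input node
#'   indices for each node.  The stored column order matters: when a node
#'   looks up its truth table, the first input supplies the most significant
#'   bit of the row index.
#' @param truthTables integer matrix (`n` rows, `2^k` columns) of output bits,
#'   one row per node, indexed by the input pattern as described above.
#' @return an object of class `boolean_network` with fields `n`, `k`,
#'   `inputs` and `truthTables`.
#' @examples
#' net <- motifNetwork("AND")
#' networkStep(net, "101")
#' @export
booleanNetwork <- function(inputs, truthTables) {
  inputs <- as.matrix(inputs)
  truthTables <- as.matrix(truthTables)
  storage.mode(inputs) <- "integer"
  storage.mode(truthTables) <- "integer"
  n <- nrow(inputs)
  k <- ncol(inputs)
  if (n < 1L || k < 1L)
    stop("a network needs at least one node and one input per node")
  if (any(inputs < 1L) || any(inputs > n))
    stop("input indices must lie in [1, n]")
  if (any(apply(inputs, 1L, anyDuplicated) > 0L))
    stop("each node must have k distinct input indices")
  if (nrow(truthTables) != n || ncol(truthTables) != 2L^k)
    stop("truthTables must be an n x 2^k matrix")
  if (!all(truthTables %in% c(0L, 1L)))
    stop("truth table entries must be 0 or 1")
  structure(list(n = n, k = k, inputs = inputs, truthTables = truthTables),
            class = "boolean_network")
}

#' Generate a random NK Boolean network
#'
#' For each node, `k` distinct input nodes are drawn uniformly (self-loops
#' permitted) and a random truth table is assigned, each output bit uniform
#' on \{0, 1\}.  All randomness comes from R's RNG, so `set.seed()` makes the
#' construction reproducible.
#'
#' @param n number of nodes (N).
#' @param k number of inputs per node (K), `1 <= k <= n`.
#' @return a [booleanNetwork()] object.
#' @examples
#' set.seed(1)
#' net <- generateRandomNetwork(5, 2)
#' @export
generateRandomNetwork <- function(n, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (is.na(n) || is.na(k) || k < 1L || k > n)
    stop("invalid parameters: need 1 <= k <= n")
  inputs <- t(vapply(seq_len(n), function(i) sample.int(n, k),
                     integer(k)))
  if (k == 1L) inputs <- matrix(inputs, nrow = n)
  tables <- matrix(sample(c(0L, 1L), n * 2L^k, replace = TRUE), nrow = n)
  booleanNetwork(inputs, tables)
}

#' Three-node ring motif networks
#'
#' A fully specified 3-node motif: nodes A, B, C arranged in a ring where
#' each node reads itself and its predecessor (B reads \{B, A\}, C reads
#' \{C, B\}, A reads \{A, C\}), and every node applies the same named 2-input
#' logic function.
#'
#' @param logic `"AND"` or `"XOR"`.
#' @return a [booleanNetwork()] object with `n = 3`, `k = 2`.
#' @examples
#' mapStateSpace(motifNetwork("XOR"))
#' @export
motifNetwork <- function(logic = c("AND", "XOR")) {
  logic <- match.arg(logic)
  inputs <- rbind(c(1L, 3L), c(2L, 1L), c(3L, 2L))
  row <- switch(logic,
                AND = c(0L, 0L, 0L, 1L),
                XOR = c(0L, 1L, 1L, 0L))
  booleanNetwork(inputs, rbind(row, row, row))
}

assertState <- function(state, n) {
  if (!is.character(state) || length(state) != 1L || is.na(state))
    stop("state must be a single bit string")
  if (nchar(state) != n)
    stop("state length ", nchar(state), " does not match network size ", n)
  if (grepl("[^01]", state))
    stop("state may only contain the characters 0 and 1")
  invisible(state)
}

#' Advance a network by one synchronous step
#'
#' All node outputs are computed from the pre-step state and committed
#' together.
#'
#' @param net a [booleanNetwork()].
#' @param state bit string of length `net$n` (node 1 leftmost).
#' @return the successor state as a bit string.
#' @examples
#' networkStep(motifNetwork("AND"), "101")  # "100"
#' @export
networkStep <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  assertState(state, net$n)
  cpp_network_step(net, state)
}

#' Flip one bit of a network state
#'
#' Implements the effector semantics of the controller: action index `i`
#' (1-based, leftmost = 1) inverts the i-th character; action 0 means "no
#' action" and returns the state unchanged.
#'
#' @param state bit string.
#' @param action integer in `[0, nchar(state)]`.
#' @return the modified bit string.
#' @examples
#' flipBit("00110", 2)  # "01110"
#' @export
flipBit <- function(state, action) {
  assertState(state, nchar(state))
  action <- as.integer(action)
  if (is.na(action) || action < 0L || action > nchar(state))
    stop("invalid action: must lie in [0, ", nchar(state), "]")
  if (action == 0L) return(state)
  ch <- substr(state, action, action)
  substr(state, action, action) <- if (ch == "1") "0" else "1"
  state
}

#' Read / write a network definition file
#'
#' Networks are stored as JSON with fields `n`, `k`, `inputs` (per-node lists
#' of 1-based indices) and `truth_tables` (per-node bit lists); the file
#' round-trips losslessly through [readNetwork()].
#'
#' @param net a [booleanNetwork()].
#' @param path file path.
#' @return `writeNetwork()` returns `path` invisibly; `readNetwork()` returns
#'   a [booleanNetwork()].
#' @export
writeNetwork <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  obj <- list(n = net$n, k = net$k,
              inputs = lapply(seq_len(net$n), function(i)
                unname(net$inputs[i, ])),
              truth_tables = lapply(seq_len(net$n), function(i)
                unname(net$truthTables[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    if (is.null(dim(x))) x <- matrix(x, nrow = obj$n, byrow = TRUE)
    matrix(as.integer(x), nrow = obj$n)
  }
  booleanNetwork(asMat(obj$inputs), asMat(obj$truth_tables))
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("NK Boolean network: N = %d nodes, K = %d inputs per node\n",
              x$n, x$k))
  cat("wiring (first input = most significant truth-table bit):\n")
  for (i in seq_len(min(x$n, 10L)))
    cat(sprintf("  node %d <- (%s)  table [%s]\n", i,
                paste(x$inputs[i, ], collapse = ", "),
                paste(x$truthTables[i, ], collapse = "")))
  if (x$n > 10L) cat("  ...\n")
  invisible(x)
}
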