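# Independent brute-force oracles, kept deliberately separate from the
# package implementation (plain R, no bit tricks).

allStatesOracle <- function(n) {
  grid <- expand.grid(rep(list(c("0", "1")), n), stringsAsFactors = FALSE)
  sort(apply(grid, 1L, paste, collapse = ""))
}

# one synchronous step, evaluated character by character
oracleStep <- function(net, state) {
  bits <- as.integer(strsplit(state, "")[[1L]])
  out <- integer(net$n)
  for (i in seq_len(net$n)) {
    idx <- 0L
    for (j in seq_len(net$k)) idx <- idx * 2L + bits[net$inputs[i, j]]
    out[i] <- net$truthTables[i, idx + 1L]
  }
  paste(out, collapse = "")
}

# attractors and basin assignment by exhaustive trajectory iteration:
# every start state is advanced 2^N steps (guaranteed to settle), then the
# cycle is read off
oracleStateSpace <- function(net) {
  sts <- allStatesOracle(net$n)
  cycleOf <- character(0L)
  cycles <- list()
  for (s in sts) {
    cur <- s
    for (i in seq_len(2L^net$n)) cur <- oracleStep(net, cur)
    cyc <- cur
    nxt <- oracleStep(net, cur)
    while (nxt != cur) {
      cyc <- c(cyc, nxt)
      nxt <- oracleStep(net, nxt)
    }
    key <- paste(sort(cyc), collapse = ",")
    cycleOf[s] <- key
    cycles[[key]] <- sort(cyc)
  }
  list(cycles = unname(cycles), basinKey = cycleOf)
}

# a small random population of syntactically valid classifiers
randomPopulation <- function(m, n, actions = 0:n) {
  conds <- vapply(seq_len(m), function(i)
    paste(sample(c("0", "1", "#"), n, replace = TRUE), collapse = ""),
    character(1L))
  df <- data.frame(condition = conds,
                   action = sample(actions, m, replace = TRUE),
                   prediction = runif(m, 0, 1000),
                   error = runif(m, 0, 50),
                   fitness = runif(m),
                   numerosity = sample(1:3, m, replace = TRUE),
                   experience = sample(0:60, m, replace = TRUE),
                   actionSetSize = runif(m, 1, 20),
                   timeStamp = 0L, stringsAsFactors = FALSE)
  # unique (condition, action) pairs, as a population requires
  df <- df[!duplicated(df[c("condition", "action")]), ]
  structure(df, class = c("xcs_population", "data.frame"),
            conditionLength = n)
}
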