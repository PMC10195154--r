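# Independent oracles used across tests: affine-gap global alignment
# (Gotoh), exhaustive Dollo enumeration, exhaustive single-split
# changepoint scan, and hand-rolled Felsenstein contrasts.

nwOracle <- function(a, b, open = 10, ext = 0.5) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive minimum-loss Dollo assignments (no duplicate regain) for a
# rooted binary tree and one vector of leaf states (BOTH/ONE)
dolloOracle <- function(tree, leaf_states) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  grid <- expand.grid(rep(list(c("BOTH", "ONE")), nn),
                      stringsAsFactors = FALSE)
  bestk <- Inf
  best <- list()
  for (r in seq_len(nrow(grid))) {
    sts <- c(unname(leaf_states[tree$tip.label]),
             unname(unlist(grid[r, ])))
    k <- 0L; ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- sts[tree$edge[e, 1]]; ch <- sts[tree$edge[e, 2]]
      if (p == "ONE" && ch == "BOTH") { ok <- FALSE; break }
      if (p == "BOTH" && ch == "ONE") k <- k + 1L
    }
    if (!ok) next
    if (k < bestk) { bestk <- k; best <- list(sts) }
    else if (k == bestk) best[[length(best) + 1L]] <- sts
  }
  list(min_losses = bestk, states = best)
}

# best single mean-shift split of a series by exhaustive RSS scan
singleSplitOracle <- function(x, min_len = 3L) {
  n <- length(x)
  rss <- function(v) sum((v - mean(v))^2)
  best <- Inf; arg <- NA_integer_
  for (s in min_len:(n - min_len)) {
    v <- rss(x[1:s]) + rss(x[(s + 1):n])
    if (v < best) { best <- v; arg <- s }
  }
  arg
}

# Felsenstein contrasts from first principles for small trees
picOracle <- function(tree, x) {
  ntip <- ape::Ntip(tree)
  val <- c(unname(x[tree$tip.label]), rep(NA_real_, tree$Nnode))
  vl <- numeric(ntip + tree$Nnode)
  el <- numeric(ntip + tree$Nnode)
  el[tree$edge[, 2]] <- tree$edge.length
  contrasts <- numeric(0)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (node in unique(po[, 1])) {
    ch <- po[po[, 1] == node, 2]
    v1 <- el[ch[1]] + vl[ch[1]]; v2 <- el[ch[2]] + vl[ch[2]]
    contrasts <- c(contrasts, (val[ch[1]] - val[ch[2]]) / sqrt(v1 + v2))
    val[node] <- (val[ch[1]] / v1 + val[ch[2]] / v2) / (1 / v1 + 1 / v2)
    vl[node] <- v1 * v2 / (v1 + v2)
  }
  contrasts
}

# small presence matrix built from per-species state vectors
presenceMat <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  m
}
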