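# Independent oracles and shared fixtures for the test suite.

# Brute-force betweenness by exhaustive simple-path enumeration
# (edge length = 1/|w|, fractional credit over tied geodesics).
brute_betweenness <- function(w) {
  p <- nrow(w)
  len <- ifelse(w != 0, 1 / abs(w), Inf)
  b <- numeric(p)
  if (p < 3) return(b)
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    paths <- list()
    best <- Inf
    rec <- function(path, d) {
      v <- path[length(path)]
      if (d > best + 1e-12) return()
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(path = path, d = d)
        if (d < best) best <<- d
        return()
      }
      for (u in seq_len(p))
        if (!(u %in% path) && is.finite(len[v, u]))
          rec(c(path, u), d + len[v, u])
    }
    rec(s, 0)
    if (!is.finite(best)) next
    geod <- Filter(function(x) abs(x$d - best) <= 1e-12, paths)
    for (g in geod) {
      inner <- g$path[-c(1, length(g$path))]
      for (v in inner) b[v] <- b[v] + 1 / length(geod)
    }
  }
  b
}

# Exact 0/1 Ising distribution by state enumeration (p <= 12).
ising_exact <- function(W, h) {
  p <- length(h)
  states <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(states) <- NULL
  en <- as.numeric(states %*% h) + rowSums((states %*% W) * states) / 2
  pr <- exp(en - max(en))
  list(states = states, probs = pr / sum(pr))
}

ising_exact_moments <- function(W, h) {
  ex <- ising_exact(W, h)
  p <- ncol(ex$states)
  m1 <- colSums(ex$states * ex$probs)
  m2 <- t(ex$states) %*% (ex$states * ex$probs)
  list(marginals = m1, pair = m2)
}

# Edge-recovery summary against a planted truth.
sens_fdp <- function(w_est, w_true) {
  eu <- w_est[upper.tri(w_est)] != 0
  tu <- w_true[upper.tri(w_true)] != 0
  c(sens = if (sum(tu) == 0) NA_real_ else sum(eu & tu) / sum(tu),
    fdp = if (sum(eu) == 0) 0 else sum(eu & !tu) / sum(eu))
}

# Shared planted truths (p = 10).
ggm_truth_p10 <- function(weight = 0.35) {
  make_truth_network(paste0("V", 1:10),
                     data.frame(i = c(1, 2, 3, 5, 6, 8, 9, 1),
                                j = c(2, 3, 4, 6, 7, 9, 10, 5),
                                weight = weight),
                     kinds = "continuous")
}

ising_truth_p10 <- function() {
  tn <- make_truth_network(paste0("V", 1:10),
                           data.frame(i = c(1, 2, 3, 5, 6, 8),
                                      j = c(2, 3, 4, 6, 7, 9),
                                      weight = c(1.2, 1, -1, 1.2, 1, 1.2)))
  tn$fields <- rep(-0.5, 10)
  tn
}

# Mixed binary/continuous sample with known conditional structure:
# binaries from an Ising truth; continuous nodes are linear in the
# binaries (coefficient matrix `bc`) plus correlated Gaussian noise with
# partial-correlation structure `cc_truth`. The joint is a pairwise MRF
# whose graph is the block union PROVIDED each continuous node regressed
# on binaries is isolated in `cc_truth` (otherwise B %*% K terms add
# extra edges).
sample_mixed <- function(ising_truth, bc, cc_truth, n, seed) {
  xb <- sample_ising_gibbs(ising_truth, n, seed = seed)
  zc <- sample_gaussian(cc_truth, n, seed = seed + 1000L)
  xc <- xb %*% bc + zc
  colnames(xc) <- cc_truth$node_names
  cbind(xb, xc)
}

# Adjacency of the mixed truth above (block union).
mixed_truth_adj <- function(ising_truth, bc, cc_truth) {
  pb <- length(ising_truth$node_names)
  pc <- length(cc_truth$node_names)
  adj <- matrix(0, pb + pc, pb + pc)
  adj[1:pb, 1:pb] <- ising_truth$weights != 0
  adj[pb + (1:pc), pb + (1:pc)] <- cc_truth$weights != 0
  adj[1:pb, pb + (1:pc)] <- bc != 0
  adj[pb + (1:pc), 1:pb] <- t(bc != 0)
  adj
}

# A small fitted-model wrapper for hand-built weight matrices.
toy_model <- function(w, family = "ising", nodes = NULL) {
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(w)))
  dimnames(w) <- list(nodes, nodes)
  network_model(family, w, gamma = 0.25, symmetrization = "AND")
}
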