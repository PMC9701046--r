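# Independent oracles used across tests. These are deliberately naive,
# brute-force implementations kept separate from the package code paths.

# hypergeometric upper-tail P(X >= nf) by explicit summation over the support
oracle_hyper_upper <- function(nf, n, Nf, N) {
  hi <- min(n, Nf)
  if (nf > hi) return(0)
  k <- seq(max(nf, 0), hi)
  sum(choose(Nf, k) * choose(N - Nf, n - k)) / choose(N, n)
}

# classical one-way ANOVA F and p for one gene's log2 values
oracle_anova <- function(y, group) {
  fit <- stats::oneway.test(y ~ group, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value))
}

# adjacency matrix of a coexpr_network, in node order
net_adjacency <- function(net) {
  nodes <- net$nodes$gene
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(net$edges) > 0) {
    A[cbind(net$edges$from, net$edges$to)] <- 1L
    A[cbind(net$edges$to, net$edges$from)] <- 1L
  }
  A
}

# brute-force local clustering coefficient from an adjacency matrix
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}

# brute-force k-core by exhaustive subset search: a node's core number is the
# largest k such that some subgraph containing it has minimum degree >= k.
# Only feasible for small n.
oracle_kcore_subsets <- function(A) {
  n <- nrow(A)
  core <- rep(0L, n)
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < 2) next
    sub <- A[members, members, drop = FALSE]
    mindeg <- min(rowSums(sub))
    core[members] <- pmax(core[members], as.integer(mindeg))
  }
  core
}

# independent k-core via iterative peeling (for graphs too big for subsets)
oracle_kcore_peel <- function(A) {
  n <- nrow(A)
  core <- rep(0L, n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      low <- which(deg < k)
      if (length(low) == 0) break
      core[which(alive)[low]] <- k - 1L
      alive[which(alive)[low]] <- FALSE
    }
    if (!any(alive)) break
    k <- k + 1L
  }
  core
}

# small helper: expression matrix from a plain matrix of log2 group means
# with iid noise, 3 groups x n_rep replicates
make_em <- function(log2_means, n_rep = 3, sd = 0, groups = NULL,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(log2_means)
  if (is.null(groups)) groups <- paste0("grp", seq_len(m))
  G <- nrow(log2_means)
  L <- log2_means[, rep(seq_len(m), each = n_rep), drop = FALSE]
  if (sd > 0) L <- L + matrix(rnorm(G * m * n_rep, sd = sd), G)
  if (is.null(rownames(log2_means)))
    rownames(L) <- sprintf("g%03d", seq_len(G))
  colnames(L) <- paste0(rep(groups, each = n_rep), "_r",
                        rep(seq_len(n_rep), m))
  design <- data.frame(sample = colnames(L),
                       group = factor(rep(groups, each = n_rep),
                                      levels = groups))
  expr_matrix(2^L, design)
}
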