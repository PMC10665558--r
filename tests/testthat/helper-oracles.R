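# Independent oracles used across the suite. They deliberately take a
# different route than the package implementation:
#  - the covariance oracle enumerates tip pairs and their MRCA via ape::mrca,
#  - the GLS oracle inverts C densely with solve(),
#  - the Gaussian density oracle uses an eigen decomposition.

oracle_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- if (i == j) depths[i] else depths[M[i, j]]
    }
  }
  C
}

oracle_gls <- function(C, X, y) {
  Ci <- solve(C)
  XtCiX <- t(X) %*% Ci %*% X
  beta <- drop(solve(XtCiX, t(X) %*% Ci %*% y))
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Ci %*% r)
  n <- length(y)
  p <- ncol(X)
  list(beta = beta, rss = rss,
       se = sqrt(rss / (n - p) * diag(solve(XtCiX))))
}

oracle_mvn_ll <- function(y, mu, V) {
  ed <- eigen(V, symmetric = TRUE)
  z <- t(ed$vectors) %*% (y - mu)
  -0.5 * (length(y) * log(2 * pi) + sum(log(ed$values)) +
            sum(z^2 / ed$values))
}

# conditional-mean ACE oracle: joint covariance over tips and internal
# nodes from ape::mrca(full = TRUE), root state estimated by GLS
oracle_ace <- function(tree, x, sigma2) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  Mf <- ape::mrca(tree, full = TRUE)
  Vall <- matrix(depths[Mf], n + m, n + m)
  diag(Vall) <- depths
  Ct <- Vall[1:n, 1:n]
  x <- x[tree$tip.label]
  Ci <- solve(Ct)
  one <- rep(1, n)
  z0 <- drop(one %*% Ci %*% x) / drop(one %*% Ci %*% one)
  nodes <- (n + 1):(n + m)
  est <- vapply(nodes, function(a) {
    ca <- Vall[a, 1:n]
    z0 + drop(ca %*% Ci %*% (x - z0))
  }, 0)
  va <- vapply(nodes, function(a) {
    ca <- Vall[a, 1:n]
    sigma2 * (depths[a] - drop(ca %*% Ci %*% ca) +
                (1 - drop(ca %*% Ci %*% one))^2 / drop(one %*% Ci %*% one))
  }, 0)
  list(estimate = est, variance = va, root = est[1])
}

# random ultrametric tree, independent of the package's simulator
rand_coal_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

fixture_tree <- function() study_tree()
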