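# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Brute-force K2P by direct site counting on character vectors.
k2p_bruteforce <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  stopifnot(length(a) == length(b))
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  purine <- c("A", "G")
  ts <- sum((a == "A" & b == "G") | (a == "G" & b == "A") |
            (a == "C" & b == "T") | (a == "T" & b == "C"))
  tv <- sum(a != b & ((a %in% purine) != (b %in% purine)))
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Mutate a fraction of sites uniformly to a different base.
mutate_dna <- function(s, n_sub) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# --- exhaustive unrooted topology search -----------------------------------
# Trees are edge-list matrices (2 columns of node ids); leaves are 1..n,
# internal nodes are n+1, n+2, ...

enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- cbind(c(n + 1, n + 1, n + 1), c(1, 2, 3))
  trees <- list(list(edges = base, next_node = n + 2))
  for (leaf in seq(4, length.out = max(0, n - 3))) {
    trees <- do.call(c, lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edges)), function(e) {
        m <- tr$next_node
        edges <- tr$edges[-e, , drop = FALSE]
        edges <- rbind(edges,
                       c(tr$edges[e, 1], m),
                       c(m, tr$edges[e, 2]),
                       c(m, leaf))
        list(edges = edges, next_node = m + 1)
      })
    }))
  }
  lapply(trees, `[[`, "edges")
}

# Leaf sets on one side of each edge (DFS without crossing the edge).
topo_splits <- function(edges, n, labels) {
  adj <- lapply(seq_len(max(edges)), function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  })
  ref <- sort(labels)[1]
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    blocked_a <- edges[e, 1]; blocked_b <- edges[e, 2]
    seen <- rep(FALSE, length(adj))
    stack <- blocked_b; seen[blocked_b] <- TRUE
    while (length(stack) > 0) {
      v <- stack[1]; stack <- stack[-1]
      for (w in adj[[v]]) {
        if (!(v == blocked_b && w == blocked_a) && !seen[w]) {
          seen[w] <- TRUE; stack <- c(stack, w)
        }
      }
    }
    side <- labels[which(seen[seq_len(n)])]
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(labels, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# Least-squares branch fit of a distance matrix on a fixed topology;
# returns the residual sum of squares and fitted path distances.
ls_fit_topology <- function(edges, D) {
  n <- nrow(D)
  adj <- lapply(seq_len(max(edges)), function(v) {
    which(edges[, 1] == v | edges[, 2] == v)
  })
  other <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
  path_edges <- function(from, to) {
    # DFS recording edge path
    stack <- list(list(v = from, path = integer(0)))
    seen <- rep(FALSE, max(edges)); seen[from] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[1]]; stack <- stack[-1]
      if (cur$v == to) return(cur$path)
      for (e in adj[[cur$v]]) {
        w <- other(e, cur$v)
        if (!seen[w]) {
          seen[w] <- TRUE
          stack <- c(list(list(v = w, path = c(cur$path, e))), stack)
        }
      }
    }
    stop("no path")
  }
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  d <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    A[k, path_edges(pairs[k, 1], pairs[k, 2])] <- 1
    d[k] <- D[pairs[k, 1], pairs[k, 2]]
  }
  fit <- stats::lsfit(A, d, intercept = FALSE)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients,
       fitted = d - fit$residuals)
}

# Best topology for D by exhaustive least squares (n <= 5 is practical).
best_topology_splits <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  topos <- enumerate_topologies(n)
  rss <- vapply(topos, function(tp) ls_fit_topology(tp, D)$rss, numeric(1))
  topo_splits(topos[[which.min(rss)]], n, labels)
}

# Random additive distance matrix from a random tree; returns both.
random_additive <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  phy <- ape::rtree(n, rooted = FALSE)
  phy$tip.label <- labels
  phy$edge.length <- stats::runif(length(phy$edge.length), 0.05, 1)
  D <- stats::cophenetic(phy)[labels, labels]
  list(tree = phy, D = D)
}

# Path-length (patristic) matrix of a phylo tree, ordered like `labels`.
patristic <- function(phy, labels) {
  stats::cophenetic(phy)[labels, labels]
}
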