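#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: at each step the pair (i, j)
#' minimizing \eqn{S(i,j) = (n-2) d_{ij} - R_i - R_j} (with \eqn{R_i} the row
#' sum over active nodes) is joined; branch lengths follow the usual split
#' formulas.  Two deterministic conventions make runs bit-reproducible
#' across platforms: ties in \eqn{S} are broken by the lexicographically
#' smallest label pair (an internal node carries the smallest leaf label of
#' its subtree), and a negative branch length is clamped to 0 with the
#' deficit moved to its sibling edge so the joined pair's distance is
#' preserved.
#'
#' @param dm a \code{k2p_matrix} (must contain no saturated pair), or a
#'   symmetric numeric matrix with dimnames.
#' @return an unrooted tree of class \code{phylo} (root node is the final
#'   trifurcation).
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "k2p_matrix")) {
    if (any(dm$saturated[upper.tri(dm$saturated)])) {
      stop("distance matrix contains saturated pairs; resolve before NJ",
           call. = FALSE)
    }
    D <- dm$d
  } else {
    D <- as.matrix(dm)
  }
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  ids <- seq_len(n)            # node ids of active nodes (leaves are 1..n)
  labs <- labels               # tie-break label per active node
  next_id <- n + 1L
  ep <- ec <- integer(0); el <- numeric(0)  # edge parent/child/length

  add_edge <- function(p, ch, len) {
    ep <<- c(ep, p); ec <<- c(ec, ch); el <<- c(el, len)
  }

  while (length(ids) > 3L) {
    m <- length(ids)
    R <- rowSums(D)
    S <- (m - 2) * D - outer(R, R, "+")
    diag(S) <- Inf
    smin <- min(S)
    tol <- 1e-10 * (1 + abs(smin))
    cand <- which(S <= smin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    l1 <- pmin(labs[cand[, 1]], labs[cand[, 2]])
    l2 <- pmax(labs[cand[, 1]], labs[cand[, 2]])
    pick <- order(l1, l2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    dij <- D[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(0, bi + bj); bj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, ids[i], bi)
    add_edge(u, ids[j], bj)

    du <- (D[i, ] + D[j, ] - dij) / 2
    du <- pmax(du, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    ids <- c(ids[keep], u)
    labs <- c(labs[keep], min(labs[c(i, j)]))
  }

  # terminal three-point formulas
  b1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  root <- next_id
  add_edge(root, ids[1], b1)
  add_edge(root, ids[2], b2)
  add_edge(root, ids[3], b3)

  build_phylo(n, labels, root, ep, ec, el)
}

# Assemble an ape "phylo" from edges in construction-id space, renumbering
# internal nodes to ape's convention (root = n + 1, preorder).
build_phylo <- function(n, labels, root, ep, ec, el) {
  children <- split(seq_along(ep), ep)
  n_internal <- length(unique(ep))
  newid <- integer(root)
  newid[seq_len(n)] <- seq_len(n)
  next_internal <- n + 1L
  edge <- matrix(0L, length(ep), 2L)
  len <- numeric(length(ep))
  row <- 0L
  recurse <- function(node) {
    newid[node] <<- next_internal
    next_internal <<- next_internal + 1L
    for (e in children[[as.character(node)]]) {
      row <<- row + 1L
      myrow <- row
      child <- ec[e]
      if (child > n) {
        edge[myrow, 1L] <<- newid[node]
        recurse(child)
        edge[myrow, 2L] <<- newid[child]
      } else {
        edge[myrow, ] <<- c(newid[node], child)
      }
      len[myrow] <<- el[e]
    }
  }
  recurse(root)
  len[len == 0] <- 0  # normalize any negative zero
  # edges were emitted in preorder, i.e. already in cladewise order
  structure(list(edge = edge, edge.length = len,
                 tip.label = labels, Nnode = n_internal),
            class = "phylo")
}

#' Non-trivial bipartitions (splits) of an unrooted tree
#'
#' Each internal edge of an unrooted tree bipartitions the leaves.  Splits
#' are returned as canonical keys — the sorted leaf labels on the side not
#' containing the alphabetically first leaf, joined by \code{"|"} — so keys
#' are comparable between trees on the same leaf set.  Trivial splits
#' (single leaf on a side) are not reported.
#'
#' @param phy a \code{phylo} tree.
#' @return character vector of split keys (possibly empty).
#' @export
tree_splits <- function(phy) {
  tips <- phy$tip.label
  n <- length(tips)
  if (n < 4L) return(character(0))
  ref <- sort(tips)[1]
  pp <- ape::prop.part(phy)
  keys <- character(0)
  for (k in seq_along(pp)) {
    clade <- tips[pp[[k]]]
    sz <- length(clade)
    if (sz < 2L || sz > n - 2L) next
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Felsenstein column-resampling bootstrap: each replicate resamples
#' alignment columns of the haplotype sequences with replacement, recomputes
#' the K2P matrix and its NJ tree, and the support of a bipartition is the
#' fraction of (retained) replicates whose tree contains it.  A replicate
#' producing a saturated pair is dropped with a message; more than 10%
#' dropped is an error.  The reported tree is the NJ tree of the original
#' data annotated with integer percent supports as internal node labels.
#'
#' @param seqs named character vector of equal-length haplotype sequences.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed for the replicate resampling.
#' @return object of class \code{nj_boot}: list with \code{tree} (annotated
#'   \code{phylo}), \code{support} (data.frame split/support for the
#'   original tree's internal splits), \code{B}, \code{n_dropped},
#'   \code{seed}.
#' @export
bootstrap_support <- function(seqs, B = 1000L, seed = 1L) {
  stopifnot(B >= 1L)
  enc <- encode_dna(seqs)
  L <- ncol(enc)
  dm0 <- k2p_matrix_from_codes(enc)
  if (any(dm0$saturated[upper.tri(dm0$saturated)])) {
    stop("original matrix has saturated pairs; cannot bootstrap", call. = FALSE)
  }
  tree0 <- nj_tree(dm0)
  splits0 <- tree_splits(tree0)
  counts <- stats::setNames(rep(0L, length(splits0)), splits0)
  dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(L, L, replace = TRUE)
      dmb <- try(k2p_matrix_from_codes(enc[, cols, drop = FALSE]),
                 silent = TRUE)
      if (inherits(dmb, "try-error") ||
          any(dmb$saturated[upper.tri(dmb$saturated)])) {
        dropped <- dropped + 1L
        message(sprintf("bootstrap replicate %d dropped (saturated pair)", b))
        next
      }
      sb <- tree_splits(nj_tree(dmb))
      hit <- splits0 %in% sb
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (dropped > 0.1 * B) {
    stop(sprintf("%d of %d bootstrap replicates dropped (saturation)",
                 dropped, B), call. = FALSE)
  }
  used <- B - dropped
  support <- counts / used
  list_support <- data.frame(split = splits0, support = unname(support),
                             stringsAsFactors = FALSE)
  structure(list(tree = annotate_support(tree0, support),
                 support = list_support, B = B, n_dropped = dropped,
                 seed = seed),
            class = "nj_boot")
}

# Attach integer percent supports as node labels of the matching internal
# nodes; nodes without a tracked split (root, trivial) get an empty label.
annotate_support <- function(phy, support) {
  tips <- phy$tip.label
  n <- length(tips)
  ref <- sort(tips)[1]
  pp <- ape::prop.part(phy)
  lab <- character(phy$Nnode)
  for (k in seq_along(pp)) {
    clade <- tips[pp[[k]]]
    sz <- length(clade)
    if (sz < 2L || sz > n - 2L) next
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      lab[k] <- as.character(round(100 * support[[key]]))
    }
  }
  phy$node.label <- lab
  phy
}

#' @export
print.nj_boot <- function(x, ...) {
  cat(sprintf("NJ tree with bootstrap supports: %d leaves, B = %d (%d dropped), seed %d\n",
              length(x$tree$tip.label), x$B, x$n_dropped, x$seed))
  invisible(x)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with the requested precision; internal node
#' labels (integer percent supports, when present) are preserved.
#'
#' @param tree a \code{phylo} or \code{nj_boot} object.
#' @param path optional output file; when NULL the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  if (inherits(tree, "nj_boot")) tree <- tree$tree
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
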