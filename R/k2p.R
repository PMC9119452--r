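#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence has a gap or an ambiguity code are excluded
#' (pairwise deletion).  With transition proportion \eqn{P} (A<->G, C<->T)
#' and transversion proportion \eqn{Q} over the compared sites, the distance
#' is \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#' When a logarithm argument is non-positive the pair is saturated: \code{d}
#' is \code{NA} and \code{saturated = TRUE} (no exception), so callers can
#' exclude such pairs explicitly.
#'
#' @param seq1,seq2 equal-length DNA strings (uppercase IUPAC).
#' @return list with \code{d}, \code{P}, \code{Q}, \code{n_sites},
#'   \code{saturated}.
#' @examples
#' s <- paste(rep("ACGT", 10), collapse = "")
#' k2p(s, s)$d  # 0
#' @export
k2p <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  enc <- encode_dna(c(seq1, seq2))
  k2p_from_codes(enc[1, ], enc[2, ])
}

# Core K2P on integer-coded site vectors (1=A, 2=G, 3=C, 4=T; NA = deleted).
k2p_from_codes <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites after pairwise deletion", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  # purines coded 1,2; pyrimidines 3,4: a mismatch within the same class of
  # two is a transition, across classes a transversion
  ts <- sum(diff & ((x <= 2L) == (y <= 2L)))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    return(list(d = NA_real_, P = P, Q = Q, n_sites = n, saturated = TRUE))
  }
  list(d = -0.5 * log(a1) - 0.25 * log(a2), P = P, Q = Q, n_sites = n,
       saturated = FALSE)
}

#' Pairwise K2P distance matrix over haplotypes
#'
#' Computes every unordered pair once.  Saturated pairs are flagged in the
#' \code{saturated} component, set \code{NA} in \code{d}, and reported with
#' a warning; downstream summaries exclude them rather than clipping.
#'
#' @param x a named character vector of equal-length sequences, or a
#'   \code{haplotype_table} (uses its \code{haplotype} names and sequences).
#' @return object of class \code{k2p_matrix}: list with matrices \code{d},
#'   \code{P}, \code{Q}, \code{n_sites}, logical \code{saturated}, and
#'   \code{labels}.  Diagonals are exactly 0.
#' @export
k2p_matrix <- function(x) {
  seqs <- as_named_seqs(x)
  if (length(seqs) < 2L) stop("need at least 2 haplotypes", call. = FALSE)
  enc <- encode_dna(seqs)
  res <- k2p_matrix_from_codes(enc)
  n_sat <- sum(res$saturated[upper.tri(res$saturated)])
  if (n_sat > 0L) {
    warning(sprintf("%d saturated pair(s) flagged and excluded from summaries",
                    n_sat), call. = FALSE)
  }
  res
}

k2p_matrix_from_codes <- function(enc) {
  n <- nrow(enc)
  labels <- rownames(enc) %||% as.character(seq_len(n))
  d <- P <- Q <- matrix(0, n, n, dimnames = list(labels, labels))
  ns <- matrix(ncol(enc), n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- k2p_from_codes(enc[i, ], enc[j, ])
      d[i, j] <- d[j, i] <- p$d
      P[i, j] <- P[j, i] <- p$P
      Q[i, j] <- Q[j, i] <- p$Q
      ns[i, j] <- ns[j, i] <- p$n_sites
      sat[i, j] <- sat[j, i] <- p$saturated
    }
  }
  structure(list(d = d, P = P, Q = Q, n_sites = ns, saturated = sat,
                 labels = labels), class = "k2p_matrix")
}

as_named_seqs <- function(x) {
  if (inherits(x, "haplotype_table")) {
    nm <- if (all(!is.na(x$haplotype))) x$haplotype else
      paste0("h", seq_len(nrow(x)))
    stats::setNames(x$sequence, nm)
  } else if (inherits(x, "aligned_set")) {
    stats::setNames(x$records$sequence, x$records$id)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    x
  }
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat(sprintf("k2p_matrix: %d haplotypes, %d saturated pair(s)\n",
              length(x$labels), sum(x$saturated[upper.tri(x$saturated)])))
  print(round(x$d, 4))
  invisible(x)
}

#' Within- and between-group distance summaries
#'
#' Means are unweighted over haplotype pairs — haplotype frequencies and
#' numbers of individuals never enter the averages.  Within-group rows have
#' \code{group_a == group_b}; a single-haplotype group reports
#' mean = min = max = 0 with \code{n_pairs = 0} by convention.  Saturated
#' pairs are dropped from the statistics.
#'
#' @param dm a \code{k2p_matrix}.
#' @param group_map named character vector, haplotype label -> group.
#' @param exclude haplotype labels to leave out entirely (e.g. haplotypes of
#'   hybrid-suspect groups, which are excluded from species averages).
#' @return data.frame with columns group_a, group_b, mean, min, max, n_pairs.
#' @export
group_summaries <- function(dm, group_map, exclude = character(0)) {
  stopifnot(inherits(dm, "k2p_matrix"))
  labels <- setdiff(dm$labels, exclude)
  unmapped <- setdiff(labels, names(group_map))
  if (length(unmapped) > 0L) {
    stop("unmapped haplotype(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(unname(group_map[labels]))
  rows <- list()
  for (i in seq_along(groups)) {
    for (j in i:length(groups)) {
      a <- labels[group_map[labels] == groups[i]]
      b <- labels[group_map[labels] == groups[j]]
      rows[[length(rows) + 1L]] <-
        pair_stats(dm, a, b, groups[i], groups[j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Summary over cross pairs of label sets a, b (a == b means within-group).
pair_stats <- function(dm, a, b, name_a, name_b) {
  within <- identical(name_a, name_b)
  if (within && length(a) == 1L) {
    return(data.frame(group_a = name_a, group_b = name_b,
                      mean = 0, min = 0, max = 0, n_pairs = 0L,
                      stringsAsFactors = FALSE))
  }
  if (within) {
    pairs <- utils::combn(a, 2L)
    d <- dm$d[cbind(pairs[1, ], pairs[2, ])]
    s <- dm$saturated[cbind(pairs[1, ], pairs[2, ])]
  } else {
    grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    d <- dm$d[cbind(grid$a, grid$b)]
    s <- dm$saturated[cbind(grid$a, grid$b)]
  }
  d <- d[!s]
  if (length(d) == 0L) {
    return(data.frame(group_a = name_a, group_b = name_b,
                      mean = NA_real_, min = NA_real_, max = NA_real_,
                      n_pairs = 0L, stringsAsFactors = FALSE))
  }
  data.frame(group_a = name_a, group_b = name_b,
             mean = mean(d), min = min(d), max = max(d),
             n_pairs = length(d), stringsAsFactors = FALSE)
}

#' Barcoding-gap assessment
#'
#' Pools the within-group and between-group distance ranges and reports
#' whether they overlap.  A clear gap (no overlap, large fold ratio between
#' the mean between-species and mean within-species distances) is what makes
#' barcode-based species identification reliable.
#'
#' @param within within-group summary rows (\code{group_a == group_b}).
#' @param between between-group summary rows.
#' @return object of class \code{gap_report}: list with \code{within_range},
#'   \code{between_range}, \code{overlap} and \code{fold_ratio}
#'   (\code{Inf} when the mean within-distance is 0).
#' @export
barcode_gap <- function(within, between) {
  if (nrow(within) == 0L || nrow(between) == 0L) {
    stop("need both within- and between-group summaries", call. = FALSE)
  }
  wr <- c(min(within$min, na.rm = TRUE), max(within$max, na.rm = TRUE))
  br <- c(min(between$min, na.rm = TRUE), max(between$max, na.rm = TRUE))
  mw <- mean(within$mean, na.rm = TRUE)
  mb <- mean(between$mean, na.rm = TRUE)
  structure(list(within_range = wr, between_range = br,
                 overlap = br[1] <= wr[2],
                 fold_ratio = if (mw == 0) Inf else mb / mw,
                 mean_within = mw, mean_between = mb),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("within:  %.4f-%.4f (mean %.4f)\n", x$within_range[1],
              x$within_range[2], x$mean_within))
  cat(sprintf("between: %.4f-%.4f (mean %.4f)\n", x$between_range[1],
              x$between_range[2], x$mean_between))
  cat(sprintf("barcoding gap: %s (fold ratio %.1f)\n",
              if (x$overlap) "ranges OVERLAP" else "no overlap",
              x$fold_ratio))
  invisible(x)
}

#' Write a labeled square distance matrix to TSV
#'
#' @param dm a \code{k2p_matrix}.
#' @param path output path.
#' @param digits decimal places (default 4, the conventional reporting
#'   precision for barcode distances).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, digits = 4) {
  m <- format(round(dm$d, digits), nsmall = digits, trim = TRUE)
  m[dm$saturated] <- "SATURATED"
  diag(m) <- "0"
  out <- cbind(haplotype = dm$labels, as.data.frame(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
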