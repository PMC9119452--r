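#' Read a local reference library (FASTA + taxonomy TSV)
#'
#' A local stand-in for a public barcode reference library: sequences in
#' FASTA, taxonomy in a TSV with columns \code{sequence_id}, \code{species},
#' \code{source_tag} and optional \code{location}.
#'
#' @param fasta_path reference sequences (FASTA).
#' @param meta_path taxonomy table (TSV).
#' @return data.frame with columns id, species, source, location, sequence.
#' @export
read_reference_library <- function(fasta_path, meta_path) {
  fa <- read_barcode_fasta(fasta_path)
  tab <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sequence_id", "species")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("reference taxonomy missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  i <- match(fa$id, tab$sequence_id)
  if (anyNA(i)) {
    stop("reference sequence(s) without taxonomy: ",
         paste(fa$id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  data.frame(id = fa$id, species = tab$species[i],
             source = (tab$source_tag %||% rep(NA_character_, nrow(tab)))[i],
             location = (tab$location %||% rep(NA_character_, nrow(tab)))[i],
             sequence = fa$sequence, stringsAsFactors = FALSE)
}

#' Identify a query sequence against a reference library
#'
#' Percent identity is computed over pairwise-deleted sites (both sequences
#' A/C/G/T) of the shared region; sequences of unequal length are compared
#' over their common prefix, which assumes a shared alignment frame.  Hits
#' are ranked species-level by the best identity among that species'
#' reference entries; hits below \code{min_identity} are omitted.  When two
#' or more species tie for the top identity (at 4 decimal places) the call
#' is \code{"AMBIGUOUS"} rather than broken arbitrarily — distinct species
#' can share identical barcodes.
#'
#' @param query a DNA string (uppercase IUPAC).
#' @param reference a reference library data.frame (see
#'   [read_reference_library()]).
#' @param min_identity minimum percent identity to report a hit (default 97,
#'   a conventional barcoding screen).
#' @param min_overlap minimum number of compared sites for a valid
#'   comparison (default 200).
#' @return list with \code{hits} (data.frame species, identity, k2p_d,
#'   ref_id, n_sites ranked by descending identity), \code{called_species}
#'   (top species, \code{"AMBIGUOUS"} on a tie, \code{NA} with no hit) and
#'   \code{ambiguous} flag.
#' @export
identify_species <- function(query, reference, min_identity = 97,
                             min_overlap = 200L) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("reference library is empty", call. = FALSE)
  }
  qlen <- nchar(query)
  res <- lapply(seq_len(nrow(reference)), function(i) {
    ref_seq <- reference$sequence[i]
    L <- min(qlen, nchar(ref_seq))
    if (L < min_overlap) return(NULL)
    enc <- encode_dna(c(substr(query, 1L, L), substr(ref_seq, 1L, L)))
    ok <- !is.na(enc[1, ]) & !is.na(enc[2, ])
    n <- sum(ok)
    if (n < min_overlap) return(NULL)
    ident <- 100 * sum(enc[1, ok] == enc[2, ok]) / n
    p <- k2p_from_codes(enc[1, ], enc[2, ])
    data.frame(species = reference$species[i], identity = ident,
               k2p_d = p$d, ref_id = reference$id[i], n_sites = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) {
    stop("query shares no usable region (>= ", min_overlap,
         " sites) with any reference entry", call. = FALSE)
  }
  # species-level: best entry per species
  res <- res[order(-res$identity, res$species), , drop = FALSE]
  res <- res[!duplicated(res$species), , drop = FALSE]
  hits <- res[res$identity >= min_identity, , drop = FALSE]
  rownames(hits) <- NULL
  if (nrow(hits) == 0L) {
    return(list(hits = hits, called_species = NA_character_,
                ambiguous = FALSE))
  }
  top <- round(hits$identity[1], 4)
  ties <- unique(hits$species[round(hits$identity, 4) == top])
  if (length(ties) > 1L) {
    list(hits = hits, called_species = "AMBIGUOUS", ambiguous = TRUE)
  } else {
    list(hits = hits, called_species = hits$species[1], ambiguous = FALSE)
  }
}

#' Identify every haplotype of a table against a reference library
#'
#' @param tab a named \code{haplotype_table}.
#' @inheritParams identify_species
#' @return data.frame with one row per haplotype: query, called_species,
#'   top_identity, top_k2p_d, second_species, second_identity, ambiguous.
#' @export
identify_all <- function(tab, reference, min_identity = 97,
                         min_overlap = 200L) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- identify_species(tab$sequence[i], reference,
                          min_identity = min_identity,
                          min_overlap = min_overlap)
    h <- r$hits
    data.frame(query = tab$haplotype[i],
               group = tab$group[i],
               called_species = r$called_species,
               top_identity = if (nrow(h) > 0) h$identity[1] else NA_real_,
               top_k2p_d = if (nrow(h) > 0) h$k2p_d[1] else NA_real_,
               second_species = if (nrow(h) > 1) h$species[2] else NA_character_,
               second_identity = if (nrow(h) > 1) h$identity[2] else NA_real_,
               ambiguous = r$ambiguous,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag morphology/molecular discrepancies and hybrid evidence
#'
#' Per sample: \code{discrepancy} is TRUE when the molecular call differs
#' from the morphological species label (an AMBIGUOUS call, and a
#' same-genus different-species call, both count as discrepancies);
#' \code{hybrid_evidence} is TRUE when a hybrid-suspect sample's
#' mitochondrial call differs from its morphological label — the
#' mitochondrial genome of one parent species in a hybrid.
#'
#' @param assignments per-haplotype assignment table from [identify_all()].
#' @param tab the named \code{haplotype_table} (provides haplotype
#'   membership).
#' @param records the annotated sample records (species label and
#'   hybrid-suspect flag per sample id).
#' @return data.frame with one row per sample: id, species, haplotype,
#'   called_species, discrepancy, hybrid_evidence.
#' @export
flag_discrepancies <- function(assignments, tab, records) {
  i <- match(tab$haplotype, assignments$query)
  if (anyNA(i)) {
    stop("assignment missing for haplotype(s): ",
         paste(tab$haplotype[is.na(i)], collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(tab)), function(k) {
    ids <- strsplit(tab$members[k], ",", fixed = TRUE)[[1]]
    data.frame(id = ids, haplotype = tab$haplotype[k],
               called_species = assignments$called_species[i[k]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  j <- match(out$id, records$id)
  if (anyNA(j)) {
    stop("sample(s) missing from records: ",
         paste(out$id[is.na(j)], collapse = ", "), call. = FALSE)
  }
  out$species <- records$species[j]
  hybrid_suspect <- records$hybrid_suspect[j] %in% TRUE
  out$discrepancy <- !is.na(out$called_species) &
    out$called_species != out$species
  out$hybrid_evidence <- hybrid_suspect & out$discrepancy
  out <- out[c("id", "species", "haplotype", "called_species",
               "discrepancy", "hybrid_evidence")]
  rownames(out) <- NULL
  out
}

#' Population-structured distance table
#'
#' Groups haplotypes into named populations (e.g. a species split by
#' geography) and reports, for every unordered pair of populations
#' including self-pairs, the unweighted mean and range of the cross-pair
#' K2P distances.  The self-pair of a singleton population reports 0.
#'
#' @param dm a \code{k2p_matrix}.
#' @param groups named list: population name -> character vector of
#'   haplotype labels.  Populations must be disjoint and all members present
#'   in the matrix.
#' @return data.frame with columns group_a, group_b, mean, min, max,
#'   n_pairs, ordered following the input group order.
#' @export
population_table <- function(dm, groups) {
  stopifnot(inherits(dm, "k2p_matrix"), length(groups) >= 1L)
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("population groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(all_members, dm$labels)
  if (length(missing) > 0L) {
    stop("haplotype(s) not in distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nms <- names(groups)
  rows <- list()
  for (i in seq_along(groups)) {
    for (j in i:length(groups)) {
      rows[[length(rows) + 1L]] <-
        pair_stats(dm, groups[[i]], groups[[j]], nms[i], nms[j])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a population distance table in mean-line/range-line layout
#'
#' Lower-triangular matrix layout with, in each cell, the mean K2P value on
#' one line and the min-max range on the next.
#'
#' @param pop_table output of [population_table()].
#' @param path output TSV path.
#' @param digits decimal places (default 4).
#' @return `path`, invisibly.
#' @export
write_population_table <- function(pop_table, path, digits = 4) {
  nms <- unique(c(pop_table$group_a, pop_table$group_b))
  fmt <- function(x) format(round(x, digits), nsmall = digits, trim = TRUE)
  lines <- paste(c("", nms), collapse = "\t")
  for (a in nms) {
    mean_cells <- range_cells <- character(0)
    for (b in nms) {
      row <- pop_table[(pop_table$group_a == a & pop_table$group_b == b) |
                       (pop_table$group_a == b & pop_table$group_b == a), ]
      if (nrow(row) == 0L || match(b, nms) > match(a, nms)) {
        mean_cells <- c(mean_cells, "")
        range_cells <- c(range_cells, "")
      } else {
        mean_cells <- c(mean_cells, fmt(row$mean[1]))
        range_cells <- c(range_cells,
                         paste0(fmt(row$min[1]), "-", fmt(row$max[1])))
      }
    }
    lines <- c(lines, paste(c(a, mean_cells), collapse = "\t"),
               paste(c("", range_cells), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
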