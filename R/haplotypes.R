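#' Collapse aligned sequences into haplotypes
#'
#' Within each group, sequences identical over all unambiguous (A/C/G/T)
#' positions are one haplotype.  A sequence carrying ambiguity codes joins an
#' existing unambiguous haplotype if and only if it is compatible with
#' exactly one of them at every ambiguous position; otherwise it stands as
#' its own haplotype flagged \code{ambiguous_only}.  Samples flagged
#' \code{hybrid_suspect} are collapsed in a parallel group of their own
#' (group label suffixed \code{*}) and are never merged with non-suspect
#' samples of the same species, so that suspected introgressed mitochondria
#' cannot inflate within-species variation.
#'
#' @param aligned an \code{aligned_set} from [trim_to_region()], or a record
#'   data.frame of equal-length sequences.
#' @param group_key \code{"species"} or \code{"species+location"}.
#' @return a \code{haplotype_table}: data.frame with one row per haplotype
#'   and columns group, species, n_samples (group size), haplotype (NA until
#'   [name_haplotypes()] is applied), sequence, count, frequency, members
#'   (comma-separated sample ids), ambiguous_only.  Rows are ordered within
#'   a group by descending count, ties by first appearance.
#' @export
collapse_haplotypes <- function(aligned, group_key = c("species", "species+location")) {
  group_key <- match.arg(group_key)
  records <- if (inherits(aligned, "aligned_set")) aligned$records else aligned
  if (nrow(records) == 0L) stop("no records to collapse", call. = FALSE)
  if (anyNA(records$species)) {
    stop("records lack species labels; join metadata first", call. = FALSE)
  }
  base <- if (group_key == "species") records$species
          else paste(records$species, records$location, sep = " @ ")
  group <- ifelse(records$hybrid_suspect %in% TRUE, paste0(base, "*"), base)

  out <- lapply(unique(group), function(g) {
    idx <- which(group == g)
    collapse_one_group(records[idx, , drop = FALSE], g)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("haplotype_table", "data.frame")
  tab
}

# Collapse one group of records sharing a group label.
collapse_one_group <- function(rec, group_label) {
  n <- nrow(rec)
  # exact collapse, clusters in first-appearance order
  first <- !duplicated(rec$sequence)
  reps <- rec$sequence[first]
  cluster <- match(rec$sequence, reps)
  members <- split(rec$id, cluster)

  is_ambig <- grepl("[^ACGT]", reps)
  merged_into <- seq_along(reps)
  ambiguous_only <- rep(FALSE, length(reps))
  anchors <- which(!is_ambig)
  for (k in which(is_ambig)) {
    compat <- anchors[vapply(anchors, function(a) {
      ambiguity_compatible(reps[k], reps[a])
    }, logical(1))]
    if (length(compat) == 1L) merged_into[k] <- compat
    else ambiguous_only[k] <- TRUE
  }

  keep <- sort(unique(merged_into))
  counts <- vapply(keep, function(k) {
    sum(lengths(members[as.character(which(merged_into == k))]))
  }, integer(1))
  mem <- vapply(keep, function(k) {
    paste(unlist(members[as.character(which(merged_into == k))]), collapse = ",")
  }, character(1))
  ord <- order(-counts, keep)  # desc count, ties by first appearance
  keep <- keep[ord]; counts <- counts[ord]; mem <- mem[ord]

  data.frame(group = group_label,
             species = sub("\\*$", "", sub(" @ .*$", "", group_label)),
             n_samples = n,
             haplotype = NA_character_,
             sequence = reps[keep],
             count = counts,
             frequency = counts / n,
             members = mem,
             ambiguous_only = ambiguous_only[keep],
             stringsAsFactors = FALSE)
}

# TRUE when an ambiguity-carrying sequence is compatible with an unambiguous
# haplotype: equal at its A/C/G/T positions, and the haplotype base lies in
# the ambiguity set elsewhere.
ambiguity_compatible <- function(ambig, anchor) {
  a <- strsplit(ambig, "", fixed = TRUE)[[1]]
  b <- strsplit(anchor, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) return(FALSE)
  all(vapply(seq_along(a), function(i) b[i] %in% .iupac_sets[[a[i]]], logical(1)))
}

#' Assign letter names to haplotypes
#'
#' Haplotypes are named species acronym + capital letter in table order
#' (A, B, ... then AA, AB, ... past 26).  Haplotypes of a hybrid-suspect
#' group keep the species acronym with a \code{*} suffix on the name so
#' labels stay unique in downstream distance matrices and trees.
#'
#' @param tab a \code{haplotype_table} from [collapse_haplotypes()].
#' @param acronyms named character vector, species -> 2-3 letter code; when
#'   NULL, codes are derived from the species name initials and uniquified.
#' @return the table with the \code{haplotype} column filled; naming is
#'   deterministic for identical input.
#' @export
name_haplotypes <- function(tab, acronyms = NULL) {
  species <- unique(tab$species)
  if (is.null(acronyms)) {
    acronyms <- default_acronyms(species)
  } else {
    miss <- setdiff(species, names(acronyms))
    if (length(miss) > 0L) {
      stop("no acronym for species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(acronyms[species])) {
      stop("species acronyms must be unique", call. = FALSE)
    }
  }
  # letters run across all groups of one species (locations, hybrid group)
  # in table order, so e.g. a species split by geography still gets A..D
  for (sp in unique(tab$species)) {
    idx <- which(tab$species == sp)
    suffix <- ifelse(endsWith(tab$group[idx], "*"), "*", "")
    tab$haplotype[idx] <- paste0(acronyms[[sp]], letter_series(length(idx)),
                                 suffix)
  }
  if (anyDuplicated(tab$haplotype)) {
    stop("haplotype names are not unique; check the acronym map",
         call. = FALSE)
  }
  tab
}

# "Garra rufa" -> "Gr"; collisions are extended with further characters of
# the name until unique (make.unique as a last resort).
default_acronyms <- function(species) {
  words <- strsplit(species, "[ _]+")
  code <- vapply(words, function(w) {
    if (length(w) >= 2L) paste0(toupper(substr(w[1], 1, 1)),
                                tolower(substr(w[2], 1, 1)))
    else paste0(toupper(substr(w[1], 1, 1)), tolower(substr(w[1], 2, 2)))
  }, character(1))
  flat <- vapply(words, paste, character(1), collapse = "")
  k <- 3L
  while (anyDuplicated(code) && k <= max(nchar(flat))) {
    dup <- duplicated(code) | duplicated(code, fromLast = TRUE)
    code[dup] <- paste0(code[dup], tolower(substr(flat[dup], k, k)))
    k <- k + 1L
  }
  if (anyDuplicated(code)) code <- make.unique(code, sep = "")
  stats::setNames(code, species)
}

#' Mark haplotypes as known or new relative to a reference library
#'
#' A haplotype is "known" when its exact sequence occurs in the reference
#' library and "new" otherwise — the book-keeping used to count barcodes a
#' survey adds to a public library.
#'
#' @param tab a \code{haplotype_table}.
#' @param reference a reference library data.frame with a \code{sequence}
#'   column (possibly zero rows).
#' @return the table with a logical \code{new} column; the per-species count
#'   of new haplotypes is available via [summary_new_haplotypes()].
#' @export
new_vs_reference <- function(tab, reference) {
  ref_seqs <- if (is.null(reference) || nrow(reference) == 0L) character(0)
              else reference$sequence
  tab$new <- !(tab$sequence %in% ref_seqs)
  tab
}

#' @rdname new_vs_reference
#' @export
summary_new_haplotypes <- function(tab) {
  if (is.null(tab$new)) stop("run new_vs_reference() first", call. = FALSE)
  agg <- stats::aggregate(cbind(n_new = tab$new),
                          by = list(species = tab$species), FUN = sum)
  agg[order(agg$species), , drop = FALSE]
}

#' Write a haplotype frequency table to TSV
#'
#' Columns: species, n_samples, haplotype, count, frequency (4 decimal
#' places) and, when present, the new-to-reference flag.
#'
#' @param tab a named \code{haplotype_table}.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(tab, path) {
  out <- data.frame(species = tab$group, n_samples = tab$n_samples,
                    haplotype = tab$haplotype, count = tab$count,
                    frequency = sprintf("%.4f", tab$frequency),
                    stringsAsFactors = FALSE)
  if (!is.null(tab$new)) out$new <- ifelse(tab$new, "new", "known")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
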