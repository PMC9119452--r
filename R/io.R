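#' Read barcode sequences from a FASTA file
#'
#' Reads a FASTA file into a barcode record table.  The first
#' whitespace-delimited token of each header is taken as the sample id.
#' Sequences are stored uppercase with \code{U} mapped to \code{T}; any
#' character outside the IUPAC DNA alphabet (ACGT, ambiguity codes, \code{-})
#' is an error.  Metadata columns (\code{species}, \code{location},
#' \code{hybrid_suspect}) are left \code{NA} until joined with
#' \code{\link{join_metadata}}.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns \code{id}, \code{species},
#'   \code{location}, \code{hybrid_suspect}, \code{sequence}; zero rows for
#'   an empty file.
#' @seealso [join_metadata()], [trim_to_region()]
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_records())
  if (!startsWith(lines[[1]], ">")) {
    stop("not FASTA: first non-blank line must start with '>'", call. = FALSE)
  }
  fa <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  ids <- vapply(fa, function(s) attr(s, "name"), character(1))
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- vapply(seq_along(fa), function(i) {
    s <- as.character(fa[[i]])
    if (!nzchar(s)) stop("empty sequence for header ", sQuote(ids[i]),
                         call. = FALSE)
    canonicalize_dna(s, context = paste0("entry ", sQuote(ids[i])))
  }, character(1))
  data.frame(id = ids, species = NA_character_, location = NA_character_,
             hybrid_suspect = NA, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(id = character(0), species = character(0),
             location = character(0), hybrid_suspect = logical(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Write barcode records to FASTA
#'
#' @param records a record data.frame with \code{id} and \code{sequence}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(records, path) {
  seqinr::write.fasta(as.list(records$sequence), names = records$id,
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header \code{id}, \code{species}, \code{location},
#' \code{hybrid_suspect}; the hybrid flag is parsed from
#' yes/no/true/false/1/0 (case-insensitive).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns id, species, location, hybrid_suspect.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "species", "location", "hybrid_suspect")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$hybrid_suspect <- parse_flag(tab$hybrid_suspect)
  tab[need]
}

parse_flag <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "true", "1")] <- TRUE
  out[lx %in% c("no", "false", "0")] <- FALSE
  if (anyNA(out)) {
    stop("unparseable hybrid_suspect value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Join sequence records with sample metadata
#'
#' Every record must be present in the metadata table; metadata ids must be
#' unique.  Extra metadata rows (samples without a sequence) are ignored.
#'
#' @param records record data.frame from [read_barcode_fasta()].
#' @param metadata data.frame with columns id, species, location,
#'   hybrid_suspect (see [read_sample_metadata()]).
#' @return the records annotated with species, location and hybrid flag.
#' @export
join_metadata <- function(records, metadata) {
  dup <- metadata$id[duplicated(metadata$id)]
  if (length(dup) > 0L) {
    stop("duplicate metadata id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(records$id, metadata$id)
  if (length(missing) > 0L) {
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  i <- match(records$id, metadata$id)
  records$species <- metadata$species[i]
  records$location <- metadata$location[i]
  records$hybrid_suspect <- as.logical(metadata$hybrid_suspect[i])
  records
}

#' Trim sequences to a shared analysis region
#'
#' Barcode amplicons are usually longer than the region every sample covers;
#' analyses run on a common window (e.g. a 530 bp COI core).  In
#' \code{"explicit"} mode the window is given as 1-based inclusive
#' \code{start}..\code{end}; records too short to cover it are dropped with a
#' warning and returned separately.  In \code{"auto"} mode the maximal window
#' covered by every sequence (ignoring leading/trailing gaps \code{-} and
#' \code{N} runs) is used; internal gaps inside the auto window are an error,
#' since coding-region barcodes are effectively indel-free.
#'
#' @param records annotated record data.frame.
#' @param mode \code{"auto"} or \code{"explicit"}.
#' @param start,end 1-based inclusive window bounds (explicit mode).
#' @return an object of class \code{aligned_set}: list with \code{records}
#'   (equal-length sequences), \code{length}, \code{window} (1-based bounds)
#'   and \code{dropped} (records that could not cover the window).
#' @export
trim_to_region <- function(records, mode = c("auto", "explicit"),
                           start = NULL, end = NULL) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("no records to trim", call. = FALSE)
  lens <- nchar(records$sequence)
  if (mode == "explicit") {
    if (is.null(start) || is.null(end)) {
      stop("explicit mode needs start and end", call. = FALSE)
    }
    if (start < 1L || end < start) stop("invalid window", call. = FALSE)
    keep <- lens >= end
    dropped <- records[!keep, , drop = FALSE]
    if (nrow(dropped) > 0L) {
      warning(sprintf("dropped %d record(s) shorter than window end %d: %s",
                      nrow(dropped), end,
                      paste(dropped$id, collapse = ", ")), call. = FALSE)
    }
    records <- records[keep, , drop = FALSE]
    if (nrow(records) == 0L) stop("no record covers the window", call. = FALSE)
    records$sequence <- substr(records$sequence, start, end)
    window <- c(start, end)
  } else {
    if (length(unique(lens)) != 1L) {
      stop("auto mode requires equal-length (aligned) input sequences",
           call. = FALSE)
    }
    L <- lens[1]
    cov <- t(vapply(strsplit(records$sequence, "", fixed = TRUE),
                    function(ch) {
                      real <- !(ch %in% c("-", "N", "?"))
                      if (!any(real)) c(NA_integer_, NA_integer_)
                      else range(which(real))
                    }, integer(2)))
    if (anyNA(cov)) {
      stop("record(s) with no called bases: ",
           paste(records$id[is.na(cov[, 1])], collapse = ", "), call. = FALSE)
    }
    start <- max(cov[, 1]); end <- min(cov[, 2])
    if (start > end) stop("sequences share no overlapping region", call. = FALSE)
    records$sequence <- substr(records$sequence, start, end)
    gapped <- grepl("-", records$sequence, fixed = TRUE)
    if (any(gapped)) {
      stop("internal gap inside shared region in: ",
           paste(records$id[gapped], collapse = ", "), call. = FALSE)
    }
    dropped <- empty_records()
    window <- c(start, end)
  }
  structure(list(records = records,
                 length = as.integer(window[2] - window[1] + 1L),
                 window = as.integer(window),
                 dropped = dropped),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("aligned_set: %d sequence(s) of %d bp (window %d..%d), %d dropped\n",
              nrow(x$records), x$length, x$window[1], x$window[2],
              nrow(x$dropped)))
  invisible(x)
}
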