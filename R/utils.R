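# Internal helpers shared across modules.

# IUPAC ambiguity codes -> sets of compatible bases (integer codes 1..4 for
# A, G, C, T).  '-' (gap) and '?' are treated as fully missing.
.base_code <- c(A = 1L, G = 2L, C = 3L, T = 4L)

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T")
)

.iupac_alphabet <- names(.iupac_sets)

# Canonicalize a DNA string: uppercase, U -> T.  Errors (with `context` in
# the message) on characters outside the IUPAC DNA alphabet.
canonicalize_dna <- function(x, context = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  chars <- unique(strsplit(paste(x, collapse = ""), "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, .iupac_alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character(s) %s in %s",
                 paste(sQuote(bad), collapse = ", "), context), call. = FALSE)
  }
  x
}

# Encode equal-length DNA strings as an integer matrix (rows = sequences,
# columns = sites); anything other than A/C/G/T becomes NA and is handled by
# pairwise deletion downstream.
encode_dna <- function(seqs) {
  stopifnot(length(seqs) > 0L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length", call. = FALSE)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  enc <- matrix(.base_code[m], nrow = length(seqs), ncol = L)
  rownames(enc) <- names(seqs)
  enc
}

decode_dna <- function(enc) {
  bases <- names(.base_code)
  apply(enc, 1L, function(r) paste(ifelse(is.na(r), "N", bases[r]), collapse = ""))
}

# Haplotype letter series: A..Z, AA, AB, ... (bijective base-26).
letter_series <- function(n) {
  vapply(seq_len(n), function(i) {
    s <- character(0)
    while (i > 0L) {
      r <- (i - 1L) %% 26L
      s <- c(LETTERS[r + 1L], s)
      i <- (i - 1L) %/% 26L
    }
    paste(s, collapse = "")
  }, character(1))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
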