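#' Read nucleotide sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a
#' [Biostrings::DNAStringSet]. Residues are uppercased and RNA `U` is mapped
#' to DNA `T`, so downstream code works on a single DNA+IUPAC alphabet.
#' Empty records are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record, order
#'   preserved; names are the full header lines (without the `>`).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgu"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop("malformed FASTA (line 1): expected a '>' header in ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no records in FASTA file: ", path)
  chars <- toupper(as.character(raw))
  chars <- chartr("U", "T", chars)
  empty <- which(nchar(chars) == 0L)
  if (length(empty) > 0L)
    stop("empty FASTA record: ", names(raw)[empty[1L]])
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(raw)
  out
}

#' Write sequences to a FASTA file
#'
#' Each record is written as a header line followed by the residues on a
#' single line, so that `read_fasta(write_fasta(x, f))` round-trips.
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  chars <- as_seq_chars(seqs)
  if (length(chars) > 0L && (is.null(names(chars)) || any(!nzchar(names(chars)))))
    stop("all sequences must have nonempty ids")
  lines <- if (length(chars) == 0L) character(0)
           else as.vector(rbind(paste0(">", names(chars)), unname(chars)))
  writeLines(lines, path)
  invisible(path)
}

# internal: coerce DNAStringSet / DNAString / character to a named character
# vector of uppercase residues
as_seq_chars <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (methods::is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq"
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("cannot interpret object of class ", class(x)[1L], " as sequences")
  }
  toupper(chartr("U", "T", out))
}

# internal: a single sequence as one character scalar
as_seq_string <- function(x) {
  chars <- as_seq_chars(x)
  if (length(chars) != 1L) stop("expected a single sequence, got ", length(chars))
  unname(chars)
}

# Fractional one-hot rows for the full DNA+IUPAC alphabet, fixed column
# order A, C, G, T.  Ambiguity codes get the uniform distribution over their
# compatible bases so every row sums to 1.
iupac_onehot_rows <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  rows <- t(vapply(map, function(bases) {
    b <- strsplit(bases, "")[[1L]]
    r <- as.numeric(c("A", "C", "G", "T") %in% b)
    r / sum(r)
  }, numeric(4)))
  colnames(rows) <- c("A", "C", "G", "T")
  rows
})

#' One-hot encode a nucleotide sequence
#'
#' Transforms a sequence of length `L` into an `L x 4` matrix with column
#' order `A, C, G, T`. Unambiguous bases give indicator rows; IUPAC
#' ambiguity codes give the uniform fractional vector over their compatible
#' bases (e.g. `N` maps to `(1/4, 1/4, 1/4, 1/4)`), so every row sums to 1
#' and the per-position pattern reward stays bounded.
#'
#' @param seq A single sequence: character scalar, [Biostrings::DNAString],
#'   or length-1 [Biostrings::DNAStringSet].
#' @return An `L x 4` numeric matrix.
#' @examples
#' one_hot_encode("ACGT")
#' one_hot_encode("NR")
#' @export
one_hot_encode <- function(seq) {
  s <- as_seq_string(seq)
  if (nchar(s) == 0L) stop("cannot encode an empty sequence")
  chars <- strsplit(s, "")[[1L]]
  idx <- match(chars, rownames(iupac_onehot_rows))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("invalid residue '", chars[bad], "' at position ", bad)
  }
  m <- iupac_onehot_rows[idx, , drop = FALSE]
  rownames(m) <- NULL
  m
}
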