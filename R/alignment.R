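# IUPAC DNA -> 4-bit mask over {A=1, C=2, G=4, T=8}; gap-like symbols carry
# full uncertainty (15).
.iupac_masks <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  # A|G
  Y = 10L, # C|T
  S = 6L,  # C|G
  W = 9L,  # A|T
  K = 12L, # G|T
  M = 3L,  # A|C
  B = 14L, # C|G|T
  D = 13L, # A|G|T
  H = 11L, # A|C|T
  V = 7L,  # A|C|G
  N = 15L, `-` = 15L, `?` = 15L
)

#' Encode an IUPAC DNA character as a 4-bit state mask
#'
#' States are one-hot encoded (A=1, C=2, G=4, T=8) and IUPAC ambiguity codes
#' are the bitwise OR of their constituent bases (e.g. R = A|G = 5). Gaps
#' (`-`), `?` and `N` all encode full uncertainty (15). Input is
#' case-insensitive and `U` is treated as `T`.
#'
#' @param c A single character (or vector of single characters).
#' @return Integer mask(s) in `[1, 15]`.
#' @examples
#' encode_state("R") # 5
#' encode_state("-") # 15
#' @export
encode_state <- function(c) {
  key <- toupper(as.character(c))
  out <- .iupac_masks[key]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("encoding error: unknown character '", key[bad],
         "' at position ", bad, call. = FALSE)
  }
  unname(out)
}

#' Construct an encoded alignment
#'
#' @param data Integer matrix of encoded states (taxa in rows, sites in
#'   columns), entries in `[1, 15]`, or a character matrix of IUPAC symbols.
#' @param taxa Taxon labels; defaults to rownames of `data`.
#' @param weights Per-site positive integer multiplicities (default all 1).
#' @return An object of class `plf_alignment` with fields `taxa`, `data`,
#'   `weights`.
#' @export
plf_alignment <- function(data, taxa = rownames(data), weights = NULL) {
  if (is.character(data)) {
    data <- matrix(encode_state(data), nrow = nrow(data),
                   dimnames = dimnames(data))
  }
  storage.mode(data) <- "integer"
  m <- nrow(data); n <- ncol(data)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(m))
  if (m < 2L) stop("alignment must contain at least two sequences (m >= 2)")
  if (n < 1L) stop("alignment must contain at least one site")
  if (any(data < 1L | data > 15L)) stop("encoded states must lie in [1, 15]")
  if (is.null(weights)) weights <- rep.int(1L, n)
  weights <- as.integer(weights)
  if (length(weights) != n || any(weights < 1L)) {
    stop("weights must be positive integers, one per site")
  }
  rownames(data) <- taxa
  structure(list(taxa = as.character(taxa), data = data, weights = weights),
            class = "plf_alignment")
}

#' @export
print.plf_alignment <- function(x, ...) {
  cat("plf_alignment:", nrow(x$data), "taxa x", ncol(x$data),
      "site patterns (", sum(x$weights), "sites )\n")
  invisible(x)
}

# Relaxed sequential PHYLIP: "m n" header, then one record per line with a
# whitespace-separated name. ape's reader targets strict (fixed-width) PHYLIP.
.read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed PHYLIP header: ", lines[1])
  m <- hdr[1]; n <- hdr[2]
  if (length(lines) - 1L < m) stop("PHYLIP file declares ", m,
                                   " sequences but has fewer records")
  taxa <- character(m); seqs <- character(m)
  for (i in seq_len(m)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    taxa[i] <- parts[1]
    seqs[i] <- paste(parts[-1], collapse = "")
  }
  if (any(nchar(seqs) != n)) {
    stop("length-mismatch error: sequence lengths differ from header (n = ",
         n, ")")
  }
  list(taxa = taxa, seqs = seqs)
}

.read_fasta_chars <- function(path) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = FALSE)
  if (is.matrix(d)) d <- lapply(seq_len(nrow(d)), function(i) d[i, ]) |>
      stats::setNames(rownames(d))
  lens <- lengths(d)
  if (length(unique(lens)) != 1L) {
    stop("length-mismatch error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  list(taxa = names(d), seqs = vapply(d, paste, "", collapse = ""))
}

#' Read a DNA alignment from FASTA or relaxed PHYLIP
#'
#' Sequences are encoded into 4-bit state masks via [encode_state()]. Taxon
#' order follows the file.
#'
#' @param path File path.
#' @param format `"fasta"` (wrapped or unwrapped, multi-record) or `"phylip"`
#'   (relaxed sequential: header "m n", whitespace-separated names).
#' @return A [plf_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  rec <- switch(format,
    fasta  = .read_fasta_chars(path),
    phylip = .read_relaxed_phylip(path)
  )
  chars <- strsplit(rec$seqs, "")
  n <- length(chars[[1]])
  mat <- matrix(0L, nrow = length(chars), ncol = n,
                dimnames = list(rec$taxa, NULL))
  for (i in seq_along(chars)) {
    if (length(chars[[i]]) != n) {
      stop("length-mismatch error: sequence '", rec$taxa[i],
           "' has length ", length(chars[[i]]), ", expected ", n)
    }
    mat[i, ] <- encode_state(chars[[i]])
  }
  plf_alignment(mat, taxa = rec$taxa)
}

#' Write an alignment to FASTA
#'
#' Encoded masks are decoded back to IUPAC characters (15 is written as `-`).
#'
#' @param aln A [plf_alignment()].
#' @param path Output file path.
#' @export
write_fasta <- function(aln, path) {
  rev_map <- character(15L)
  for (nm in names(.iupac_masks)) {
    v <- .iupac_masks[[nm]]
    if (!nzchar(rev_map[v])) rev_map[v] <- nm
  }
  rev_map[15L] <- "-"
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(c(paste0(">", aln$taxa[i]),
                 paste(rev_map[aln$data[i, ]], collapse = "")), con)
  }
  invisible(path)
}

#' Collapse identical alignment columns into weighted site patterns
#'
#' Standard "aliasing" (site-pattern compression): identical full-height
#' columns are merged, first-occurrence order is preserved and the per-pattern
#' weight records the multiplicity. Idempotent; the weighted likelihood over
#' the compressed alignment equals the unweighted likelihood of the original.
#'
#' @param a A [plf_alignment()].
#' @return A compressed [plf_alignment()] with `sum(weights)` equal to the
#'   input's total site count. The attribute `site_map` gives, for every
#'   input column, the index of its pattern in the output.
#' @export
compress_patterns <- function(a) {
  stopifnot(inherits(a, "plf_alignment"))
  key <- apply(a$data, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  w <- vapply(seq_len(sum(first)),
              function(j) sum(a$weights[idx == j]), 0L)
  out <- plf_alignment(a$data[, first, drop = FALSE], taxa = a$taxa,
                       weights = as.integer(w))
  # map from input column to its pattern, so callers can expand
  # per-pattern quantities back to per-site order
  attr(out, "site_map") <- idx
  out
}
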