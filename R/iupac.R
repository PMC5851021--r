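# IUPAC nucleotide degeneracy codes and elementary base-set algebra.
# The code table is taken from Biostrings::IUPAC_CODE_MAP (the standard
# 15-letter alphabet); gap "-" is handled separately by callers.

.iupac_map <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

# minimal code lookup: names are sorted, collapsed base sets ("A","AG","ACGT",...)
.iupac_rev <- local({
  sets <- vapply(.iupac_map, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(sets), sets)
})

.complement_from <- "ACGTRYSWKMBDHVN-"
.complement_to   <- "TGCAYRSWMKVHDBN-"

#' Expand an IUPAC code to its set of concrete bases
#'
#' @param code A single IUPAC nucleotide letter (one of the 15 standard
#'   codes, e.g. `"R"`, `"N"`, `"A"`).
#' @return Character vector of concrete bases (subset of A, C, G, T).
#' @examples
#' base_set("Y")  # C, T
#' base_set("H")  # A, C, T
#' @export
base_set <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  b <- .iupac_map[[code]]
  if (is.null(b)) stop("invalid IUPAC code: '", code, "'", call. = FALSE)
  b
}

#' Minimal IUPAC code covering a set of bases
#'
#' Inverse of [base_set()]: returns the unique single-letter code whose base
#' set equals the given set.
#'
#' @param bases Character vector of concrete bases (A/C/G/T, duplicates ok).
#' @return A single IUPAC letter.
#' @examples
#' iupac_code(c("A", "G"))       # "R"
#' iupac_code(c("A", "G", "T"))  # "D"
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be concrete (A/C/G/T), got: ",
         paste(setdiff(bases, c("A", "C", "G", "T")), collapse = ","),
         call. = FALSE)
  .iupac_rev[[paste(sort(bases), collapse = "")]]
}

#' Does a concrete base fall within an IUPAC code's base set?
#'
#' Vectorised over `base` and `code` (recycled to a common length).
#'
#' @param base Concrete base(s), A/C/G/T.
#' @param code IUPAC code letter(s).
#' @return Logical vector.
#' @examples
#' iupac_match("A", "R")  # TRUE
#' iupac_match("C", "R")  # FALSE
#' @export
iupac_match <- function(base, code) {
  base <- toupper(base); code <- toupper(code)
  if (!all(base %in% c("A", "C", "G", "T")))
    stop("base must be one of A/C/G/T", call. = FALSE)
  if (!all(code %in% names(.iupac_map)))
    stop("invalid IUPAC code: ",
         paste(unique(code[!code %in% names(.iupac_map)]), collapse = ","),
         call. = FALSE)
  n <- max(length(base), length(code))
  base <- rep_len(base, n); code <- rep_len(code, n)
  mapply(function(b, cd) b %in% .iupac_map[[cd]], base, code,
         USE.NAMES = FALSE)
}

# fast 4 x 15 compatibility lookup used in inner loops (primer scanning)
.iupac_compat <- local({
  codes <- names(.iupac_map)
  m <- matrix(FALSE, 4L, length(codes),
              dimnames = list(c("A", "C", "G", "T"), codes))
  for (cd in codes) m[.iupac_map[[cd]], cd] <- TRUE
  m
})

#' Complement of a nucleotide string, IUPAC-aware
#'
#' Complements every letter in place (no reversal); gaps pass through.
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Complemented string(s).
#' @export
dna_complement <- function(x) {
  chartr(.complement_from, .complement_to, toupper(x))
}

#' Reverse complement of a nucleotide string, IUPAC-aware
#' @inheritParams dna_complement
#' @return Reverse-complemented string(s).
#' @export
dna_revcomp <- function(x) {
  vapply(dna_complement(x),
         function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         "", USE.NAMES = FALSE)
}

#' Enumerate all concrete realizations of a degenerate sequence
#'
#' Expands each IUPAC position into its base set and returns every
#' combination; the count is the product of the per-position degeneracies.
#'
#' @param seq An IUPAC nucleotide string.
#' @param max_expansion Refuse to expand beyond this many realizations
#'   (default 64), to catch runaway degeneracy in primer design.
#' @return Character vector of concrete sequences.
#' @examples
#' expand_degenerate("AR")  # "AA", "AG"
#' @export
expand_degenerate <- function(seq, max_expansion = 64L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  sets <- lapply(chars, base_set)
  n <- prod(lengths(sets))
  if (n > max_expansion)
    stop("degenerate expansion of ", n, " sequences exceeds cap of ",
         max_expansion, call. = FALSE)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Number of concrete realizations of a degenerate sequence
#' @inheritParams expand_degenerate
#' @return Integer count (product of per-position base-set sizes).
#' @export
degeneracy <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  prod(vapply(chars, function(c) length(base_set(c)), 1L))
}

.valid_iupac_string <- function(x, allow_gap = TRUE) {
  chars <- unique(strsplit(toupper(x), "")[[1]])
  ok <- names(.iupac_map)
  if (allow_gap) ok <- c(ok, "-")
  all(chars %in% ok)
}
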