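# Per-species IUPAC consensus sequences from pre-aligned COI sets.
#
# The consensus absorbs every observed intraspecific variant: each column
# becomes the minimal IUPAC code covering the union of observed bases, so
# that downstream SNP selection can distinguish interspecific variation
# (concrete, differing codes between species) from intraspecific variation
# (degenerate codes within a species).

#' Construct an aligned per-species sequence set
#'
#' @param species_name Species binomial (free text).
#' @param sequences Character vector of equal-length aligned nucleotide
#'   strings over A/C/G/T/N/-.
#' @param family Fly family, e.g. `"Calliphoridae"`; metadata.
#' @param source_ids Optional per-sequence identifiers (e.g. GenBank
#'   accessions); metadata only.
#' @return An `aligned_seq_set` object.
#' @export
aligned_seq_set <- function(species_name, sequences, family = "other",
                            source_ids = NULL) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L)
    stop("need at least one sequence for ", species_name, call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences for ", species_name,
         " have unequal lengths: ", paste(unique(lens), collapse = ","),
         call. = FALSE)
  bad <- vapply(sequences, function(s)
    !all(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N", "-")),
    NA)
  if (any(bad))
    stop("sequences for ", species_name,
         " contain characters outside A/C/G/T/N/-", call. = FALSE)
  if (!is.null(source_ids) && length(source_ids) != length(sequences))
    stop("source_ids length must match sequence count", call. = FALSE)
  structure(
    list(species_name = species_name, family = family,
         sequences = sequences, source_ids = source_ids),
    class = "aligned_seq_set")
}

#' Build an IUPAC consensus for one species
#'
#' Per alignment column, the consensus letter is the minimal IUPAC code
#' whose base set equals the union of observed concrete bases. `N` is
#' treated as missing data (it contributes nothing unless the whole column
#' is N, which stays `N`); a column containing any gap yields `-` and is
#' excluded from SNP candidacy downstream.
#'
#' @param seqs An [aligned_seq_set()].
#' @return A `species_consensus` object with fields `species_name`,
#'   `family`, `consensus` (IUPAC string) and `length`.
#' @examples
#' s <- aligned_seq_set("Lucilia sp.", c("AAT", "AGT", "ATT"))
#' build_consensus(s)$consensus  # "ADT"
#' @export
build_consensus <- function(seqs) {
  if (!inherits(seqs, "aligned_seq_set"))
    stop("seqs must be an aligned_seq_set", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs$sequences, ""))
  cons <- apply(mat, 2L, function(col) {
    if (any(col == "-")) return("-")
    obs <- col[col != "N"]
    if (length(obs) == 0L) return("N")
    iupac_code(obs)
  })
  structure(
    list(species_name = seqs$species_name, family = seqs$family,
         consensus = paste(cons, collapse = ""), length = ncol(mat)),
    class = "species_consensus")
}

#' @export
print.species_consensus <- function(x, ...) {
  ndeg <- sum(!strsplit(x$consensus, "")[[1]] %in% c("A", "C", "G", "T", "-"))
  cat("<species_consensus> ", x$species_name, " (", x$family, ")\n",
      "  length ", x$length, ", ", ndeg, " degenerate position(s)\n",
      sep = "")
  invisible(x)
}

#' Read per-species alignments listed in a manifest
#'
#' The manifest is a delimited text file with columns `file`, `species`,
#' `family`; `file` paths are resolved relative to the manifest's
#' directory. Each file is an aligned multi-FASTA for one species.
#'
#' @param manifest_path Path to the manifest (CSV or TSV, sniffed from the
#'   extension; default comma).
#' @return List of [aligned_seq_set()] objects.
#' @export
read_species_alignments <- function(manifest_path) {
  sep <- if (grepl("\\.tsv$", manifest_path)) "\t" else ","
  man <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("file", "species", "family")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    dss <- Biostrings::readDNAStringSet(f)
    aligned_seq_set(man$species[i], as.character(dss),
                    family = man$family[i], source_ids = names(dss))
  })
}

#' Write consensus sequences to FASTA
#'
#' One record per species; the header carries the species name and family.
#'
#' @param consensuses List of `species_consensus` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensuses, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(consensuses, function(cs) gsub("-", "-", cs$consensus), ""))
  names(seqs) <- vapply(consensuses, function(cs)
    paste0(cs$species_name, " family=", cs$family), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
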