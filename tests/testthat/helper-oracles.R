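# Shared helpers: independent brute-force oracles and tiny fixtures built
# in code.

# brute-force minimum discriminating subset size: enumerate every subset
# of sites by bitmask and test vector distinctness by string comparison
# (independent of the package's pair-mask search)
brute_min_subset_size <- function(site_bases) {
  # site_bases: list of named base vectors (one per site, names = species)
  n <- length(site_bases)
  species <- names(site_bases[[1]])
  m <- vapply(site_bases, function(b) b[species], character(length(species)))
  best <- NA_integer_
  powers <- 2^(seq_len(n) - 1L)
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, powers) != 0L)
    if (!is.na(best) && length(idx) >= best) next
    keys <- apply(m[, idx, drop = FALSE], 1L, paste, collapse = "")
    if (!anyDuplicated(keys)) best <- length(idx)
  }
  best
}

# random discriminating instance: species x sites base matrix where the
# full site set always separates all species
random_instance <- function(n_species, n_sites) {
  repeat {
    m <- matrix(sample(c("A", "C", "G", "T"), n_species * n_sites,
                       replace = TRUE),
                n_species, n_sites,
                dimnames = list(paste0("sp", seq_len(n_species)), NULL))
    keys <- apply(m, 1L, paste, collapse = "")
    informative <- apply(m, 2L, function(col) length(unique(col)) >= 2L)
    if (!anyDuplicated(keys) && all(informative)) return(m)
  }
}

instance_sites <- function(m) {
  lapply(seq_len(ncol(m)), function(j)
    snp_site(paste0("s", j), j, m[, j]))
}

# tiny consensus fixtures from raw strings
make_consensuses <- function(seqs) {
  lapply(names(seqs), function(nm) {
    cs <- build_consensus(aligned_seq_set(nm, seqs[[nm]]))
    cs
  })
}

# bare base vector of a genotype_vector (drop class/status/provenance)
gt_bases <- function(gt) {
  x <- unclass(gt)
  attributes(x) <- NULL
  x
}

read_transcription <- function(file) {
  read.csv(system.file("extdata", "transcription", file,
                       package = "snapanel"),
           stringsAsFactors = FALSE, colClasses = "character")
}
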