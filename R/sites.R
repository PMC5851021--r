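# Interspecific SNP discovery and minimal discriminating-site selection.
#
# A candidate site is a column where every species' consensus is a single
# concrete base (no intraspecific degeneracy), no species has a gap, and at
# least two species differ. Selecting the smallest site combination whose
# genotype vectors are pairwise distinct is a set-cover problem over
# species pairs; we solve it exactly for small candidate counts and fall
# back to greedy pair-separation above a configurable bound.

#' Construct a SNP site
#'
#' @param label Site label, e.g. `"CA90"`.
#' @param position 1-based coordinate on the shared reference.
#' @param per_species_base Named character vector, species -> concrete base
#'   as reported in the detection channel (the base the dye reports; for
#'   reverse-direction sites this is the complement of the sense strand).
#' @param direction `"forward"` or `"reverse"` (extension strand).
#' @return An `snp_site` object.
#' @export
snp_site <- function(label, position, per_species_base,
                     direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(length(position) == 1L, position >= 1)
  bases <- toupper(unlist(per_species_base))
  if (is.null(names(bases)) || any(names(bases) == ""))
    stop("per_species_base must be named by species", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("site ", label, ": per-species bases must be concrete A/C/G/T",
         call. = FALSE)
  if (length(unique(bases)) < 2L)
    stop("site ", label, " is non-informative: all species share base ",
         bases[[1]], call. = FALSE)
  structure(
    list(label = as.character(label), position = as.integer(position),
         direction = direction, per_species_base = bases),
    class = "snp_site")
}

#' Find candidate interspecific SNP sites
#'
#' Scans aligned species consensuses and returns every position that is
#' concrete (non-degenerate) and ungapped in all species and at which at
#' least two species differ. Intraspecifically variable positions (any
#' degenerate code) are excluded entirely.
#'
#' @param consensuses List of `species_consensus` objects of equal length.
#' @param direction Direction tag attached to the returned sites
#'   (candidates themselves are strand-symmetric).
#' @return List of [snp_site()] objects, labelled `<prefix><position>`.
#' @param label_prefix Prefix for auto-generated site labels (default
#'   `"site"`).
#' @export
find_candidate_sites <- function(consensuses, direction = "forward",
                                 label_prefix = "site") {
  if (length(consensuses) < 2L)
    stop("need at least two species to find interspecific SNPs",
         call. = FALSE)
  lens <- vapply(consensuses, function(cs) cs$length, 1L)
  if (length(unique(lens)) != 1L)
    stop("consensus lengths differ: ", paste(unique(lens), collapse = ","),
         call. = FALSE)
  species <- vapply(consensuses, function(cs) cs$species_name, "")
  mat <- do.call(rbind, lapply(consensuses,
                               function(cs) strsplit(cs$consensus, "")[[1]]))
  rownames(mat) <- species
  concrete <- apply(mat, 2L, function(col)
    all(col %in% c("A", "C", "G", "T")))
  varying <- apply(mat, 2L, function(col) length(unique(col)) >= 2L)
  keep <- which(concrete & varying)
  lapply(keep, function(p) {
    bases <- mat[, p]
    if (direction == "reverse") bases <- dna_complement(bases)
    snp_site(paste0(label_prefix, p), p,
             stats::setNames(bases, species), direction = direction)
  })
}

#' Assemble a genotype table from sites and consensuses
#'
#' Builds the per-species ordered base vectors for the given sites, read
#' from each species' consensus. Reverse-direction sites report the
#' complement of the sense-strand base (the detection-channel base).
#'
#' @param sites Ordered list of [snp_site()] objects.
#' @param consensuses List of `species_consensus` objects; if `NULL`, the
#'   table is assembled from the sites' own `per_species_base` maps.
#' @return A `genotype_table`: list with `sites`, `species`, and `vectors`
#'   (named list of character vectors, one base per site).
#' @export
build_genotype_table <- function(sites, consensuses = NULL) {
  if (length(sites) < 1L) stop("no sites given", call. = FALSE)
  if (is.null(consensuses)) {
    species <- names(sites[[1]]$per_species_base)
    vectors <- lapply(species, function(sp)
      vapply(sites, function(s) {
        if (!sp %in% names(s$per_species_base))
          stop("species ", sp, " missing from site ", s$label, call. = FALSE)
        s$per_species_base[[sp]]
      }, ""))
  } else {
    species <- vapply(consensuses, function(cs) cs$species_name, "")
    vectors <- lapply(consensuses, function(cs) {
      chars <- strsplit(cs$consensus, "")[[1]]
      vapply(sites, function(s) {
        b <- chars[s$position]
        if (!b %in% c("A", "C", "G", "T"))
          stop("position ", s$position, " is degenerate or gapped in ",
               cs$species_name, " ('", b, "')", call. = FALSE)
        if (s$direction == "reverse") dna_complement(b) else b
      }, "")
    })
  }
  names(vectors) <- species
  structure(list(sites = sites, species = species, vectors = vectors),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", length(x$species), " species x ",
      length(x$sites), " sites\n", sep = "")
  m <- do.call(rbind, x$vectors)
  colnames(m) <- vapply(x$sites, function(s) s$label, "")
  print(m, quote = FALSE)
  invisible(x)
}

#' Check that a genotype table identifies every species uniquely
#'
#' @param table A `genotype_table` with complete reference vectors.
#' @return List with `is_unique` (logical), `n_distinct` (count of distinct
#'   vectors), `n_species`, and `collisions` (list of species groups
#'   sharing a vector; empty when unique).
#' @export
verify_uniqueness <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  nsite <- length(table$sites)
  bad <- vapply(table$vectors, function(v)
    length(v) != nsite || anyNA(v), NA)
  if (any(bad))
    stop("incomplete reference table for: ",
         paste(table$species[bad], collapse = ", "), call. = FALSE)
  keys <- vapply(table$vectors, paste, "", collapse = "")
  groups <- split(table$species, keys)
  collisions <- unname(groups[lengths(groups) > 1L])
  list(is_unique = length(collisions) == 0L,
       n_distinct = length(unique(keys)),
       n_species = length(table$species),
       collisions = collisions)
}

# pack the species pairs separated by each site into bit words (31 bits
# per integer) so subset coverage checks are cheap inside the search
.pair_masks <- function(sites, species) {
  np <- length(species)
  pairs <- utils::combn(np, 2L)
  npair <- ncol(pairs)
  nword <- (npair + 30L) %/% 31L
  masks <- matrix(0L, nrow = length(sites), ncol = nword)
  for (si in seq_along(sites)) {
    b <- sites[[si]]$per_species_base[species]
    sep <- b[pairs[1L, ]] != b[pairs[2L, ]]
    for (k in which(sep)) {
      w <- (k - 1L) %/% 31L + 1L
      bit <- (k - 1L) %% 31L
      masks[si, w] <- bitwOr(masks[si, w], bitwShiftL(1L, bit))
    }
  }
  full <- integer(nword)
  for (k in seq_len(npair)) {
    w <- (k - 1L) %/% 31L + 1L
    full[w] <- bitwOr(full[w], bitwShiftL(1L, (k - 1L) %% 31L))
  }
  list(masks = masks, full = full, pairs = pairs)
}

#' Select a minimal discriminating site combination
#'
#' Finds a smallest set of candidate sites under which every species'
#' genotype vector is distinct. With at most `exact_limit` candidates the
#' search is exhaustive over subsets of increasing size (the result is a
#' certified minimum); above it a greedy pair-separation set cover is used
#' and the result carries `exact = FALSE`. Ties between equal-size minimal
#' panels are broken by the lexicographically smallest sorted position
#' tuple, so results are reproducible.
#'
#' @param candidates List of [snp_site()] objects covering a common species
#'   set.
#' @param species Character vector of species to discriminate; defaults to
#'   the species named in the first candidate.
#' @param exact_limit Candidate count up to which the exhaustive search is
#'   used (default 20).
#' @return Ordered list of [snp_site()] (sorted by position), with
#'   attributes `exact` (logical optimality certificate) and `n_candidates`.
#' @export
select_minimal_panel <- function(candidates, species = NULL,
                                 exact_limit = 20L) {
  if (length(candidates) < 1L) stop("no candidate sites", call. = FALSE)
  if (is.null(species)) species <- names(candidates[[1]]$per_species_base)
  if (length(species) < 2L)
    stop("need at least two species", call. = FALSE)
  # deterministic ordering by position
  pos <- vapply(candidates, function(s) s$position, 1L)
  candidates <- candidates[order(pos)]
  pm <- .pair_masks(candidates, species)
  covered_all <- vapply(seq_len(ncol(pm$masks)), function(w)
    Reduce(bitwOr, pm$masks[, w]), 1L)
  if (!identical(covered_all, pm$full)) {
    miss <- integer(0)
    for (k in seq_len(ncol(pm$pairs))) {
      w <- (k - 1L) %/% 31L + 1L; bit <- (k - 1L) %% 31L
      if (bitwAnd(covered_all[w], bitwShiftL(1L, bit)) == 0L)
        miss <- c(miss, k)
    }
    pairnames <- apply(pm$pairs[, miss, drop = FALSE], 2L, function(pr)
      paste(species[pr], collapse = " / "))
    stop("candidates cannot separate species pair(s): ",
         paste(pairnames, collapse = "; "), call. = FALSE)
  }
  n <- length(candidates)
  if (n <= exact_limit) {
    # subsets enumerated size-first, lexicographically, so the first hit is
    # the minimum-cardinality panel with the smallest position tuple
    for (k in seq_len(n)) {
      idx <- seq_len(k)
      repeat {
        acc <- integer(length(pm$full))
        for (i in idx) acc <- bitwOr(acc, pm$masks[i, ])
        if (identical(as.integer(acc), pm$full)) {
          res <- candidates[idx]
          attr(res, "exact") <- TRUE
          attr(res, "n_candidates") <- n
          return(res)
        }
        # advance to next k-combination of 1..n in lexicographic order
        j <- k
        while (j >= 1L && idx[j] == n - k + j) j <- j - 1L
        if (j < 1L) break
        idx[j] <- idx[j] + 1L
        if (j < k) idx[(j + 1L):k] <- idx[j] + seq_len(k - j)
      }
    }
  }
  # greedy pair-separation set cover
  uncovered <- pm$full
  chosen <- integer(0)
  popcount <- function(words) sum(vapply(words, function(w) {
    c <- 0L
    while (w != 0L) { c <- c + bitwAnd(w, 1L); w <- bitwShiftR(w, 1L) }
    c
  }, 1L))
  while (any(uncovered != 0L)) {
    gains <- vapply(seq_len(n), function(i)
      if (i %in% chosen) -1L else
        popcount(bitwAnd(pm$masks[i, ], uncovered)), 1L)
    best <- which.max(gains)  # ties -> smallest index = smallest position
    if (gains[best] <= 0L) stop("greedy cover stalled", call. = FALSE)
    chosen <- c(chosen, best)
    uncovered <- bitwAnd(uncovered, bitwNot(pm$masks[best, ]))
  }
  res <- candidates[sort(chosen)]
  attr(res, "exact") <- FALSE
  attr(res, "n_candidates") <- n
  res
}
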