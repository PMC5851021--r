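# PCR and single-base-extension (SBE) primer design.
#
# SBE primers bind immediately adjacent to a SNP so that the single
# dideoxy base added by the polymerase IS the SNP's detection-channel
# base. Products from different sites are separated electrophoretically by
# prepending 5' poly-T tails of staggered lengths (the size ladder).

#' Construct an SBE primer
#'
#' @param site_label Label of the SNP site the primer interrogates.
#' @param specific_seq IUPAC string: the 3' portion that anneals
#'   immediately adjacent to the SNP on the extension strand.
#' @param tail_len Number of 5' poly-T residues.
#' @param direction `"forward"` or `"reverse"` extension strand.
#' @param role `"universal"` (default in-silico extension set) or
#'   `"low-signal-alternate"` (extra primers for weak-signal samples).
#' @param concentration Optimal multiplex concentration in uM; metadata.
#' @return An `sbe_primer`; `$seq` is the full tailed sequence and
#'   `$total_len` its length.
#' @export
sbe_primer <- function(site_label, specific_seq, tail_len = 0L,
                       direction = c("forward", "reverse"),
                       role = c("universal", "low-signal-alternate"),
                       concentration = NA_real_) {
  direction <- match.arg(direction)
  role <- match.arg(role)
  specific_seq <- toupper(specific_seq)
  if (!.valid_iupac_string(specific_seq, allow_gap = FALSE))
    stop("specific_seq contains non-IUPAC characters", call. = FALSE)
  tail_len <- as.integer(tail_len)
  stopifnot(tail_len >= 0L)
  structure(
    list(site_label = site_label, specific_seq = specific_seq,
         tail_len = tail_len,
         seq = paste0(strrep("T", tail_len), specific_seq),
         total_len = tail_len + nchar(specific_seq),
         direction = direction, role = role,
         concentration = concentration),
    class = "sbe_primer")
}

#' @export
print.sbe_primer <- function(x, ...) {
  cat("<sbe_primer> ", x$site_label, " (", x$direction, ", ", x$role,
      ")\n  5'-", x$seq, "-3'  (", x$tail_len, " T tail + ",
      nchar(x$specific_seq), " specific = ", x$total_len, " nt)\n",
      sep = "")
  invisible(x)
}

#' Design an SBE primer against a set of species consensuses
#'
#' Takes the `flank_len` bases immediately adjacent to the SNP on the
#' extension strand (5' of the SNP for forward sites; the reverse
#' complement of the bases 3' of the SNP for reverse sites). Positions
#' where species differ, or where any species is intraspecifically
#' variable, are encoded as the minimal IUPAC code covering all observed
#' bases. The poly-T tail fills the primer to `target_total_len`.
#'
#' @param consensuses List of `species_consensus` objects (the panel
#'   species).
#' @param site An [snp_site()].
#' @param flank_len Length of the sequence-specific 3' portion.
#' @param target_total_len Total primer length including tail (the site's
#'   rung on the size ladder).
#' @param max_degeneracy Cap on the number of concrete realizations of the
#'   specific portion; design fails loudly beyond it (default 64).
#' @return An [sbe_primer()] with `role = "universal"`.
#' @export
design_sbe_primer <- function(consensuses, site, flank_len,
                              target_total_len, max_degeneracy = 64L) {
  stopifnot(inherits(site, "snp_site"))
  flank_len <- as.integer(flank_len)
  if (flank_len > target_total_len)
    stop("flank_len exceeds target_total_len", call. = FALSE)
  p <- site$position
  if (site$direction == "forward") {
    if (p - flank_len < 1L)
      stop("flank runs off the 5' end for site ", site$label, call. = FALSE)
    span <- (p - flank_len):(p - 1L)
  } else {
    maxlen <- consensuses[[1]]$length
    if (p + flank_len > maxlen)
      stop("flank runs off the 3' end for site ", site$label, call. = FALSE)
    span <- (p + 1L):(p + flank_len)
  }
  cols <- lapply(consensuses, function(cs)
    strsplit(cs$consensus, "")[[1]][span])
  specific <- vapply(seq_len(flank_len), function(i) {
    codes <- vapply(cols, `[[`, "", i)
    if (any(codes == "-"))
      stop("gap in primer flank at reference position ", span[i],
           call. = FALSE)
    iupac_code(unique(unlist(lapply(codes, base_set))))
  }, "")
  specific <- paste(specific, collapse = "")
  if (site$direction == "reverse") specific <- dna_revcomp(specific)
  if (degeneracy(specific) > max_degeneracy)
    stop("degeneracy explosion for site ", site$label, ": ",
         degeneracy(specific), " realizations exceed cap ", max_degeneracy,
         "; split the site into alternate primers manually", call. = FALSE)
  sbe_primer(site$label, specific,
             tail_len = target_total_len - flank_len,
             direction = site$direction, role = "universal")
}

#' Amplicon length from primer spans
#'
#' Inclusive distance from the forward primer's first base to the reverse
#' primer's last base, both in 1-based reference coordinates.
#'
#' @param forward_span,reverse_span Length-2 integer vectors
#'   `c(start, end)`, or `NULL`/`NA` when the binding site is outside the
#'   numbered region.
#' @return Amplicon length in bp, or `NA` (with a message attribute) when
#'   a span is unknown.
#' @examples
#' amplicon_length(c(1416, 1439), c(1543, 1566))  # 151
#' @export
amplicon_length <- function(forward_span, reverse_span) {
  unknown <- function(which) {
    out <- NA_integer_
    attr(out, "reason") <- paste(which, "span unknown; length not derivable")
    out
  }
  if (is.null(forward_span) || anyNA(forward_span)) return(unknown("forward"))
  if (is.null(reverse_span) || anyNA(reverse_span)) return(unknown("reverse"))
  stopifnot(length(forward_span) == 2L, length(reverse_span) == 2L)
  if (reverse_span[1] <= forward_span[2])
    stop("reverse primer is not downstream of the forward primer",
         call. = FALSE)
  as.integer(reverse_span[2] - forward_span[1] + 1L)
}

#' Heuristic self-structure check for a primer
#'
#' `self_dimer_score` is the longest run of contiguous Watson-Crick pairs
#' formed between two antiparallel copies of the primer over all ungapped
#' offsets; `hairpin_score` is the longest intramolecular stem with a loop
#' of at least 3 bases. Degenerate positions count as pairable if any
#' realization pairs. This is a screening heuristic, not a thermodynamic
#' model.
#'
#' @param seq IUPAC primer sequence, length >= 8.
#' @param max_dimer,max_hairpin Pass thresholds (defaults 8 and 6): scores
#'   must stay strictly below them.
#' @return List with `self_dimer_score`, `hairpin_score`, `pass`.
#' @export
check_self_structure <- function(seq, max_dimer = 8L, max_hairpin = 6L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 8L) stop("sequence too short for structure check (< 8 nt)",
                   call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  sets <- lapply(chars, base_set)
  compl <- list(A = "T", C = "G", G = "C", T = "A")
  canpair <- function(i, j) {
    a <- sets[[i]]
    b <- unlist(compl[sets[[j]]], use.names = FALSE)
    length(intersect(a, b)) > 0L
  }
  # self-dimer: slide the sequence against an antiparallel copy; position i
  # of copy 1 pairs with position (off + 1 - i) of copy 2
  dimer <- 0L
  for (off in seq_len(2L * L - 1L)) {
    run <- 0L
    for (i in seq_len(L)) {
      j <- off + 1L - i
      if (j >= 1L && j <= L && canpair(i, j)) {
        run <- run + 1L
        if (run > dimer) dimer <- run
      } else run <- 0L
    }
  }
  # hairpin: stem s[i..i+k-1] pairs s[j-k+1..j] with loop >= 3
  hairpin <- 0L
  for (i in seq_len(L)) {
    if (L < i + 4L) break
    for (j in seq(L, i + 4L, by = -1L)) {
      k <- 0L
      # extending pair (i+k, j-k) must leave a loop of >= 3 bases
      while (j - i - 2L * k >= 4L && canpair(i + k, j - k)) k <- k + 1L
      if (k > hairpin) hairpin <- k
    }
  }
  list(self_dimer_score = dimer, hairpin_score = hairpin,
       pass = dimer < max_dimer && hairpin < max_hairpin)
}

#' Plan a poly-T size ladder
#'
#' Assigns each site an arithmetic target total length so SBE products
#' from different sites separate cleanly in one capillary run.
#'
#' @param n_sites Number of sites (or a list of sites).
#' @param start_len First rung (default 25 nt).
#' @param step Rung spacing (default 10 nt; must exceed the expected
#'   capillary size jitter).
#' @return Integer vector of target total lengths, one per site.
#' @examples
#' plan_size_ladder(6, 25, 10)  # 25 35 45 55 65 75
#' @export
plan_size_ladder <- function(n_sites, start_len = 25L, step = 10L) {
  if (is.list(n_sites)) n_sites <- length(n_sites)
  stopifnot(n_sites >= 1L, step >= 1L)
  as.integer(start_len + step * (seq_len(n_sites) - 1L))
}

#' Export primers as FASTA
#'
#' One record per primer, poly-T tail included; headers carry site, role
#' and direction.
#'
#' @param primers List of [sbe_primer()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_fasta <- function(primers, path) {
  seqs <- Biostrings::DNAStringSet(vapply(primers, `[[`, "", "seq"))
  names(seqs) <- vapply(primers, function(p)
    paste0(p$site_label, " role=", p$role, " direction=", p$direction,
           " tail=", p$tail_len), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
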