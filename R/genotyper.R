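# Genotype calling: from capillary peak tables (dye colour + size) or in
# silico from query sequences, then species assignment against a panel's
# genotype table.
#
# SNaPshot dye chemistry ties each dideoxy base to one dye colour:
# A = dR6G (green), C = dTAMRA (black), G = dR110 (blue), T = dROX (red).

.dye_of_base <- c(A = "green", C = "black", G = "blue", T = "red")
.base_of_dye <- c(green = "A", black = "C", blue = "G", red = "T")
.dye_synonyms <- c(dr6g = "green", dtamra = "black", dr110 = "blue",
                   drox = "red", green = "green", black = "black",
                   blue = "blue", red = "red")

#' Map dye colour to the extended base, and back
#'
#' The SNaPshot chemistry is a fixed bijection: green = A (dR6G),
#' black = C (dTAMRA), blue = G (dR110), red = T (dROX). `dye_to_base`
#' also accepts the dye chemistry names.
#'
#' @param dye Dye colour name(s) or chemistry name(s).
#' @param base Concrete base(s) A/C/G/T.
#' @return Character vector of bases / dye colours.
#' @examples
#' dye_to_base("green")  # "A"
#' base_to_dye("T")      # "red"
#' @export
dye_to_base <- function(dye) {
  key <- gsub("[^a-z0-9]", "", tolower(dye))
  colour <- .dye_synonyms[key]
  if (anyNA(colour))
    stop("unknown dye: ", paste(unique(dye[is.na(colour)]), collapse = ","),
         call. = FALSE)
  unname(.base_of_dye[colour])
}

#' @rdname dye_to_base
#' @export
base_to_dye <- function(base) {
  base <- toupper(base)
  out <- .dye_of_base[base]
  if (anyNA(out))
    stop("unknown base: ", paste(unique(base[is.na(out)]), collapse = ","),
         call. = FALSE)
  unname(out)
}

#' Construct a peak profile
#'
#' One capillary run's peak table: dye colour, size in nucleotide units
#' (relative to the size standard), and height (RFU).
#'
#' @param dye Character vector of dye colours (or chemistry names).
#' @param size Numeric peak sizes (> 0).
#' @param height Numeric peak heights (>= 0).
#' @return A `peak_profile` data frame with columns `dye`, `size`,
#'   `height`.
#' @export
peak_profile <- function(dye = character(), size = numeric(),
                         height = numeric()) {
  stopifnot(length(dye) == length(size), length(size) == length(height))
  if (length(size) && (any(size <= 0) || any(height < 0)))
    stop("peak sizes must be > 0 and heights >= 0", call. = FALSE)
  if (length(dye)) dye <- .dye_synonyms[gsub("[^a-z0-9]", "", tolower(dye))]
  if (anyNA(dye)) stop("unknown dye name in profile", call. = FALSE)
  structure(data.frame(dye = unname(dye), size = size, height = height,
                       stringsAsFactors = FALSE),
            class = c("peak_profile", "data.frame"))
}

#' Read a peak table from delimited text
#'
#' Expects a header with columns `dye`, `size`, `height` (comma- or
#' tab-delimited, sniffed). Dye entries may be colour names or chemistry
#' names (dR6G/dTAMRA/dR110/dROX).
#'
#' @param path Input file.
#' @return A [peak_profile()].
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("dye", "size", "height")
  if (!all(need %in% names(df)))
    stop("peak table must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  peak_profile(df$dye, as.numeric(df$size), as.numeric(df$height))
}

#' Write a peak table as CSV
#' @param profile A [peak_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("dye", "size", "height")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# per-site assignment windows: observed mean +/- max(3 sd, 1 nt)
.site_windows <- function(calibration) {
  w <- pmax(3 * calibration$sd, 1.0)
  data.frame(site = calibration$site,
             lo = calibration$mean - w, hi = calibration$mean + w,
             stringsAsFactors = FALSE)
}

#' Interpret a peak profile as per-site bases
#'
#' Peaks below `min_rel_height` of the tallest peak are discarded as
#' noise. Each surviving peak is binned into the site whose window
#' (observed mean +/- max(3 sd, 1 nt)) contains its size; peaks outside
#' every window are ignored. A site with exactly one assigned peak yields
#' the dye's base; none yields missing; more than one is flagged
#' ambiguous rather than guessed.
#'
#' @param profile A [peak_profile()].
#' @param calibration Data frame with columns `site`, `expected`, `mean`,
#'   `lo`, `hi`, `sd` (as stored in a panel), or a `panel`.
#' @param min_rel_height Noise floor as a fraction of the tallest peak
#'   (default 0.10).
#' @return A `genotype_vector`: named base vector (`NA` = missing) with a
#'   per-site `status` attribute (`"called"`, `"missing"`,
#'   `"ambiguous"`) and provenance `"peaks"`.
#' @export
assign_peaks <- function(profile, calibration, min_rel_height = 0.10) {
  if (inherits(calibration, "panel")) calibration <- calibration$calibration
  win <- .site_windows(calibration)
  if (nrow(win) > 1L) {
    o <- order(win$lo)
    if (any(win$hi[o][-nrow(win)] > win$lo[o][-1L]))
      stop("calibration windows overlap; size ladder too tight",
           call. = FALSE)
  }
  prof <- as.data.frame(profile)
  if (nrow(prof) > 0L) {
    keep <- prof$height >= min_rel_height * max(prof$height)
    prof <- prof[keep, , drop = FALSE]
  }
  bases <- stats::setNames(rep(NA_character_, nrow(win)), win$site)
  status <- stats::setNames(rep("missing", nrow(win)), win$site)
  for (i in seq_len(nrow(win))) {
    hit <- prof$size >= win$lo[i] & prof$size <= win$hi[i]
    n <- sum(hit)
    if (n == 1L) {
      bases[i] <- dye_to_base(prof$dye[hit])
      status[i] <- "called"
    } else if (n > 1L) {
      status[i] <- "ambiguous"
    }
  }
  genotype_vector(bases, status = status, provenance = "peaks")
}

#' Construct a genotype vector
#'
#' @param bases Named character vector of per-site bases; `NA` for
#'   missing.
#' @param status Optional per-site status (`"called"`, `"missing"`,
#'   `"ambiguous"`); derived from `bases` when omitted.
#' @param provenance `"sequence"` or `"peaks"`.
#' @return A `genotype_vector`.
#' @export
genotype_vector <- function(bases, status = NULL,
                            provenance = c("sequence", "peaks")) {
  provenance <- match.arg(provenance)
  if (is.null(status))
    status <- ifelse(is.na(bases), "missing", "called")
  structure(bases, status = status, provenance = provenance,
            class = "genotype_vector")
}

#' @export
print.genotype_vector <- function(x, ...) {
  shown <- ifelse(is.na(unclass(x)),
                  ifelse(attr(x, "status") == "ambiguous", "?", "."),
                  unclass(x))
  cat("<genotype_vector> (", attr(x, "provenance"), ")\n", sep = "")
  print(stats::setNames(shown, names(x)), quote = FALSE)
  invisible(x)
}

# scan a (possibly degenerate) primer along a concrete sequence; returns
# 0-based offsets of matches with <= max_mismatch mismatches, none inside
# the protected columns (primer positions given in `protect`)
.scan_primer <- function(qchars, pchars, max_mismatch = 1L,
                         protect = integer()) {
  L <- length(pchars)
  n <- length(qchars)
  if (n < L) return(integer())
  nstart <- n - L + 1L
  mism <- integer(nstart)
  protected_ok <- rep(TRUE, nstart)
  compat <- .iupac_compat
  for (i in seq_len(L)) {
    qs <- qchars[i:(i + nstart - 1L)]
    ok <- rep(FALSE, nstart)
    known <- qs %in% rownames(compat)
    ok[known] <- compat[cbind(qs[known], pchars[i])]
    mism <- mism + !ok
    if (i %in% protect) protected_ok <- protected_ok & ok
  }
  which(mism <= max_mismatch & protected_ok) - 1L
}

#' Genotype a query sequence in silico
#'
#' Simulates the single-base extension: for each panel site, the
#' universal SBE primer's sequence-specific portion is located on the
#' appropriate strand of the query (both query orientations are tried, so
#' reverse-complemented input gives the same result), allowing at most
#' `max_mismatch` mismatches and none within the 3'-terminal 3 bases. The
#' reported base is the templated extension base, complemented into the
#' detection channel for reverse-direction sites. Sites whose primer
#' binds nowhere, or at more than one locus, are left missing.
#'
#' @param query A nucleotide string over A/C/G/T/N (or a
#'   `Biostrings::DNAString`).
#' @param panel A [load_panel()] result.
#' @param max_mismatch Mismatch tolerance outside the 3' clamp (default
#'   1).
#' @param use_alternates Also try `low-signal-alternate` primers (default
#'   `FALSE`; universal primers suffice for the packaged panels).
#' @return A `genotype_vector` with provenance `"sequence"`.
#' @export
in_silico_genotype <- function(query, panel, max_mismatch = 1L,
                               use_alternates = FALSE) {
  query <- toupper(as.character(query))
  if (!nzchar(query)) stop("empty query sequence", call. = FALSE)
  strands <- list(fwd = strsplit(query, "")[[1]],
                  rev = strsplit(dna_revcomp(query), "")[[1]])
  sites <- panel$sites
  bases <- stats::setNames(rep(NA_character_, length(sites)),
                           vapply(sites, `[[`, "", "label"))
  status <- stats::setNames(rep("missing", length(sites)), names(bases))
  for (si in seq_along(sites)) {
    site <- sites[[si]]
    primers <- Filter(function(p) p$site_label == site$label &&
                        (use_alternates || p$role == "universal"),
                      panel$sbe_primers)
    if (length(primers) == 0L) next
    found <- list()  # keyed by strand:pos to dedupe overlapping primers
    for (pr in primers) {
      if (site$direction == "forward") {
        pch <- strsplit(pr$specific_seq, "")[[1]]
        protect <- (length(pch) - 2L):length(pch)
      } else {
        # reverse primer binds the minus strand; equivalently search its
        # reverse complement on the plus strand, extension one base 5'
        pch <- strsplit(dna_revcomp(pr$specific_seq), "")[[1]]
        protect <- 1:3
      }
      L <- length(pch)
      for (st in names(strands)) {
        qch <- strands[[st]]
        offs <- .scan_primer(qch, pch, max_mismatch, protect)
        for (o in offs) {
          if (site$direction == "forward") {
            ext <- o + L + 1L          # base templated just 3' of primer
            if (ext > length(qch)) next
            b <- qch[ext]
          } else {
            ext <- o                   # base just 5' of the footprint
            if (ext < 1L) next
            b <- dna_complement(qch[ext])
          }
          if (!b %in% c("A", "C", "G", "T")) next
          found[[paste0(st, ":", ext)]] <- b
        }
      }
    }
    if (length(found) == 1L) {
      bases[si] <- found[[1L]]
      status[si] <- "called"
    } else if (length(found) > 1L) {
      ub <- unique(unlist(found))
      if (length(ub) == 1L) {  # same locus hit via both primers/strands
        bases[si] <- ub
        status[si] <- "called"
      } else status[si] <- "ambiguous"
    }
  }
  genotype_vector(bases, status = status, provenance = "sequence")
}

#' Call a species from a genotype vector
#'
#' Candidate species are those whose complete reference vector agrees
#' with every non-missing observed base. Exactly one candidate gives a
#' unique identification; several give an ambiguous call listing the
#' candidate set; none gives a no-match, with the nearest species by
#' Hamming distance reported strictly as a labelled hint, never as an
#' identification.
#'
#' @param genotype A [genotype_vector()] (ambiguous sites count as
#'   missing).
#' @param table A `genotype_table` (or a `panel`).
#' @return A `species_call`: list with `status` (`"unique"`,
#'   `"ambiguous"`, `"no-match"`), `species` (name or candidate set),
#'   `per_site_evidence` data frame, `n_sites_used`, and `nearest` (hint,
#'   no-match only).
#' @export
call_species <- function(genotype, table) {
  if (inherits(table, "panel")) table <- table$genotype_table
  chk <- verify_uniqueness(table)
  if (!chk$is_unique)
    stop("reference table does not uniquely identify its species",
         call. = FALSE)
  obs <- unclass(genotype)
  nsite <- length(table$sites)
  if (length(obs) != nsite)
    stop("genotype length ", length(obs), " does not match table (",
         nsite, " sites)", call. = FALSE)
  used <- !is.na(obs)
  agree <- vapply(table$vectors, function(ref)
    all(ref[used] == obs[used]), NA)
  cands <- table$species[agree]
  labels <- vapply(table$sites, `[[`, "", "label")
  status <- if (length(cands) == 1L) "unique"
            else if (length(cands) >= 2L) "ambiguous" else "no-match"
  nearest <- NULL
  expected <- rep(NA_character_, nsite)
  if (status == "unique") {
    expected <- table$vectors[[cands]]
  } else if (status == "no-match") {
    dists <- vapply(table$vectors, function(ref)
      sum(ref[used] != obs[used]), 1L)
    nearest <- list(species = table$species[which.min(dists)],
                    hamming = min(dists),
                    note = "nearest reference only; NOT an identification")
  }
  evidence <- data.frame(
    site = labels,
    observed = unname(obs),
    site_status = unname(attr(genotype, "status")),
    expected = expected,
    match = ifelse(is.na(obs) | is.na(expected), NA, obs == expected),
    stringsAsFactors = FALSE)
  structure(
    list(status = status,
         species = if (length(cands)) cands else character(),
         per_site_evidence = evidence,
         n_sites_used = sum(used),
         nearest = nearest,
         provenance = attr(genotype, "provenance")),
    class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat("<species_call> status: ", x$status, "\n", sep = "")
  if (x$status == "unique") {
    cat("  species: ", x$species, "\n", sep = "")
  } else if (x$status == "ambiguous") {
    cat("  candidates (", length(x$species), "): ",
        paste(x$species, collapse = "; "), "\n", sep = "")
  } else if (!is.null(x$nearest)) {
    cat("  no reference matches; nearest (hint only): ",
        x$nearest$species, " at Hamming distance ", x$nearest$hamming,
        "\n", sep = "")
  }
  cat("  sites used: ", x$n_sites_used, "/",
      nrow(x$per_site_evidence), "\n", sep = "")
  invisible(x)
}

#' Call a species directly from a peak profile
#'
#' Pipeline of [assign_peaks()] and [call_species()]; the evidence table
#' carries the peak-derived bases.
#'
#' @inheritParams assign_peaks
#' @param panel A [load_panel()] result.
#' @return A `species_call`.
#' @export
call_from_peaks <- function(profile, panel, min_rel_height = 0.10) {
  gt <- assign_peaks(profile, panel$calibration, min_rel_height)
  call_species(gt, panel$genotype_table)
}

#' Write a species call report
#'
#' Tab-separated: a header block (status, species/candidates, sites used)
#' followed by the per-site evidence table.
#'
#' @param call A `species_call`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_call_report <- function(call, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("status\t", call$status),
    paste0("species\t", paste(call$species, collapse = ";")),
    if (!is.null(call$nearest))
      paste0("nearest_hint\t", call$nearest$species, " (Hamming ",
             call$nearest$hamming, "; not an identification)"),
    paste0("n_sites_used\t", call$n_sites_used),
    ""), con)
  utils::write.table(call$per_site_evidence, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
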