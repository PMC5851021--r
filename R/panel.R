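# The panel: the complete description of one family's SNaPshot assay —
# PCR pair, ordered SNP sites, SBE primer set with its size ladder,
# per-species genotype table, size calibration, and species metadata.
# Serialized as a versioned YAML document; two validated panels ship with
# the package: "CA" (11 Calliphoridae species, 6 sites) and "SA"
# (7 Sarcophagidae species, 4 sites).

.panel_schema_version <- 1L

#' Load a SNaPshot panel
#'
#' @param name_or_path `"CA"` or `"SA"` for the packaged panels, or a
#'   path to a panel YAML document.
#' @return A validated `panel` object (all invariants enforced at load;
#'   see [validate_panel()]).
#' @examples
#' ca <- load_panel("CA")
#' length(ca$sites)  # 6
#' @export
load_panel <- function(name_or_path) {
  path <- if (name_or_path %in% c("CA", "SA")) {
    system.file("extdata", paste0("panel_", name_or_path, ".yaml"),
                package = "snapanel", mustWork = TRUE)
  } else name_or_path
  if (!file.exists(path))
    stop("panel document not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  panel <- .panel_from_doc(doc)
  validate_panel(panel)
  panel
}

.panel_from_doc <- function(doc) {
  need <- c("schema_version", "name", "family", "sites", "sbe_primers",
            "genotypes")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("panel document missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (doc$schema_version > .panel_schema_version)
    stop("panel schema_version ", doc$schema_version,
         " is newer than supported (", .panel_schema_version, ")",
         call. = FALSE)
  species <- names(doc$genotypes)
  site_labels <- vapply(doc$sites, `[[`, "", "label")
  vectors <- lapply(doc$genotypes, function(g) {
    strsplit(toupper(as.character(g)), "")[[1]]
  })
  sites <- lapply(seq_along(doc$sites), function(i) {
    s <- doc$sites[[i]]
    bases <- vapply(vectors, `[[`, "", i)
    snp_site(s$label, s$position,
             stats::setNames(bases, species),
             direction = s$direction)
  })
  calibration <- data.frame(
    site = site_labels,
    expected = vapply(doc$sites, function(s) as.integer(s$expected_size), 1L),
    mean = vapply(doc$sites, function(s) as.numeric(s$observed_mean), 1),
    lo = vapply(doc$sites, function(s) as.numeric(s$observed_range[[1]]), 1),
    hi = vapply(doc$sites, function(s) as.numeric(s$observed_range[[2]]), 1),
    sd = vapply(doc$sites, function(s) as.numeric(s$observed_sd), 1),
    stringsAsFactors = FALSE)
  primers <- lapply(doc$sbe_primers, function(p) {
    site <- sites[[match(p$site, site_labels)]]
    if (is.na(match(p$site, site_labels)))
      stop("SBE primer references unknown site ", p$site, call. = FALSE)
    seq <- toupper(p$seq)
    tail_len <- as.integer(p$tail_len)
    specific <- substring(seq, tail_len + 1L)
    if (paste0(strrep("T", tail_len), specific) != seq)
      stop("primer for ", p$site, ": tail_len inconsistent with sequence",
           call. = FALSE)
    sbe_primer(p$site, specific, tail_len = tail_len,
               direction = site$direction,
               role = if (is.null(p$role)) "universal" else p$role,
               concentration = if (is.null(p$concentration)) NA_real_
                               else as.numeric(p$concentration))
  })
  gt <- build_genotype_table(sites)
  pcr <- doc$pcr
  structure(
    list(schema_version = as.integer(doc$schema_version),
         name = doc$name, family = doc$family,
         pcr = pcr, sites = sites, sbe_primers = primers,
         genotype_table = gt, calibration = calibration,
         species = species,
         species_metadata = doc$species_metadata,
         notes = doc$notes),
    class = "panel")
}

#' Validate a panel's invariants
#'
#' Checks that the genotype table uniquely identifies every species
#' (naming colliding species on failure), that every site has exactly one
#' universal SBE primer whose total length equals the site's expected
#' ladder size, that universal primer lengths are pairwise distinct
#' across sites, that calibration statistics are coherent
#' (`lo <= mean <= hi`, `sd >= 0`) and that adjacent assignment windows
#' do not overlap.
#'
#' @param panel A `panel` object.
#' @return The panel, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel"))
  chk <- verify_uniqueness(panel$genotype_table)
  if (!chk$is_unique) {
    coll <- vapply(chk$collisions, paste, "", collapse = " / ")
    stop("panel ", panel$name, ": genotype vectors collide for: ",
         paste(coll, collapse = "; "), call. = FALSE)
  }
  cal <- panel$calibration
  if (any(cal$sd < 0) || any(cal$lo > cal$mean) || any(cal$hi < cal$mean))
    stop("panel ", panel$name, ": incoherent calibration statistics",
         call. = FALSE)
  labels <- cal$site
  uni_len <- integer(length(labels))
  for (i in seq_along(labels)) {
    uni <- Filter(function(p) p$site_label == labels[i] &&
                    p$role == "universal", panel$sbe_primers)
    if (length(uni) != 1L)
      stop("panel ", panel$name, ": site ", labels[i], " has ",
           length(uni), " universal primers (need exactly 1)",
           call. = FALSE)
    uni_len[i] <- uni[[1]]$total_len
    if (uni_len[i] != cal$expected[i])
      stop("panel ", panel$name, ": site ", labels[i],
           " universal primer length ", uni_len[i],
           " != expected ladder size ", cal$expected[i], call. = FALSE)
    alt <- Filter(function(p) p$site_label == labels[i] &&
                    p$role != "universal", panel$sbe_primers)
    badalt <- vapply(alt, function(p) p$total_len != cal$expected[i], NA)
    if (any(badalt))
      stop("panel ", panel$name, ": alternate primer for ", labels[i],
           " is off its ladder rung", call. = FALSE)
  }
  if (anyDuplicated(uni_len))
    stop("panel ", panel$name, ": size-ladder collision between sites",
         call. = FALSE)
  win <- .site_windows(cal)
  o <- order(win$lo)
  if (nrow(win) > 1L &&
      any(win$hi[o][-nrow(win)] > win$lo[o][-1L]))
    stop("panel ", panel$name, ": peak assignment windows overlap",
         call. = FALSE)
  invisible(panel)
}

#' Write a panel document
#'
#' Serializes a panel back to the YAML dialect read by [load_panel()];
#' the read/write round trip is lossless.
#'
#' @param panel A `panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cal <- panel$calibration
  doc <- list(
    schema_version = panel$schema_version,
    name = panel$name,
    family = panel$family,
    pcr = panel$pcr,
    sites = lapply(seq_along(panel$sites), function(i) {
      s <- panel$sites[[i]]
      list(label = s$label, position = s$position,
           direction = s$direction,
           expected_size = cal$expected[i],
           observed_mean = cal$mean[i],
           observed_range = c(cal$lo[i], cal$hi[i]),
           observed_sd = cal$sd[i])
    }),
    sbe_primers = lapply(panel$sbe_primers, function(p) {
      out <- list(site = p$site_label, seq = p$seq,
                  tail_len = p$tail_len, role = p$role)
      if (!is.na(p$concentration)) out$concentration <- p$concentration
      out
    }),
    genotypes = stats::setNames(
      lapply(panel$genotype_table$vectors, paste, collapse = ""),
      panel$species),
    species_metadata = panel$species_metadata,
    notes = panel$notes)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.panel <- function(x, ...) {
  cat("<panel> ", x$name, " (", x$family, "): ",
      length(x$species), " species x ", length(x$sites), " sites\n",
      sep = "")
  cat("  sites: ",
      paste(vapply(x$sites, `[[`, "", "label"), collapse = ", "),
      "\n  ladder: ",
      paste(x$calibration$expected, collapse = ", "), " nt\n",
      "  SBE primers: ", length(x$sbe_primers), " (",
      sum(vapply(x$sbe_primers, function(p) p$role == "universal", NA)),
      " universal)\n", sep = "")
  invisible(x)
}
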