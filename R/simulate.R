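# Seeded simulators: synthetic per-species reference sequences consistent
# with a panel's genotype table and primer footprints, specimen sequences
# with background mutation, and noisy capillary peak profiles.
#
# The true COI references behind the packaged panels are not distributed;
# synthetic_reference() builds stand-ins that satisfy every constraint the
# panel itself imposes (primer binding footprints, per-species SNP bases),
# which is exactly what the downstream machinery exercises.

# evaluate expr under a given RNG seed without disturbing the caller's
# RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Bundles the knobs of the sequence and peak simulators. Defaults mirror
#' the packaged panels' validation conditions: 10 specimens per species,
#' background mutation rate 1% per non-panel site, per-site size noise at
#' the panels' observed SDs, no dropout.
#'
#' @param seed Integer RNG seed.
#' @param n_per_species Sequences per species for
#'   [simulate_sequences()].
#' @param background_mut_rate Per-position substitution probability
#'   outside panel positions and primer footprints.
#' @param size_noise_sd Per-site peak-size SD; `NULL` means use the
#'   panel's calibration SDs.
#' @param dropout_prob Probability that a site's peak is absent.
#' @param height_cv Coefficient of variation of (lognormal) peak heights.
#' @param height_mean Median peak height, RFU.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_per_species = 10L,
                       background_mut_rate = 0.01, size_noise_sd = NULL,
                       dropout_prob = 0, height_cv = 0.25,
                       height_mean = 2000) {
  stopifnot(background_mut_rate >= 0, background_mut_rate <= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            is.null(size_noise_sd) || all(size_noise_sd >= 0),
            height_cv >= 0)
  structure(list(seed = as.integer(seed),
                 n_per_species = as.integer(n_per_species),
                 background_mut_rate = background_mut_rate,
                 size_noise_sd = size_noise_sd,
                 dropout_prob = dropout_prob,
                 height_cv = height_cv, height_mean = height_mean),
            class = "sim_config")
}

# positions a simulator must not mutate: SNP sites plus every primer
# footprint on the sense strand (SBE and PCR)
.protected_positions <- function(panel) {
  pos <- vapply(panel$sites, `[[`, 1L, "position")
  prot <- pos
  for (pr in panel$sbe_primers) {
    site <- panel$sites[[match(pr$site_label,
                               vapply(panel$sites, `[[`, "", "label"))]]
    L <- nchar(pr$specific_seq)
    span <- if (site$direction == "forward")
      (site$position - L):(site$position - 1L)
    else (site$position + 1L):(site$position + L)
    prot <- c(prot, span)
  }
  for (side in c("forward", "reverse")) {
    sp <- panel$pcr[[side]]$span
    if (!is.null(sp) && !anyNA(unlist(sp)))
      prot <- c(prot, sp[[1]]:sp[[2]])
  }
  sort(unique(prot))
}

#' Synthetic per-species reference sequences for a panel
#'
#' Builds one concrete sense-strand reference per panel species on a
#' fixed random background, constrained so that (i) every position under
#' a primer footprint (SBE specific portions and coordinate-bearing PCR
#' primers) carries a base drawn from the intersection of all covering
#' primers' IUPAC sets, and (ii) each SNP position carries the species'
#' genotype-table base (sense strand; the complement of the
#' detection-channel base for reverse-direction sites). These are
#' synthetic stand-ins for the real COI consensuses, which are not
#' distributed with the package; they satisfy every sequence constraint
#' the panel encodes and are deterministic for a given panel.
#'
#' @param panel A [load_panel()] result.
#' @param length Reference length (default 1600, covering both packaged
#'   panels' coordinate ranges).
#' @return Named character vector of sequences, one per species.
#' @export
synthetic_reference <- function(panel, length = 1600L) {
  labels <- vapply(panel$sites, `[[`, "", "label")
  maxpos <- max(vapply(panel$sites, `[[`, 1L, "position"),
                unlist(lapply(c(panel$pcr$forward$span,
                                panel$pcr$reverse$span), as.integer)),
                0L)
  if (length < maxpos)
    stop("reference length too short for the panel's coordinates",
         call. = FALSE)
  seed <- 20180L + sum(utf8ToInt(panel$name))
  background <- .with_seed(seed,
    sample(c("A", "C", "G", "T"), length, replace = TRUE))
  # intersect IUPAC constraints of all primer footprints, sense strand
  constraint <- vector("list", length)
  impose <- function(span, iupac_sense) {
    codes <- strsplit(iupac_sense, "")[[1]]
    for (k in seq_along(span)) {
      p <- span[k]
      s <- base_set(codes[k])
      cur <- constraint[[p]]
      isect <- if (is.null(cur)) s else intersect(cur, s)
      if (length(isect) == 0L) {
        warning("conflicting primer constraints at position ", p,
                "; keeping earlier constraint", call. = FALSE)
        isect <- cur
      }
      constraint[[p]] <<- isect
    }
  }
  for (pr in panel$sbe_primers) {
    if (pr$role != "universal") next
    site <- panel$sites[[match(pr$site_label, labels)]]
    L <- nchar(pr$specific_seq)
    if (site$direction == "forward") {
      impose((site$position - L):(site$position - 1L), pr$specific_seq)
    } else {
      impose((site$position + 1L):(site$position + L),
             dna_revcomp(pr$specific_seq))
    }
  }
  fsp <- panel$pcr$forward$span
  if (!is.null(fsp) && !anyNA(unlist(fsp)))
    impose(fsp[[1]]:fsp[[2]], panel$pcr$forward$seq)
  rsp <- panel$pcr$reverse$span
  if (!is.null(rsp) && !anyNA(unlist(rsp)))
    impose(rsp[[1]]:rsp[[2]], dna_revcomp(panel$pcr$reverse$seq))
  base_chars <- background
  for (p in seq_len(length))
    if (!is.null(constraint[[p]]))
      base_chars[p] <- sort(constraint[[p]])[1L]
  refs <- vapply(panel$species, function(sp) {
    chars <- base_chars
    for (s in panel$sites) {
      b <- s$per_species_base[[sp]]
      chars[s$position] <- if (s$direction == "reverse")
        dna_complement(b) else b
    }
    paste(chars, collapse = "")
  }, "")
  refs
}

#' Simulate specimen sequences for every panel species
#'
#' Draws `n_per_species` sequences per species from its reference
#' (degenerate reference positions, if any, sampled uniformly from their
#' base sets), holding panel SNP positions fixed at the species' bases
#' and substituting other positions i.i.d. at
#' `cfg$background_mut_rate`. By default mutations also avoid primer
#' footprints so binding is undisturbed; `hostile = TRUE` lifts that
#' protection (SNP positions stay fixed) to stress mismatch tolerance.
#'
#' @param panel A [load_panel()] result.
#' @param cfg A [sim_config()].
#' @param references Optional named per-species sequences; defaults to
#'   [synthetic_reference()].
#' @param hostile Allow mutations inside primer footprints.
#' @return Named character vector (`"<species>|<replicate>"`), attribute
#'   `species` carrying the true labels. Deterministic given `cfg$seed`.
#' @export
simulate_sequences <- function(panel, cfg = sim_config(),
                               references = NULL, hostile = FALSE) {
  if (is.null(references)) references <- synthetic_reference(panel)
  protected <- if (hostile)
    vapply(panel$sites, `[[`, 1L, "position")
  else .protected_positions(panel)
  bases <- c("A", "C", "G", "T")
  .with_seed(cfg$seed, {
    out <- character(0)
    labs <- character(0)
    for (sp in panel$species) {
      chars0 <- strsplit(references[[sp]], "")[[1]]
      free <- setdiff(which(chars0 %in% bases), protected)
      deg <- which(!chars0 %in% c(bases, "-"))
      for (r in seq_len(cfg$n_per_species)) {
        chars <- chars0
        for (d in deg) chars[d] <- sample(base_set(chars0[d]), 1L)
        if (cfg$background_mut_rate > 0 && length(free)) {
          hit <- free[stats::runif(length(free)) < cfg$background_mut_rate]
          for (h in hit) chars[h] <- sample(setdiff(bases, chars[h]), 1L)
        }
        out <- c(out, paste(chars, collapse = ""))
        labs <- c(labs, sp)
      }
    }
    names(out) <- paste0(labs, "|", ave(labs, labs, FUN = seq_along))
    attr(out, "species") <- labs
    out
  })
}

#' Simulate one capillary peak profile for a species
#'
#' One peak per non-dropped panel site: dye from the species' base, size
#' drawn from a Normal centred on the site's observed calibration mean
#' (SD from `cfg$size_noise_sd` or the panel calibration), truncated at
#' +/- 3 SD; height lognormal with median `cfg$height_mean` and CV
#' `cfg$height_cv`.
#'
#' @param species Species name (must be in the panel).
#' @param panel A [load_panel()] result.
#' @param cfg A [sim_config()].
#' @param seed Seed for this profile (default `cfg$seed`); vary it across
#'   replicates.
#' @return A [peak_profile()]. Deterministic given the seed.
#' @export
simulate_profile <- function(species, panel, cfg = sim_config(),
                             seed = cfg$seed) {
  if (!species %in% panel$species)
    stop("unknown species for panel ", panel$name, ": ", species,
         call. = FALSE)
  cal <- panel$calibration
  sds <- if (is.null(cfg$size_noise_sd)) cal$sd
         else rep_len(cfg$size_noise_sd, nrow(cal))
  ref <- panel$genotype_table$vectors[[species]]
  .with_seed(seed, {
    keep <- stats::runif(nrow(cal)) >= cfg$dropout_prob
    # truncated-normal sizes via inverse CDF restricted to +/- 3 sigma
    u <- stats::runif(nrow(cal), stats::pnorm(-3), stats::pnorm(3))
    sizes <- cal$mean + sds * stats::qnorm(u)
    sdlog <- sqrt(log(1 + cfg$height_cv^2))
    heights <- stats::rlnorm(nrow(cal), log(cfg$height_mean), sdlog)
    peak_profile(base_to_dye(ref[keep]), sizes[keep], heights[keep])
  })
}
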