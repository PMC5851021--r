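# Dye mapping, peak assignment, in-silico genotyping, species calling.

test_that("dye/base mapping is the SNaPshot bijection", {
  expect_identical(dye_to_base("green"), "A")
  expect_identical(base_to_dye("T"), "red")
  for (d in c("green", "black", "blue", "red")) {
    expect_identical(base_to_dye(dye_to_base(d)), d)
  }
  # chemistry names are accepted
  expect_identical(dye_to_base(c("dR6G", "dTAMRA", "dR110", "dROX")),
                   c("A", "C", "G", "T"))
  expect_error(dye_to_base("purple"), "unknown dye")
  expect_error(base_to_dye("N"), "unknown base")
})

test_that("assign_peaks bins by calibration window and flags ambiguity", {
  ca <- load_panel("CA")
  # a lone green peak near the CA90 observed mean
  gt <- assign_peaks(peak_profile("green", 28.7, 1000), ca)
  expect_identical(unname(unclass(gt)["CA90"]), "A")
  expect_identical(sum(!is.na(unclass(gt))), 1L)
  # a peak outside every window is ignored
  gt <- assign_peaks(peak_profile("green", 10.0, 1000), ca)
  expect_true(all(is.na(unclass(gt))))
  # two surviving peaks in one window -> ambiguous, not guessed
  gt <- assign_peaks(peak_profile(c("green", "red"), c(28.6, 28.9),
                                  c(1000, 900)), ca)
  expect_true(is.na(unclass(gt)["CA90"]))
  expect_identical(unname(attr(gt, "status")["CA90"]), "ambiguous")
  # noise floor: peaks under min_rel_height of the tallest are dropped
  gt <- assign_peaks(peak_profile(c("green", "red"), c(28.6, 28.9),
                                  c(1000, 50)), ca)
  expect_identical(unname(unclass(gt)["CA90"]), "A")
})

test_that("assign_peaks refuses overlapping calibration windows", {
  cal <- data.frame(site = c("a", "b"), expected = c(25L, 26L),
                    mean = c(25, 26), lo = c(24, 25), hi = c(26, 27),
                    sd = c(1.2, 1.2))
  expect_error(assign_peaks(peak_profile(), cal), "overlap")
})

test_that("peak CSV round-trips and accepts chemistry dye names", {
  prof <- peak_profile(c("green", "black"), c(28.7, 38.2), c(1200, 800))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peaks(prof, path)
  back <- read_peaks(path)
  expect_equal(as.data.frame(back), as.data.frame(prof))
  writeLines(c("dye,size,height", "dR6G,28.7,1200", "dROX,78.6,900"), path)
  back <- read_peaks(path)
  expect_identical(back$dye, c("green", "red"))
  writeLines(c("colour,size", "green,28.7"), path)
  expect_error(read_peaks(path), "header")
})

test_that("in-silico genotyping reproduces both fixture genotype tables", {
  for (nm in c("CA", "SA")) {
    panel <- load_panel(nm)
    refs <- synthetic_reference(panel)
    for (sp in panel$species) {
      gt <- in_silico_genotype(refs[[sp]], panel)
      expect_identical(gt_bases(gt), panel$genotype_table$vectors[[sp]],
                       label = paste(nm, sp))
    }
  }
})

test_that("in-silico genotyping is strand symmetric and degrades gracefully", {
  ca <- load_panel("CA")
  refs <- synthetic_reference(ca)
  q <- refs[["Phormia regina"]]
  expect_identical(unclass(in_silico_genotype(dna_revcomp(q), ca)),
                   unclass(in_silico_genotype(q, ca)))
  # removing the CA243 footprint leaves only that site missing
  # (CA243's specific portion covers 220..242; truncating at 200 also
  # removes CA252/CA261, so instead mutate the footprint heavily)
  qq <- strsplit(q, "")[[1]]
  qq[230:242] <- "G"
  gt <- in_silico_genotype(paste(qq, collapse = ""), ca)
  expect_true(is.na(unclass(gt)["CA243"]))
  expect_false(anyNA(unclass(gt)[c("CA90", "CA72", "CA168")]))
  expect_error(in_silico_genotype("", ca), "empty query")
})

test_that("call_species separates unique, ambiguous, and no-match", {
  ca <- load_panel("CA")
  # the reference vector of each species calls that species (Tables are
  # self-consistent)
  for (sp in ca$species) {
    cl <- call_species(genotype_vector(
      stats::setNames(ca$genotype_table$vectors[[sp]],
                      vapply(ca$sites, `[[`, "", "label"))), ca)
    expect_identical(cl$status, "unique")
    expect_identical(cl$species, sp)
  }
  # (A, C, T, C, NA, T): the two Lucilia species differing only at CA252
  gt <- genotype_vector(c(CA90 = "A", CA72 = "C", CA168 = "T",
                          CA261 = "C", CA252 = NA, CA243 = "T"))
  cl <- call_species(gt, ca)
  expect_identical(cl$status, "ambiguous")
  expect_setequal(cl$species, c("Lucilia ampullacea", "Lucilia caesar"))
  # all-missing -> ambiguous with every species
  cl <- call_species(genotype_vector(rep(NA_character_, 6)), ca)
  expect_identical(cl$status, "ambiguous")
  expect_length(cl$species, 11)
  # an impossible vector -> no-match with a labelled nearest hint
  gt <- genotype_vector(c(CA90 = "G", CA72 = "G", CA168 = "G",
                          CA261 = "G", CA252 = "G", CA243 = "G"))
  cl <- call_species(gt, ca)
  expect_identical(cl$status, "no-match")
  expect_length(cl$species, 0)
  expect_match(cl$nearest$note, "NOT an identification")
  expect_error(call_species(genotype_vector(c(a = "A")), ca),
               "does not match")
})

test_that("non-missing information only ever shrinks the candidate set", {
  ca <- load_panel("CA")
  labels <- vapply(ca$sites, `[[`, "", "label")
  set.seed(31)
  for (i in 1:20) {
    sp <- sample(ca$species, 1)
    full <- ca$genotype_table$vectors[[sp]]
    miss <- sample(6, sample(0:5, 1))
    partial <- stats::setNames(full, labels)
    partial[miss] <- NA
    cands1 <- call_species(genotype_vector(partial), ca)$species
    # reveal one more site
    if (length(miss)) {
      reveal <- partial
      reveal[miss[1]] <- full[miss[1]]
      cands2 <- call_species(genotype_vector(reveal), ca)$species
      expect_true(all(cands2 %in% cands1))
      expect_true(sp %in% cands2)
    }
  }
})

test_that("call_from_peaks pipelines peak assignment into calling", {
  sa <- load_panel("SA")
  # noiseless profile at the calibration means
  cfg <- sim_config(size_noise_sd = 0, dropout_prob = 0)
  prof <- simulate_profile("Sarcophaga peregrina", sa, cfg, seed = 9)
  expect_equal(prof$size, sa$calibration$mean)
  cl <- call_from_peaks(prof, sa)
  expect_identical(cl$status, "unique")
  expect_identical(cl$species, "Sarcophaga peregrina")
  # deleting the discriminating peak for L. caesar gives the known pair
  ca <- load_panel("CA")
  profc <- simulate_profile("Lucilia caesar", ca,
                            sim_config(size_noise_sd = 0), seed = 9)
  profc <- profc[profc$size != ca$calibration$mean[
    ca$calibration$site == "CA252"], ]
  cl <- call_from_peaks(profc, ca)
  expect_identical(cl$status, "ambiguous")
  expect_setequal(cl$species, c("Lucilia ampullacea", "Lucilia caesar"))
  # empty profile -> ambiguous across all species
  cl <- call_from_peaks(peak_profile(), sa)
  expect_identical(cl$status, "ambiguous")
  expect_length(cl$species, 7)
})

test_that("call reports serialize with status, species and evidence", {
  sa <- load_panel("SA")
  prof <- simulate_profile("Sarcophaga dux", sa,
                           sim_config(size_noise_sd = 0), seed = 3)
  cl <- call_from_peaks(prof, sa)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_call_report(cl, path)
  lines <- readLines(path)
  expect_identical(lines[1], "status\tunique")
  expect_identical(lines[2], "species\tSarcophaga dux")
  expect_true(any(grepl("^SA1491\t", lines)))
})
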