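# Seeded simulators: reproducibility, noise calibration, and end-to-end
# recovery of the true species.

test_that("synthetic references honour every panel constraint", {
  for (nm in c("CA", "SA")) {
    panel <- load_panel(nm)
    refs <- synthetic_reference(panel)
    expect_identical(names(refs), panel$species)
    # identical calls are deterministic
    expect_identical(synthetic_reference(panel), refs)
    # genotype table read off the references equals the fixture table
    cons <- lapply(names(refs), function(sp)
      build_consensus(aligned_seq_set(sp, refs[[sp]],
                                      family = panel$family)))
    gt <- build_genotype_table(panel$sites, cons)
    for (sp in panel$species) {
      expect_identical(gt$vectors[[sp]],
                       panel$genotype_table$vectors[[sp]])
    }
    # candidate discovery on the references finds exactly the panel sites
    cands <- find_candidate_sites(cons)
    expect_setequal(vapply(cands, `[[`, 1L, "position"),
                    vapply(panel$sites, `[[`, 1L, "position"))
  }
})

test_that("the minimal panel re-derived from synthetic references matches", {
  # all six CA sites are essential: the exact search over the candidates
  # recovered from the references returns exactly the fixture's six
  ca <- load_panel("CA")
  refs <- synthetic_reference(ca)
  cons <- lapply(names(refs), function(sp)
    build_consensus(aligned_seq_set(sp, refs[[sp]])))
  cands <- find_candidate_sites(cons)
  sel <- select_minimal_panel(cands)
  expect_true(attr(sel, "exact"))
  expect_setequal(vapply(sel, `[[`, 1L, "position"),
                  vapply(ca$sites, `[[`, 1L, "position"))
})

test_that("simulate_sequences is seed-deterministic and label-faithful", {
  sa <- load_panel("SA")
  cfg <- sim_config(seed = 7, n_per_species = 3)
  s1 <- simulate_sequences(sa, cfg)
  s2 <- simulate_sequences(sa, cfg)
  expect_identical(s1, s2)
  s3 <- simulate_sequences(sa, sim_config(seed = 8, n_per_species = 3))
  expect_false(identical(unname(s1), unname(s3)))
  expect_length(s1, 3 * 7)
  expect_identical(attr(s1, "species"), rep(sa$species, each = 3))
  # zero mutation, concrete references -> sequences equal the reference
  s0 <- simulate_sequences(sa, sim_config(seed = 1, n_per_species = 1,
                                          background_mut_rate = 0))
  refs <- synthetic_reference(sa)
  expect_identical(unname(unclass(s0)[1]), unname(refs[1]))
})

test_that("genotyping simulated sequences recovers every species label", {
  for (nm in c("CA", "SA")) {
    panel <- load_panel(nm)
    seqs <- simulate_sequences(panel, sim_config(seed = 1,
                                                 n_per_species = 10,
                                                 background_mut_rate = 0.01))
    truth <- attr(seqs, "species")
    for (i in seq_along(seqs)) {
      cl <- call_species(in_silico_genotype(seqs[[i]], panel), panel)
      expect_identical(cl$status, "unique", label = paste(nm, truth[i], i))
      expect_identical(cl$species, truth[i])
    }
  }
})

test_that("simulate_profile is deterministic and obeys its knobs", {
  sa <- load_panel("SA")
  cfg <- sim_config(seed = 5)
  p1 <- simulate_profile("Sarcophaga dux", sa, cfg)
  p2 <- simulate_profile("Sarcophaga dux", sa, cfg)
  expect_identical(p1, p2)
  # noiseless: sizes are exactly the calibration means
  p0 <- simulate_profile("Sarcophaga dux", sa,
                         sim_config(size_noise_sd = 0), seed = 2)
  expect_equal(p0$size, sa$calibration$mean)
  # total dropout: empty profile
  pd <- simulate_profile("Sarcophaga dux", sa,
                         sim_config(dropout_prob = 1), seed = 2)
  expect_identical(nrow(pd), 0L)
  expect_error(simulate_profile("no such fly", sa), "unknown species")
})

test_that("simulated size noise matches the configured sd within 20%", {
  sa <- load_panel("SA")
  sizes <- vapply(1:1000, function(i)
    simulate_profile("Sarcophaga similis", sa, sim_config(), seed = i)$size[3],
    1)
  target <- sa$calibration$sd[3]
  expect_lt(abs(stats::sd(sizes) - target) / target, 0.20)
  expect_lt(abs(mean(sizes) - sa$calibration$mean[3]), 0.05)
  # truncation: nothing beyond 3 sigma
  expect_true(all(abs(sizes - sa$calibration$mean[3]) <= 3 * target + 1e-9))
})

test_that("peak pipeline on simulated profiles returns the true species", {
  # moderate replicate count here; the full 100-replicate sweep is the
  # concordance check in the acceptance tests
  for (nm in c("CA", "SA")) {
    panel <- load_panel(nm)
    for (k in seq_along(panel$species)) {
      sp <- panel$species[k]
      for (r in 1:5) {
        prof <- simulate_profile(sp, panel, sim_config(),
                                 seed = 1000L * k + r)
        cl <- call_from_peaks(prof, panel)
        expect_identical(cl$status, "unique", label = paste(nm, sp, r))
        expect_identical(cl$species, sp)
      }
    }
  }
})

test_that("hostile mutations inside footprints are tolerated up to the clamp", {
  # with background mutation allowed inside primer footprints most calls
  # should still succeed thanks to the 1-mismatch tolerance, and failures
  # must be missing sites, never wrong bases
  sa <- load_panel("SA")
  seqs <- simulate_sequences(sa, sim_config(seed = 3, n_per_species = 5,
                                            background_mut_rate = 0.005),
                             hostile = TRUE)
  truth <- attr(seqs, "species")
  for (i in seq_along(seqs)) {
    gt <- in_silico_genotype(seqs[[i]], sa)
    ref <- sa$genotype_table$vectors[[truth[i]]]
    called <- !is.na(unclass(gt))
    expect_true(all(unclass(gt)[called] == ref[called]),
                label = paste("no wrong base for", truth[i], i))
  }
})
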