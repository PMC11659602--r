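# Seeded generators: library composition, selection dynamics, plates
# and sensorgrams.

test_that("library length distribution matches the normalized sub-library ratio", {
  spec <- library_spec()
  # normalized weights sum to 1
  expect_equal(sum(spec$length_probs), 1)
  n <- 100000
  reads <- sample_library(spec, n, seed = 11)
  lens <- (nchar(reads) - 3 - 21) / 3
  p10 <- 80 / 113.0338
  se <- sqrt(p10 * (1 - p10) / n)
  expect_lt(abs(mean(lens == 10) - p10), 3 * se)
  p9 <- 32 / 113.0338
  expect_lt(abs(mean(lens == 9) - p9), 3 * sqrt(p9 * (1 - p9) / n))
  expect_true(all(lens %in% 6:10))
})

test_that("sampled reads are NNK by construction with the expected amber rate", {
  reads <- sample_library(n = 5000, seed = 12)
  regions <- substr(reads, 4, nchar(reads) - 21)
  expect_true(all(validate_nnk(regions)))
  # TAG is 1 of 32 NNK codons: expected stop count per read ~ len/32
  n_tag <- vapply(regions, function(r) {
    cods <- substring(r, seq(1, nchar(r), 3), seq(3, nchar(r), 3))
    sum(cods == "TAG")
  }, numeric(1L), USE.NAMES = FALSE)
  lens <- nchar(regions) / 3
  expect_equal(mean(n_tag), mean(lens) / 32, tolerance = 0.15)
  # byte-stable across runs under a fixed seed
  expect_identical(reads, sample_library(n = 5000, seed = 12))
})

test_that("expectation-mode selection doubles the frequency ratio of a 2:1 fitness pair", {
  set.seed(13)
  winners <- data.frame(peptide = c("yAD2KLWNH", "yWD2KLFNH"),
                        fitness = c(2, 1))
  cfg <- selection_config(rounds = 3, reads_per_round = 10000,
                          winners = winners, washes_enabled = FALSE,
                          pool_size = 2, seed = 13)
  sim <- evolve_selection(cfg, expectation = TRUE)
  freqs <- sim$truth
  iA <- 3L  # winners follow the pool sequences
  iB <- 4L
  ratios <- vapply(freqs, function(f) f[iA] / f[iB], numeric(1L))
  expect_equal(ratios, c(1, 2, 4, 8) * ratios[1L] / 1,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("denaturing washes collapse the warhead-free mass; without them it only drifts", {
  cfg <- selection_config(rounds = 3, reads_per_round = 5000,
                          warhead_wash_survival = 0.01,
                          washes_enabled = TRUE, pool_size = 1000, seed = 14)
  sim <- evolve_selection(cfg)
  wf <- vapply(sim$ledger$rounds, `[[`, numeric(1L), "warhead_free_mass")
  # closed form: after r rounds the free mass odds shrink by survival^r
  f0 <- wf[["round0"]]
  odds0 <- f0 / (1 - f0)
  expect_equal(wf[["round2"]],
               odds0 * 0.01^2 / (1 + odds0 * 0.01^2), tolerance = 1e-9)
  expect_lt(wf[["round2"]], 0.01)
  # washes off: the mass fractions stay constant (fitness all 1)
  cfg_off <- selection_config(rounds = 3, reads_per_round = 5000,
                              washes_enabled = FALSE, pool_size = 1000,
                              seed = 14)
  sim_off <- evolve_selection(cfg_off)
  wf_off <- vapply(sim_off$ledger$rounds, `[[`, numeric(1L),
                   "warhead_free_mass")
  expect_equal(unname(diff(range(wf_off))), 0, tolerance = 1e-12)
})

test_that("emitted read totals reconcile with the generator ledger", {
  cfg <- selection_config(rounds = 2, reads_per_round = 2000,
                          pool_size = 500, seed = 15)
  out_dir <- withr::local_tempdir()
  sim <- evolve_selection(cfg, out_dir = out_dir)
  expect_true(file.exists(file.path(out_dir, "truth_ledger.json")))
  for (rn in names(sim$reads)) {
    expect_identical(length(sim$reads[[rn]]),
                     as.integer(sim$ledger$rounds[[rn]]$emitted))
    expect_identical(length(read_fastq_reads(sim$fastq_paths[[rn]])),
                     2000L)
  }
  # counting the emitted reads recovers the emission counts exactly
  cnt <- tabulate_rounds(sim$reads["round1"])
  rec <- decode_reads(unique(sim$reads$round1))
  expect_identical(sum(cnt$rounds[[1L]]$count),
                   sum(sim$reads$round1 %in% rec$dna[rec$valid]))
})

test_that("noise-free plates equal the closed-form activity ratio", {
  truth <- krippendorff_model(covalent_params(1.5, 0.13),
                              substrate_context(10, 1.36))
  plate <- simulate_colder_plate(truth)
  des <- default_colder_design()
  p0 <- progress_curve(0, truth, 1, des$times_min)
  for (i in seq_along(des$concs_uM)) {
    want <- progress_curve(des$concs_uM[i], truth, 1, des$times_min) / p0
    expect_equal(plate$activity[i, ], want, tolerance = 1e-12)
  }
  # zero-inhibitor row is exactly 1
  expect_equal(plate$activity[des$concs_uM == 0, ], rep(1, 5),
               ignore_attr = TRUE)
})

test_that("noisy sensorgrams are seeded and reduce to the clean simulation", {
  p <- two_state_params(1e5, 0.016, 0.25 / 60, 0, 100)
  sch <- default_scheme(0.16e-6)
  times <- seq(0, 3600, 20)
  clean <- simulate_two_state(p, sch, times)
  g0 <- simulate_sensorgram_noisy(p, sch, noise_model(), times = times)
  expect_identical(g0$response, clean$response)
  g1 <- simulate_sensorgram_noisy(p, sch,
                                  noise_model(spr_sigma = 0.5, spr_drift = 1e-4,
                                              seed = 16), times = times)
  g2 <- simulate_sensorgram_noisy(p, sch,
                                  noise_model(spr_sigma = 0.5, spr_drift = 1e-4,
                                              seed = 16), times = times)
  expect_identical(g1$response, g2$response)
  expect_gt(sd(g1$response - clean$response), 0)
  # drift enters linearly
  expect_equal(mean(g1$response - clean$response), 1e-4 * mean(times),
               tolerance = 0.5)
})

test_that("plate and sensorgram CSV round-trip through their readers", {
  truth <- krippendorff_model(covalent_params(0.78, 0.17),
                              substrate_context(10, 1.36))
  plate <- simulate_colder_plate(truth)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(plate, tf)
  back <- read_plate_csv(tf)
  expect_equal(back$activity, plate$activity, ignore_attr = TRUE)
  expect_equal(back$quench_times, plate$quench_times)

  p <- two_state_params(1e5, 0.016, 0.25 / 60, 0, 100)
  sch <- default_scheme(0.16e-6)
  g <- simulate_two_state(p, sch, seq(0, 3600, 10))
  tg <- withr::local_tempfile(fileext = ".csv")
  write_sensorgram_csv(g, tg)
  ty <- withr::local_tempfile(fileext = ".yaml")
  write_scheme_yaml(sch, ty)
  sch2 <- read_scheme_yaml(ty)
  g2 <- read_sensorgram_csv(tg, sch2)
  expect_equal(g2$response, g$response)
  expect_equal(sch2$segments$conc_M, sch$segments$conc_M)
})
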