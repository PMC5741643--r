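test_that("charge inference from isotope spacing", {
  expect_equal(charge_from_spacing(0.502), 2L)
  expect_equal(charge_from_spacing(0.334), 3L)
  expect_true(is.na(charge_from_spacing(1.003)))   # z = 1 never assigned
  expect_true(is.na(charge_from_spacing(0.45)))    # residual too large
  expect_true(is.na(charge_from_spacing(0.25)))    # z = 4 never assigned
})

test_that("envelope detection: clean, interleaved and sub-threshold cases", {
  # one clean 5-peak 3+ envelope
  pt <- as_peak_table(envelope_rows(3138.37, rt = 10.05, z = 3))
  env <- detect_envelopes(pt)
  expect_length(env, 1L)
  expect_equal(env[[1]]$charge, 3L)
  expect_equal(env[[1]]$mono_mz, mz_for_charge(3138.37, 3L),
               tolerance = 1e-9)
  expect_equal(env[[1]]$n_peaks, 5L)

  # interleaved 2+ and 3+ envelopes of two different masses, one rt bin
  pt2 <- as_peak_table(envelope_rows(3138.37, 20.01, 3, base = 1200),
                       envelope_rows(2950.10, 20.03, 2, base = 800))
  env2 <- detect_envelopes(pt2)
  expect_length(env2, 2L)
  zs <- sort(vapply(env2, `[[`, integer(1), "charge"))
  expect_equal(zs, c(2L, 3L))
  for (e in env2) {
    want <- if (e$charge == 3L) mz_for_charge(3138.37, 3L)
            else mz_for_charge(2950.10, 2L)
    expect_equal(e$mono_mz, want, tolerance = 1e-9)
  }

  # two isolated peaks never form an envelope
  pt3 <- as_peak_table(data.frame(rt = 5, mz = c(1200, 1200.5017),
                                  intensity = c(100, 80)))
  expect_length(detect_envelopes(pt3), 0L)

  # peaks outside the acquisition window are ignored
  pt4 <- as_peak_table(envelope_rows(2879.14, 8.01, 3))  # 3+ below 1000
  expect_length(detect_envelopes(pt4), 0L)
})

test_that("two same-bin envelopes a few Da apart stay separate", {
  pt <- as_peak_table(envelope_rows(3100.00, 15.01, 2, base = 1500),
                      envelope_rows(3102.95, 15.02, 2, base = 400))
  env <- detect_envelopes(pt)
  expect_length(env, 2L)
  monos <- sort(vapply(env, `[[`, numeric(1), "mono_mz"))
  expect_equal(monos, sort(c(mz_for_charge(3100, 2L),
                             mz_for_charge(3102.95, 2L))),
               tolerance = 1e-9)
})

test_that("deconvolution merges charge states and applies the mass window", {
  pt <- as_peak_table(envelope_rows(3138.37, 12.01, 3, base = 1200),
                      envelope_rows(3138.37, 12.02, 2, base = 700))
  obs <- deconvolute(detect_envelopes(pt))
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$M, 3138.37, tolerance = 1e-6)
  expect_equal(obs$charges, "2+3")
  expect_equal(obs$SI, 1200)          # summed 3+ intensity only
  expect_equal(obs$abundance, "high")

  # the published triply charged reading: 1047.14 maps back to 3138.4
  env1 <- detect_envelopes(as_peak_table(envelope_rows(3138.4, 6.01, 3)))
  expect_equal(round(deconvolute(env1)$M, 1), 3138.4)

  # outside the 2700-3300 window: dropped
  out <- deconvolute(detect_envelopes(as_peak_table(
    envelope_rows(2500, 9.01, 2))))
  expect_equal(nrow(out), 0L)
  # but admitted for an alkylated set (upper bound + 400)
  alk <- deconvolute(detect_envelopes(as_peak_table(
    envelope_rows(3486.55, 9.01, 2))), alkylated = TRUE)
  expect_equal(nrow(alk), 1L)

  # 2+-only support: SI is zero and abundance low
  only2 <- deconvolute(detect_envelopes(as_peak_table(
    envelope_rows(3100, 11.01, 2))))
  expect_equal(only2$SI, 0)
})

test_that("alkylation confirmation is tri-state and uses the wide tol", {
  native <- data.frame(obs_id = "o1", M = 3138.3, rt = 1, SI = 500,
                       abundance = "medium", n_envelopes = 1L,
                       charges = "3", alkylation_confirmed = "untested")
  # the observed pair from the worked example deviates 0.42 from the
  # theoretical shift; the default tolerance accepts it
  alk <- data.frame(M = 3486.9)
  got <- confirm_alkylation(native, alk)
  expect_equal(got$alkylation_confirmed, "yes")
  expect_equal(confirm_alkylation(native,
                                  data.frame(M = 3000))$alkylation_confirmed,
               "no")
  expect_equal(confirm_alkylation(native, NULL)$alkylation_confirmed,
               "untested")
})

test_that("mass matching is strict-< with a unique best per observation", {
  cand <- data.frame(precursor_id = c("a", "b"), cd_index = 1L,
                     start_offset = 0L, topology = "cyclic",
                     sequence = "X", n_cys = 6L, n_disulfide = 3L,
                     calc_mass = c(3138.37, 3138.10),
                     calc_mass_alkylated = NA, mz2 = NA, mz3 = NA,
                     flags = "")
  obs <- data.frame(obs_id = "o1", M = 3138.30, rt = 1, SI = 100,
                    abundance = "low", n_envelopes = 1L, charges = "3",
                    alkylation_confirmed = "untested")
  mt <- match_predicted(cand, obs)
  expect_equal(nrow(mt), 2L)              # both within tolerance
  expect_equal(sum(mt$best), 1L)
  expect_equal(mt$precursor_id[mt$best], "a")  # minimal |delta|
  # delta at the tolerance is not a match (strict inequality)
  obs2 <- obs; obs2$M <- 3138.0
  cand2 <- cand[1, ]; cand2$calc_mass <- 3138.4
  expect_equal(nrow(match_predicted(cand2, obs2)), 0L)
  # symmetric in sign of the difference
  cand3 <- cand[1, ]; cand3$calc_mass <- obs$M - 0.39
  expect_equal(nrow(match_predicted(cand3, obs)), 1L)
})

test_that("abundance binning: boundaries fall in the closed middle bin", {
  expect_equal(abundance_level(c(100, 249.9, 250, 500, 1000, 1000.1, 1500)),
               c("low", "low", "medium", "medium", "medium", "high",
                 "high"))
  expect_error(abundance_level(-1), "SI")
})
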