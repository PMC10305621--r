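test_that("profile generation is reproducible and respects priors", {
  expect_length(generate_strain_profiles(0), 0)

  p1 <- generate_strain_profiles(24, c("k1", "k2"), seed = 3)
  p2 <- generate_strain_profiles(24, c("k1", "k2"), seed = 3)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_strain_profiles(24, c("k1", "k2"),
                                                      seed = 4)))

  # zero reduction priors: every assay is flat
  pr <- profile_priors(k_red = c(0, 0), inactive_fraction = 0,
                       oxidizer_fraction = 0)
  profs <- generate_strain_profiles(6, "ket", priors = pr, seed = 1)
  rd <- simulate_assay(profs, "ket", times = c(4, 24), noise_sd = 0)
  expect_equal(rd$conversion, c(0, 0))

  expect_error(profile_priors(k_red = c(0.5, 0.1)), "range")
  expect_error(profile_priors(inactive_fraction = 1.5), "0, 1")
})

test_that("empty pools and single-member closed forms", {
  rd <- simulate_assay(list(), "ket", times = c(4, 24), noise_sd = 0)
  expect_equal(rd$conversion, c(0, 0))
  expect_true(all(is.na(rd$alcohol_ee)))

  s <- strain_profile("s1", list(ket = list(k_red_R = 0.1)))
  rd <- simulate_assay(list(s), "ket", times = 24, noise_sd = 0)
  expect_equal(rd$conversion, 1 - exp(-2.4), tolerance = 1e-7)
  expect_equal(rd$alcohol_ee, 1)
})

test_that("pooled rates are additive and conserve mass", {
  a <- strain_profile("a", list(ket = list(k_red_R = 0.07)))
  b <- strain_profile("b", list(ket = list(k_red_R = 0.05, k_red_S = 0.02)))
  rd <- simulate_assay(list(a, b), "ket", times = c(4, 24), noise_sd = 0)
  # parallel catalysts: total reduction 0.14
  expect_equal(rd$conversion, 1 - exp(-0.14 * c(4, 24)), tolerance = 1e-6)

  set.seed(17)
  for (i in 1:10) {
    profs <- generate_strain_profiles(5, "ket",
                                      priors = profile_priors(),
                                      seed = 100 + i)
    terms <- clmscreen:::pool_terms(profs, "ket", "aerobic")
    tr <- clmscreen:::integrate_pool(terms, times = c(1, 4, 24))
    expect_true(all(abs(tr$K + tr$R + tr$S - 1) < 1e-6))
  }
})

test_that("adding an oxidation-free member never decreases conversion", {
  set.seed(23)
  pr <- profile_priors(oxidizer_fraction = 0, inactive_fraction = 0.3)
  for (i in 1:15) {
    profs <- generate_strain_profiles(4, "ket", priors = pr, seed = 200 + i)
    base <- simulate_assay(profs[1:3], "ket", times = c(2, 4, 24),
                           noise_sd = 0)
    more <- simulate_assay(profs, "ket", times = c(2, 4, 24), noise_sd = 0)
    expect_true(all(more$conversion >= base$conversion - 1e-9))
  }
})

test_that("noiseless pooled assay with one active member equals its control", {
  active <- strain_profile("act", list(ket = list(k_red_R = 0.12,
                                                  k_red_S = 0.03)))
  inert <- lapply(1:4, function(i) strain_profile(paste0("i", i)))
  pool <- simulate_assay(c(list(active), inert), "ket", times = c(4, 24),
                         noise_sd = 0)
  ctrl <- simulate_assay(list(active), "ket", times = c(4, 24), noise_sd = 0)
  expect_equal(pool$conversion, ctrl$conversion, tolerance = 1e-9)
  expect_equal(pool$alcohol_ee, ctrl$alcohol_ee, tolerance = 1e-9)
})

test_that("anaerobic incubation silences oxygen-dependent oxidation", {
  ox <- strain_profile("ox", list(alc = list(k_ox_S = 0.5)),
                       oxygen_dependent_oxidation = TRUE)
  an <- simulate_assay(list(ox), "alc", times = 24, aeration = "anaerobic",
                       y0 = c(K = 0, R = 0.5, S = 0.5), noise_sd = 0)
  expect_equal(an$conversion, 0)
  ae <- simulate_assay(list(ox), "alc", times = 24, aeration = "aerobic",
                       y0 = c(K = 0, R = 0.5, S = 0.5), noise_sd = 0)
  expect_gt(ae$conversion, 0.4)
})

test_that("readout tables are seed-deterministic", {
  fx <- make_study_fixture()
  r1 <- simulate_library(fx$designs$clm1, fx$profiles$clm1,
                         fx$mixtures[fx$channels$clm1], seed = 99)
  r2 <- simulate_library(fx$designs$clm1, fx$profiles$clm1,
                         fx$mixtures[fx$channels$clm1], seed = 99)
  expect_identical(r1, r2)
})

test_that("the study fixture encodes the designed decoding situations", {
  fx <- make_study_fixture()
  d1 <- fx$designs$clm1; d2 <- fx$designs$clm2
  expect_equal(unname(colSums(d1$incidence)), rep(5, 4))
  expect_equal(unname(colSums(d2$incidence)), rep(5, 4))
  sig <- function(d, s) d$batch_ids[d$incidence[s, ] == 1L]
  expect_identical(sig(d1, "s01"), "D")
  expect_identical(sig(d1, "s02"), c("A", "D"))
  expect_identical(sig(d1, "s03"), c("A", "D"))
  expect_identical(sig(d1, "s04"), "B")
  expect_identical(sig(d2, "t01"), "E")
  expect_identical(sig(d2, "t02"), c("E", "F"))
  expect_identical(sig(d2, "t03"), c("E", "F"))

  # shipped CSV fixtures agree with the in-code reconstruction
  f1 <- system.file("extdata", "design_clm1_synthetic.csv",
                    package = "clmscreen")
  expect_identical(read_design(f1)$incidence, d1$incidence)

  # the E/F tandem pools show the non-monotone product curve
  rd <- simulate_library(d2, fx$profiles$clm2,
                         fx$mixtures[fx$channels$clm2], noise_sd = 0)
  for (b in c("E", "F")) {
    d <- rd[rd$batch_or_strain == b & rd$substrate == "acetophenone" &
              rd$mode == "pooled", ]
    expect_gt(d$conversion[d$time_h == 4],
              d$conversion[d$time_h == 24] + 0.10)
  }
  # and G/H do not
  for (b in c("G", "H")) {
    d <- rd[rd$batch_or_strain == b & rd$substrate == "acetophenone" &
              rd$mode == "pooled", ]
    expect_gte(d$conversion[d$time_h == 24], d$conversion[d$time_h == 4])
  }
})

test_that("both batch-B hypotheses suppress the aromatic conversions", {
  for (mode in c("oxidation", "inhibition")) {
    fx <- make_study_fixture(batch_b_mode = mode)
    rd <- simulate_library(fx$designs$clm1, fx$profiles$clm1,
                           fx$mixtures["mixture1"], noise_sd = 0)
    b <- rd[rd$batch_or_strain == "B" & rd$substrate == "acetonaphthone" &
              rd$mode == "pooled" & rd$time_h == 24, ]
    expect_lt(b$conversion, 0.5)
  }
})
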