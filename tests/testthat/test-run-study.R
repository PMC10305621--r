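test_that("the end-to-end study reproduces the pooled-assay arithmetic", {
  rep <- run_study(run_config(seed = 1))

  expect_identical(rep$accounting$pooled_assays, 12L)
  expect_identical(rep$accounting$confirmatory_assays, 4L)
  expect_identical(rep$accounting$total, 16L)
  expect_identical(rep$accounting$conventional, 120L)

  # the three unique/ambiguous decoding situations
  expect_true(rep$reports$clm1[["2-octanone"]]$unique)
  expect_identical(rep$reports$clm1[["2-octanone"]]$candidate_sets[[1L]],
                   "s01")
  expect_same_sets(rep$reports$clm1[["propiophenone"]]$candidate_sets,
                   list("s02", "s03"))
  expect_true(rep$reports$clm2[["3-octanone"]]$unique)

  # tandem channel: E/F anomaly decoded to the two signature-mates
  tand <- rep$tandem_reports[["clm2.acetophenone"]]
  expect_same_sets(tand$candidate_sets, list("t02", "t03"))
  expect_setequal(vapply(tand$anomalies, `[[`, character(1), "batch"),
                  c("E", "F"))

  # confirmations: the oxidizer transforms the racemic alcohol, its
  # signature-mate does not
  expect_setequal(names(rep$confirmations), c("s02", "s03", "t02", "t03"))
  expect_gt(max(rep$confirmations$t03$readouts$conversion), 0.2)
  expect_equal(max(rep$confirmations$t02$readouts$conversion), 0)

  # batch-B interference kept as suspicion, separate from candidates
  expect_true(length(rep$interference_suspects) >= 1L)
  expect_true(any(vapply(rep$interference_suspects, function(s) {
    "s04" %in% s$exclusive_strains
  }, logical(1))))
})

test_that("identical seeds give identical reports", {
  r1 <- run_study(run_config(seed = 11))
  r2 <- run_study(run_config(seed = 11))
  expect_identical(r1$readouts, r2$readouts)
  expect_identical(r1$accounting, r2$accounting)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_study_report(r1, p1)
  write_study_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an inactive library yields empty hits and no candidates", {
  d <- build_design(6, 3, 2, seed = 1)
  profs <- lapply(d$strain_ids, strain_profile)
  rd <- simulate_library(d, profs, list(m = "ket"), noise_sd = 0)
  h <- call_hits(rd, d)[["ket"]]
  expect_length(h$active_batches, 0)
  rep_ <- candidates(d, h)
  expect_identical(rep_$candidate_sets, list(character(0)))
  expect_length(flag_anomalies(rd), 0)
})

cli_path <- function() {
  system.file("cli", "clm.R", package = "clmscreen")
}

run_cli <- function(...) {
  env <- paste0("R_LIBS=", paste(.libPaths(),
                                 collapse = .Platform$path.sep))
  out <- suppressWarnings(
    system2("Rscript", c(cli_path(), ...), stdout = TRUE, stderr = TRUE,
            env = env))
  list(status = attr(out, "status") %||% 0L, out = out)
}

test_that("CLI subcommands run end to end on the fixture", {
  expect_true(nzchar(cli_path()))
  tmp <- withr::local_tempdir()

  des <- file.path(tmp, "design.csv")
  r <- run_cli("design", "--strains", "12", "--batches", "4",
               "--pool-size", "5", "--seed", "3", "--out", des)
  expect_identical(r$status, 0L)
  d <- read_design(des)
  expect_equal(unname(colSums(d$incidence)), rep(5, 4))

  rds <- file.path(tmp, "readouts.csv")
  r <- run_cli("simulate", "--seed", "2", "--out", rds)
  expect_identical(r$status, 0L)
  rd <- read_readouts(rds)
  expect_true(all(c("pooled", "control") %in% rd$mode))

  fx1 <- system.file("extdata", "design_clm1_synthetic.csv",
                     package = "clmscreen")
  r <- run_cli("decode", "--design", fx1, "--readouts", rds,
               "--threshold", "0.5", "--timepoint", "24")
  expect_identical(r$status, 0L)
  expect_match(r$out, "unique assignment", all = FALSE)

  r <- run_cli("kinetics", "--k-red-R", "0.1", "--times", "0,4,24")
  expect_identical(r$status, 0L)
  expect_match(r$out, "conversion", all = FALSE)

  r <- run_cli("stereo", "--total-alcohol", "0.85", "--ee", "0.83")
  expect_identical(r$status, 0L)
  expect_match(r$out, "\"reduction_present\":true", all = FALSE)

  rep_json <- file.path(tmp, "report.json")
  r <- run_cli("run", "--seed", "1", "--out", rep_json)
  expect_identical(r$status, 0L)
  js <- jsonlite::read_json(rep_json)
  expect_equal(js$accounting$total, 16)
  expect_equal(js$accounting$conventional, 120)
})
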