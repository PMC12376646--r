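test_that("simulation is byte-deterministic given config and seed", {
  a <- simulate_panel(tiny_config(seed = 5L))
  b <- simulate_panel(tiny_config(seed = 5L))
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_panel(tiny_config(seed = 6L))
  expect_false(identical(a$data, c$data))
})

test_that("noiseless uptake-free panels return the configured g through the pipeline", {
  cfg <- tiny_config(seed = 9L, noise_cv = 0, beta_zero = TRUE)
  sim <- simulate_panel(cfg)
  res <- run_pipeline(pipeline_config(
    input = sim$data, n_perm = 19, seed = 1,
    route_table = cfg$route_table, tissues = c(cfg$tissues, "serum")))
  truth <- sim$truth[sim$truth$tissue != "serum", ]
  got <- dplyr::inner_join(
    res$pseudo_rates[, c("tissue", "species", "g_mean")],
    truth[, c("tissue", "species", "g_true")], by = c("tissue", "species"))
  expect_gt(nrow(got), 0)
  expect_lt(max(abs(got$g_mean - got$g_true)), 1e-3)
})

test_that("generated noiseless MIDs are valid distributions", {
  cfg <- tiny_config(seed = 13L, noise_cv = 0)
  sim <- simulate_panel(cfg)
  sums <- sim$data |>
    dplyr::group_by(.data$sample_id, .data$species) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  expect_true(all(sums$total > 0))
  expect_true(all(sim$data$intensity >= 0))
  expect_true(all(sim$truth$labeling_extent_true >= 0 &
                    sim$truth$labeling_extent_true <= 1))
})

test_that("liver-coupled serum makes liver the most serum-similar tissue", {
  tissues <- c("liver", "lung", "cortex", "muscle")
  rt <- default_route_table()
  rt <- rt[rt$species == "FFA(16:0)", ]
  cfg <- simulation_config(
    seed = 21L, tissues = tissues, route_table = rt,
    timepoints = 24, replicates = c(`24` = 6L),
    acetyl = default_acetyl_table(tissues),
    g = default_g_table(tissues, rt$species),
    beta = default_beta_table(tissues, rt$species),
    intensity = default_intensity_table(tissues, rt$species))
  sim <- simulate_panel(cfg)
  res <- run_pipeline(pipeline_config(
    input = sim$data, n_perm = 19, seed = 1, route_table = rt,
    tissues = c(tissues, "serum")))
  sim16 <- res$similarity[res$similarity$species == "FFA(16:0)", ]
  expect_equal(sim16$tissue[which.max(sim16$median_similarity)], "liver")
  ds <- res$donor_screen
  expect_equal(ds$verdict[ds$tissue == "liver"], "donor-consistent")
  expect_equal(ds$verdict[ds$tissue == "cortex"], "not-donor-consistent")
})

test_that("aging scenario scales g per tissue and validates multipliers", {
  cfg <- tiny_config(seed = 3L)
  old <- aging_scenario(cfg, c(liver = 0.6), age_group = "old")
  expect_equal(old$age_g_multiplier[["liver"]], 0.6)
  expect_equal(old$age_g_multiplier[["lung"]], 1)
  expect_equal(old$age_group, "old")
  expect_error(aging_scenario(cfg, c(liver = 1.2)), "multipliers")
  expect_error(aging_scenario(cfg, c(skin = 0.5)), "unknown tissues")
  # the realized ground truth reflects the decline exactly
  young <- simulate_panel(cfg)
  aged <- simulate_panel(old)
  jt <- dplyr::inner_join(
    young$truth[young$truth$tissue != "serum",
                c("tissue", "species", "g_true")],
    aged$truth[aged$truth$tissue != "serum",
               c("tissue", "species", "g_true")],
    by = c("tissue", "species"), suffix = c("_young", "_old"))
  ratio <- jt$g_true_old / jt$g_true_young
  expect_equal(unname(ratio[jt$tissue == "liver"]), rep(0.6, 2))
  expect_equal(unname(ratio[jt$tissue == "lung"]), rep(1, 2))
})

test_that("config validation rejects inconsistent fraction sums", {
  tissues <- c("liver", "lung")
  rt <- default_route_table()[default_route_table()$species == "FFA(16:0)", ]
  g <- default_g_table(tissues, rt$species)
  g$g <- 0.8
  beta <- default_beta_table(tissues, rt$species)
  beta$beta <- 0.4
  expect_error(
    simulation_config(seed = 1L, tissues = tissues, route_table = rt,
                      timepoints = 24, replicates = c(`24` = 4L),
                      acetyl = default_acetyl_table(tissues), g = g,
                      beta = beta,
                      intensity = default_intensity_table(tissues, rt$species)),
    "exceeds 1")
  expect_error(simulation_config(seed = NULL), "seed")
})

test_that("the worked fixture is stable and matches its shipped copy", {
  wf <- worked_fixture()
  expect_equal(nrow(wf$data), 848)
  shipped <- system.file("extdata", "worked_fixture.csv", package = "ffatrace")
  expect_true(nzchar(shipped))
  disk <- readr::read_csv(shipped, show_col_types = FALSE)
  expect_equal(as.data.frame(wf$data), as.data.frame(disk), tolerance = 1e-12)
  truth_disk <- readr::read_csv(
    system.file("extdata", "worked_fixture_truth.csv", package = "ffatrace"),
    show_col_types = FALSE)
  expect_equal(as.data.frame(wf$truth), as.data.frame(truth_disk),
               tolerance = 1e-12)
})
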