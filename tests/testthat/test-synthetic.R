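test_that("the discovery specification transcribes the published table", {
  specs <- default_discovery_spec()
  expect_length(specs, 6L)
  expect_equal(sum(vapply(specs, `[[`, integer(1), "n")), 10023L)
  expect_equal(vapply(specs, `[[`, numeric(1), "male_fraction")[c("CL1", "CL2", "CL4")],
               c(CL1 = 1, CL2 = 0, CL4 = 1))
  cl6 <- specs$CL6
  expect_equal(cl6$htn, 1)
  expect_equal(cl6$fhdm, 1)
  expect_equal(cl6$prevalence, 121 / 277)
  expect_equal(cl6$n, 277L)
  expect_equal(specs$CL5$male_fraction, 1258 / 2645)
  expect_equal(specs$CL3$age_mean, 47.89)
})

test_that("generated cohorts are deterministic and match their spec", {
  cfg <- simulation_config(seed = 21)
  coh <- generate_cohort(cfg)
  expect_identical(coh, generate_cohort(cfg))
  expect_equal(nrow(coh), 10023L)
  comp <- split(coh, coh$true_cluster)
  for (s in cfg$specs) {
    sub <- comp[[s$name]]
    # prevalence within 3 binomial standard errors
    se <- sqrt(s$prevalence * (1 - s$prevalence) / s$n)
    expect_lt(abs(mean(sub$dm) - s$prevalence), 3 * se + 1e-12)
    # age mean within 3 SE of the truncated-normal expectation
    a <- (cfg$age_window[1] - s$age_mean) / s$age_sd
    b <- (cfg$age_window[2] - s$age_mean) / s$age_sd
    trunc_mean <- s$age_mean + s$age_sd *
      (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
    expect_lt(abs(mean(sub$age) - trunc_mean),
              3 * s$age_sd / sqrt(s$n))
    expect_true(all(sub$htn == s$htn))
    expect_true(all(sub$fhdm == s$fhdm))
    expect_equal(abs(mean(sub$sex == 0) - s$male_fraction) <
                   3 / sqrt(s$n) + 1e-12, TRUE)
  }
  # prior diagnoses only among baseline diabetics
  expect_true(all(coh$prior_dx[coh$dm == 0] == 0))
})

test_that("zero prevalence and zero hazard degenerate correctly", {
  spec0 <- cluster_spec("Z", 200, 0.5, 50, 5, 25, 3, 0, 0,
                        prevalence = 0, hazard = 0)
  cfg <- simulation_config(specs = list(Z = spec0), seed = 2,
                           censoring_rate = 0)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$dm == 0))
  fu <- generate_followup(coh, cfg)
  expect_true(all(fu$event == 0))
  expect_true(all(fu$followup_months == cfg$followup_months_max))
})

test_that("follow-up reproduces the exponential incidence law", {
  h <- 0.01
  spec <- cluster_spec("A", 4000, 0.5, 50, 5, 25, 3, 0, 0,
                       prevalence = 0, hazard = h)
  cfg <- simulation_config(specs = list(A = spec), seed = 5,
                           censoring_rate = 0,
                           followup_months_max = 120)
  fu <- generate_followup(generate_cohort(cfg), cfg)
  for (t in c(12, 24, 60)) {
    expected <- 1 - exp(-h * t)
    observed <- mean(fu$followup_months <= t & fu$event == 1)
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(observed - expected), 3 * se)
  }
  # doubling the hazard raises the event fraction at any common horizon
  spec2 <- cluster_spec("B", 4000, 0.5, 50, 5, 25, 3, 0, 0,
                        prevalence = 0, hazard = 2 * h)
  cfg2 <- simulation_config(specs = list(A = spec, B = spec2), seed = 5,
                            censoring_rate = 0)
  fu2 <- generate_followup(generate_cohort(cfg2), cfg2)
  for (t in c(12, 60, 120)) {
    frac <- tapply(fu2$event == 1 & fu2$followup_months <= t,
                   fu2$true_cluster, mean)
    expect_gt(frac[["B"]], frac[["A"]])
  }
  # monthly recording: integer months, events need positive follow-up
  expect_true(all(fu$followup_months == round(fu$followup_months)))
  expect_true(all(fu$followup_months >= 1))
  # hazards are mandatory
  cfg_nh <- simulation_config(
    specs = list(A = cluster_spec("A", 10, 0.5, 50, 5, 25, 3, 0, 0, 0.1)),
    seed = 1)
  expect_error(generate_followup(generate_cohort(cfg_nh), cfg_nh),
               "no hazard")
})

test_that("biomarker cell means are honoured exactly as sd tends to 0", {
  bm <- list(ndm = c(fg = 5, tchol = 190, tg = 130, hdl = 46),
             dm = c(fg = 7, tchol = 200, tg = 170, hdl = 43))
  sds0 <- list(ndm = c(fg = 0, tchol = 0, tg = 0, hdl = 0),
               dm = c(fg = 0, tchol = 0, tg = 0, hdl = 0))
  spec <- cluster_spec("A", 50, 0.5, 50, 5, 25, 3, 0, 0, 0.5,
                       biomarker_means = bm, biomarker_sds = sds0)
  cfg <- simulation_config(specs = list(A = spec), seed = 3)
  coh <- generate_biomarkers(generate_cohort(cfg), cfg)
  expect_true(all(coh$fg[coh$dm == 0] == 5))
  expect_true(all(coh$fg[coh$dm == 1] == 7))
  expect_true(all(coh$hdl[coh$dm == 1] == 43))
})

test_that("additive cells keep the interaction null-calibrated", {
  # cluster effect + status effect, no interaction: the interaction F
  # test should reject at about its nominal level
  make_cfg <- function(seed) {
    specs <- lapply(1:3, function(i) {
      shift <- c(0, 10, 25)[i]
      bm <- list(ndm = c(fg = 5, tchol = 180 + shift, tg = 130, hdl = 46),
                 dm = c(fg = 5, tchol = 195 + shift, tg = 130, hdl = 46))
      sds <- list(ndm = c(fg = 1, tchol = 30, tg = 50, hdl = 10),
                  dm = c(fg = 1, tchol = 30, tg = 50, hdl = 10))
      cluster_spec(paste0("C", i), 120, 0.5, 50, 5, 25, 3, 0, 0, 0.5,
                   biomarker_means = bm, biomarker_sds = sds)
    })
    names(specs) <- paste0("C", 1:3)
    simulation_config(specs = specs, seed = seed)
  }
  rejections <- vapply(1:200, function(s) {
    coh <- generate_biomarkers(generate_cohort(make_cfg(s)), make_cfg(s))
    res <- two_way_anova(coh$tchol, coh$true_cluster, coh$dm)
    res$p_value[res$effect == "interaction"] < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("a planted one-cell interaction is detected with high power", {
  # 1-SD bump in a single (cluster, status) cell, 200 per cell
  make_cfg <- function(seed) {
    specs <- lapply(1:2, function(i) {
      bump <- if (i == 2) 30 else 0   # +1 SD in cluster 2 diabetics
      bm <- list(ndm = c(fg = 5, tchol = 180, tg = 130, hdl = 46),
                 dm = c(fg = 5, tchol = 195 + bump, tg = 130, hdl = 46))
      sds <- list(ndm = c(fg = 1, tchol = 30, tg = 50, hdl = 10),
                  dm = c(fg = 1, tchol = 30, tg = 50, hdl = 10))
      cluster_spec(paste0("C", i), 400, 0.5, 50, 5, 25, 3, 0, 0, 0.5,
                   biomarker_means = bm, biomarker_sds = sds)
    })
    names(specs) <- paste0("C", 1:2)
    simulation_config(specs = specs, seed = seed)
  }
  hits <- vapply(1:30, function(s) {
    coh <- generate_biomarkers(generate_cohort(make_cfg(s)), make_cfg(s))
    res <- two_way_anova(coh$tchol, coh$true_cluster, coh$dm)
    res$p_value[res$effect == "interaction"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("simulation configurations round-trip through YAML", {
  cfg <- simulation_config(seed = 17, censoring_rate = 0.004,
                           flip_rate = 0.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$censoring_rate, cfg$censoring_rate)
  expect_equal(back$flip_rate, cfg$flip_rate)
  expect_equal(lapply(back$specs, `[[`, "prevalence"),
               lapply(cfg$specs, `[[`, "prevalence"))
  expect_equal(back$specs$CL3$biomarker_means$dm,
               cfg$specs$CL3$biomarker_means$dm)
  # identical cohorts from the reloaded configuration
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})

test_that("stratified subsampling preserves the cluster composition", {
  cfg <- simulation_config(seed = 9)
  coh <- generate_cohort(cfg)
  set.seed(31)
  sub <- stratified_subsample(coh, 3000)
  expect_lt(abs(nrow(sub) - 3000), 10)
  frac_full <- table(coh$true_cluster) / nrow(coh)
  frac_sub <- table(sub$true_cluster) / nrow(sub)
  expect_lt(max(abs(frac_full - frac_sub)), 0.01)
  # flip noise produces impure categorical flags when requested
  cfgf <- simulation_config(seed = 9, flip_rate = 0.05)
  cohf <- generate_cohort(cfgf)
  cl5 <- cohf[cohf$true_cluster == "CL5", ]
  expect_true(any(cl5$htn == 0))
})
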