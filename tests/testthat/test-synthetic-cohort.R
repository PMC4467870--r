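# Synthetic cohort generator: design, determinism, censoring, and recovery
# of the configured truth.

test_that("default design is the unbalanced 167-sample 5x3x4 factorial", {
  d <- default_design()
  expect_equal(sum(d$cell_counts$n), 167)
  expect_equal(nrow(d$cell_counts), 60)
  expect_true(all(d$cell_counts$n >= 2))
  expect_equal(sort(unique(d$cell_counts$n)), c(2L, 3L))
  expect_equal(sum(d$cell_counts$n == 3), 47)
})

test_that("default config carries the 25 survey parameters in order", {
  cfg <- default_config(seed = 1)
  ref <- reference_survey()
  expect_identical(names(cfg$parameters), ref$parameter)
  expect_true(all(vapply(cfg$parameters, function(p) p$residual_sd > 0,
                         logical(1))))
  # all offsets sum to zero
  for (p in cfg$parameters)
    for (e in p$effects) expect_lt(abs(sum(e)), 1e-8)
  # active terms are exactly the survey's significant terms
  map <- c(c = "cultivar", h = "harvest", p = "practice",
           `c:h` = "cultivar:harvest", `c:p` = "cultivar:practice",
           `p:h` = "practice:harvest", `c:p:h` = "cultivar:practice:harvest")
  for (i in seq_len(nrow(ref))) {
    active <- unname(map[names(map)[!is.na(unlist(ref[i, names(map)]))]])
    expect_setequal(names(cfg$parameters[[i]]$effects), active)
  }
})

test_that("p-coumaric harvest pattern matches the reported level means", {
  cfg <- default_config(seed = 7)
  big <- generate_cohort(
    structure(list(design = inflate_design(default_design(), 20),
                   parameters = cfg$parameters, seed = 7L),
              class = "generator_config"))
  m <- tapply(big[["p-Coumaric acid"]], big$harvest, mean)
  expect_equal(unname(m["October"]), 0.52, tolerance = 0.01)
  expect_equal(unname(m["December"]), 0.17, tolerance = 0.01)
  expect_equal(unname(m["February"]), 0.02, tolerance = 0.01)
  expect_identical(unname(m["April"]), 0)
  # non-detects only in April
  expect_true(all(big[["p-Coumaric acid"]][big$harvest != "April"] > 0))
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- default_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c3 <- generate_cohort(cfg, seed_override = 12)
  expect_false(isTRUE(all.equal(a$Fructose, c3$Fructose)))
  # conservation: designed rows, 3 factors + 25 parameters + id
  expect_equal(nrow(a), 167)
  expect_equal(ncol(a), 1 + 3 + 25)
})

test_that("per-parameter substreams are independent of the parameter list", {
  cfg <- default_config(seed = 5)
  full <- generate_cohort(cfg)
  cfg2 <- cfg
  cfg2$parameters <- cfg$parameters[c("Fructose", "Citric acid")]
  two <- generate_cohort(cfg2)
  expect_identical(full$Fructose, two$Fructose)
  expect_identical(full[["Citric acid"]], two[["Citric acid"]])
})

test_that("degenerate noise collapses to the grand mean", {
  cfg <- default_config(seed = 1)
  spec <- parameter_spec("Fructose", grand_mean = 1.28, residual_sd = 1e-9,
                         effects = list(), unit = "%")
  cfg$parameters <- list(Fructose = spec)
  out <- generate_cohort(cfg)
  expect_equal(out$Fructose, rep(1.28, 167), tolerance = 1e-6)
})

test_that("censor_nondetects follows its definition", {
  expect_equal(censor_nondetects(c(0.005, 0.03), 0.01), c(0, 0.03))
  x <- c(-1, 0, 0.2, 5)
  expect_identical(censor_nondetects(x, 0), x)
  expect_error(censor_nondetects(x, -1), "detection_limit")
  # April draws under the default config are all censored to exactly 0
  coh <- default_cohort_fixture()
  expect_true(all(coh[["p-Coumaric acid"]][coh$harvest == "April"] == 0))
})

test_that("large-sample cell means recover the configured (censored) truth", {
  cfg <- default_config(seed = 3)
  cfg$design <- inflate_design(cfg$design, 60)  # ~10,000 samples
  big <- generate_cohort(cfg)
  cell <- interaction(big$cultivar, big$practice, big$harvest, drop = FALSE)
  z_all <- c()
  for (pname in names(cfg$parameters)) {
    truth <- configured_cell_means(cfg, pname)
    key <- interaction(factor(truth$cultivar, levels = levels(big$cultivar)),
                       factor(truth$practice, levels = levels(big$practice)),
                       factor(truth$harvest, levels = levels(big$harvest)))
    emp <- tapply(big[[pname]], cell, mean)[as.character(key)]
    se <- (tapply(big[[pname]], cell, sd) /
             sqrt(tapply(big[[pname]], cell, length)))[as.character(key)]
    dev <- abs(emp - truth$mu_obs)
    z <- ifelse(se > 0, dev / se, ifelse(dev < 1e-8, 0, Inf))
    z_all <- c(z_all, z)
  }
  expect_gte(mean(z_all <= 3), 0.99)   # 3-SE criterion, nominal 99.7 %
  expect_true(all(z_all <= 5))
})

test_that("explained variance of a clean harvest-only parameter matches the survey", {
  # lycopene: single active term, negligible clipping, so the realized
  # R^2 should sit at the survey's 53.9 % figure
  cfg <- default_config(seed = 9)
  cfg$design <- inflate_design(cfg$design, 60)
  big <- generate_cohort(cfg)
  r <- suppressWarnings(
    fit_factorial_glm(big$Lycopene, big[c("cultivar", "practice", "harvest")],
                      parameter = "Lycopene"))
  expect_equal(r$explained_variance_pct, 53.9, tolerance = 2 / 53.9)
})

test_that("fitting the factorial GLM to a large cohort recovers the planted structure", {
  cfg <- default_config(seed = 2)
  cfg$design <- inflate_design(cfg$design, 24)  # ~4,000 samples
  big <- generate_cohort(cfg)
  ref <- reference_survey()
  map <- term_labels <- c(c = "cultivar", h = "harvest", p = "practice",
                          `c:h` = "cultivar:harvest", `c:p` = "cultivar:practice",
                          `p:h` = "practice:harvest",
                          `c:p:h` = "cultivar:practice:harvest")
  miss_active <- 0L; n_active <- 0L
  fp_inactive <- 0L; n_inactive <- 0L
  for (i in seq_len(nrow(ref))) {
    pname <- ref$parameter[i]
    r <- suppressWarnings(
      fit_factorial_glm(big[[pname]], big[c("cultivar", "practice", "harvest")],
                        parameter = pname))
    active <- unname(map[names(map)[!is.na(unlist(ref[i, names(map)]))]])
    inactive <- setdiff(names(r$p_values), active)
    n_active <- n_active + length(active)
    n_inactive <- n_inactive + length(inactive)
    miss_active <- miss_active + sum(r$p_values[active] >= 0.01)
    fp_inactive <- fp_inactive + sum(r$p_values[inactive] < 0.05)
  }
  expect_equal(n_active, 79L)
  expect_equal(miss_active, 0L)
  # truly-null terms have uniform p-values; allow up to the 99.9 % binomial
  # bound of the nominal 5 % false-positive rate
  expect_lte(fp_inactive, qbinom(0.999, n_inactive, 0.05))
})

test_that("cohort CSV and config JSON round-trip", {
  coh <- default_cohort_fixture()
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$Fructose, coh$Fructose)
  expect_identical(as.character(back$harvest), as.character(coh$harvest))

  cfg <- default_config(seed = 4)
  j <- tempfile(fileext = ".json")
  config_to_json(cfg, j)
  cfg2 <- config_from_json(j)
  # JSON carries full double precision up to one ulp
  a <- generate_cohort(cfg); b <- generate_cohort(cfg2)
  for (p in parameter_names(a))
    expect_equal(b[[p]], a[[p]], tolerance = 1e-12)
  expect_identical(as.character(b$cultivar), as.character(a$cultivar))
})

test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(parameter_spec("x", 1, residual_sd = 0), "residual_sd")
  expect_error(parameter_spec("x", 1, 1, effects = list(harvest = c(a = 1, b = 1))),
               "sum to zero")
  cc <- default_design()$cell_counts
  cc$n[1] <- -1L
  expect_error(factor_design(cc), "negative")
  lv <- factor_levels(); lv$practice <- c("organic", "organic", "no-soil")
  expect_error(factor_design(default_design()$cell_counts, lv), "duplicated")
})
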