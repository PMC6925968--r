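# the three standard-error methods and their supporting operations

test_that("linearization scores match hand computation and sum to zero", {
  spec <- toy_spec_1stage()
  tab <- data.frame(facility_id = c("A", "B"), stratum = "s1", region = "r",
                    weight = c(1, 1), ind_y = c(0, 1))
  u <- linearize_mean(tab, spec, "ind_y")
  expect_equal(u, c(-0.25, 0.25))

  tab$ind_y <- c(1, 1)
  expect_equal(linearize_mean(tab, spec, "ind_y"), c(0, 0))

  cl <- toy_clients()
  u2 <- linearize_mean(cl, toy_spec_3stage(), "ind_b")
  expect_equal(sum(u2, na.rm = TRUE), 0)
  expect_true(is.na(u2[3]))  # missing indicator -> missing score
})

test_that("svy1 reproduces the two-observation hand example (V = 0.25)", {
  spec <- toy_spec_1stage()
  tab <- data.frame(facility_id = c("A", "B"), stratum = "s1", region = "r",
                    weight = c(1, 1), ind_y = c(0, 1))
  v <- svy1_variance(tab, spec, "ind_y")
  expect_equal(v$se^2, 0.25)       # equals s^2/n for two observations
  expect_equal(v$estimate, 0.5)
  expect_equal(v$df, 1)
})

test_that("svy1 is zero without between-PSU variation and scale-free", {
  spec <- toy_spec_3stage()
  cl <- toy_clients()
  cl$ind_c <- 1  # constant indicator
  expect_equal(svy1_variance(cl, spec, "ind_c")$se, 0)

  v1 <- svy1_variance(cl, spec, "ind_a")
  cl2 <- cl; cl2$weight <- cl2$weight * 7.3
  v2 <- svy1_variance(cl2, spec, "ind_a")
  expect_equal(v1$se, v2$se)
  expect_equal(v1$estimate, v2$estimate)
})

test_that("svy3 of a census is exactly zero", {
  spec <- design_spec(stages = list(stage_spec("facility_id", "fpc_n")),
                      strata_cols = "stratum", domain_col = "region",
                      weight_col = "weight")
  tab <- data.frame(facility_id = paste0("F", 1:4), stratum = "s1",
                    region = "r", weight = 1, fpc_n = 4,
                    ind_y = c(0, 1, 1, 0))
  expect_equal(svy3_variance(tab, spec, "ind_y")$se, 0)
})

test_that("svy3 with infinite fpc reproduces svy1 exactly", {
  spec <- spa_design_spec()
  pop <- generate_facility_population(small_spa_config())
  smp <- draw_spa_sample(pop, seed = 44)
  cl <- smp$clients
  cl$fpc_facility <- Inf
  cl$fpc_provider <- Inf
  cl$fpc_client <- Inf
  v3 <- svy3_variance(cl, spec, smp$indicators)
  v1 <- svy1_variance(cl, spec, smp$indicators)
  expect_equal(v3$se, v1$se, tolerance = 1e-12)
})

test_that("fully enumerated inner stages reduce svy3 to the first stage", {
  # stage 2 and 3 are censuses: inner terms vanish, leaving the fpc'd
  # between-PSU formula
  spec <- spa_design_spec()
  n_prov <- c(2, 3, 2, 1)
  fac <- rep(paste0("F", 1:4), n_prov)
  prov <- paste0(fac, "_P", unlist(lapply(n_prov, seq_len)))
  tab <- data.frame(
    facility_id = rep(fac, each = 2),
    provider_id = rep(prov, each = 2),
    client_id = paste0("c", seq_len(2 * length(prov))),
    region = "r", facility_type = "t", weight = 2.5,
    fpc_facility = 10,
    fpc_provider = rep(rep(n_prov, n_prov), each = 2),  # all providers kept
    fpc_client = 2,                                     # both clients kept
    stringsAsFactors = FALSE)
  set.seed(5)
  tab$ind_y <- rbinom(nrow(tab), 1, 0.5)
  v3 <- svy3_variance(tab, spec, "ind_y")

  # single-stage equivalent with fpc at the facility level only
  spec1 <- design_spec(stages = list(stage_spec("facility_id",
                                                "fpc_facility")),
                       strata_cols = c("region", "facility_type"),
                       domain_col = "region", weight_col = "weight")
  v1f <- svy3_variance(tab, spec1, "ind_y")
  expect_equal(v3$se, v1f$se, tolerance = 1e-12)
})

test_that("svy3 matches the textbook stratified (1-f)s^2/n formula", {
  # single-stage stratified SRS without clustering
  spec <- design_spec(stages = list(stage_spec("unit_id", "fpc_n")),
                      strata_cols = "stratum", domain_col = "region",
                      weight_col = "weight")
  set.seed(17)
  tab <- data.frame(
    unit_id = paste0("u", 1:12),
    stratum = rep(c("s1", "s2"), each = 6),
    region = "r",
    weight = rep(c(20 / 6, 14 / 6), each = 6),  # N_h / n_h
    fpc_n = rep(c(20, 14), each = 6),
    ind_y = rbinom(12, 1, 0.5))
  v <- svy3_variance(tab, spec, "ind_y")

  Wtot <- sum(tab$weight)
  vh <- vapply(c("s1", "s2"), function(s) {
    y <- tab$ind_y[tab$stratum == s]
    N <- tab$fpc_n[tab$stratum == s][1]
    n <- length(y)
    # variance of the stratum total, propagated to the Hajek mean
    (N^2 * (1 - n / N) * stats::var(y) / n) / Wtot^2
  }, numeric(1))
  expect_equal(v$se^2, sum(vh), tolerance = 1e-12)
})

test_that("svy3 variance estimator is design-unbiased on a two-stage toy", {
  # 2 strata x N=4 PSUs, n=2 sampled; M=3 SSUs per PSU, m=2 sampled.
  # Equal weights, fixed finite population: the empirical variance of the
  # Hajek mean over repeated draws must match the average estimated
  # variance within Monte-Carlo error.
  set.seed(23)
  popy <- array(rbinom(24, 1, 0.5), dim = c(3, 4, 2))  # ssu x psu x stratum
  draw_once <- function() {
    rows <- list()
    for (h in 1:2) {
      psus <- sample.int(4, 2)
      for (j in psus) {
        ssus <- sample.int(3, 2)
        rows[[length(rows) + 1L]] <- data.frame(
          psu_id = paste0("h", h, "p", j),
          ssu_id = paste0("h", h, "p", j, "s", ssus),
          stratum = paste0("h", h), region = "r",
          weight = (4 / 2) * (3 / 2),
          fpc_psu = 4, fpc_ssu = 3,
          ind_y = popy[ssus, j, h])
      }
    }
    do.call(rbind, rows)
  }
  spec <- design_spec(stages = list(stage_spec("psu_id", "fpc_psu"),
                                    stage_spec("ssu_id", "fpc_ssu")),
                      strata_cols = "stratum", domain_col = "region",
                      weight_col = "weight")
  S <- 3000
  est <- vhat <- numeric(S)
  for (s in seq_len(S)) {
    tab <- draw_once()
    v <- svy3_variance(tab, spec, "ind_y")
    est[s] <- v$estimate
    vhat[s] <- v$se^2
  }
  v_emp <- stats::var(est)
  se_vemp <- v_emp * sqrt(2 / (S - 1))
  se_mvhat <- stats::sd(vhat) / sqrt(S)
  expect_lt(abs(v_emp - mean(vhat)),
            3 * sqrt(se_vemp^2 + se_mvhat^2))
})

test_that("bootstrap is degenerate for a constant indicator", {
  spec <- toy_spec_3stage()
  cl <- toy_clients()
  cl$ind_c <- 1
  fac <- toy_facilities()
  b <- cluster_bootstrap(fac, cl, spec, "ind_c", B = 50, seed = 2)
  expect_equal(b$se, 0)
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$estimate, 1)
})

test_that("bootstrap SE agrees with svy1 on a large single-stage sample", {
  # many PSUs per stratum, so the (n-1)/n resampling deflation is small
  cfg <- facility_population_config(
    n_regions = 2,
    facility_types = c("dispensary", "clinic"),
    facilities_per_stratum = c(dispensary = 400, clinic = 300),
    sample_per_stratum = c(dispensary = 80, clinic = 60),
    providers_per_facility = list(dispensary = c(1, 3), clinic = c(1, 3)),
    indicator_model = list(ind_x = list(
      level = "client", intercept = 0,
      type_effects = c(dispensary = 0.4, clinic = -0.4),
      region_sd = 0.2, facility_sd = 0.5)),
    seed = 61)
  pop <- generate_facility_population(cfg)
  smp <- draw_spa_sample(pop, seed = 62)
  v1 <- svy1_variance(smp$clients, spa_design_spec(), "ind_x")
  b <- cluster_bootstrap(smp$facilities, smp$clients, spa_design_spec(),
                         "ind_x", B = 400, seed = 63)
  expect_lt(abs(b$se - v1$se) / v1$se, 0.15)
})

test_that("confidence intervals clip, degenerate and widen as documented", {
  expect_equal(confidence_interval(0.4, 0, df = 10), c(0.4, 0.4))
  ci <- confidence_interval(0.5, 0.1, df = Inf)
  expect_equal(ci, c(0.304, 0.696), tolerance = 1e-3)
  expect_equal(confidence_interval(0.99, 0.1, df = Inf)[2], 1)
  expect_equal(confidence_interval(0, 0.1, df = 5)[1], 0)
  # unbounded quantities are not clipped
  expect_lt(confidence_interval(-2, 1, df = 20, clip = NULL)[1], -2)
})
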