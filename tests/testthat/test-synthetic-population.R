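# finite-population generators and design-consistent sample draws

test_that("facility universe has the configured structure and is seeded", {
  cfg <- facility_population_config(
    n_regions = 2, facility_types = c("hospital", "dispensary"),
    facilities_per_stratum = c(hospital = 3, dispensary = 3),
    sample_per_stratum = c(hospital = 3, dispensary = 2),
    providers_per_facility = list(hospital = c(2, 4), dispensary = c(1, 2)),
    seed = 9)
  pop <- generate_facility_population(cfg)
  expect_equal(nrow(pop$facilities), 2 * 2 * 3)
  expect_true(all(table(pop$facilities$stratum) == 3))
  expect_true(all(pop$clients$client_id != ""))
  # truth is the plain mean over all population clients
  nat <- pop$truth[pop$truth$domain == "national", ]
  expect_equal(nat$truth[nat$indicator == "ind_wait_ok"],
               mean(pop$clients$ind_wait_ok))

  pop2 <- generate_facility_population(cfg)
  expect_identical(pop$clients, pop2$clients)
})

test_that("with zero effects the population rate matches the intercept", {
  flat <- list(ind_flat = list(
    level = "client", intercept = stats::qlogis(0.3),
    type_effects = c(hospital = 0, health_center = 0, dispensary = 0,
                     clinic = 0),
    region_sd = 0, facility_sd = 0))
  rates <- vapply(1:8, function(s) {
    cfg <- facility_population_config(n_regions = 2, indicator_model = flat,
                                      seed = s)
    pop <- generate_facility_population(cfg)
    pop$truth$truth[pop$truth$domain == "national"]
  }, numeric(1))
  n_cl <- 2500  # approximate clients per universe at this scale
  expect_lt(abs(mean(rates) - 0.3), 3 * sqrt(0.3 * 0.7 / (8 * n_cl)))
})

test_that("systematic PPS follows the cumulative-total method", {
  # sizes 1,2,3,4; n = 2 -> interval 5; start 2.0 selects units 2 and 4
  expect_identical(systematic_pps_sample(c(1, 2, 3, 4), 2, u = 2.0),
                   c(2L, 4L))
  # census returns everything for any start
  expect_identical(systematic_pps_sample(c(5, 1, 2), 3), 1:3)
  expect_error(systematic_pps_sample(c(10, 1, 1), 2), "certainty")
})

test_that("systematic PPS inclusion frequencies match n*size/total", {
  sizes <- c(1, 2, 3, 4)
  n_draw <- 20000
  set.seed(31)
  counts <- integer(4)
  for (i in seq_len(n_draw)) {
    sel <- systematic_pps_sample(sizes, 2)
    counts[sel] <- counts[sel] + 1L
  }
  p_hat <- counts / n_draw
  p_true <- 2 * sizes / sum(sizes)
  tol <- 3 * sqrt(p_true * (1 - p_true) / n_draw)
  expect_true(all(abs(p_hat - p_true) <= tol))
})

test_that("facility sample weights are exact inverse inclusion probabilities", {
  pop <- generate_facility_population(small_spa_config())
  smp <- draw_spa_sample(pop, seed = 5)
  fac <- smp$facilities

  # certainty stratum (hospitals): all units, weight exactly 1
  hosp <- fac[fac$facility_type == "hospital", ]
  expect_equal(nrow(hosp), 2L)
  expect_true(all(hosp$weight == 1))

  # Horvitz-Thompson identity: facility weights sum to N_h exactly per stratum
  for (s in unique(fac$stratum)) {
    expect_equal(sum(fac$weight[fac$stratum == s]),
                 fac$fpc_facility[fac$stratum == s][1])
  }

  # every facility here has at most 8 providers, so all providers are kept
  # (the "fewer than eight: take all" rule) and the client weight reduces to
  # facility weight x roster / observed
  cl <- smp$clients
  expect_true(all(table(pop$providers$facility_id) <=
                    pop$config$provider_sample_threshold))
  fac_w <- fac$weight[match(cl$facility_id, fac$facility_id)]
  observed <- ave(cl$weight, cl$provider_id, FUN = length)
  expect_true(all(abs(cl$weight - fac_w * cl$fpc_client / observed) < 1e-9))
})

test_that("client observation caps are respected", {
  pop <- generate_facility_population(
    facility_population_config(n_regions = 2, clients_per_provider_mean = 8,
                               seed = 12))
  smp <- draw_spa_sample(pop, seed = 13)
  per_prov <- table(smp$clients$provider_id)
  per_fac <- table(smp$clients$facility_id)
  expect_true(all(per_prov <= pop$config$max_clients_per_provider))
  expect_true(all(per_fac <= pop$config$max_clients_per_facility))
})

test_that("same seed gives byte-identical sample CSVs", {
  pop <- generate_facility_population(small_spa_config())
  s1 <- draw_spa_sample(pop, seed = 99)
  s2 <- draw_spa_sample(pop, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(s1$clients, f1)
  write_survey_csv(s2$clients, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("household sample: census EA takes all households at weight 1", {
  cfg <- household_population_config(
    n_regions = 1, eas_per_region = 1, ea_size_range = c(4, 4),
    n_eas_sampled_per_region = 1, households_per_ea_sampled = 10,
    women_per_household_mean = 1, eligibility_rate = 1, seed = 3)
  pop <- generate_household_population(cfg)
  smp <- draw_dhs_sample(pop, seed = 4)
  expect_true(all(smp$women$weight == 1))
  # every household with at least one eligible woman is represented
  expect_equal(sort(unique(smp$women$hh_id)),
               sort(unique(pop$women$hh_id)))
})

test_that("household draws are deterministic under a fixed seed", {
  pop <- generate_household_population(small_dhs_config())
  s1 <- draw_dhs_sample(pop, seed = 21)
  s2 <- draw_dhs_sample(pop, seed = 21)
  expect_identical(s1$women, s2$women)
})

test_that("weighted totals are unbiased for the population total (HT)", {
  # facility design: 400 draws here; the acceptance suite runs 2000
  pop <- generate_facility_population(small_spa_config())
  truth_tot <- sum(pop$clients$ind_wait_ok)
  tot <- vapply(1:400, function(i) {
    smp <- draw_spa_sample(pop, seed = 1000 + i)
    sum(smp$clients$weight * smp$clients$ind_wait_ok)
  }, numeric(1))
  mc_se <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - truth_tot), 3 * mc_se)
})
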