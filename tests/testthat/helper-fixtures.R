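# small in-code fixtures shared by the test files

# one-stage design: facility = ultimate unit
toy_spec_1stage <- function() {
  design_spec(stages = list(stage_spec("facility_id")),
              strata_cols = "stratum", domain_col = "region",
              weight_col = "weight")
}

# three-stage facility -> provider -> client spec without fpc columns
toy_spec_3stage <- function(fpc = FALSE) {
  if (fpc) return(spa_design_spec())
  design_spec(
    stages = list(stage_spec("facility_id"), stage_spec("provider_id"),
                  stage_spec("client_id")),
    strata_cols = c("region", "facility_type"),
    domain_col = "region", weight_col = "weight")
}

# minimal client table: one row per client, fully nested ids
toy_clients <- function() {
  data.frame(
    facility_id = c("F1", "F1", "F1", "F2", "F2", "F3"),
    provider_id = c("F1P1", "F1P1", "F1P2", "F2P1", "F2P1", "F3P1"),
    client_id = paste0("c", 1:6),
    region = c("R1", "R1", "R1", "R1", "R1", "R2"),
    facility_type = c("hosp", "hosp", "hosp", "disp", "disp", "disp"),
    weight = c(1, 1, 2, 4, 4, 3),
    ind_a = c(1, 0, 1, 0, 1, 1),
    ind_b = c(0, 0, NA, 1, 0, 1),
    stringsAsFactors = FALSE)
}

toy_facilities <- function() {
  data.frame(
    facility_id = c("F1", "F2", "F3"),
    region = c("R1", "R1", "R2"),
    facility_type = c("hosp", "disp", "disp"),
    weight = c(1, 4, 3),
    stringsAsFactors = FALSE)
}

# small facility universe used by the Monte-Carlo oracles
small_spa_config <- function(seed = 7L) {
  facility_population_config(
    n_regions = 1,
    facilities_per_stratum = c(hospital = 2, health_center = 4,
                               dispensary = 6, clinic = 3),
    sample_per_stratum = c(hospital = 2, health_center = 2,
                           dispensary = 3, clinic = 1),
    clients_per_provider_mean = 3,
    seed = seed)
}

small_dhs_config <- function(seed = 7L) {
  household_population_config(
    n_regions = 1, eas_per_region = 8, ea_size_range = c(20, 40),
    n_eas_sampled_per_region = 3, households_per_ea_sampled = 5,
    women_per_household_mean = 1, eligibility_rate = 0.6, seed = seed)
}
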