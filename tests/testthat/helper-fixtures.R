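# shared fixtures: the packaged base case, a cached full-model run, the
# published outcome totals, and small toy inputs used by hand-trace oracles

base_params <- crc_parameters()

.model_cache <- new.env(parent = emptyenv())
cached_base_model <- function() {
  if (is.null(.model_cache$m))
    .model_cache$m <- run_model(base_params)
  .model_cache$m
}

# published per-strategy totals (outcome table of the comparative study)
published_totals <- tibble::tibble(
  strategy = c("none", "fit", "m3crc", "colonoscopy"),
  total_cost = c(225515010, 262159983, 606234678, 690947627),
  total_cases = c(3233, 3087, 1611, 1575),
  life_years_lost = c(5635, 5297, 2783, 2719))

# zero-hazard life table: nobody dies before the closure age
flat_life_table <- function(max_age = 100)
  make_life_table(0, 0, anchor_age = 50, max_age = max_age)

# minimal two-cycle world: one incidence band at 1000/100k, no background
# mortality, for hand-traced engine checks
toy_params <- function(overrides = list()) {
  crc_parameters(
    overrides = utils::modifyList(list(
      economics = list(start_age = 50, end_age = 51, discount_rate = 0),
      incidence = list(age_from = 50, age_to = 51, rate = 1000)),
      overrides),
    life_table = flat_life_table())
}
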