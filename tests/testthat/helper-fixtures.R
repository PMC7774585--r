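# Frozen published scoring table: group -> level -> weight. Used to assert
# registry fidelity cell by cell.
published_weights <- list(
  "Childhood trauma" = c(Yes = 4, No = -0.5),
  "Ethnicity" = c(
    "White" = -2,
    "Black Caribbean, low ethnic density" = 6,
    "Black Caribbean, medium ethnic density" = 5.5,
    "Black Caribbean, high ethnic density" = 3.5,
    "Other, low ethnic density" = 3.5,
    "Other, medium ethnic density" = 3,
    "Other, high ethnic density" = 1
  ),
  "Immigration" = c(
    "Not immigrant" = -0.5,
    "1st generation, North Africa" = 3,
    "1st generation, other region" = 2,
    "2nd generation, North Africa" = 2.5,
    "2nd generation, other region" = 1.5
  ),
  "Non-right-handedness" = c(Yes = 2, No = 0),
  "Pollution" = c(Yes = 2, No = -5.5),
  "Urbanicity" = c(Yes = 1, No = -2.5),
  "Winter or spring birth in northern hemisphere" = c(Yes = 0, No = 0),
  "Paternal age" = c("<35" = -0.5, "35-45" = 0.5, ">45" = 3.5),
  "Low paternal socioeconomic status" = c(Yes = 1, No = 0),
  "Parental severe mental illness" = c(Yes = 5.5, No = -2),
  "Adult life events" = c(Yes = 5.5, No = -2),
  "Daily smoker" = c(Yes = 3, No = -0.5),
  "Heavy cannabis use" = c(Yes = 7, No = 0),
  "Hearing problems in past 12 months" = c(Yes = 2, No = 0),
  "Trait anhedonia" = c(Yes = 6.5, No = 0),
  "Male & 25-35 years old" = c(Yes = 2, No = 0)
)

# A complete all-reference raw record (maximally protective); override fields
# to build test respondents.
make_raw <- function(...) {
  base <- list(
    respondent_id = "T001", age = 40, sex = "female",
    ethnicity = "white", ethnic_density = NA,
    immigration = "none", origin = "not_applicable",
    paternal_age = 30,
    childhood_trauma = FALSE, non_right_handedness = FALSE,
    pollution = FALSE, urbanicity = FALSE, winter_spring_birth = FALSE,
    low_paternal_ses = FALSE, parental_smi = FALSE,
    adult_life_events = FALSE, daily_smoker = FALSE,
    heavy_cannabis = FALSE, hearing_problems = FALSE,
    trait_anhedonia = FALSE
  )
  utils::modifyList(base, list(...), keep.null = TRUE)
}

raw_list_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    as.data.frame(r[ppscore::response_columns()], stringsAsFactors = FALSE)
  }))
}

# Independent oracle for achievable totals: iterated unique pairwise sums
# over one level per group (covers all < 1e6 combinations without
# materialising them).
enumerate_totals <- function(registry = ppscore::default_registry()) {
  sums <- 0
  for (g in ppscore::registry_weights(registry)) {
    sums <- unique(as.vector(outer(sums, unname(g), "+")))
  }
  sort(sums)
}

# Serialise a registry to a structured override file (JSON or YAML).
registry_to_file <- function(registry, path) {
  obj <- list(
    factor_count = registry$factor_count,
    groups = lapply(unname(registry$groups), function(g) {
      list(name = g$name,
           evidence_class = g$evidence_class,
           reference_level = g$reference_level,
           components = as.list(g$components),
           levels = as.list(stats::setNames(g$levels$weight, g$levels$label)))
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  path
}

# Sample symmetric about 0 (skewness exactly 0) whose kurtosis is tuned to
# the adjusted Jarque-Bera null expectation 3(n-1)/(n+1), so both terms of
# the statistic vanish.
zero_ajb_sample <- function(n = 20) {
  stopifnot(n %% 2 == 0, n >= 8)
  target <- 3 * (n - 1) / (n + 1)
  build <- function(a) c(rep(c(-1, 1), (n - 2) / 2), -a, a)
  kurt <- function(a) {
    d <- build(a) # mean is exactly 0 by symmetry
    mean(d^4) / mean(d^2)^2
  }
  a <- stats::uniroot(function(a) kurt(a) - target, c(1.001, 50),
                      tol = 1e-12)$root
  build(a)
}
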