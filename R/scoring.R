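#' Relative risk implied by a total PPS score
#'
#' Scores live on a `10*log10` odds scale, so a total of `s` points maps to a
#' relative risk of `10^(s/10)`: 0 points is the population baseline (RR = 1),
#' +10 points a tenfold risk, -10 points a tenth. The transformation is
#' strictly increasing and log-linear: `rr_from_score(a + b)` equals
#' `rr_from_score(a) * rr_from_score(b)`.
#'
#' @param score Numeric vector of PPS points (any real value accepted).
#' @return Positive numeric vector of relative risks, full precision (round
#'   for display; published values are shown to 2 decimals).
#' @examples
#' rr_from_score(9)     # 7.94...
#' rr_from_score(0)     # 1
#' rr_from_score(39.5)  # 8912.51...
#' @export
rr_from_score <- function(score) {
  stopifnot(is.numeric(score))
  10^(score / 10)
}

# group name -> response column for the simple yes/no items
boolean_item_map <- c(
  "Childhood trauma" = "childhood_trauma",
  "Non-right-handedness" = "non_right_handedness",
  "Pollution" = "pollution",
  "Urbanicity" = "urbanicity",
  "Winter or spring birth in northern hemisphere" = "winter_spring_birth",
  "Low paternal socioeconomic status" = "low_paternal_ses",
  "Parental severe mental illness" = "parental_smi",
  "Adult life events" = "adult_life_events",
  "Daily smoker" = "daily_smoker",
  "Heavy cannabis use" = "heavy_cannabis",
  "Hearing problems in past 12 months" = "hearing_problems",
  "Trait anhedonia" = "trait_anhedonia"
)

#' Column dictionary for raw questionnaire responses
#'
#' @return Character vector of the expected response CSV columns.
#' @export
response_columns <- function() {
  c("respondent_id", "age", "sex", "ethnicity", "ethnic_density",
    "immigration", "origin", "paternal_age", unname(boolean_item_map))
}

missing_item <- function(item, policy, group, registry) {
  if (policy == "reference") {
    list(level = registry$groups[[group]]$reference_level,
         warning = sprintf("item '%s' missing; imputed reference level of '%s'",
                           item, group))
  } else {
    stop(sprintf("missing required item '%s' (group '%s')", item, group),
         call. = FALSE)
  }
}

#' Resolve raw responses into an exposure profile
#'
#' Maps one respondent's questionnaire answers onto exactly one level per
#' registry group, applying the instrument's dependency logic: the immigration
#' item is the combination of generation and region of origin; the ethnicity
#' item combines ethnicity with local ethnic density (density is ignored for
#' White respondents, who carry a single weight); paternal age is binned as
#' `<35`, `35-45`, `>45` (boundary ages 35 and 45 fall in the middle bin); and
#' "Male & 25-35 years old" is Yes exactly when sex is male and age is in
#' \[25, 35\]. Implausible cross-item combinations (e.g. a non-immigrant with a
#' region of origin) produce warning records, not errors.
#'
#' @param raw A one-row data.frame or named list of responses; see
#'   [response_columns()]. Booleans are logical (readers map yes/no).
#' @param registry A `pps_registry`; defaults to [default_registry()].
#' @param policy Missing-data policy: `"strict"` (default) raises an error
#'   naming the missing item; `"reference"` imputes the group's reference
#'   level and records a warning.
#' @param min_age Inclusion floor in years (default 14); younger respondents
#'   are flagged with a warning record.
#' @return A `pps_profile`: list with `respondent_id`, `selections` (named
#'   character, one level label per group) and `warnings`.
#' @export
resolve_profile <- function(raw, registry = default_registry(),
                            policy = c("strict", "reference"), min_age = 14) {
  policy <- match.arg(policy)
  raw <- as.list(raw)
  get <- function(col) {
    v <- raw[[col]]
    if (is.null(v) || length(v) != 1 || is.na(v)) NULL else v
  }
  sel <- character()
  warnings <- character()

  age <- get("age")
  sex <- get("sex")
  if (!is.null(age) && age < min_age) {
    warnings <- c(warnings, sprintf("age %s below inclusion floor %s", age, min_age))
  }

  for (group in names(boolean_item_map)) {
    item <- boolean_item_map[[group]]
    v <- get(item)
    if (is.null(v)) {
      m <- missing_item(item, policy, group, registry)
      sel[group] <- m$level
      warnings <- c(warnings, m$warning)
    } else {
      if (!is.logical(v)) stop("item '", item, "' must be logical", call. = FALSE)
      sel[group] <- if (v) "Yes" else "No"
    }
  }

  # ethnicity x ethnic density
  eth <- get("ethnicity")
  if (is.null(eth)) {
    m <- missing_item("ethnicity", policy, "Ethnicity", registry)
    sel["Ethnicity"] <- m$level
    warnings <- c(warnings, m$warning)
  } else if (eth == "white") {
    sel["Ethnicity"] <- "White"
  } else if (eth %in% c("black_caribbean", "other")) {
    den <- get("ethnic_density")
    if (is.null(den) || identical(den, "not_applicable")) {
      m <- missing_item("ethnic_density", policy, "Ethnicity", registry)
      sel["Ethnicity"] <- m$level
      warnings <- c(warnings, m$warning)
    } else if (!den %in% c("low", "medium", "high")) {
      stop("unknown ethnic_density label '", den, "'", call. = FALSE)
    } else {
      who <- if (eth == "black_caribbean") "Black Caribbean" else "Other"
      sel["Ethnicity"] <- sprintf("%s, %s ethnic density", who, den)
    }
  } else {
    stop("unknown ethnicity label '", eth, "'", call. = FALSE)
  }

  # immigration generation x origin
  imm <- get("immigration")
  org <- get("origin")
  if (is.null(imm)) {
    m <- missing_item("immigration", policy, "Immigration", registry)
    sel["Immigration"] <- m$level
    warnings <- c(warnings, m$warning)
  } else if (imm == "none") {
    sel["Immigration"] <- "Not immigrant"
    if (!is.null(org) && !identical(org, "not_applicable")) {
      warnings <- c(warnings,
                    "origin given for a non-immigrant; ignored")
    }
  } else if (imm %in% c("first_generation", "second_generation")) {
    if (is.null(org) || identical(org, "not_applicable")) {
      m <- missing_item("origin", policy, "Immigration", registry)
      sel["Immigration"] <- m$level
      warnings <- c(warnings, m$warning)
    } else if (!org %in% c("north_africa", "other")) {
      stop("unknown origin label '", org, "'", call. = FALSE)
    } else {
      gen <- if (imm == "first_generation") "1st" else "2nd"
      reg_lab <- if (org == "north_africa") "North Africa" else "other region"
      sel["Immigration"] <- sprintf("%s generation, %s", gen, reg_lab)
      if (org == "north_africa" && identical(eth, "black_caribbean")) {
        warnings <- c(warnings,
                      "implausible combination: Black Caribbean ethnicity with North African origin")
      }
    }
  } else {
    stop("unknown immigration label '", imm, "'", call. = FALSE)
  }

  # paternal age bins; boundary ages 35 and 45 go to the middle bin
  pa <- get("paternal_age")
  if (is.null(pa)) {
    m <- missing_item("paternal_age", policy, "Paternal age", registry)
    sel["Paternal age"] <- m$level
    warnings <- c(warnings, m$warning)
  } else {
    if (!is.numeric(pa)) stop("paternal_age must be numeric", call. = FALSE)
    sel["Paternal age"] <- if (pa < 35) "<35" else if (pa <= 45) "35-45" else ">45"
  }

  # male & 25-35
  if (is.null(sex) || is.null(age)) {
    item <- if (is.null(sex)) "sex" else "age"
    m <- missing_item(item, policy, "Male & 25-35 years old", registry)
    sel["Male & 25-35 years old"] <- m$level
    warnings <- c(warnings, m$warning)
  } else {
    if (!sex %in% c("male", "female", "other")) {
      stop("unknown sex label '", sex, "'", call. = FALSE)
    }
    sel["Male & 25-35 years old"] <-
      if (sex == "male" && age >= 25 && age <= 35) "Yes" else "No"
  }

  sel <- sel[names(registry$groups)]
  names(sel) <- names(registry$groups)
  structure(
    list(respondent_id = if (is.null(get("respondent_id"))) NA_character_ else
           as.character(get("respondent_id")),
         selections = sel, warnings = warnings),
    class = "pps_profile"
  )
}

#' Score an exposure profile
#'
#' Computes the weighted sum of the selected level weights, the per-group
#' contributions, and the implied relative risk. All weights are half-integers,
#' so the total is exact in floating point.
#'
#' @param profile A `pps_profile` (see [resolve_profile()]), or a named
#'   character vector / list of level selections keyed by group name.
#' @param registry A `pps_registry`.
#' @return A `pps_score`: list with `total` (PPS points), `contributions`
#'   (named numeric, one entry per group), `relative_risk`
#'   (`rr_from_score(total)`), plus the profile's `respondent_id` and
#'   `warnings`.
#' @export
score_profile <- function(profile, registry = default_registry()) {
  if (inherits(profile, "pps_profile")) {
    sel <- profile$selections
    rid <- profile$respondent_id
    warn <- profile$warnings
  } else {
    sel <- unlist(profile)
    rid <- NA_character_
    warn <- character()
  }
  w <- registry_weights(registry)
  missing_groups <- setdiff(names(w), names(sel))
  if (length(missing_groups)) {
    stop("profile missing group(s): ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  }
  contributions <- vapply(names(w), function(group) {
    lev <- sel[[group]]
    ww <- w[[group]]
    if (!lev %in% names(ww)) {
      stop(sprintf("unknown level '%s' for group '%s'", lev, group),
           call. = FALSE)
    }
    ww[[lev]]
  }, numeric(1))
  total <- sum(contributions)
  structure(
    list(respondent_id = rid, total = total, contributions = contributions,
         relative_risk = rr_from_score(total), warnings = warn),
    class = "pps_score"
  )
}

#' @export
print.pps_score <- function(x, ...) {
  cat(sprintf("PPS total: %g (RR = %.2f)\n", x$total, x$relative_risk))
  invisible(x)
}

# Shared summary over a vector of totals: mean/sd/median, quartile ranges
# reported as observed (min, max) within each quartile bin, and the
# percentage of scores strictly above each threshold.
summarise_scores <- function(totals, thresholds = c(5, 15)) {
  n <- length(totals)
  stopifnot(n >= 1)
  q <- stats::quantile(totals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bin <- 1L + (totals > q[1]) + (totals > q[2]) + (totals > q[3])
  qr <- data.frame(
    quartile = paste0("Q", 1:4),
    min = vapply(1:4, function(b) if (any(bin == b)) min(totals[bin == b]) else NA_real_, 0),
    max = vapply(1:4, function(b) if (any(bin == b)) max(totals[bin == b]) else NA_real_, 0),
    pct = vapply(1:4, function(b) 100 * sum(bin == b) / n, 0)
  )
  thr <- vapply(thresholds, function(t) 100 * sum(totals > t) / n, 0)
  names(thr) <- as.character(thresholds)
  list(
    n = n,
    mean = mean(totals),
    sd = if (n > 1) stats::sd(totals) else 0,
    median = stats::median(totals),
    min = min(totals),
    max = max(totals),
    quartile_ranges = qr,
    threshold_proportions = thr
  )
}

#' Score a cohort of respondents
#'
#' Resolves and scores every respondent, then summarises the distribution of
#' totals: mean, SD, median, observed (min, max) per quartile bin with bin
#' percentages, and the percentage of the cohort strictly above each
#' threshold (published convention: "PPS > 5 (RR > 3)").
#'
#' @param responses A data.frame of raw responses (one row per respondent;
#'   see [response_columns()]) or a list of such records.
#' @param registry A `pps_registry`.
#' @param thresholds Numeric vector of strictly increasing score thresholds
#'   (default `c(5, 15)`).
#' @param policy Missing-data policy: `"strict"` (error), `"reference"`
#'   (impute reference levels), or `"exclude"` (drop respondents whose
#'   records cannot be resolved strictly; their ids are reported).
#' @param min_age Inclusion floor passed to [resolve_profile()].
#' @return A list with `results` (one `pps_score` per scored respondent) and
#'   `summary` (a `pps_cohort_summary`).
#' @export
score_cohort <- function(responses, registry = default_registry(),
                         thresholds = c(5, 15),
                         policy = c("strict", "reference", "exclude"),
                         min_age = 14) {
  policy <- match.arg(policy)
  if (is.data.frame(responses)) {
    responses <- lapply(seq_len(nrow(responses)), function(i) as.list(responses[i, ]))
  }
  if (length(responses) == 0) stop("empty cohort", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  excluded <- character()
  results <- list()
  for (raw in responses) {
    if (policy == "exclude") {
      prof <- tryCatch(resolve_profile(raw, registry, "strict", min_age),
                       error = function(e) e)
      if (inherits(prof, "error")) {
        rid <- raw$respondent_id
        excluded <- c(excluded, if (is.null(rid)) NA_character_ else as.character(rid))
        next
      }
    } else {
      prof <- resolve_profile(raw, registry, policy, min_age)
    }
    results[[length(results) + 1L]] <- score_profile(prof, registry)
  }
  if (length(results) == 0) stop("no scorable respondents in cohort", call. = FALSE)
  totals <- vapply(results, `[[`, numeric(1), "total")
  s <- summarise_scores(totals, thresholds)
  s$excluded <- excluded
  summary <- structure(s, class = "pps_cohort_summary")
  list(results = results, summary = summary)
}

#' @export
print.pps_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d: mean %.2f (SD = %.2f), median %g (RR = %.2f)\n",
              x$n, x$mean, x$sd, x$median, rr_from_score(x$median)))
  qr <- x$quartile_ranges
  for (i in seq_len(nrow(qr))) {
    cat(sprintf("  %s (%g to %g): %.1f%%\n", qr$quartile[i], qr$min[i],
                qr$max[i], qr$pct[i]))
  }
  for (t in names(x$threshold_proportions)) {
    cat(sprintf("  PPS > %s: %.1f%%\n", t, x$threshold_proportions[[t]]))
  }
  if (length(x$excluded)) {
    cat("  excluded respondents:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
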