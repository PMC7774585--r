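#' Convert an odds ratio to PPS points
#'
#' The Psychosis Polyrisk Score expresses each factor's effect size on a
#' decibel-like scale: `weight = 10 * log10(OR)`, rounded to the nearest half
#' point. Every weight of the shipped instrument is a half-integer on this
#' scale, and a total score `s` maps back to a relative risk of `10^(s/10)`
#' (see [rr_from_score()]).
#'
#' @param odds_ratio Positive numeric vector of odds ratios.
#' @return Numeric vector of PPS points (multiples of 0.5), monotone
#'   non-decreasing in `odds_ratio`.
#' @examples
#' weight_from_or(1)    # 0
#' weight_from_or(10)   # 10
#' weight_from_or(5.01) # 7
#' @export
weight_from_or <- function(odds_ratio) {
  if (!is.numeric(odds_ratio) || any(!is.finite(odds_ratio)) ||
      any(odds_ratio <= 0)) {
    stop("`odds_ratio` must be finite and strictly positive", call. = FALSE)
  }
  round(10 * log10(odds_ratio) * 2) / 2
}

#' Combine a base weight with a nested-category increment
#'
#' Logically dependent exposures (immigration generation x region of origin,
#' ethnicity x ethnic density) are folded into single scored items by adding
#' weights on the log-odds scale: the extra risk of the nested category is a
#' constant increment over the base category (+1 point for North African
#' origin over other regions, +2.5 for Black Caribbean over other non-White
#' ethnicity, at every level of the conditioning factor).
#'
#' @param base_weight,increment_weight PPS points; each must be a multiple
#'   of 0.5.
#' @return `base_weight + increment_weight`, a multiple of 0.5.
#' @examples
#' combine_nested_weights(2, 1)     # 1st generation, North Africa: 3
#' combine_nested_weights(1.5, 1)   # 2nd generation, North Africa: 2.5
#' combine_nested_weights(3.5, 2.5) # Black Caribbean, low density: 6
#' @export
combine_nested_weights <- function(base_weight, increment_weight) {
  stopifnot(is.numeric(base_weight), is.numeric(increment_weight))
  if (any(!is_half_step(base_weight)) || any(!is_half_step(increment_weight))) {
    stop("weights must be multiples of 0.5", call. = FALSE)
  }
  base_weight + increment_weight
}

is_half_step <- function(w, tol = 1e-9) {
  is.finite(w) & abs(w * 2 - round(w * 2)) < tol
}

new_factor_group <- function(name, labels, weights, evidence_class,
                             reference, components = character()) {
  stopifnot(length(labels) == length(weights))
  structure(
    list(
      name = name,
      levels = data.frame(label = labels, weight = weights,
                          stringsAsFactors = FALSE),
      evidence_class = evidence_class,
      reference_level = reference,
      components = components
    ),
    class = "pps_factor_group"
  )
}

#' The default PPS factor registry
#'
#' Builds the published scoring instrument: 16 scored factor groups covering
#' 22 operationalised risk/protective factors. Each group offers a set of
#' mutually exclusive levels with half-integer weights (units of
#' `10*log10(OR)`); a scored profile selects exactly one level per group. The
#' immigration item combines generation and region of origin, and the
#' ethnicity item combines ethnicity and local ethnic density, because those
#' underlying factors cannot be held in arbitrary conjunction.
#'
#' Evidence-class tags are carried as metadata only; they never enter the
#' score. The `reference_level` of each group is its unexposed/baseline level
#' (which may carry a negative, protective weight).
#'
#' @return An object of class `pps_registry`: a list with `groups` (named list
#'   of factor groups) and `factor_count` (22).
#' @examples
#' reg <- default_registry()
#' length(reg$groups)   # 16
#' reg$factor_count     # 22
#' @seealso [validate_registry()], [registry_weights()], [load_registry()]
#' @export
default_registry <- function() {
  g <- list(
    new_factor_group("Childhood trauma", c("Yes", "No"), c(4, -0.5), "IV", "No"),
    new_factor_group(
      "Ethnicity",
      c("White",
        "Black Caribbean, low ethnic density",
        "Black Caribbean, medium ethnic density",
        "Black Caribbean, high ethnic density",
        "Other, low ethnic density",
        "Other, medium ethnic density",
        "Other, high ethnic density"),
      c(-2, 6, 5.5, 3.5, 3.5, 3, 1),
      "I", "White",
      components = c("Black Caribbean ethnicity", "non-White ethnicity",
                     "ethnic density of local area")
    ),
    new_factor_group(
      "Immigration",
      c("Not immigrant",
        "1st generation, North Africa", "1st generation, other region",
        "2nd generation, North Africa", "2nd generation, other region"),
      c(-0.5, 3, 2, 2.5, 1.5),
      "II", "Not immigrant",
      components = c("1st generation immigrant", "2nd generation immigrant",
                     "North African origin")
    ),
    new_factor_group("Non-right-handedness", c("Yes", "No"), c(2, 0), "III", "No"),
    new_factor_group("Pollution", c("Yes", "No"), c(2, -5.5), "IV", "No"),
    new_factor_group("Urbanicity", c("Yes", "No"), c(1, -2.5), "III", "No"),
    new_factor_group("Winter or spring birth in northern hemisphere",
                     c("Yes", "No"), c(0, 0), "III", "No"),
    new_factor_group("Paternal age", c("<35", "35-45", ">45"),
                     c(-0.5, 0.5, 3.5), "III", "<35"),
    new_factor_group("Low paternal socioeconomic status",
                     c("Yes", "No"), c(1, 0), "IV", "No"),
    new_factor_group("Parental severe mental illness",
                     c("Yes", "No"), c(5.5, -2), "IV", "No"),
    new_factor_group("Adult life events", c("Yes", "No"), c(5.5, -2), "IV", "No"),
    new_factor_group("Daily smoker", c("Yes", "No"), c(3, -0.5), "IV", "No"),
    new_factor_group("Heavy cannabis use", c("Yes", "No"), c(7, 0), "III", "No"),
    new_factor_group("Hearing problems in past 12 months",
                     c("Yes", "No"), c(2, 0), "IV", "No"),
    new_factor_group("Trait anhedonia", c("Yes", "No"), c(6.5, 0), "III", "No"),
    new_factor_group("Male & 25-35 years old", c("Yes", "No"), c(2, 0), "IV", "No")
  )
  names(g) <- vapply(g, `[[`, character(1), "name")
  structure(list(groups = g, factor_count = 22L), class = "pps_registry")
}

#' Validate a factor registry
#'
#' Checks structural invariants of a registry and returns violations as data
#' rather than raising conditions: duplicate group names, empty groups,
#' duplicate level labels within a group, weights that are not multiples of
#' 0.5, and missing or unknown reference levels.
#'
#' @param registry A `pps_registry`.
#' @return A character vector of violation messages; `character(0)` when the
#'   registry is valid.
#' @examples
#' validate_registry(default_registry()) # character(0)
#' @export
validate_registry <- function(registry) {
  violations <- character()
  if (!inherits(registry, "pps_registry") || !is.list(registry$groups)) {
    return("not a pps_registry object")
  }
  nms <- vapply(registry$groups, `[[`, character(1), "name")
  dup <- unique(nms[duplicated(nms)])
  for (d in dup) violations <- c(violations, sprintf("duplicate group name: '%s'", d))
  for (grp in registry$groups) {
    lv <- grp$levels
    if (is.null(lv) || nrow(lv) == 0) {
      violations <- c(violations, sprintf("group '%s' has no levels", grp$name))
      next
    }
    dupl <- unique(lv$label[duplicated(lv$label)])
    for (d in dupl) {
      violations <- c(violations,
                      sprintf("group '%s': duplicate level label '%s'", grp$name, d))
    }
    bad <- lv$label[!is_half_step(lv$weight)]
    for (b in bad) {
      violations <- c(violations,
                      sprintf("group '%s': level '%s' weight is not a multiple of 0.5",
                              grp$name, b))
    }
    if (is.null(grp$reference_level) || length(grp$reference_level) != 1 ||
        !(grp$reference_level %in% lv$label)) {
      violations <- c(violations,
                      sprintf("group '%s': missing or unknown reference level", grp$name))
    }
  }
  violations
}

#' Per-group weight lookup
#'
#' @param registry A `pps_registry`.
#' @return Named list mapping group name to a named numeric vector of level
#'   weights.
#' @export
registry_weights <- function(registry) {
  lapply(registry$groups, function(g) {
    stats::setNames(g$levels$weight, g$levels$label)
  })
}

#' Load a factor registry from a JSON or YAML file
#'
#' The file mirrors the registry structure: a top-level `factor_count` and a
#' `groups` list whose entries carry `name`, `evidence_class`,
#' `reference_level`, optional `components`, and `levels` as a label -> weight
#' mapping. The loaded registry is validated with [validate_registry()] and
#' loading fails on any violation.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `pps_registry`.
#' @export
load_registry <- function(path) {
  raw <- read_structured(path)
  if (is.null(raw$groups)) stop("registry file has no 'groups' entry", call. = FALSE)
  groups <- lapply(raw$groups, function(g) {
    w <- unlist(g$levels)
    new_factor_group(
      name = g$name,
      labels = names(w),
      weights = as.numeric(w),
      evidence_class = if (is.null(g$evidence_class)) "IV" else g$evidence_class,
      reference = g$reference_level,
      components = if (is.null(g$components)) character() else unlist(g$components)
    )
  })
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  fc <- if (is.null(raw$factor_count)) length(groups) else as.integer(raw$factor_count)
  reg <- structure(list(groups = groups, factor_count = fc), class = "pps_registry")
  v <- validate_registry(reg)
  if (length(v)) {
    stop("invalid registry in '", path, "': ", paste(v, collapse = "; "),
         call. = FALSE)
  }
  reg
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' @export
print.pps_registry <- function(x, ...) {
  cat("PPS factor registry:", length(x$groups), "scored groups,",
      x$factor_count, "operationalised factors\n")
  for (g in x$groups) {
    cat(sprintf("  %-46s [class %-3s] %d level(s), ref '%s'\n",
                g$name, g$evidence_class, nrow(g$levels), g$reference_level))
  }
  invisible(x)
}
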