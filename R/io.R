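parse_boolean_column <- function(x, column) {
  out <- rep(NA, length(x))
  v <- tolower(trimws(x))
  out[v %in% c("yes", "true", "1")] <- TRUE
  out[v %in% c("no", "false", "0")] <- FALSE
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("cannot parse '%s' as yes/no in column '%s', row %d",
                 x[bad[1]], column, bad[1]), call. = FALSE)
  }
  out
}

parse_numeric_column <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("cannot parse '%s' as a number in column '%s', row %d",
                 x[bad[1]], column, bad[1]), call. = FALSE)
  }
  out
}

#' Read raw questionnaire responses from CSV
#'
#' Expects a header row matching [response_columns()] exactly (any order).
#' Booleans are encoded yes/no (case-insensitive; true/false and 1/0 also
#' accepted), categorical labels are lower-snake-case, and empty cells become
#' missing values handled by the scoring policy. Parse failures cite the row
#' and column.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with one typed row per respondent; row order
#'   preserved.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  expected <- response_columns()
  unknown <- setdiff(names(df), expected)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(expected, names(df))
  if (length(absent)) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  df <- df[, expected]
  for (col in c("age", "paternal_age")) {
    df[[col]] <- parse_numeric_column(df[[col]], col)
  }
  for (col in unname(boolean_item_map)) {
    df[[col]] <- parse_boolean_column(df[[col]], col)
  }
  for (col in c("sex", "ethnicity", "ethnic_density", "immigration", "origin")) {
    v <- trimws(df[[col]])
    v[v == ""] <- NA_character_
    df[[col]] <- v
  }
  df
}

#' Write raw responses to CSV
#'
#' Inverse of [read_responses()]: booleans are serialised yes/no, missing
#' values as empty cells. A fixed seed upstream therefore yields a
#' byte-identical file.
#'
#' @param responses Data.frame of raw responses.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_responses <- function(responses, path) {
  df <- responses[, response_columns(), drop = FALSE]
  for (col in unname(boolean_item_map)) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", ifelse(df[[col]], "yes", "no"))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

empty_responses <- function() {
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(response_columns())),
                    response_columns()),
    stringsAsFactors = FALSE
  )
  for (col in c("age", "paternal_age")) df[[col]] <- numeric(0)
  for (col in unname(boolean_item_map)) df[[col]] <- logical(0)
  df
}

#' Generate a synthetic fixture cohort of raw responses
#'
#' Desk-scale stand-in for a recruited cohort: samples one exposure level per
#' factor group per respondent from the prevalence configuration (independent
#' groups, the same sampling model as [simulate_population()]) and back-fills
#' raw questionnaire fields consistent with the sampled levels — a respondent
#' sampled as "Male & 25-35: Yes" gets male sex and an age in \[25, 35\], a
#' paternal-age bin gets an age drawn within that bin, and the combined
#' ethnicity/immigration levels are decomposed into their raw categorical
#' items. Deterministic for a fixed seed.
#'
#' @inheritParams validate_prevalences
#' @param n Number of respondents (0 gives an empty, valid cohort).
#' @param seed Integer seed (required).
#' @param path Optional CSV path; if given, the cohort is also written via
#'   [write_responses()].
#' @return A data.frame of raw responses (invisibly also written to `path`
#'   when provided).
#' @export
generate_fixture_cohort <- function(prevalences = default_prevalences(),
                                    n, seed, registry = default_registry(),
                                    path = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  cfg <- validate_prevalences(prevalences, registry)
  if (n == 0) {
    df <- empty_responses()
    if (!is.null(path)) write_responses(df, path)
    return(df)
  }
  set.seed(as.integer(seed))
  sampled <- lapply(names(cfg), function(group) {
    p <- cfg[[group]]
    names(p)[sample.int(length(p), n, replace = TRUE, prob = unname(p))]
  })
  names(sampled) <- names(cfg)

  df <- as.data.frame(lapply(empty_responses(), function(col) rep(col[NA], n)),
                      stringsAsFactors = FALSE)
  names(df) <- response_columns()
  df$respondent_id <- sprintf("R%05d", seq_len(n))

  for (group in names(boolean_item_map)) {
    df[[boolean_item_map[[group]]]] <- sampled[[group]] == "Yes"
  }

  eth <- sampled[["Ethnicity"]]
  df$ethnicity <- ifelse(eth == "White", "white",
                         ifelse(startsWith(eth, "Black Caribbean"),
                                "black_caribbean", "other"))
  df$ethnic_density <- rep("not_applicable", n)
  df$ethnic_density[grepl("low ethnic", eth)] <- "low"
  df$ethnic_density[grepl("medium ethnic", eth)] <- "medium"
  df$ethnic_density[grepl("high ethnic", eth)] <- "high"

  imm <- sampled[["Immigration"]]
  df$immigration <- ifelse(imm == "Not immigrant", "none",
                           ifelse(startsWith(imm, "1st"), "first_generation",
                                  "second_generation"))
  df$origin <- ifelse(imm == "Not immigrant", "not_applicable",
                      ifelse(grepl("North Africa", imm), "north_africa", "other"))

  pa <- sampled[["Paternal age"]]
  df$paternal_age <- NA_real_
  df$paternal_age[pa == "<35"] <- sample(20:34, sum(pa == "<35"), replace = TRUE)
  df$paternal_age[pa == "35-45"] <- sample(35:45, sum(pa == "35-45"), replace = TRUE)
  df$paternal_age[pa == ">45"] <- sample(46:60, sum(pa == ">45"), replace = TRUE)

  m25 <- sampled[["Male & 25-35 years old"]] == "Yes"
  df$sex <- NA_character_
  df$age <- NA_real_
  df$sex[m25] <- "male"
  df$age[m25] <- sample(25:35, sum(m25), replace = TRUE)
  k <- sum(!m25)
  if (k > 0) {
    sex_no <- sample(c("male", "female"), k, replace = TRUE)
    age_no <- ifelse(sex_no == "male",
                     sample(c(14:24, 36:70), k, replace = TRUE),
                     sample(14:70, k, replace = TRUE))
    df$sex[!m25] <- sex_no
    df$age[!m25] <- age_no
  }

  if (!is.null(path)) write_responses(df, path)
  df
}

# Fingerprint of the scoring instrument, embedded in reports so a run can be
# reproduced bit-identically with the same registry.
registry_hash <- function(registry) {
  canonical <- jsonlite::toJSON(registry_weights(registry), digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canonical), tmp)
  unname(tools::md5sum(tmp))
}

report_meta <- function(registry, seed = NULL, n = NULL) {
  meta <- list(
    schema_version = "1.0",
    package = "ppscore",
    package_version = as.character(utils::packageVersion("ppscore")),
    registry_hash = registry_hash(registry)
  )
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  if (!is.null(n)) meta$n <- n
  meta
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
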