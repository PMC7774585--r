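#' An illustrative default prevalence configuration
#'
#' Per-group categorical distributions over exposure levels, used by the
#' population simulator and the fixture generator. The values are round,
#' plausible general-population prevalences chosen for illustration; they are
#' NOT the prevalence table used in the published simulation (which is in
#' unavailable supplementary material), so simulated moments under this
#' configuration are not expected to match published ones. Override with
#' [load_prevalences()] when real prevalence data are available.
#'
#' @return A named list (one entry per registry group) of named probability
#'   vectors over that group's level labels, each summing to 1.
#' @export
default_prevalences <- function() {
  list(
    "Childhood trauma" = c(Yes = 0.30, No = 0.70),
    "Ethnicity" = c(
      "White" = 0.85,
      "Black Caribbean, low ethnic density" = 0.005,
      "Black Caribbean, medium ethnic density" = 0.010,
      "Black Caribbean, high ethnic density" = 0.015,
      "Other, low ethnic density" = 0.030,
      "Other, medium ethnic density" = 0.040,
      "Other, high ethnic density" = 0.050
    ),
    "Immigration" = c(
      "Not immigrant" = 0.85,
      "1st generation, North Africa" = 0.01,
      "1st generation, other region" = 0.07,
      "2nd generation, North Africa" = 0.01,
      "2nd generation, other region" = 0.06
    ),
    "Non-right-handedness" = c(Yes = 0.10, No = 0.90),
    "Pollution" = c(Yes = 0.30, No = 0.70),
    "Urbanicity" = c(Yes = 0.50, No = 0.50),
    "Winter or spring birth in northern hemisphere" = c(Yes = 0.50, No = 0.50),
    "Paternal age" = c("<35" = 0.60, "35-45" = 0.30, ">45" = 0.10),
    "Low paternal socioeconomic status" = c(Yes = 0.20, No = 0.80),
    "Parental severe mental illness" = c(Yes = 0.05, No = 0.95),
    "Adult life events" = c(Yes = 0.30, No = 0.70),
    "Daily smoker" = c(Yes = 0.20, No = 0.80),
    "Heavy cannabis use" = c(Yes = 0.05, No = 0.95),
    "Hearing problems in past 12 months" = c(Yes = 0.10, No = 0.90),
    "Trait anhedonia" = c(Yes = 0.10, No = 0.90),
    "Male & 25-35 years old" = c(Yes = 0.10, No = 0.90)
  )
}

#' Validate a prevalence configuration against a registry
#'
#' @param prevalences Named list of named probability vectors, keyed by group
#'   then level.
#' @param registry A `pps_registry`.
#' @return Invisibly, the configuration with probabilities ordered as in the
#'   registry. Errors describe every mismatch found.
#' @export
validate_prevalences <- function(prevalences, registry = default_registry()) {
  problems <- character()
  missing <- setdiff(names(registry$groups), names(prevalences))
  if (length(missing)) {
    problems <- c(problems, paste("no prevalences for group(s):",
                                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(prevalences), names(registry$groups))
  if (length(extra)) {
    problems <- c(problems, paste("prevalences for unknown group(s):",
                                  paste(extra, collapse = ", ")))
  }
  out <- list()
  for (group in intersect(names(registry$groups), names(prevalences))) {
    p <- unlist(prevalences[[group]])
    labels <- registry$groups[[group]]$levels$label
    if (!setequal(names(p), labels)) {
      problems <- c(problems, sprintf("group '%s': levels do not match registry", group))
      next
    }
    p <- p[labels]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      problems <- c(problems,
                    sprintf("group '%s': probabilities must be non-negative and sum to 1 (sum = %.12g)",
                            group, sum(p)))
      next
    }
    out[[group]] <- p
  }
  if (length(problems)) {
    stop("invalid prevalence configuration: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  invisible(out)
}

#' Load a prevalence configuration from JSON or YAML
#'
#' The file is keyed by group name, then level label, with probabilities as
#' values. The configuration is validated against `registry` before use.
#'
#' @inheritParams validate_prevalences
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return The validated configuration.
#' @export
load_prevalences <- function(path, registry = default_registry()) {
  raw <- read_structured(path)
  cfg <- lapply(raw, function(p) unlist(p))
  validate_prevalences(cfg, registry)
}

#' Analytic mean and SD of the simulated score distribution
#'
#' Under the simulator's independence assumption the total score is a sum of
#' independent categorical terms, so its moments are available in closed
#' form: `mean = sum_g sum_l p_gl * w_gl` and
#' `var = sum_g (sum_l p_gl * w_gl^2 - (sum_l p_gl * w_gl)^2)`. This is the
#' oracle the Monte-Carlo simulator is tested against.
#'
#' @inheritParams validate_prevalences
#' @return A list with `mean` and `sd` (PPS points).
#' @export
expected_score <- function(prevalences = default_prevalences(),
                           registry = default_registry()) {
  cfg <- validate_prevalences(prevalences, registry)
  w <- registry_weights(registry)
  m <- 0
  v <- 0
  for (group in names(w)) {
    p <- cfg[[group]]
    ww <- w[[group]][names(p)]
    mg <- sum(p * ww)
    m <- m + mg
    v <- v + sum(p * ww^2) - mg^2
  }
  list(mean = m, sd = sqrt(v))
}

#' Simulate the PPS distribution in a synthetic general population
#'
#' Draws `n` synthetic individuals ("permutations"), each built by sampling
#' one level per factor group independently from the prevalence configuration,
#' and sums the level weights into a total score per individual. Sampling is
#' chunked so very large `n` (the published run used 10,000,000) stays within
#' modest memory. The score sample is summarised like a cohort (quartile
#' ranges, threshold proportions) plus an adjusted Jarque-Bera normality test.
#'
#' @inheritParams validate_prevalences
#' @param n Number of simulated individuals (default 1e7, the published run).
#' @param seed Integer seed; required, so every run is reproducible.
#' @param thresholds Score thresholds for the strict "proportion above" summary.
#' @param keep_scores If `TRUE`, attach the raw score vector to the result.
#' @param chunk_size Individuals sampled per chunk.
#' @return A `pps_simulation_summary`: `n_permutations`, `seed`, `mean`, `sd`,
#'   `median`, `min`, `max`, `quartile_ranges`, `threshold_proportions`,
#'   `normality` (list with `statistic`, `p`, or `NA`s for a degenerate
#'   constant sample), and optionally `scores`.
#' @examples
#' sim <- simulate_population(n = 1e4, seed = 42)
#' sim$mean
#' @export
simulate_population <- function(prevalences = default_prevalences(),
                                registry = default_registry(),
                                n = 1e7, seed, thresholds = c(5, 15),
                                keep_scores = FALSE, chunk_size = 1e6) {
  if (missing(seed)) stop("`seed` is required for simulation", call. = FALSE)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(round(n))
  cfg <- validate_prevalences(prevalences, registry)
  w <- registry_weights(registry)
  set.seed(as.integer(seed))
  scores <- numeric(n)
  done <- 0L
  while (done < n) {
    take <- as.integer(min(chunk_size, n - done))
    idx <- seq.int(done + 1L, done + take)
    chunk <- numeric(take)
    for (group in names(w)) {
      p <- cfg[[group]]
      ww <- unname(w[[group]][names(p)])
      k <- sample.int(length(p), take, replace = TRUE, prob = unname(p))
      chunk <- chunk + ww[k]
    }
    scores[idx] <- chunk
    done <- done + take
  }
  s <- summarise_scores(scores, thresholds)
  s$n_permutations <- n
  s$seed <- as.integer(seed)
  s$normality <- if (s$sd > 0) {
    adjusted_jarque_bera(scores)
  } else {
    list(statistic = NA_real_, p = NA_real_)
  }
  if (keep_scores) s$scores <- scores
  structure(s, class = c("pps_simulation_summary", "pps_cohort_summary"))
}

#' @export
print.pps_simulation_summary <- function(x, ...) {
  cat(sprintf("Simulated population (n = %d, seed = %d)\n", x$n_permutations, x$seed))
  cat(sprintf("  scores range %g (RR = %.2f) to %g (RR = %.2f)\n",
              x$min, rr_from_score(x$min), x$max, rr_from_score(x$max)))
  cat(sprintf("  mean %.3f (SD = %.2f), median %g (RR = %.2f)\n",
              x$mean, x$sd, x$median, rr_from_score(x$median)))
  if (!is.na(x$normality$statistic)) {
    cat(sprintf("  adjusted Jarque-Bera = %.1f, p %s\n", x$normality$statistic,
                format.pval(x$normality$p, eps = 0.001)))
  }
  invisible(x)
}

#' Adjusted Jarque-Bera normality test
#'
#' Moment-based normality test with exact small-sample corrections: with
#' sample skewness `S = m3 / m2^(3/2)` and kurtosis `K = m4 / m2^2` (biased
#' central moments), the statistic is
#' `AJB = S^2 / Var(S) + (K - E(K))^2 / Var(K)` where
#' `E(K) = 3(n-1)/(n+1)`, `Var(S) = 6(n-2) / ((n+1)(n+3))` and
#' `Var(K) = 24n(n-2)(n-3) / ((n+1)^2 (n+3)(n+5))`, referred to a chi-square
#' distribution with 2 degrees of freedom. Unlike the classic Jarque-Bera
#' test it holds its nominal level at moderate n.
#'
#' @param sample Numeric vector, length >= 8, not constant.
#' @return A list with `statistic` (>= 0), `p` (in (0, 1]), `skewness` and
#'   `kurtosis`.
#' @export
adjusted_jarque_bera <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 8) stop("adjusted Jarque-Bera requires n >= 8", call. = FALSE)
  m <- mean(sample)
  d <- sample - m
  m2 <- mean(d^2)
  if (m2 <= 0) stop("constant sample: moments undefined", call. = FALSE)
  S <- mean(d^3) / m2^1.5
  K <- mean(d^4) / m2^2
  var_s <- 6 * (n - 2) / ((n + 1) * (n + 3))
  e_k <- 3 * (n - 1) / (n + 1)
  var_k <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  stat <- S^2 / var_s + (K - e_k)^2 / var_k
  list(statistic = stat,
       p = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K)
}

#' Histogram of simulated scores for export
#'
#' Counts scores at each attained half-point value, suitable for plotting the
#' population score distribution or writing as a CSV of (score, count).
#'
#' @param scores Numeric vector of simulated scores (see
#'   `simulate_population(..., keep_scores = TRUE)`).
#' @return A data.frame with columns `score` and `count`.
#' @export
score_histogram <- function(scores) {
  tab <- table(scores)
  data.frame(score = as.numeric(names(tab)), count = as.integer(tab))
}
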