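# Study-database module: the tabular study container, CSV readers/writers,
# validation rules, and the logit/variance transform that prepares observed
# prevalences for the Gaussian meta-regression likelihood.

STUDY_COLUMNS <- c(
  "study_id", "country", "region", "mid_year", "sex", "age_lo", "age_hi",
  "coverage", "urbanisation", "n_sample", "prev_low", "prev_obese"
)

SEX_LEVELS <- c("female", "male")
COVERAGE_LEVELS <- c("national", "subnational", "community")
URBAN_LEVELS <- c("urban", "rural", "mixed")
CATEGORY_LEVELS <- c("low", "obese")

# enum normalisation: case-insensitive with documented synonyms
normalise_enum <- function(x, levels, synonyms = NULL, field = "value") {
  x <- tolower(trimws(as.character(x)))
  if (!is.null(synonyms)) {
    hit <- x %in% names(synonyms)
    x[hit] <- unname(synonyms[x[hit]])
  }
  x
}

URBAN_SYNONYMS <- c(both = "mixed", all = "mixed", combined = "mixed")
SEX_SYNONYMS <- c(f = "female", m = "male", women = "female", men = "male",
                  girls = "female", boys = "male")

#' Construct a study table
#'
#' One row per study x sex x age band; `prev_low` and `prev_obese` hold the
#' measured prevalence of the low-BMI category (underweight for adults,
#' thinness for ages 5-19) and of obesity.  `NA` in a prevalence column means
#' the study did not report that category.  The constructor normalises enum
#' columns (case-insensitive, "both" -> "mixed") but performs no semantic
#' validation; see [validate_studies()].
#'
#' @param df data.frame with the documented columns
#' @param window integer length-2 analysis year window (inclusive)
#' @return a `study_table` (data.frame subclass) with a `window` attribute
#' @export
study_table <- function(df, window = c(1990, 2022)) {
  missing <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop_dbm("study table schema error: missing column(s) %s",
             paste(missing, collapse = ", "))
  }
  df <- df[STUDY_COLUMNS]
  df$study_id <- as.character(df$study_id)
  df$country <- toupper(trimws(as.character(df$country)))
  df$region <- as.character(df$region)
  df$sex <- normalise_enum(df$sex, SEX_LEVELS, SEX_SYNONYMS)
  df$coverage <- normalise_enum(df$coverage, COVERAGE_LEVELS)
  df$urbanisation <- normalise_enum(df$urbanisation, URBAN_LEVELS,
                                    URBAN_SYNONYMS)
  for (col in c("mid_year", "age_lo", "age_hi", "n_sample")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("prev_low", "prev_obese")) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    if (length(bad) > 0) {
      stop_dbm("unparseable prevalence in column %s at row %d: '%s'",
               col, bad[1], as.character(raw[bad[1]]))
    }
    num[!is.na(raw) & raw == ""] <- NA_real_
    df[[col]] <- num
  }
  rownames(df) <- NULL
  structure(df, window = as.integer(window),
            class = c("study_table", "data.frame"))
}

#' Read a study table from CSV
#'
#' Columns: `study_id,country,region,mid_year,sex,age_lo,age_hi,coverage,
#' urbanisation,n_sample,prev_low,prev_obese` (UTF-8, header required).
#' Row order is preserved and no semantic validation is applied beyond type
#' parsing -- a row with `prev_low + prev_obese > 1` is read back verbatim
#' and only flagged later by [validate_studies()].
#'
#' @param path CSV file path
#' @param window analysis year window passed to [study_table()]
#' @return a `study_table`
#' @export
read_study_table <- function(path, window = c(1990, 2022)) {
  if (!file.exists(path)) stop_dbm("study table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  study_table(df, window = window)
}

#' Write a study table to CSV
#'
#' Inverse of [read_study_table()]; round-trip is the identity on valid
#' tables.
#'
#' @param studies a `study_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_study_table <- function(studies, path) {
  utils::write.csv(as.data.frame(studies), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate a study table
#'
#' Checks every row against the study-observation invariants and returns a
#' report of violations (a data.frame with `row`, `rule`, `message`); an
#' empty report means the table is valid.  Violations are data, not
#' exceptions, and the input is never mutated.
#'
#' Rules: `sex-enum`, `coverage-enum`, `urban-enum`, `age-order`
#' (`age_lo < age_hi`), `sample-size` (`n_sample >= 1`), `prev-range`
#' (each reported prevalence in \[0, 1\]), `category-sum`
#' (`prev_low + prev_obese <= 1`), `year-window` (`mid_year` inside the
#' table's analysis window), `no-category` (no prevalence reported at all).
#'
#' @param studies a `study_table`
#' @return data.frame with columns `row`, `rule`, `message`
#' @export
validate_studies <- function(studies) {
  out <- list()
  add <- function(rows, rule, message) {
    if (length(rows) > 0) {
      out[[length(out) + 1]] <<- data.frame(
        row = rows, rule = rule, message = message,
        stringsAsFactors = FALSE)
    }
  }
  n <- nrow(studies)
  if (n == 0) {
    return(data.frame(row = integer(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  add(which(!(studies$sex %in% SEX_LEVELS)), "sex-enum",
      "sex must be female or male")
  add(which(!(studies$coverage %in% COVERAGE_LEVELS)), "coverage-enum",
      "coverage must be national, subnational, or community")
  add(which(!(studies$urbanisation %in% URBAN_LEVELS)), "urban-enum",
      "urbanisation must be urban, rural, or mixed")
  add(which(!(studies$age_lo < studies$age_hi)), "age-order",
      "age_lo must be strictly below age_hi")
  add(which(is.na(studies$n_sample) | studies$n_sample < 1), "sample-size",
      "n_sample must be a positive integer")
  in01 <- function(p) is.na(p) | (p >= 0 & p <= 1)
  add(which(!(in01(studies$prev_low) & in01(studies$prev_obese))),
      "prev-range", "prevalence must lie in [0, 1]")
  psum <- ifelse(is.na(studies$prev_low), 0, studies$prev_low) +
    ifelse(is.na(studies$prev_obese), 0, studies$prev_obese)
  add(which(in01(studies$prev_low) & in01(studies$prev_obese) & psum > 1),
      "category-sum", "prev_low + prev_obese must not exceed 1")
  add(which(is.na(studies$prev_low) & is.na(studies$prev_obese)),
      "no-category", "at least one category prevalence required")
  window <- attr(studies, "window") %||% c(-Inf, Inf)
  add(which(is.na(studies$mid_year) | studies$mid_year < window[1] |
              studies$mid_year > window[2]),
      "year-window",
      sprintf("mid_year must lie in [%s, %s]", window[1], window[2]))
  report <- do.call(rbind, out)
  if (is.null(report)) {
    report <- data.frame(row = integer(), rule = character(),
                         message = character(), stringsAsFactors = FALSE)
  }
  report[order(report$row), , drop = FALSE]
}

#' Logit transform of observed prevalences
#'
#' Converts one category's observed prevalences into likelihood-ready pairs
#' (y, v): y is the logit of the continuity-corrected proportion and v its
#' delta-method sampling variance.  With x = round(prev * n) (ties away from
#' zero) successes out of n, the corrected proportion is
#' p~ = (x + 0.5) / (n + 1) and
#'   y = log(p~ / (1 - p~)),   v = 1 / ((n + 1) * p~ * (1 - p~)).
#' The correction keeps y and v finite for observed prevalences of exactly
#' 0 or 1.  Rows not reporting the requested category are dropped.
#'
#' @param studies a `study_table`
#' @param category `"low"` or `"obese"`
#' @return data.frame with all study keys plus `y`, `v`, `category`
#' @export
logit_transform <- function(studies, category = c("low", "obese")) {
  category <- match.arg(category)
  prev <- studies[[paste0("prev_", category)]]
  keep <- which(!is.na(prev))
  df <- as.data.frame(studies)[keep, setdiff(STUDY_COLUMNS,
                                             c("prev_low", "prev_obese"))]
  n <- studies$n_sample[keep]
  x <- round_half_away(prev[keep] * n)
  p_tilde <- (x + 0.5) / (n + 1)
  df$category <- category
  df$y <- logit(p_tilde)
  df$v <- 1 / ((n + 1) * p_tilde * (1 - p_tilde))
  rownames(df) <- NULL
  df
}

#' Read a country-to-region hierarchy
#'
#' CSV columns `country,region`.  Every country must map to exactly one
#' region.
#'
#' @param path CSV path
#' @return data.frame `country`, `region` of class `region_hierarchy`
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_hierarchy(df)
}

#' @rdname read_hierarchy
#' @param df data.frame with columns `country`, `region`
#' @export
region_hierarchy <- function(df) {
  if (!all(c("country", "region") %in% names(df))) {
    stop_dbm("hierarchy schema error: need columns country, region")
  }
  df$country <- toupper(trimws(df$country))
  dup <- unique(df$country[duplicated(df$country)])
  if (length(dup) > 0) {
    stop_dbm("countries mapped to more than one region: %s",
             paste(dup, collapse = ", "))
  }
  structure(df[c("country", "region")],
            class = c("region_hierarchy", "data.frame"))
}

#' Age-standard weight table
#'
#' Ordered, non-overlapping, contiguous age bands with positive weights that
#' sum to one.  [who_age_standard()] returns the WHO world standard
#' population weights restricted to the adult (20+) or school-age (5-19)
#' domain and renormalised.
#'
#' @param df data.frame with columns `age_lo`, `age_hi`, `weight`
#' @return data.frame of class `age_standard`
#' @export
age_standard <- function(df) {
  need <- c("age_lo", "age_hi", "weight")
  if (!all(need %in% names(df))) {
    stop_dbm("age standard schema error: need columns %s",
             paste(need, collapse = ", "))
  }
  df <- df[order(df$age_lo), need]
  if (any(df$weight <= 0)) stop_dbm("age standard weights must be positive")
  if (any(df$age_lo >= df$age_hi)) stop_dbm("age bands must have age_lo < age_hi")
  if (nrow(df) > 1 && any(df$age_lo[-1] != df$age_hi[-nrow(df)])) {
    stop_dbm("age standard bands must be contiguous")
  }
  if (abs(sum(df$weight) - 1) > 1e-6) {
    stop_dbm("age standard weights must sum to 1 (got %.6f)", sum(df$weight))
  }
  df$weight <- df$weight / sum(df$weight)
  rownames(df) <- NULL
  structure(df, class = c("age_standard", "data.frame"))
}

#' @rdname age_standard
#' @param path CSV path with columns `age_lo,age_hi,weight`
#' @export
read_age_standard <- function(path) {
  age_standard(utils::read.csv(path, stringsAsFactors = FALSE))
}

# WHO world standard population (per 100 000), 5-year bands
WHO_STANDARD <- data.frame(
  age_lo = c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55,
             60, 65, 70, 75, 80, 85),
  age_hi = c(5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60,
             65, 70, 75, 80, 85, 200),
  pop = c(8860, 8690, 8600, 8470, 8220, 7930, 7610, 7150, 6590, 6040,
          5370, 4550, 3720, 2960, 2210, 1520, 910, 635)
)

#' @rdname age_standard
#' @param domain `"adult"` (5-year bands 20-24 ... 80-84, then 85+) or
#'   `"school"` (1-year bands 5 ... 19, 5-year weights split evenly)
#' @export
who_age_standard <- function(domain = c("adult", "school")) {
  domain <- match.arg(domain)
  if (domain == "adult") {
    w <- WHO_STANDARD[WHO_STANDARD$age_lo >= 20, ]
    df <- data.frame(age_lo = w$age_lo, age_hi = w$age_hi,
                     weight = w$pop / sum(w$pop))
  } else {
    w <- WHO_STANDARD[WHO_STANDARD$age_lo >= 5 & WHO_STANDARD$age_hi <= 20, ]
    age_lo <- 5:19
    pop <- rep(w$pop / 5, each = 5)
    df <- data.frame(age_lo = age_lo, age_hi = age_lo + 1,
                     weight = pop / sum(pop))
  }
  age_standard(df)
}

#' Read a population table
#'
#' CSV columns `country,year,sex,age_lo,age_hi,persons`; used for
#' persons-affected calculations and population-weighted aggregation.
#'
#' @param path CSV path
#' @return data.frame of class `population_table`
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  population_table(df)
}

#' @rdname read_population
#' @param df data.frame with the documented columns
#' @export
population_table <- function(df) {
  need <- c("country", "year", "sex", "age_lo", "age_hi", "persons")
  if (!all(need %in% names(df))) {
    stop_dbm("population schema error: need columns %s",
             paste(need, collapse = ", "))
  }
  if (any(df$persons < 0)) stop_dbm("persons must be non-negative")
  df$country <- toupper(trimws(df$country))
  df$sex <- normalise_enum(df$sex, SEX_LEVELS, SEX_SYNONYMS)
  structure(df[need], class = c("population_table", "data.frame"))
}
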