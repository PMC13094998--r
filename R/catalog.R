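#' Need catalog of the CCEC grassroots-CDC reference study
#'
#' The 13 collaborative-development needs (Q1--Q13) of grassroots centres for
#' disease control and prevention in the Chengdu--Chongqing Economic Circle,
#' grouped under 4 primary needs. This is the default catalog used throughout
#' the package; a custom catalog may be supplied anywhere a `catalog` argument
#' appears.
#'
#' @return A data.frame with columns `need_id`, `primary_need`,
#'   `secondary_need` (13 rows, ordered Q1...Q13).
#' @export
#' @examples
#' head(ccec_need_catalog(), 3)
ccec_need_catalog <- function() {
  path <- system.file("extdata", "ccec_need_catalog.csv",
                      package = "kanoneeds", mustWork = TRUE)
  catalog <- read.csv(path, stringsAsFactors = FALSE)
  validate_need_catalog(catalog)
  catalog
}

#' Read a need catalog from CSV
#'
#' @param path CSV with columns `need_id`, `primary_need`, `secondary_need`.
#' @return Validated catalog data.frame.
#' @export
read_need_catalog <- function(path) {
  catalog <- read.csv(path, stringsAsFactors = FALSE)
  validate_need_catalog(catalog)
  catalog
}

#' Validate a need catalog
#'
#' Requires the three catalog columns, non-empty unique need ids, and each
#' need assigned to exactly one primary need (a need id appears once).
#'
#' @param catalog A catalog data.frame.
#' @return `catalog`, invisibly; errors if invalid.
#' @export
validate_need_catalog <- function(catalog) {
  required <- c("need_id", "primary_need", "secondary_need")
  missing_cols <- setdiff(required, names(catalog))
  if (length(missing_cols) > 0) {
    stop("need catalog is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(catalog) < 1L) stop("need catalog must have at least one need", call. = FALSE)
  if (anyDuplicated(catalog$need_id)) {
    stop("need catalog ids must be unique", call. = FALSE)
  }
  if (any(!nzchar(catalog$need_id))) stop("empty need_id in catalog", call. = FALSE)
  invisible(catalog)
}

#' Reference attribute-frequency profile (CCEC study, n = 110)
#'
#' Per-need Kano attribute percentages and the published better (SI) / worse
#' (DSI) coefficients of the CCEC grassroots-CDC needs assessment, as reported
#' for its 110 valid questionnaires. Percentage columns `A`, `I`, `M`, `O`,
#' `Q`, `R` are in percent (each row sums to 100); `si` and `dsi` are the
#' coefficients rounded to 3 decimal places as published.
#'
#' @return A 13-row data.frame keyed by `need_id`.
#' @seealso [ccec_counts()] to reconstruct integer respondent counts.
#' @export
#' @examples
#' ccec_frequencies()[1, ]
ccec_frequencies <- function() {
  path <- system.file("extdata", "ccec_attribute_frequencies.csv",
                      package = "kanoneeds", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Reconstruct reference respondent counts from the bundled percentages
#'
#' Applies [percentages_to_counts()] to every row of [ccec_frequencies()] at
#' the study size (110 valid questionnaires), yielding the integer
#' attribute-count table from which all reference coefficients follow.
#'
#' @param n Number of respondents behind the percentages (default 110).
#' @return A `kano_frequency` data.frame: `need_id`, integer columns
#'   `A`, `O`, `M`, `I`, `R`, `Q`, and `n`.
#' @export
#' @examples
#' ccec_counts()[1, ]   # Q1: A=12 O=25 M=60 I=8 R=3 Q=2
ccec_counts <- function(n = 110L) {
  ref <- ccec_frequencies()
  counts <- lapply(seq_len(nrow(ref)), function(i) {
    p <- unlist(ref[i, kano_attributes()])
    percentages_to_counts(p, n)
  })
  out <- data.frame(need_id = ref$need_id,
                    do.call(rbind, counts),
                    n = n,
                    stringsAsFactors = FALSE)
  as_kano_frequency(out)
}

#' Demographic strata of the CCEC reference study
#'
#' The six demographic fields recorded per respondent, each with its closed
#' category set and the marginal proportions observed among the study's 110
#' valid questionnaires. Used as the default sampling marginals by
#' [study_design()].
#'
#' @return Named list (one element per field) of named numeric vectors of
#'   category proportions, each summing to 1.
#' @export
#' @examples
#' ccec_demographics()$region
ccec_demographics <- function() {
  list(
    region        = c(Sichuan = 49, Chongqing = 61) / 110,
    gender        = c(Male = 44, Female = 66) / 110,
    age_group     = c("<=30" = 42, "31-50" = 64, ">=51" = 4) / 110,
    cdc_level     = c(district_county = 85, municipal_plus = 25) / 110,
    field_of_work = c(health_technology = 90, administrative_logistics = 20) / 110,
    job_position  = c(leader = 33, ordinary = 77) / 110
  )
}

#' Names of the demographic fields
#'
#' @return Character vector of the six demographic column names used in the
#'   wide response schema.
#' @export
demographic_fields <- function() {
  names(ccec_demographics())
}
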