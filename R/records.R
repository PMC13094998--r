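#' Item column names of the wide response schema
#'
#' The wide CSV schema stores one row per respondent: `respondent_id`, the six
#' demographic fields, then one positive and one negative answer column per
#' catalog need, named `q01_pos`, `q01_neg`, ..., in catalog order.
#'
#' @param catalog Need catalog data.frame.
#' @return Data.frame with columns `need_id`, `pos`, `neg` giving the column
#'   names of each need's answer pair.
#' @export
item_columns <- function(catalog = ccec_need_catalog()) {
  validate_need_catalog(catalog)
  idx <- seq_len(nrow(catalog))
  data.frame(need_id = catalog$need_id,
             pos = sprintf("q%02d_pos", idx),
             neg = sprintf("q%02d_neg", idx),
             stringsAsFactors = FALSE)
}

#' Validate a wide respondent table
#'
#' Checks schema completeness and answer codes. Respondent ids must be present
#' and unique; answer cells must be integer codes 1--5 or `NA` (missing
#' answers are legal here and handled by [screen_respondents()]).
#'
#' @param records Wide data.frame of respondent records.
#' @param catalog Need catalog.
#' @param require_demographics Require the six demographic columns
#'   (default `TRUE`).
#' @return `records` with answer columns coerced to integer, invisibly
#'   returned; errors report the offending row and column.
#' @export
validate_responses <- function(records, catalog = ccec_need_catalog(),
                               require_demographics = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("respondent table is empty or not a data.frame", call. = FALSE)
  }
  cols <- item_columns(catalog)
  need_cols <- c("respondent_id",
                 if (require_demographics) demographic_fields(),
                 cols$pos, cols$neg)
  missing_cols <- setdiff(need_cols, names(records))
  if (length(missing_cols) > 0) {
    stop("respondent table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$respondent_id)) {
    stop("respondent_id values must be unique", call. = FALSE)
  }
  for (cn in c(cols$pos, cols$neg)) {
    v <- records[[cn]]
    iv <- suppressWarnings(as.integer(v))
    bad <- which((!is.na(v) & is.na(iv)) | (!is.na(iv) & (iv < 1L | iv > 5L)))
    if (length(bad) > 0) {
      stop(sprintf("invalid Likert code in column '%s', row %d (value '%s'); codes must be 1-5",
                   cn, bad[1], as.character(v[bad[1]])), call. = FALSE)
    }
    records[[cn]] <- iv
  }
  invisible(records)
}

#' Read wide-format questionnaire responses from CSV
#'
#' @param path CSV path; UTF-8, "." decimal point.
#' @param catalog Need catalog the items must match.
#' @param require_demographics Require the six demographic columns.
#' @return Validated wide data.frame.
#' @export
read_responses <- function(path, catalog = ccec_need_catalog(),
                           require_demographics = TRUE) {
  records <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  records <- validate_responses(records, catalog, require_demographics)
  records
}

#' Read long-format questionnaire responses
#'
#' Long schema: one row per answered question with columns `respondent_id`,
#' `need_id`, `direction` (`"pos"` or `"neg"`) and `code`. Demographics, if
#' available, are supplied as a separate table keyed by `respondent_id`.
#'
#' @param path Long CSV path, or a data.frame in the long schema.
#' @param catalog Need catalog; unknown `need_id` values are an error.
#' @param demographics Optional data.frame keyed by `respondent_id` with the
#'   six demographic columns to merge in.
#' @return Wide respondent table (same schema as [read_responses()]; answer
#'   cells with no long row are `NA`).
#' @export
read_responses_long <- function(path, catalog = ccec_need_catalog(),
                                demographics = NULL) {
  long <- if (is.data.frame(path)) path else {
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  required <- c("respondent_id", "need_id", "direction", "code")
  missing_cols <- setdiff(required, names(long))
  if (length(missing_cols) > 0) {
    stop("long response table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(long$need_id), catalog$need_id)
  if (length(unknown) > 0) {
    stop("unknown need_id in long responses: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(long$direction %in% c("pos", "neg"))) {
    stop("direction must be 'pos' or 'neg'", call. = FALSE)
  }
  cols <- item_columns(catalog)
  ids <- unique(long$respondent_id)
  wide <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
  for (cn in c(cols$pos, cols$neg)) wide[[cn]] <- NA_integer_
  col_of <- c(stats::setNames(cols$pos, paste0(cols$need_id, ".pos")),
              stats::setNames(cols$neg, paste0(cols$need_id, ".neg")))
  key <- paste(long$need_id, long$direction, sep = ".")
  ri <- match(long$respondent_id, ids)
  ci <- match(col_of[key], names(wide))
  for (k in seq_len(nrow(long))) {
    wide[ri[k], ci[k]] <- as.integer(long$code[k])
  }
  if (!is.null(demographics)) {
    wide <- merge(wide, demographics, by = "respondent_id",
                  all.x = TRUE, sort = FALSE)
  }
  validate_responses(wide, catalog,
                     require_demographics = !is.null(demographics))
  wide[order(match(wide$respondent_id, ids)), , drop = FALSE]
}

# Extract respondent x need integer matrices of answers (internal).
item_matrix <- function(records, catalog, direction = c("pos", "neg")) {
  direction <- match.arg(direction)
  cols <- item_columns(catalog)
  m <- as.matrix(records[, cols[[direction]], drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(records$respondent_id, cols$need_id)
  m
}

#' Classify every answered item of every respondent
#'
#' @param records Wide respondent table (validated; no missing answers).
#' @param catalog Need catalog.
#' @param matrix Classification matrix.
#' @return Respondent x need character matrix of Kano attribute symbols.
#' @export
classify_records <- function(records, catalog = ccec_need_catalog(),
                             matrix = kano_matrix()) {
  validate_kano_matrix(matrix)
  pos <- item_matrix(records, catalog, "pos")
  neg <- item_matrix(records, catalog, "neg")
  if (anyNA(pos) || anyNA(neg)) {
    stop("cannot classify records with missing answers; screen first",
         call. = FALSE)
  }
  att <- matrix(matrix[cbind(as.vector(pos), as.vector(neg))],
                nrow = nrow(pos), dimnames = dimnames(pos))
  att
}
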