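#' Likert response levels of the Kano questionnaire
#'
#' Each need is asked twice: a positive (functional) question, "how would you
#' feel if this need were met", and a negative (dysfunctional) question, "how
#' would you feel if it were not". Both use the same five-point scale, coded
#' 1--5.
#'
#' @return Character vector of the five level labels, in code order
#'   (1 = "Like" ... 5 = "Dislike").
#' @export
#' @examples
#' likert_levels()
likert_levels <- function() {
  c("Like", "Should be", "Does not matter", "Can accept", "Dislike")
}

#' The six Kano attribute symbols
#'
#' M = must-be, O = one-dimensional, A = attractive, I = indifferent,
#' R = reverse, Q = questionable. Only \{A, O, M, I\} enter the better/worse
#' coefficient denominators; R and Q are retained in frequency tables.
#'
#' @return Character vector `c("A", "O", "M", "I", "R", "Q")`.
#' @export
kano_attributes <- function() {
  c("A", "O", "M", "I", "R", "Q")
}

# Fixed multiset of cells in the 5x5 classification matrix.
.matrix_cell_counts <- c(A = 3, O = 1, M = 3, I = 9, R = 7, Q = 2)

#' Kano two-dimensional classification matrix
#'
#' The 5 x 5 lookup table mapping a (positive, negative) Likert answer pair to
#' a Kano attribute. Rows index the positive answer, columns the negative
#' answer; loaders must not transpose. The cell layout is fixed: the "Like"
#' row is Q, A, A, A, O; the middle three rows are R, I, I, I, M; the
#' "Dislike" row is R, R, R, R, Q.
#'
#' @return A 5 x 5 character matrix of class `kano_matrix`, with
#'   `dimnames = list(positive = ..., negative = ...)`.
#' @export
#' @examples
#' m <- kano_matrix()
#' m["Like", "Dislike"]   # "O"
kano_matrix <- function() {
  lv <- likert_levels()
  m <- rbind(
    c("Q", "A", "A", "A", "O"),
    c("R", "I", "I", "I", "M"),
    c("R", "I", "I", "I", "M"),
    c("R", "I", "I", "I", "M"),
    c("R", "R", "R", "R", "Q")
  )
  dimnames(m) <- list(positive = lv, negative = lv)
  validate_kano_matrix(m)
  structure(m, class = c("kano_matrix", class(m)))
}

#' Validate a Kano classification matrix
#'
#' Checks that the matrix is 5 x 5, every cell carries one of the six
#' attribute symbols, and the cell multiset is exactly
#' \{A: 3, O: 1, M: 3, I: 9, R: 7, Q: 2\}.
#'
#' @param m A 5 x 5 character matrix.
#' @return `m`, invisibly; errors if invalid.
#' @export
validate_kano_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(5L, 5L))) {
    stop("classification matrix must be 5 x 5", call. = FALSE)
  }
  if (!all(m %in% kano_attributes())) {
    stop("classification matrix cells must be one of ",
         paste(kano_attributes(), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(m, levels = names(.matrix_cell_counts)))
  if (!all(as.integer(counts) == unname(.matrix_cell_counts))) {
    stop("classification matrix cell multiset must be {A:3, O:1, M:3, I:9, R:7, Q:2}, got {",
         paste(names(counts), as.integer(counts), sep = ":", collapse = ", "),
         "}", call. = FALSE)
  }
  invisible(m)
}

# Validate integer Likert codes, naming the offending field in the error.
check_likert <- function(x, field) {
  x <- as.integer(x)
  bad <- is.na(x) | x < 1L | x > 5L
  if (any(bad)) {
    stop(sprintf("'%s' must contain integer Likert codes 1-5 (offending value: %s)",
                 field, paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Classify a positive/negative answer pair
#'
#' Vectorised lookup in the Kano classification matrix. Codes follow
#' [likert_levels()]: 1 = "Like" ... 5 = "Dislike".
#'
#' @param positive Integer codes (1--5) of the positive-question answers.
#' @param negative Integer codes (1--5) of the negative-question answers.
#' @param matrix A classification matrix, by default [kano_matrix()].
#' @return Character vector of Kano attribute symbols, same length as the
#'   inputs (recycled to common length).
#' @export
#' @examples
#' classify_pair(1, 5)   # "O"
#' classify_pair(2, 5)   # "M"
#' classify_pair(c(1, 5), c(1, 1))   # "Q" "R"
classify_pair <- function(positive, negative, matrix = kano_matrix()) {
  validate_kano_matrix(matrix)
  positive <- check_likert(positive, "positive")
  negative <- check_likert(negative, "negative")
  n <- max(length(positive), length(negative))
  positive <- rep_len(positive, n)
  negative <- rep_len(negative, n)
  unname(matrix[cbind(positive, negative)])
}
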