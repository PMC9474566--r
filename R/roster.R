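#' Physician roster and travel-time matrix
#'
#' A physician roster is a data frame with one row per physician and columns
#' `physician_id` (unique character ids), `role` (integer, 1 = general
#' practitioner including pediatricians, 0 = medical specialist), `status`
#' (`licensed`/`employed`/`authorized`), `practice_form`
#' (`single`/`group`/`ambulatory-center`), `specialty` (categorical label)
#' and planar coordinates `x_km`, `y_km`. A travel-time matrix is a square
#' symmetric numeric matrix of pairwise travel times in minutes with a zero
#' diagonal, indexed in roster order.
#'
#' @param roster data frame with the columns listed above.
#' @return `as_physician_roster()` returns a validated object of class
#'   `physician_roster`.
#' @seealso [generate_roster()] to simulate one.
#' @export
as_physician_roster <- function(roster) {
  roster <- as.data.frame(roster, stringsAsFactors = FALSE)
  validate_roster(roster)
  class(roster) <- c("physician_roster", "data.frame")
  roster
}

ROSTER_STATUS_LEVELS <- c("licensed", "employed", "authorized")
ROSTER_PRACTICE_LEVELS <- c("single", "group", "ambulatory-center")

validate_roster <- function(roster) {
  required <- c("physician_id", "role", "status", "practice_form", "specialty")
  missing <- setdiff(required, names(roster))
  if (length(missing) > 0L) {
    stop("roster is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(roster$physician_id)) {
    stop("physician_id values must be unique")
  }
  if (!all(roster$role %in% c(0L, 1L))) {
    stop("role must be binary: 1 = GP (with pediatricians), 0 = specialist")
  }
  if (!all(roster$status %in% ROSTER_STATUS_LEVELS)) {
    stop("status must be one of: ", paste(ROSTER_STATUS_LEVELS, collapse = ", "))
  }
  if (!all(roster$practice_form %in% ROSTER_PRACTICE_LEVELS)) {
    stop("practice_form must be one of: ",
         paste(ROSTER_PRACTICE_LEVELS, collapse = ", "))
  }
  invisible(roster)
}

#' @rdname as_physician_roster
#' @param ttm square numeric matrix of travel times in minutes, with
#'   physician ids as row and column names.
#' @return `as_travel_time_matrix()` returns a validated matrix of class
#'   `travel_time_matrix`.
#' @export
as_travel_time_matrix <- function(ttm) {
  ttm <- as.matrix(ttm)
  validate_ttm(ttm)
  class(ttm) <- c("travel_time_matrix", class(matrix()))
  ttm
}

validate_ttm <- function(ttm) {
  if (nrow(ttm) != ncol(ttm)) stop("travel-time matrix must be square")
  if (!all(is.finite(ttm))) stop("travel times must be finite")
  if (any(ttm < 0)) stop("travel times must be nonnegative")
  if (any(abs(diag(ttm)) > 0)) stop("travel-time diagonal must be zero")
  if (max(abs(ttm - t(ttm))) > 1e-8) stop("travel-time matrix must be symmetric")
  invisible(ttm)
}

#' Read and write rosters and travel-time matrices
#'
#' Plain-CSV interchange. The travel-time CSV carries physician ids as both
#' a header row and a first column.
#'
#' @param path file path.
#' @return `read_roster()` a `physician_roster`; `read_travel_time()` a
#'   `travel_time_matrix`. The writers return their input invisibly.
#' @export
read_roster <- function(path) {
  as_physician_roster(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_roster
#' @param roster a `physician_roster`.
#' @export
write_roster <- function(roster, path) {
  write.csv(as.data.frame(roster), path, row.names = FALSE)
  invisible(roster)
}

#' @rdname read_roster
#' @export
read_travel_time <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  as_travel_time_matrix(m)
}

#' @rdname read_roster
#' @param ttm a `travel_time_matrix`.
#' @export
write_travel_time <- function(ttm, path) {
  write.csv(as.data.frame(unclass(ttm)), path, row.names = TRUE)
  invisible(ttm)
}
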