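# Reading, validating and writing the delimited-text tables the pipeline
# consumes: stratified study counts, standard populations, longitudinal
# cohort records and population projections. All files are plain UTF-8
# delimited text with "." as the decimal mark; the delimiter is
# configurable and defaults to a comma. Open-ended strata are written and
# read as age_hi = Inf (the literal "Inf").

VALID_SEX <- c("female", "male", "combined")

#' Coerce a data frame to a validated study table
#'
#' A study table holds one row per study x sex x age stratum with the case
#' count and population denominator for that cell. Validation enforces
#' `0 <= cases <= population`, integer counts, a recognised `sex` value
#' (`"female"`, `"male"` or `"combined"`) and, within each study x sex,
#' non-overlapping ordered age strata. The derived column
#' `prevalence = cases/population` is (re)computed, never trusted from disk.
#'
#' @param x A data frame with columns `study_id`, `sex`, `age_lo`, `age_hi`,
#'   `cases`, `population`. Additional columns (e.g. a `study_type` flag
#'   marking cohort studies excluded from meta-analysis) are preserved.
#' @return The validated table, class `c("study_table", "data.frame")`,
#'   ordered by study, sex and lower age bound.
#' @seealso [read_study_table()], [write_study_table()]
#' @export
as_study_table <- function(x) {
  req <- c("study_id", "sex", "age_lo", "age_hi", "cases", "population")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("study table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)
  x$study_id <- as.character(x$study_id)
  x$sex <- as.character(x$sex)
  for (col in c("age_lo", "age_hi", "cases", "population")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  bad_sex <- !x$sex %in% VALID_SEX
  if (any(bad_sex)) {
    stop("invalid sex value(s) in row(s) ",
         paste(which(bad_sex), collapse = ", "),
         " (expected female, male or combined)", call. = FALSE)
  }
  num_bad <- function(test, what) {
    if (any(test, na.rm = TRUE) || anyNA(test)) {
      stop("validation error in row(s) ",
           paste(which(test | is.na(test)), collapse = ", "), ": ", what,
           call. = FALSE)
    }
  }
  num_bad(x$cases < 0 | x$cases != round(x$cases),
          "cases must be a nonnegative integer")
  num_bad(x$population < 1 | x$population != round(x$population),
          "population must be a positive integer")
  num_bad(x$cases > x$population, "cases exceed population")
  if (nrow(x)) {
    for (g in split(x, list(x$study_id, x$sex), drop = TRUE)) {
      validate_strata(g$age_lo, g$age_hi,
                      where = paste0("study ", g$study_id[1], " / ", g$sex[1]))
    }
  }
  x$prevalence <- ifelse(x$population > 0, x$cases / x$population, NA_real_)
  x <- x[order(x$study_id, x$sex, x$age_lo), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("study_table", "data.frame")
  x
}

#' Read a stratified study count table
#'
#' @param file Path to a delimited text file with header columns `study_id`,
#'   `sex`, `age_lo`, `age_hi`, `cases`, `population`. `age_hi = Inf` (or an
#'   empty field) marks an open-ended stratum such as 85+.
#' @param delim Field delimiter (default `","`).
#' @return A validated study table; see [as_study_table()].
#' @examples
#' path <- system.file("extdata", "copiah_1978.csv", package = "metaprev")
#' read_study_table(path)
#' @export
read_study_table <- function(file, delim = ",") {
  x <- read_delim_file(file, delim)
  if ("age_hi" %in% names(x)) {
    x$age_hi[is.na(x$age_hi) | x$age_hi == ""] <- Inf
  }
  as_study_table(x)
}

#' Write a study table to delimited text
#'
#' Writes the six canonical columns; [read_study_table()] of the result
#' reproduces every field exactly (prevalence is recomputed from counts).
#'
#' @param x A study table.
#' @param file Output path.
#' @param delim Field delimiter (default `","`).
#' @return `file`, invisibly.
#' @export
write_study_table <- function(x, file, delim = ",") {
  stopifnot(inherits(x, "study_table"))
  cols <- c("study_id", "sex", "age_lo", "age_hi", "cases", "population")
  extra <- setdiff(names(x), c(cols, "prevalence"))
  utils::write.table(x[, c(cols, extra), drop = FALSE], file = file,
                     sep = delim, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Construct a standard population
#'
#' A standard population supplies the reference stratum counts \eqn{P_i}
#' (e.g. the 2010 US census population by age and sex) and the normalized
#' weights \eqn{w_i = P_i / \sum_j P_j} used for direct standardization.
#' Weights always sum to 1 over all rows of the table; functions that
#' standardize within a subset (one sex, say) renormalize from the counts.
#'
#' @param age_lo,age_hi Stratum bounds (exclusive upper; `Inf` allowed in the
#'   final stratum of each sex).
#' @param count Nonnegative stratum population counts with a positive sum.
#' @param sex Optional sex per stratum; defaults to `"combined"`.
#' @return A data frame of class `c("std_pop", "data.frame")` with columns
#'   `sex`, `age_lo`, `age_hi`, `count`, `weight`, ordered by sex and lower
#'   bound.
#' @examples
#' standard_population(c(45, 55), c(55, Inf), count = c(2e6, 3e6))
#' @export
standard_population <- function(age_lo, age_hi, count, sex = NULL) {
  if (is.null(sex)) sex <- rep("combined", length(age_lo))
  sex <- as.character(sex)
  stopifnot(length(age_lo) == length(age_hi),
            length(age_lo) == length(count),
            length(age_lo) == length(sex))
  if (!all(sex %in% VALID_SEX)) {
    stop("invalid sex value in standard population", call. = FALSE)
  }
  count <- as.numeric(count)
  if (any(is.na(count)) || any(count < 0)) {
    stop("standard-population counts must be nonnegative", call. = FALSE)
  }
  if (sum(count) <= 0) {
    stop("degenerate standard population: all counts are zero", call. = FALSE)
  }
  x <- data.frame(sex = sex, age_lo = as.numeric(age_lo),
                  age_hi = as.numeric(age_hi), count = count)
  for (g in split(x, x$sex)) {
    validate_strata(g$age_lo, g$age_hi,
                    where = paste0("standard population / ", g$sex[1]))
  }
  x <- x[order(x$sex, x$age_lo), , drop = FALSE]
  x$weight <- x$count / sum(x$count)
  rownames(x) <- NULL
  class(x) <- c("std_pop", "data.frame")
  x
}

#' Read a standard-population table
#'
#' @param file Delimited text with columns `age_lo`, `age_hi`, `count` and
#'   optionally `sex`.
#' @param delim Field delimiter.
#' @return A `std_pop` object; see [standard_population()].
#' @examples
#' path <- system.file("extdata", "us2010_standard.csv", package = "metaprev")
#' read_standard_population(path)
#' @export
read_standard_population <- function(file, delim = ",") {
  x <- read_delim_file(file, delim)
  req <- c("age_lo", "age_hi", "count")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("standard population is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x$age_hi[is.na(x$age_hi) | x$age_hi == ""] <- Inf
  standard_population(x$age_lo, x$age_hi, x$count,
                      sex = if ("sex" %in% names(x)) x$sex else NULL)
}

#' Read longitudinal cohort records
#'
#' One row per subject: age at entry into follow-up, age at exit (death or
#' end of study), and age at diagnosis if the subject was ever diagnosed
#' (empty/missing otherwise). A diagnosis age before entry marks a subject
#' prevalent at entry; a diagnosis age after exit is invalid.
#'
#' @param file Delimited text with columns `subject_id`, `entry_age`,
#'   `exit_age`, `diagnosis_age`.
#' @param delim Field delimiter.
#' @return A data frame of class `c("cohort_table", "data.frame")`.
#' @export
read_cohort_table <- function(file, delim = ",") {
  x <- read_delim_file(file, delim)
  as_cohort_table(x)
}

#' @rdname read_cohort_table
#' @param x A data frame with the cohort columns.
#' @export
as_cohort_table <- function(x) {
  req <- c("subject_id", "entry_age", "exit_age", "diagnosis_age")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)
  x$subject_id <- as.character(x$subject_id)
  for (col in c("entry_age", "exit_age", "diagnosis_age")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  bad <- is.na(x$entry_age) | is.na(x$exit_age) | x$entry_age < 0 |
    x$entry_age > x$exit_age
  if (any(bad)) {
    stop("invalid follow-up interval in row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  bad_dx <- !is.na(x$diagnosis_age) & x$diagnosis_age > x$exit_age
  if (any(bad_dx)) {
    stop("diagnosis after exit in row(s) ",
         paste(which(bad_dx), collapse = ", "), call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("cohort_table", "data.frame")
  x
}

# Shared low-level reader: header required; empty file with header only
# yields a zero-row data frame.
read_delim_file <- function(file, delim) {
  if (!file.exists(file)) {
    stop("file not found: ", file, call. = FALSE)
  }
  utils::read.table(file, header = TRUE, sep = delim, quote = "\"",
                    comment.char = "#", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}
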