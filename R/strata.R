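# Age-stratum conventions shared by every module.
#
# A stratum is the closed-open interval [age_lo, age_hi); the label "65-74"
# is encoded as age_lo = 65, age_hi = 75, and an open-ended terminal stratum
# ("85+") as age_hi = Inf. Encoding the exclusive upper bound avoids double
# counting at stratum boundaries.

#' Format age-stratum labels
#'
#' @param age_lo Numeric vector of inclusive lower bounds (years).
#' @param age_hi Numeric vector of exclusive upper bounds; `Inf` marks an
#'   open-ended stratum.
#' @return Character labels such as `"65-74"` or `"85+"`.
#' @examples
#' stratum_label(c(45, 85), c(55, Inf))
#' @export
stratum_label <- function(age_lo, age_hi) {
  ifelse(is.infinite(age_hi),
         paste0(format(age_lo, trim = TRUE), "+"),
         paste0(format(age_lo, trim = TRUE), "-", format(age_hi - 1, trim = TRUE)))
}

# Validate one set of stratum bounds: lower >= 0, lower < upper, only the
# last (by lower bound) stratum may be open-ended, and strata must not
# overlap. `where` names the offending table in error messages.
validate_strata <- function(age_lo, age_hi, where = "strata") {
  if (length(age_lo) != length(age_hi)) {
    stop(where, ": age_lo and age_hi differ in length", call. = FALSE)
  }
  if (any(is.na(age_lo)) || any(is.na(age_hi))) {
    stop(where, ": stratum bounds must not be missing", call. = FALSE)
  }
  if (any(age_lo < 0)) {
    stop(where, ": stratum lower bounds must be >= 0", call. = FALSE)
  }
  if (any(age_lo >= age_hi)) {
    bad <- which(age_lo >= age_hi)
    stop(where, ": lower bound not below upper bound in stratum ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(age_lo)
  lo <- age_lo[ord]
  hi <- age_hi[ord]
  if (length(lo) > 1) {
    if (any(is.infinite(hi[-length(hi)]))) {
      stop(where, ": only the final stratum may be open-ended", call. = FALSE)
    }
    if (any(hi[-length(hi)] > lo[-1] + 1e-9)) {
      stop(where, ": strata overlap", call. = FALSE)
    }
  }
  invisible(ord)
}

# Match rows of two stratified tables on stratum bounds (and sex when both
# tables carry it). Returns the index into `y` for each row of `x`; errors
# list every unmatched stratum on either side.
align_strata <- function(x, y, xname = "data", yname = "standard population") {
  use_sex <- "sex" %in% names(x) && "sex" %in% names(y)
  key <- function(d) {
    k <- paste(d$age_lo, d$age_hi, sep = ":")
    if (use_sex) k <- paste(d$sex, k, sep = ":") else k
  }
  kx <- key(x)
  ky <- key(y)
  if (anyDuplicated(kx)) {
    stop("duplicate strata in ", xname, ": ",
         paste(unique(kx[duplicated(kx)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ky)) {
    stop("duplicate strata in ", yname, ": ",
         paste(unique(ky[duplicated(ky)]), collapse = ", "), call. = FALSE)
  }
  idx <- match(kx, ky)
  if (anyNA(idx) || length(kx) != length(ky)) {
    miss_x <- kx[is.na(idx)]
    miss_y <- setdiff(ky, kx)
    stop("stratum alignment failed between ", xname, " and ", yname,
         if (length(miss_x)) paste0("; unmatched in ", xname, ": ",
                                    paste(miss_x, collapse = ", ")),
         if (length(miss_y)) paste0("; unmatched in ", yname, ": ",
                                    paste(miss_y, collapse = ", ")),
         call. = FALSE)
  }
  idx
}

#' Rebin stratified counts onto coarser age strata
#'
#' Collapses a study table onto a new age partition by exact summation of
#' cases and denominators, e.g. from the 5-year strata used for
#' standardization to the 10-year strata used for meta-analysis. Each
#' original stratum must fall entirely inside one target stratum; a stratum
#' straddling a boundary (or not covered at all) is an error — counts are
#' never interpolated.
#'
#' @param study A study table (see [read_study_table()]).
#' @param breaks Numeric vector of cut points defining the target partition,
#'   e.g. `c(45, 55, 65, 75, 85, Inf)` for 45-54 through 85+. Must be
#'   strictly increasing; the last element may be `Inf`.
#' @return A study table on the target strata, with `cases`, `population`
#'   and `prevalence` recomputed.
#' @examples
#' tab <- data.frame(study_id = "s", sex = "combined",
#'                   age_lo = c(45, 50), age_hi = c(50, 55),
#'                   cases = c(1, 2), population = c(100, 100))
#' rebin_counts(as_study_table(tab), breaks = c(45, 55))
#' @export
rebin_counts <- function(study, breaks) {
  stopifnot(is.data.frame(study), length(breaks) >= 2)
  if (any(diff(breaks) <= 0)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  lo_new <- breaks[-length(breaks)]
  hi_new <- breaks[-1]
  bin <- rep(NA_integer_, nrow(study))
  for (b in seq_along(lo_new)) {
    inside <- study$age_lo >= lo_new[b] & study$age_hi <= hi_new[b]
    bin[inside] <- b
  }
  if (anyNA(bin)) {
    bad <- which(is.na(bin))
    stop("strata not decomposable into the requested bins: ",
         paste(stratum_label(study$age_lo[bad], study$age_hi[bad]),
               collapse = ", "), call. = FALSE)
  }
  # Every occupied bin must be tiled exactly by the strata mapped into it;
  # a partially covered bin would silently deflate its denominator.
  grp <- split(seq_len(nrow(study)), list(study$study_id, study$sex, bin),
               drop = TRUE)
  for (g in grp) {
    b <- bin[g[1]]
    o <- g[order(study$age_lo[g])]
    lo <- study$age_lo[o]
    hi <- study$age_hi[o]
    tiled <- lo[1] == lo_new[b] && hi[length(hi)] == hi_new[b] &&
      (length(o) == 1 || all(hi[-length(hi)] == lo[-1]))
    if (!tiled) {
      stop("bin ", stratum_label(lo_new[b], hi_new[b]),
           " is only partially covered for ", study$study_id[g[1]], " / ",
           study$sex[g[1]], call. = FALSE)
    }
  }
  out <- aggregate(cbind(cases, population) ~ study_id + sex + bin,
                   data = cbind(study, bin = bin), FUN = sum)
  out$age_lo <- lo_new[out$bin]
  out$age_hi <- hi_new[out$bin]
  out$bin <- NULL
  as_study_table(out)
}
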