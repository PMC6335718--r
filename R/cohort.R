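#' Questionnaire items recorded for every subject
#'
#' The nine clinical signs (joint deformity and dyskinesia items) and the ten
#' general-information items collected by the KBD questionnaire. Signs are
#' coded tri-state in cohort files: 1 = present, 0 = absent, blank = missing.
#' A missing value drops the subject only from statistics involving that item.
#'
#' @format Character vectors of column names.
#' @name kbd_items
NULL

#' @rdname kbd_items
#' @export
kbd_clinical_signs <- c(
  "phalanges_tuberositas", "brachydactylia", "deformity_elbow",
  "deformity_knee", "dyskinesia_wrist", "dyskinesia_elbow",
  "dyskinesia_shoulder", "dyskinesia_knee", "dyskinesia_ankle"
)

#' @rdname kbd_items
#' @export
kbd_general_items <- c(
  "fracture", "blurred_vision", "hearing_disorder", "diarrhea", "astriction",
  "senile_wart", "decayed_tooth", "smoke", "alcohol", "family_kbd"
)

#' @rdname kbd_items
#' @export
kbd_all_items <- c(kbd_clinical_signs, kbd_general_items)

# anthropometric columns that must be numeric in a cohort file
kbd_anthropometry <- c("age", "bmi", "height", "sitting_height", "leg_length",
                       "metacarpal_length", "metacarpal_breadth")

#' Clinical severity indexes
#'
#' Computes the three body-proportion indexes used as hand/limb deformity
#' severity proxies, all dimensionless and scaled by 100:
#' \itemize{
#'   \item Manouvrier's skelic index: `(height - sitting_height) /
#'     sitting_height * 100` (leg length relative to trunk length);
#'   \item metacarpal length/breadth index: `metacarpal_length /
#'     metacarpal_breadth * 100`;
#'   \item metacarpal length/height index: `metacarpal_length / height * 100`.
#' }
#' All lengths are in centimetres. Being ratios of lengths, all three indexes
#' are invariant to a common rescaling of the anthropometry. When a
#' `leg_length` column is present it is validated against
#' `height - sitting_height` (warning beyond 0.5 cm discrepancy); the index
#' itself always uses height and sitting height.
#'
#' @param cohort A data.frame with numeric columns `height`, `sitting_height`,
#'   `metacarpal_length`, `metacarpal_breadth` (and optionally `leg_length`).
#' @return A data.frame with columns `skelic`, `mc_length_breadth`,
#'   `mc_length_height`, one row per subject.
#' @examples
#' compute_indexes(data.frame(height = 170, sitting_height = 85,
#'                            metacarpal_length = 16, metacarpal_breadth = 8))
#' @export
compute_indexes <- function(cohort) {
  need <- c("height", "sitting_height", "metacarpal_length",
            "metacarpal_breadth")
  for (f in need) {
    if (!f %in% names(cohort)) stop("missing anthropometry field: ", f)
    v <- cohort[[f]]
    if (!is.numeric(v)) stop("anthropometry field is not numeric: ", f)
    if (any(!is.na(v) & v <= 0)) stop("non-positive values in field: ", f)
  }
  h <- cohort$height; s <- cohort$sitting_height
  if (any(!is.na(h) & !is.na(s) & s >= h)) {
    warning("sitting_height >= height for some subjects")
  }
  if ("leg_length" %in% names(cohort)) {
    ll <- cohort$leg_length
    bad <- !is.na(ll) & !is.na(h) & !is.na(s) & abs(ll - (h - s)) > 0.5
    if (any(bad)) {
      warning(sum(bad), " subject(s) with leg_length inconsistent with ",
              "height - sitting_height by > 0.5 cm")
    }
  }
  data.frame(
    skelic = (h - s) / s * 100,
    mc_length_breadth = cohort$metacarpal_length /
      cohort$metacarpal_breadth * 100,
    mc_length_height = cohort$metacarpal_length / h * 100
  )
}

#' Percentage of positively stained cells
#'
#' The immunohistochemistry score for a cartilage zone:
#' `positive / (positive + negative) * 100`. Zone membership (superficial,
#' middle, deep) is a label carried alongside the counts; it does not enter
#' the formula.
#'
#' @param positive,negative Non-negative cell counts (vectorized).
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_positive(30, 70) # 30
#' @export
percent_positive <- function(positive, negative) {
  if (any(!is.finite(positive)) || any(!is.finite(negative)) ||
      any(positive < 0) || any(negative < 0)) {
    stop("counts must be finite and non-negative")
  }
  total <- positive + negative
  if (any(total == 0)) stop("zero total cell count")
  positive / total * 100
}

#' Read immunohistochemistry counts
#'
#' Small TSV with columns `sample`, `zone` (superficial/middle/deep),
#' `positive`, `negative`. Adds a `pct_positive` column via
#' [percent_positive()].
#' @param path File path.
#' @return data.frame.
#' @export
read_ihc <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "zone", "positive", "negative")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("IHC file missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$zone), c("superficial", "middle", "deep"))
  if (length(bad)) stop("unknown zone label(s): ", paste(bad, collapse = ", "))
  x$pct_positive <- percent_positive(x$positive, x$negative)
  x
}

#' Read a subject-level cohort file
#'
#' Delimited text (TSV by default, CSV accepted by extension or `sep`), one
#' subject per row, header naming the fields. Required columns: `id`,
#' `group` (control/KBD), `grade` (none/I/II). Anthropometry columns are
#' validated numeric with the offending line reported; questionnaire items are
#' tri-state (1/0/blank). Unknown columns are preserved untouched. Missing
#' values are kept missing, never imputed.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` chooses by extension (`.csv` = comma).
#' @return A data.frame of subjects (class `c("kbd_cohort", "data.frame")`).
#' @export
read_cohort <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "", na.strings = character())
  validate_cohort(coerce_cohort(x, path))
}

# convert character columns read from file to typed columns, with line numbers
# in errors (line 1 is the header)
coerce_cohort <- function(x, path = "<cohort>") {
  need <- c("id", "group", "grade")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  blank_to_na <- function(v) { v[v == ""] <- NA_character_; v }
  x[] <- lapply(x, blank_to_na)
  dup <- x$id[duplicated(x$id)]
  if (length(dup)) {
    lines <- which(x$id %in% dup) + 1L
    stop("duplicate subject id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "),
         " (lines ", paste(lines, collapse = ", "), ")")
  }
  for (f in intersect(kbd_anthropometry, names(x))) {
    v <- suppressWarnings(as.numeric(x[[f]]))
    bad <- which(is.na(v) & !is.na(x[[f]]))
    if (length(bad)) {
      stop("non-numeric value for ", f, " in ", path,
           " at line ", bad[1] + 1L, ": '", x[[f]][bad[1]], "'")
    }
    x[[f]] <- v
  }
  for (f in intersect(kbd_all_items, names(x))) {
    v <- x[[f]]
    ok <- is.na(v) | v %in% c("0", "1")
    if (!all(ok)) {
      stop("sign column ", f, " in ", path, " must be 1/0/blank; line ",
           which(!ok)[1] + 1L, " has '", v[which(!ok)[1]], "'")
    }
    x[[f]] <- as.integer(v)
  }
  class(x) <- c("kbd_cohort", "data.frame")
  x
}

#' Validate cohort invariants
#'
#' Errors on structural violations (unknown group/grade codes, grade present
#' for controls or absent for patients); warns on soft anthropometric
#' violations (sitting height not below height, metacarpal breadth not below
#' length, inconsistent leg length).
#'
#' @param cohort A cohort data.frame.
#' @return The cohort, invisibly classed `kbd_cohort`.
#' @export
validate_cohort <- function(cohort) {
  bad_group <- setdiff(unique(cohort$group), c("control", "KBD"))
  if (length(bad_group)) stop("unknown group value(s): ",
                              paste(bad_group, collapse = ", "))
  bad_grade <- setdiff(unique(as.character(cohort$grade)), c("none", "I", "II"))
  if (length(bad_grade)) stop("unknown grade value(s): ",
                              paste(bad_grade, collapse = ", "))
  mismatch <- (cohort$group == "control") != (cohort$grade == "none")
  if (any(mismatch)) {
    stop("grade must be 'none' exactly for controls; offending id(s): ",
         paste(utils::head(cohort$id[mismatch], 5), collapse = ", "))
  }
  for (f in intersect(kbd_anthropometry, names(cohort))) {
    if (any(!is.na(cohort[[f]]) & cohort[[f]] <= 0)) {
      stop("non-positive values in field: ", f)
    }
  }
  if (all(c("height", "sitting_height") %in% names(cohort))) {
    bad <- !is.na(cohort$height) & !is.na(cohort$sitting_height) &
      cohort$sitting_height >= cohort$height
    if (any(bad)) warning("sitting_height >= height for id(s): ",
                          paste(utils::head(cohort$id[bad], 5), collapse = ", "))
  }
  if (all(c("metacarpal_length", "metacarpal_breadth") %in% names(cohort))) {
    bad <- !is.na(cohort$metacarpal_length) &
      !is.na(cohort$metacarpal_breadth) &
      cohort$metacarpal_breadth >= cohort$metacarpal_length
    if (any(bad)) warning("metacarpal_breadth >= metacarpal_length for id(s): ",
                          paste(utils::head(cohort$id[bad], 5), collapse = ", "))
  }
  if (!inherits(cohort, "kbd_cohort")) {
    class(cohort) <- c("kbd_cohort", "data.frame")
  }
  invisible(cohort)
}

#' Write a cohort file
#'
#' Inverse of [read_cohort()]: UTF-8 delimited text, blank cells for missing
#' values, no quoting. `read_cohort(write_cohort(x))` restores `x` exactly.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @param sep Field separator; `NULL` chooses by extension as in
#'   [read_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    "," else "\t"
  utils::write.table(cohort, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
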