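#' Construct a long-format labeled dataset
#'
#' The universal input of the package: one row per observation, with a
#' numeric measurement (`value`), a treatment label (`treatment`), an
#' optional nuisance stratum (`stratum`) and an optional pair/subject id
#' (`block`). All test functions accept any data frame with these columns;
#' `labeled_data()` validates the shape and fixes the ordering of treatment
#' levels, which determines the sign of directional statistics (the first
#' level plays the role of sample *x* in `x̄ − ȳ`).
#'
#' @param value Numeric vector of measurements.
#' @param treatment Treatment label per observation (coerced to factor; the
#'   order of `levels`, or of first appearance, is the treatment ordering).
#' @param stratum Optional stratum label per observation.
#' @param block Optional pair/subject id per observation. Within a block each
#'   treatment may appear at most once.
#' @param levels Optional explicit ordering of treatment levels.
#'
#' @return A tibble with columns `value`, `treatment` and, when supplied,
#'   `stratum` and `block`.
#' @examples
#' labeled_data(c(3.4, 3.7, 3.0, 3.3), c("a", "a", "b", "b"))
#' @export
labeled_data <- function(value, treatment, stratum = NULL, block = NULL,
                         levels = NULL) {
  if (!is.numeric(value)) abort("`value` must be numeric.")
  if (length(treatment) != length(value)) {
    abort("`treatment` must have one label per observation.")
  }
  treatment <- if (is.null(levels)) {
    factor(treatment, levels = unique(as.character(treatment)))
  } else {
    factor(treatment, levels = levels)
  }
  if (anyNA(treatment)) abort("every observation needs a treatment label.")
  out <- tibble(value = as.numeric(value), treatment = treatment)
  if (!is.null(stratum)) out$stratum <- factor(stratum, levels = unique(as.character(stratum)))
  if (!is.null(block)) out$block <- as.character(block)
  validate_labeled_data(out)
}

validate_labeled_data <- function(data) {
  if (!is.data.frame(data)) abort("expected a data frame.")
  if (!all(c("value", "treatment") %in% names(data))) {
    abort("data must have `value` and `treatment` columns.")
  }
  if (!is.numeric(data$value)) abort("`value` must be numeric.")
  if (anyNA(data$value)) abort("`value` must not contain missing values.")
  if (!is.factor(data$treatment)) {
    data$treatment <- factor(data$treatment, levels = unique(as.character(data$treatment)))
  }
  if ("stratum" %in% names(data) && !is.factor(data$stratum)) {
    data$stratum <- factor(data$stratum, levels = unique(as.character(data$stratum)))
  }
  if ("block" %in% names(data)) {
    dup <- duplicated(data[, intersect(c("block", "treatment", "stratum"), names(data))])
    if (any(dup)) abort("within a block each treatment may appear at most once.")
  }
  as_tibble(data)
}

#' Read or write labeled data as CSV
#'
#' Long-format CSV with header `value,treatment` and optional `stratum` and
#' `block` columns is the canonical file interchange format.
#'
#' @param file Path to a CSV file.
#' @param data A labeled data frame (see [labeled_data()]).
#' @return `read_labeled_csv()` returns a validated tibble;
#'   `write_labeled_csv()` returns `data` invisibly.
#' @export
read_labeled_csv <- function(file) {
  raw <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  if (!all(c("value", "treatment") %in% names(raw))) {
    abort("CSV must have columns `value` and `treatment`.")
  }
  keep <- intersect(c("value", "treatment", "stratum", "block"), names(raw))
  validate_labeled_data(raw[keep])
}

#' @rdname read_labeled_csv
#' @export
write_labeled_csv <- function(data, file) {
  data <- validate_labeled_data(data)
  readr::write_csv(data, file, progress = FALSE)
  invisible(data)
}

# split values by treatment, in treatment-level order
split_by_treatment <- function(data) {
  split(data$value, data$treatment)
}

# values of block differences: first treatment level minus second, ordered by block
block_differences <- function(data) {
  if (!"block" %in% names(data)) {
    abort("matched-pair tests need a `block` column identifying pairs.")
  }
  lv <- levels(data$treatment)
  if (length(lv) != 2) abort("matched-pair tests need exactly two treatment levels.")
  wide <- split(data, data$block)
  d <- vapply(wide, function(b) {
    if (nrow(b) != 2 || length(unique(b$treatment)) != 2) {
      abort("every block must contain both treatments exactly once.")
    }
    b$value[b$treatment == lv[1]] - b$value[b$treatment == lv[2]]
  }, numeric(1))
  d[order(names(d))]
}
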