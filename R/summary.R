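#' Descriptive summary statistics of a sample
#'
#' Mean, population standard deviation (divisor n, the convention of the
#' printed summary tables) and range. With a single value the SD and range
#' are reported as missing rather than zero, matching how a single-specimen
#' ligament (the DOB) is tabulated.
#'
#' @param values numeric vector, finite, length >= 1.
#' @return an object of class `summary_stats`: list with `n`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
aggregate_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stopf("empty-data error: no values to aggregate")
  if (!all(is.finite(values))) stopf("values must be finite")
  n <- length(values)
  structure(list(n = n, mean = mean(values),
                 sd = if (n > 1L) pop_sd(values) else NA_real_,
                 min = if (n > 1L) min(values) else NA_real_,
                 max = if (n > 1L) max(values) else NA_real_),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats: n = %d, mean %.4g, sd %s, range [%s, %s]>\n",
              x$n, x$mean,
              if (is.na(x$sd)) "-" else sprintf("%.4g", x$sd),
              if (is.na(x$min)) "-" else sprintf("%.4g", x$min),
              if (is.na(x$max)) "-" else sprintf("%.4g", x$max)))
  invisible(x)
}

#' Summary table in the Mean / SD / Range layout
#'
#' Aggregates per-specimen records into one row per group and quantity
#' with mean, population SD and range columns, the layout of the
#' morphometry and tensile summary tables. Rounding is half away from
#' zero at the requested precision; full precision is retained when
#' `digits = NULL`.
#'
#' @param records a `data.frame` of homogeneous records, or a list of
#'   `data.frame`s with identical columns (mixed record types are
#'   rejected).
#' @param values character vector of numeric columns to summarise;
#'   defaults to every numeric column.
#' @param group grouping column, default `"ligament_id"`.
#' @param digits rounding digits for the output, or `NULL` for none.
#' @return `data.frame` with columns `group`, `quantity`, `n`, `mean`,
#'   `sd`, `min`, `max`; SD and range are `NA` for single-record groups.
#' @export
make_table <- function(records, values = NULL, group = "ligament_id",
                       digits = 2) {
  if (is.list(records) && !is.data.frame(records)) {
    if (length(records) == 0L) {
      warnf("no records to summarise; returning an empty table")
      return(data.frame(group = character(0), quantity = character(0),
                        n = integer(0), mean = numeric(0), sd = numeric(0),
                        min = numeric(0), max = numeric(0)))
    }
    if (!all(vapply(records, is.data.frame, TRUE)))
      stopf("type error: records must be data.frames")
    cols <- lapply(records, names)
    if (!all(vapply(cols, identical, TRUE, cols[[1L]])))
      stopf("type error: mixed record types (column sets differ)")
    records <- do.call(rbind, records)
  }
  if (!is.data.frame(records)) stopf("type error: records must be a data.frame")
  if (nrow(records) == 0L) {
    warnf("no records to summarise; returning an empty table")
    return(data.frame(group = character(0), quantity = character(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0),
                      min = numeric(0), max = numeric(0)))
  }
  if (!group %in% names(records)) stopf("grouping column '%s' missing", group)
  if (is.null(values))
    values <- names(records)[vapply(records, is.numeric, TRUE)]
  values <- setdiff(values, group)
  rows <- list()
  for (g in unique(records[[group]])) {
    sub <- records[records[[group]] == g, , drop = FALSE]
    for (q in values) {
      x <- sub[[q]]
      x <- x[is.finite(x)]
      if (length(x) == 0L) next
      st <- aggregate_stats(x)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, quantity = q, n = st$n, mean = st$mean, sd = st$sd,
        min = st$min, max = st$max, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(digits))
    for (cn in c("mean", "sd", "min", "max"))
      out[[cn]] <- round_half_up(out[[cn]], digits)
  names(out)[1L] <- group
  rownames(out) <- NULL
  out
}

#' Reference per-specimen tensile results
#'
#' The published per-forearm tensile test results for the four IOM
#' ligaments across five cadaveric forearms (CSA from optical CCD-laser
#' measurement; first peak and ultimate forces, stiffness and ultimate
#' strain from the force-displacement curves). Used as the input fixture
#' for reproducing the printed descriptive summary rows.
#'
#' @return `data.frame` with columns `ligament_id`, `forearm`, `csa`,
#'   `first_peak_force`, `ultimate_force`, `stiffness`, `ultimate_strain`.
#' @export
reference_tensile_results <- function() {
  path <- system.file("extdata", "tensile_specimens.csv", package = "iomorph",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
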