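#' Tensile force-displacement curve
#'
#' A recorded (or synthetic) ramp-to-failure curve: grip displacement in mm
#' against axial force in N, with the initial grip-to-grip gauge length used
#' to convert displacement to engineering strain.
#'
#' @param displacement numeric, monotone non-decreasing (mm).
#' @param force numeric, same length (N).
#' @param gauge_length initial specimen length (mm), > 0.
#' @param specimen_id,ligament_id labels.
#' @return an object of class `tensile_curve`.
#' @export
tensile_curve <- function(displacement, force, gauge_length,
                          specimen_id = "", ligament_id = "") {
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force))
    stopf("displacement and force must have the same length")
  if (length(force) < 2L) stopf("a tensile curve needs at least 2 samples")
  if (length(force) < 10L)
    warnf("tensile curve has only %d samples; analyses expect >= 10",
          length(force))
  if (!all(is.finite(force)) || !all(is.finite(displacement)))
    stopf("tensile curve contains non-finite values")
  if (any(diff(displacement) < -1e-6))
    stopf("ordering error: displacement decreases beyond tolerance 1e-6 mm")
  if (!is.numeric(gauge_length) || length(gauge_length) != 1L ||
      !is.finite(gauge_length) || gauge_length <= 0)
    stopf("gauge_length must be a single positive number (mm)")
  structure(list(displacement = displacement, force = force,
                 gauge_length = as.numeric(gauge_length),
                 specimen_id = as.character(specimen_id)[1L],
                 ligament_id = as.character(ligament_id)[1L]),
            class = "tensile_curve")
}

#' @export
print.tensile_curve <- function(x, ...) {
  cat(sprintf(
    "<tensile_curve %s/%s: %d samples, displacement %.3f-%.3f mm, max force %.2f N, gauge %.1f mm>\n",
    x$ligament_id, x$specimen_id, length(x$force),
    min(x$displacement), max(x$displacement), max(x$force), x$gauge_length))
  invisible(x)
}

#' Read a tensile curve from CSV
#'
#' The file carries metadata in leading comment lines (`# key: value`;
#' `gauge_length` is required, `specimen_id` and `ligament_id` optional)
#' followed by a header row and `displacement,force` columns. Rows with
#' non-finite values are dropped with a warning stating the count. Sample
#' order is never changed.
#'
#' @param path CSV file path.
#' @return a `tensile_curve`.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stopf("curve file not found: %s", path)
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (grepl(":", kv, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[[key]] <- val
    }
  }
  if (is.null(meta$gauge_length))
    stopf("metadata error: curve file %s lacks a 'gauge_length' header", path)
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  need <- c("displacement", "force")
  if (!all(need %in% names(df)))
    stopf("curve file %s needs columns 'displacement' and 'force'", path)
  ok <- is.finite(df$displacement) & is.finite(df$force)
  if (any(!ok))
    warnf("dropped %d row(s) with non-finite values from %s", sum(!ok), path)
  df <- df[ok, , drop = FALSE]
  tensile_curve(df$displacement, df$force,
                gauge_length = as.numeric(meta$gauge_length),
                specimen_id = meta$specimen_id %||% "",
                ligament_id = meta$ligament_id %||% "")
}

#' Write a tensile curve to CSV
#'
#' Inverse of [read_curve()]: metadata comment lines, then a
#' `displacement,force` table at full precision.
#'
#' @param curve a `tensile_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gauge_length: %.10g", curve$gauge_length),
    sprintf("# specimen_id: %s", curve$specimen_id),
    sprintf("# ligament_id: %s", curve$ligament_id),
    "displacement,force",
    sprintf("%.10g,%.10g", curve$displacement, curve$force)), con)
  invisible(path)
}

#' Trim leading pre-conditioning cycles from raw test data
#'
#' Tensile protocols commonly run cyclic pre-conditioning before the ramp
#' to failure. Cycles show up as displacement reversals; this keeps only
#' the final monotone non-decreasing run, which is the failure ramp.
#'
#' @param displacement,force raw recorded series (mm, N).
#' @param tol reversal tolerance (mm).
#' @return list with the trimmed `displacement` and `force`.
#' @export
trim_preconditioning <- function(displacement, force, tol = 1e-6) {
  if (length(displacement) != length(force))
    stopf("displacement and force must have the same length")
  rev <- which(diff(displacement) < -tol)
  start <- if (length(rev)) max(rev) + 1L else 1L
  keep <- start:length(displacement)
  list(displacement = displacement[keep], force = force[keep])
}
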