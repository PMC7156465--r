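#' Landmark roles of an IOM ligament
#'
#' The central band (CB), accessory band (AB) and distal oblique bundle
#' (DOB) are annotated at the proximal and distal insertion points on both
#' bones (`R_p`, `R_d`, `U_p`, `U_d`). The narrow dorsal oblique accessory
#' cord (DOAC) carries a single mid-fibre pair (`R_m`, `U_m`).
#'
#' @param ligament_id one of `"CB"`, `"AB"`, `"DOAC"`, `"DOB"`.
#' @return character vector of role names.
#' @export
landmark_roles <- function(ligament_id) {
  switch(ligament_id,
         CB = , AB = , DOB = c("R_p", "R_d", "U_p", "U_d"),
         DOAC = c("R_m", "U_m"),
         stopf("unknown ligament id '%s'", ligament_id))
}

#' Named attachment landmarks of one ligament
#'
#' @param ligament_id one of `"CB"`, `"AB"`, `"DOAC"`, `"DOB"`.
#' @param points named list of 3D points (mm); names must be exactly the
#'   roles returned by [landmark_roles()] for this ligament.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(ligament_id, points) {
  roles <- landmark_roles(ligament_id)
  if (!setequal(names(points), roles) || length(points) != length(roles))
    stopf("landmark schema error: %s requires exactly roles {%s}, got {%s}",
          ligament_id, paste(roles, collapse = ", "),
          paste(names(points), collapse = ", "))
  pts <- lapply(points[roles], vec3, what = "landmark")
  pm <- do.call(rbind, pts)
  d <- as.matrix(stats::dist(pm))
  if (any(d[upper.tri(d)] <= 1e-6))
    stopf("landmark validation error: two landmarks of %s coincide (within 1e-6 mm)",
          ligament_id)
  structure(list(ligament_id = ligament_id, points = pts),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set %s: %s>\n", x$ligament_id,
              paste(names(x$points), collapse = ", ")))
  invisible(x)
}

#' Read ligament landmarks from a JSON file
#'
#' The file holds an array of objects, each with a `ligament` id and a
#' `points` map from role name to `[x, y, z]` in mm. Role sets inconsistent
#' with the ligament id are rejected; landmark order within a set is the
#' canonical role order, never the file order.
#'
#' @param path JSON file path.
#' @return list of `landmark_set`, in file order.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(js) || length(js) == 0L)
    stopf("landmark file is empty or not a JSON array: %s", path)
  lapply(js, function(rec) {
    if (is.null(rec$ligament) || is.null(rec$points))
      stopf("landmark schema error: each record needs 'ligament' and 'points'")
    landmark_set(rec$ligament, lapply(rec$points, unlist))
  })
}

#' Write ligament landmarks to a JSON file
#'
#' @param landmarks a `landmark_set` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  recs <- lapply(landmarks, function(lm) {
    list(ligament = lm$ligament_id, points = lm$points)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a rigid transform to a landmark set
#'
#' @param lm a `landmark_set`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 offset (mm).
#' @return the transformed `landmark_set`.
#' @export
transform_landmarks <- function(lm, rotation = diag(3), translation = c(0, 0, 0)) {
  t0 <- vec3(translation, "translation")
  pts <- lapply(lm$points, function(p) as.numeric(rotation %*% p) + t0)
  landmark_set(lm$ligament_id, pts)
}
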