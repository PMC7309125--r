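#' The twelve anatomical landmark names
#'
#' Order used throughout the package: right/left endocanthion and
#' exocanthion (inner/outer eye corners), nasion, pronasale, subnasale,
#' gnathion, right/left cheilion (mouth corners), labiale superius and
#' inferius. Suffixes `_r`/`_l` denote the subject's anatomical right/left;
#' in the scanner frame (face looking toward +z, +y up) anatomical right is
#' at -x.
#'
#' @return character vector of length 12.
#' @export
landmark_names <- function() {
  c("en_r", "en_l", "ex_r", "ex_l", "n", "prn", "sn", "gn",
    "ch_r", "ch_l", "ls", "li")
}

#' Named 3D landmark set
#'
#' A 12 x 3 matrix (mm) with the twelve landmark names as row names; rows are
#' reordered into the canonical [landmark_names()] order.
#'
#' @param points numeric 12 x 3 matrix with row names, or a named list of
#'   length-3 points.
#' @return matrix of class `landmark_set3d`.
#' @export
landmark_set3d <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  nm <- landmark_names()
  if (is.null(rownames(points)) || !setequal(rownames(points), nm))
    stop("landmark_set3d requires exactly the 12 landmark names, got: ",
         paste(rownames(points), collapse = ", "))
  if (ncol(points) != 3 || !all(is.finite(points)))
    stop("landmarks must be finite 3D points")
  points <- points[nm, , drop = FALSE]
  colnames(points) <- c("x", "y", "z")
  class(points) <- c("landmark_set3d", class(points))
  points
}

#' @export
print.landmark_set3d <- function(x, ...) {
  cat("landmark_set3d (mm):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Read / write landmark files
#'
#' CSV files have header `name,x,y,z` with coordinates in mm (written with 6
#' decimals); JSON files are an object `{"name": [x, y, z], ...}`.
#'
#' @param path file path (`.csv` or `.json`).
#' @return [read_landmarks()]: a [landmark_set3d()].
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- do.call(rbind, obj)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "x", "y", "z") %in% names(df)))
      stop("landmark CSV must have columns name,x,y,z: ", path)
    pts <- as.matrix(df[, c("x", "y", "z")])
    rownames(pts) <- df$name
  }
  landmark_set3d(pts)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set3d()].
#' @export
write_landmarks <- function(lm, path) {
  lm <- landmark_set3d(lm)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- stats::setNames(
      lapply(seq_len(nrow(lm)), function(i) unname(round(lm[i, ], 6))),
      rownames(lm))
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  } else {
    lines <- c("name,x,y,z",
               sprintf("%s,%.6f,%.6f,%.6f", rownames(lm),
                       lm[, 1], lm[, 2], lm[, 3]))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(path)
}
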