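#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the points from their
#' centroid -- the standard scale measure of geometric morphometrics.
#'
#' @param coords k x 3 coordinate matrix (a [landmark_set3d()] works).
#' @return positive scalar.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  cs <- sqrt(sum(sweep(coords, 2, ctr)^2))
  if (cs < 1e-12)
    stop("degenerate configuration: centroid size is zero, cannot scale")
  cs
}

#' Least-squares rigid alignment (orthogonal Procrustes)
#'
#' SVD (Kabsch) solution for the proper rigid transform minimizing the sum of
#' squared distances from the transformed source to the target; reflections
#' are disallowed (anatomical landmarks are chiral), so the rotation has
#' determinant +1.
#'
#' @param source,target k x 3 matrices, k >= 3, matching row order.
#' @return list with `rotation` (3 x 3, det +1) and `translation` (length 3);
#'   the aligned source is `source %*% t(rotation) + translation` (row-wise
#'   application of `p' = R p + t`).
#' @export
rigid_align <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) != nrow(target) || ncol(source) != 3 || ncol(target) != 3)
    stop("source and target must be matching k x 3 matrices")
  if (nrow(source) < 3) stop("need at least 3 points")
  cs <- colMeans(source)
  ct <- colMeans(target)
  X <- sweep(source, 2, cs)
  Y <- sweep(target, 2, ct)
  M <- t(Y) %*% X
  sv <- svd(M)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate configuration (rank < 2 after centering)")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, translation = as.numeric(ct - R %*% cs))
}

#' Generalized Procrustes alignment
#'
#' Each configuration is scaled once to unit centroid size (about its
#' centroid), then the configurations are iteratively aligned by proper rigid
#' transforms: every sample is aligned to the current mean and the mean is
#' recomputed, until the mean moves by less than `tol` (Frobenius norm) or
#' `max_iter` is reached. No rescaling happens inside the loop. The mean is
#' initialized from the first (centered, unit-size) sample, so its
#' orientation follows the first sample; the shape of the mean and all
#' Procrustes distances are order-invariant.
#'
#' @param samples list (>= 2) of k x 3 matrices with identical row-name sets
#'   (row names optional but, when present, must match; rows are reordered to
#'   the first sample's order).
#' @param tol convergence threshold on the mean-shape change, default 1e-8.
#' @param max_iter maximum iterations, default 100.
#' @return object of class `gpa_result`: list with `aligned` (list of k x 3,
#'   unit centroid size), `mean_shape` (k x 3), `distances` (per-sample
#'   Procrustes distance from the mean) and `n_iterations`.
#' @export
gpa <- function(samples, tol = 1e-8, max_iter = 100) {
  if (length(samples) < 2) stop("need at least two samples")
  samples <- lapply(samples, as.matrix)
  ref_names <- rownames(samples[[1]])
  if (!is.null(ref_names)) {
    samples <- lapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      if (is.null(rownames(s)) || !setequal(rownames(s), ref_names))
        stop("sample ", i, " has a different landmark label set")
      s[ref_names, , drop = FALSE]
    })
  }
  k <- nrow(samples[[1]])
  if (any(vapply(samples, nrow, 0L) != k))
    stop("all samples must have the same number of landmarks")
  scaled <- lapply(samples, function(s) {
    ctr <- colMeans(s)
    sweep(s, 2, ctr) / centroid_size(s)
  })
  mean_shape <- scaled[[1]]
  aligned <- scaled
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    aligned <- lapply(scaled, function(s) {
      tr <- rigid_align(s, mean_shape)
      transform_points(s, tr$rotation, tr$translation)
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  distances <- vapply(aligned, function(a) sqrt(sum((a - mean_shape)^2)), 0)
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 distances = distances, n_iterations = n_iter),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf(
    "gpa_result: %d samples, %d landmarks, %d iterations\nProcrustes distances from mean: %s\n",
    length(x$aligned), nrow(x$mean_shape), x$n_iterations,
    paste(sprintf("%.4g", x$distances), collapse = " ")))
  invisible(x)
}

#' Procrustes distance of each sample from the mean shape
#'
#' Root summed squared distance between each aligned configuration and the
#' mean configuration.
#'
#' @param r a [gpa()] result.
#' @return numeric vector, one distance per sample.
#' @export
procrustes_distance_from_mean <- function(r) {
  stopifnot(inherits(r, "gpa_result"))
  vapply(r$aligned, function(a) sqrt(sum((a - r$mean_shape)^2)), 0)
}

#' Landmark error report
#'
#' Per-landmark Euclidean distances (mm) between two landmark sets over a
#' list of subjects, summarized as per-landmark mean and standard deviation
#' (sample, n-1 convention), an overall mean/SD over all (subject, landmark)
#' pairs, and per-subject mean errors.
#'
#' @param a,b equal-length lists of [landmark_set3d()] with matching names.
#' @return object of class `error_report`: list with `distances`
#'   (subjects x 12 matrix), `per_landmark` (data.frame landmark/mean/sd),
#'   `overall` (list mean/sd) and `per_subject` (numeric).
#' @export
landmark_errors <- function(a, b) {
  if (length(a) != length(b)) stop("landmark set lists differ in length")
  d <- t(vapply(seq_along(a), function(i) {
    ai <- landmark_set3d(a[[i]])
    bi <- landmark_set3d(b[[i]])
    sqrt(rowSums((unclass(ai) - unclass(bi))^2))
  }, stats::setNames(numeric(12), landmark_names())))
  error_report_from_distances(d)
}

error_report_from_distances <- function(d) {
  per_landmark <- data.frame(
    landmark = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, function(x) if (length(x) > 1) stats::sd(x) else 0),
    row.names = NULL)
  structure(list(
    distances = d,
    per_landmark = per_landmark,
    overall = list(mean = mean(d),
                   sd = if (length(d) > 1) stats::sd(as.numeric(d)) else 0),
    per_subject = rowMeans(d)), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  df <- rbind(x$per_landmark,
              data.frame(landmark = "Overall", mean = x$overall$mean,
                         sd = x$overall$sd))
  df$mean <- sprintf("%.2f", df$mean)
  df$sd <- sprintf("(%.2f)", df$sd)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Landmark errors averaged over two observers
#'
#' For each subject and landmark the distance is the mean of the distances
#' from the method's landmark to each observer's ground truth; aggregation
#' then proceeds as in [landmark_errors()].
#'
#' @param m list of method [landmark_set3d()]s.
#' @param obs1,obs2 aligned lists of observer ground-truth sets.
#' @return an `error_report`.
#' @export
average_over_observers <- function(m, obs1, obs2) {
  d1 <- landmark_errors(m, obs1)$distances
  d2 <- landmark_errors(m, obs2)$distances
  error_report_from_distances((d1 + d2) / 2)
}

#' Write an error report
#'
#' CSV mirrors the per-landmark mean (SD) table layout with a final Overall
#' row; JSON carries the full report.
#'
#' @param report an `error_report`.
#' @param path output path (`.csv` or `.json`).
#' @return invisibly, `path`.
#' @export
write_error_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(per_landmark = report$per_landmark, overall = report$overall,
           per_subject = report$per_subject),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- rbind(report$per_landmark,
                data.frame(landmark = "Overall", mean = report$overall$mean,
                           sd = report$overall$sd))
    lines <- c("landmark,mean_mm,sd_mm",
               sprintf("%s,%.6f,%.6f", df$landmark, df$mean, df$sd))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(path)
}
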