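#' Virtual pinhole camera
#'
#' A camera is defined by its position, focal point, up vector, vertical view
#' angle and image size. Pixels are square; the horizontal field of view
#' follows from the aspect ratio. Image coordinates have their origin at the
#' top-left corner, x to the right, y down, and pixel `(i, j)` (0-based) has
#' its center at `(i + 0.5, j + 0.5)`.
#'
#' @param position camera position, length-3 (mm).
#' @param focal_point point the camera looks at, length-3 (mm).
#' @param up approximate up direction (need not be orthogonal to the view
#'   direction, but must not be parallel to it).
#' @param view_angle vertical full view angle, degrees, in (0, 180).
#' @param image_size `c(width, height)` in pixels.
#' @return an object of class `pinhole_camera`.
#' @export
pinhole_camera <- function(position, focal_point, up = c(0, 1, 0),
                           view_angle = 50, image_size = c(512, 512)) {
  position <- as.numeric(position)
  focal_point <- as.numeric(focal_point)
  up <- as.numeric(up)
  stopifnot(length(position) == 3, length(focal_point) == 3, length(up) == 3)
  if (!all(is.finite(c(position, focal_point, up))))
    stop("camera parameters must be finite")
  d <- focal_point - position
  if (sqrt(sum(d^2)) < 1e-12) stop("camera position equals focal point")
  fn <- d / sqrt(sum(d^2))
  un <- up / sqrt(sum(up^2))
  if (abs(sum(fn * un)) >= 1 - 1e-9)
    stop("up vector is parallel to the view direction")
  if (!(view_angle > 0 && view_angle < 180))
    stop("view_angle must be in (0, 180) degrees")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 1))
    stop("image_size must be two positive integers")
  structure(list(position = position, focal_point = focal_point, up = up,
                 view_angle = view_angle, image_size = image_size),
            class = "pinhole_camera")
}

#' @export
print.pinhole_camera <- function(x, ...) {
  cat(sprintf(
    "pinhole_camera: pos (%.1f, %.1f, %.1f) -> focal (%.1f, %.1f, %.1f), %g deg, %dx%d px\n",
    x$position[1], x$position[2], x$position[3],
    x$focal_point[1], x$focal_point[2], x$focal_point[3],
    x$view_angle, x$image_size[1], x$image_size[2]))
  invisible(x)
}

# Orthonormal camera frame and per-pixel image-plane scale. s is the
# image-plane offset per pixel at unit distance along the forward axis, so the
# vertical full extent of the image is H * s = 2 * tan(view_angle / 2).
camera_basis <- function(camera) {
  fwd <- camera$focal_point - camera$position
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * camera$up[3] - fwd[3] * camera$up[2],
             fwd[3] * camera$up[1] - fwd[1] * camera$up[3],
             fwd[1] * camera$up[2] - fwd[2] * camera$up[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])
  H <- camera$image_size[2]
  s <- tan(camera$view_angle / 2 * pi / 180) / (H / 2)
  list(fwd = fwd, right = right, up = upv, s = s,
       W = camera$image_size[1], H = H)
}

#' Ray through a pixel
#'
#' @param camera a [pinhole_camera()].
#' @param pixel `c(x, y)` continuous image coordinates (pixel `(i, j)` center
#'   is `(i + 0.5, j + 0.5)`).
#' @return a `ray`: list with unit `direction` and `origin` at the camera
#'   position.
#' @export
pixel_ray <- function(camera, pixel) {
  b <- camera_basis(camera)
  if (pixel[1] < 0 || pixel[1] > b$W || pixel[2] < 0 || pixel[2] > b$H)
    stop("pixel outside image bounds")
  d <- b$fwd + b$right * (pixel[1] - b$W / 2) * b$s -
    b$up * (pixel[2] - b$H / 2) * b$s
  make_ray(camera$position, d)
}

#' Construct a ray
#' @param origin length-3 origin (mm).
#' @param direction length-3 direction; normalized internally.
#' @return a `ray` object.
#' @export
make_ray <- function(origin, direction) {
  origin <- as.numeric(origin)
  direction <- as.numeric(direction)
  len <- sqrt(sum(direction^2))
  if (len < 1e-12) stop("ray direction has zero length")
  structure(list(origin = origin, direction = direction / len), class = "ray")
}

#' Project a 3D point into image coordinates
#'
#' Inverse of [pixel_ray()] up to depth. The point must lie strictly in front
#' of the camera plane.
#'
#' @param camera a [pinhole_camera()].
#' @param p length-3 point (mm).
#' @return `c(x, y)` image coordinates.
#' @export
project_point <- function(camera, p) {
  b <- camera_basis(camera)
  d <- as.numeric(p) - camera$position
  zf <- sum(d * b$fwd)
  if (zf <= 1e-12) stop("point at or behind the camera plane")
  c(b$W / 2 + sum(d * b$right) / (zf * b$s),
    b$H / 2 - sum(d * b$up) / (zf * b$s))
}

#' Initial five-camera array
#'
#' Places five wide-angle cameras around the mesh to locate the face coarsely.
#' All cameras share the mesh centroid as focal point, a 50 degree vertical
#' view angle and +y up. The central camera sits 600 mm from the centroid in
#' +z (the scanner frame points down -z with +y vertically up, so a scanned
#' face looks toward the central camera); the other four are the central
#' camera translated 600 mm in +x, +y, -x and -y. The central camera is
#' listed first, then +x, +y, -x, -y.
#'
#' @param mesh a non-empty [triangle_mesh()].
#' @param image_size pixels, `c(width, height)`.
#' @param distance_mm offset distance, default 600.
#' @param view_angle_deg vertical view angle, default 50.
#' @return list of five [pinhole_camera()] objects.
#' @export
initial_camera_array <- function(mesh, image_size = c(512, 512),
                                 distance_mm = 600, view_angle_deg = 50) {
  ctr <- mesh_centroid(mesh)
  offsets <- rbind(c(0, 0, distance_mm),
                   c(distance_mm, 0, distance_mm),
                   c(0, distance_mm, distance_mm),
                   c(-distance_mm, 0, distance_mm),
                   c(0, -distance_mm, distance_mm))
  lapply(seq_len(5), function(i)
    pinhole_camera(position = ctr + offsets[i, ], focal_point = ctr,
                   up = c(0, 1, 0), view_angle = view_angle_deg,
                   image_size = image_size))
}

#' Frontal camera from facial landmarks
#'
#' Computes the face-centered camera used for the refined renderings. The
#' focal point is the pronasale (`prn`); the camera sits `distance_mm` from it
#' along the outward facial direction `(ch_r - ex_l) x (ch_l - ex_r)` (cross
#' product of the two diagonals joining mouth corners to opposite outer eye
#' corners), and the camera roll aligns its vertical axis with the
#' nasion-to-upper-lip vector `n - ls` (its component orthogonal to the view
#' direction; only the in-plane roll is meaningful).
#'
#' @param lm named landmark matrix (rows `ch_l`, `ch_r`, `ex_l`, `ex_r`, `n`,
#'   `prn`, `ls` required; e.g. a [landmark_set3d()]).
#' @param distance_mm camera distance from prn, default 800.
#' @param view_angle vertical view angle in degrees, default 20.
#' @param image_size pixels.
#' @return a [pinhole_camera()].
#' @export
frontal_camera <- function(lm, distance_mm = 800, view_angle = 20,
                           image_size = c(512, 512)) {
  need <- c("ch_l", "ch_r", "ex_l", "ex_r", "n", "prn", "ls")
  if (!all(need %in% rownames(lm)))
    stop("missing landmarks for frontal camera: ",
         paste(setdiff(need, rownames(lm)), collapse = ", "))
  a <- lm["ch_r", ] - lm["ex_l", ]
  b <- lm["ch_l", ] - lm["ex_r", ]
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  ncr <- sqrt(sum(cr^2))
  if (ncr <= 1e-9) stop("degenerate landmark configuration")
  dir <- cr / ncr
  prn <- lm["prn", ]
  nls <- lm["n", ] - lm["ls", ]
  # roll: in-plane component of n - ls
  nls_perp <- nls - sum(nls * dir) * dir
  if (sqrt(sum(nls_perp^2)) < 1e-9)
    stop("n - ls parallel to the view direction")
  pinhole_camera(position = prn + distance_mm * dir, focal_point = prn,
                 up = nls_perp / sqrt(sum(nls_perp^2)),
                 view_angle = view_angle, image_size = image_size)
}

#' Raw frontal direction cross product
#'
#' The unnormalized outward facial direction `(ch_r - ex_l) x (ch_l - ex_r)`
#' used by [frontal_camera()]; exposed for inspection and testing.
#'
#' @inheritParams frontal_camera
#' @return length-3 vector.
#' @export
frontal_direction <- function(lm) {
  a <- lm["ch_r", ] - lm["ex_l", ]
  b <- lm["ch_l", ] - lm["ex_r", ]
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Render a colored mesh through a pinhole camera
#'
#' Unlit software rasterization: perspective projection, nearest-hit (depth
#' buffer) visibility, barycentric interpolation of per-vertex colors.
#' Background pixels take `background` and depth `Inf`. Depth at a foreground
#' pixel is the distance from the camera position to the visible surface point
#' along that pixel's ray, making the rendering exactly consistent with
#' [cast_ray()] on [pixel_ray()]s.
#'
#' @param mesh a [triangle_mesh()] with per-vertex colors.
#' @param camera a [pinhole_camera()].
#' @param background RGB background color, default black.
#' @return an object of class `rendered_view`: list with `image`
#'   (H x W x 3 array in `[0, 1]`), `depth` (H x W matrix) and `camera`.
#' @export
render <- function(mesh, camera, background = c(0, 0, 0)) {
  if (is.null(mesh$colors))
    stop("mesh has no per-vertex colors; the landmarking pipeline requires color")
  b <- camera_basis(camera)
  res <- cpp_render(mesh$vertices, mesh$triangles - 1L, mesh$colors,
                    camera$position, b$right, b$up, b$fwd, b$s, b$W, b$H,
                    background)
  structure(list(image = res$image, depth = res$depth, camera = camera),
            class = "rendered_view")
}

#' @export
print.rendered_view <- function(x, ...) {
  fg <- sum(is.finite(x$depth))
  cat(sprintf("rendered_view: %d x %d px, %d foreground pixels\n",
              dim(x$depth)[2], dim(x$depth)[1], fg))
  invisible(x)
}

#' Cast a ray against a mesh
#'
#' Exhaustive Moller-Trumbore intersection over all triangles; returns the hit
#' with the smallest strictly positive distance, or `NULL` when the ray misses
#' the surface entirely ("no hit" is a value, not an error).
#'
#' @param mesh a [triangle_mesh()].
#' @param ray a `ray` (see [make_ray()], [pixel_ray()]).
#' @return `NULL`, or a list with `point` (length-3), `triangle` (1-based
#'   index) and `distance` (mm, > 0).
#' @export
cast_ray <- function(mesh, ray) {
  res <- cpp_cast_rays(mesh$vertices, mesh$triangles - 1L,
                       matrix(ray$origin, 1), matrix(ray$direction, 1))
  if (is.na(res$triangle[1])) return(NULL)
  list(point = res$point[1, ], triangle = res$triangle[1],
       distance = res$distance[1])
}
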