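#' Pipeline configuration
#'
#' Tunable parameters of the automatic landmarking pipeline. Defaults follow
#' the algorithm's published operating point: a five-camera array 600 mm from
#' the mesh centroid with a 50 degree view angle for coarse face location,
#' and a frontal camera 800 mm from the pronasale with a 20 degree view
#' angle; the frontal camera is computed twice (`n_refinements = 2`), the
#' second rendering feeding the final landmark extraction. Rendering
#' resolution defaults to 512 x 512 (the per-pixel footprint in the frontal
#' view is then about `2 * 800 * tan(10 deg) / 512 ~ 0.55` mm).
#'
#' @param image_size render size in pixels, `c(width, height)`.
#' @param n_refinements number of frontal-camera computations, >= 1.
#' @param array_distance_mm initial camera array offset (mm).
#' @param array_view_angle_deg initial array view angle (degrees).
#' @param frontal_distance_mm frontal camera distance from prn (mm).
#' @param frontal_view_angle_deg frontal camera view angle (degrees).
#' @param ray_miss_policy what to do when a landmark's pixel ray misses the
#'   surface: `"nearest_point"` snaps to the nearest mesh point within
#'   `ray_snap_mm` (silhouette-grazing rays can miss by sub-pixel amounts);
#'   `"error"` aborts naming the landmark.
#' @param ray_snap_mm snap cap for `"nearest_point"`, default 5 mm.
#' @param background render background color.
#' @param index_map iBUG-68 index table, see [ibug12_indices()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(image_size = c(512, 512), n_refinements = 2,
                            array_distance_mm = 600,
                            array_view_angle_deg = 50,
                            frontal_distance_mm = 800,
                            frontal_view_angle_deg = 20,
                            ray_miss_policy = c("nearest_point", "error"),
                            ray_snap_mm = 5,
                            background = c(0, 0, 0),
                            index_map = ibug12_indices()) {
  ray_miss_policy <- match.arg(ray_miss_policy)
  stopifnot(n_refinements >= 1, array_distance_mm > 0,
            frontal_distance_mm > 0,
            array_view_angle_deg > 0, array_view_angle_deg < 180,
            frontal_view_angle_deg > 0, frontal_view_angle_deg < 180,
            ray_snap_mm > 0)
  structure(list(image_size = as.integer(image_size),
                 n_refinements = as.integer(n_refinements),
                 array_distance_mm = array_distance_mm,
                 array_view_angle_deg = array_view_angle_deg,
                 frontal_distance_mm = frontal_distance_mm,
                 frontal_view_angle_deg = frontal_view_angle_deg,
                 ray_miss_policy = ray_miss_policy,
                 ray_snap_mm = ray_snap_mm,
                 background = background,
                 index_map = index_map),
            class = "pipeline_config")
}

#' Coarse face location with the five-camera array
#'
#' Renders the mesh from the five initial cameras in order (central first,
#' then +x, +y, -x, -y) and applies the detector to each rendering until one
#' yields at least one bounding box; the highest-confidence box is kept.
#'
#' @param mesh a colored [triangle_mesh()].
#' @param detector a detector (see [detect_faces()]).
#' @param config a [pipeline_config()].
#' @return list with `camera`, `view` ([render()] output), `box` and
#'   `camera_index` (1 = central).
#' @export
locate_face <- function(mesh, detector, config = pipeline_config()) {
  cams <- initial_camera_array(mesh, image_size = config$image_size,
                               distance_mm = config$array_distance_mm,
                               view_angle_deg = config$array_view_angle_deg)
  for (i in seq_along(cams)) {
    view <- render(mesh, cams[[i]], background = config$background)
    boxes <- detect_faces(detector, view$image)
    if (length(boxes)) {
      return(list(camera = cams[[i]], view = view,
                  box = select_best_box(boxes), camera_index = i))
    }
  }
  stop("face not found in any of the five initial views")
}

#' 3D landmarks from one rendered view
#'
#' Runs the 68-point landmarker inside `box`, maps the 68 points to the
#' twelve named landmarks, and casts each landmark's pixel ray back onto the
#' mesh; the landmark is the first intersection. Rays that miss are handled
#' per `config$ray_miss_policy`.
#'
#' @param mesh the [triangle_mesh()] rendered in `view`.
#' @param view a `rendered_view` of `mesh`.
#' @param box a [bounding_box()] in `view`.
#' @param landmarker a landmarker (see [landmark_face()]).
#' @param config a [pipeline_config()].
#' @return a [landmark_set3d()] with attribute `ray_status` (named character,
#'   `"hit"` or `"snapped"`).
#' @export
landmarks_from_view <- function(mesh, view, box, landmarker,
                                config = pipeline_config()) {
  lm68 <- landmark_face(landmarker, view$image, box)
  named2d <- map_68_to_12(lm68, config$index_map)
  pts <- matrix(NA_real_, 12, 3, dimnames = list(rownames(named2d), NULL))
  status <- stats::setNames(character(12), rownames(named2d))
  for (nm in rownames(named2d)) {
    r <- pixel_ray(view$camera, named2d[nm, ])
    hit <- cast_ray(mesh, r)
    if (!is.null(hit)) {
      pts[nm, ] <- hit$point
      status[nm] <- "hit"
    } else if (config$ray_miss_policy == "error") {
      stop("landmark ray missed the mesh: ", nm)
    } else {
      near <- cpp_ray_mesh_nearest(mesh$vertices, mesh$triangles - 1L,
                                   r$origin, r$direction, 1e7)
      if (near$distance > config$ray_snap_mm)
        stop("landmark ray missed the mesh by ",
             sprintf("%.2f", near$distance), " mm (> snap cap): ", nm)
      pts[nm, ] <- near$point
      status[nm] <- "snapped"
    }
  }
  out <- landmark_set3d(pts)
  attr(out, "ray_status") <- status
  out
}

#' Run the full automatic landmarking pipeline
#'
#' (1) Coarse face location with the five-camera array; (2) landmark
#' extraction from the selected view; (3) `n_refinements` rounds of frontal
#' camera computation from the current `ch_l/ch_r/ex_l/ex_r/n/prn/ls`
#' landmarks, re-rendering, re-detection and landmark re-extraction; (4) the
#' landmarks from the final frontal view are returned. If re-detection in a
#' frontal view yields no box the full image is used as the box (the frontal
#' rendering is face-centered by construction); if landmark extraction in a
#' frontal view fails, the last successful landmark set is returned with a
#' warning.
#'
#' @param mesh a colored [triangle_mesh()].
#' @param detector a face detector (default [fixture_detector()]).
#' @param landmarker a 68-point landmarker (defaults to `detector`).
#' @param config a [pipeline_config()].
#' @return a [landmark_set3d()] with attributes `camera_index` (initial view
#'   used), `frontal_camera` (final camera) and `ray_status`.
#' @export
run_pipeline <- function(mesh, detector = fixture_detector(),
                         landmarker = detector,
                         config = pipeline_config()) {
  loc <- locate_face(mesh, detector, config)
  lm <- landmarks_from_view(mesh, loc$view, loc$box, landmarker, config)
  final_cam <- loc$camera
  for (k in seq_len(config$n_refinements)) {
    cam <- frontal_camera(lm, distance_mm = config$frontal_distance_mm,
                          view_angle = config$frontal_view_angle_deg,
                          image_size = config$image_size)
    view <- render(mesh, cam, background = config$background)
    boxes <- detect_faces(detector, view$image)
    box <- if (length(boxes)) select_best_box(boxes)
           else bounding_box(0, 0, config$image_size[1], config$image_size[2],
                             confidence = 0)
    lm_new <- tryCatch(
      landmarks_from_view(mesh, view, box, landmarker, config),
      error = function(e) {
        warning("frontal refinement ", k, " failed (", conditionMessage(e),
                "); keeping previous landmarks")
        NULL
      })
    if (is.null(lm_new)) break
    lm <- lm_new
    final_cam <- cam
  }
  attr(lm, "camera_index") <- loc$camera_index
  attr(lm, "frontal_camera") <- final_cam
  lm
}
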