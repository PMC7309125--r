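test_that("centroid size matches its definition", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  # homogeneity
  expect_equal(centroid_size(sq * 3.7), 3.7 * sqrt(2), tolerance = 1e-12)
  # brute-force re-summation on a random configuration
  set.seed(2)
  x <- matrix(stats::rnorm(36), 12, 3)
  ctr <- colMeans(x)
  brute <- sqrt(sum(apply(x, 1, function(p) sum((p - ctr)^2))))
  expect_equal(centroid_size(x), brute, tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 3)), "degenerate")
})

test_that("rigid_align recovers a known proper rigid transform", {
  set.seed(3)
  x <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  R0 <- random_rotation()
  t0 <- c(4, -7, 2)
  y <- transform_points(x, R0, t0)
  tr <- rigid_align(x, y)
  expect_equal(tr$rotation, R0, tolerance = 1e-9)
  expect_equal(tr$translation, t0, tolerance = 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)

  id <- rigid_align(x, x)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("rigid_align beats random rigid transforms (Monte Carlo bound)", {
  set.seed(4)
  x <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  y <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  tr <- rigid_align(x, y)
  ssd_opt <- sum((transform_points(x, tr$rotation, tr$translation) - y)^2)
  for (i in 1:1000) {
    Rr <- random_rotation()
    tt <- stats::rnorm(3, 0, 5)
    expect_lte(ssd_opt, sum((transform_points(x, Rr, tt) - y)^2) + 1e-9)
  }
})

test_that("rigid_align refuses reflections and degenerate input", {
  set.seed(5)
  x <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  y <- x
  y[, 1] <- -y[, 1]  # reflected copy
  tr <- rigid_align(x, y)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
  line <- cbind(seq_len(5), 0, 0)
  expect_error(rigid_align(line, line), "degenerate")
})

test_that("gpa assigns zero distance to rigidly moved and rescaled copies", {
  set.seed(6)
  x <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  rownames(x) <- landmark_names()
  y <- transform_points(x * 2.5, random_rotation(), c(10, 20, -5))
  rownames(y) <- landmark_names()
  r <- gpa(list(x, y))
  expect_lt(max(r$distances), 1e-9)

  two <- gpa(list(x, x))
  expect_equal(two$distances, c(0, 0), tolerance = 1e-12)
})

test_that("gpa mean shape is order-invariant as a shape", {
  set.seed(7)
  base <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  samples <- lapply(1:8, function(i) base + matrix(stats::rnorm(36), 12, 3))
  r1 <- gpa(samples)
  r2 <- gpa(rev(samples))
  tr <- rigid_align(r2$mean_shape, r1$mean_shape)
  gap <- sqrt(sum((transform_points(r2$mean_shape, tr$rotation,
                                    tr$translation) - r1$mean_shape)^2))
  expect_lt(gap, 1e-6)
  expect_equal(sort(r1$distances), sort(r2$distances), tolerance = 1e-6)
})

test_that("gpa results carry unit centroid size and a consistent mean", {
  set.seed(8)
  base <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  samples <- lapply(1:6, function(i) base + matrix(stats::rnorm(36), 12, 3))
  r <- gpa(samples)
  for (a in r$aligned)
    expect_equal(sqrt(sum(sweep(a, 2, colMeans(a))^2)), 1, tolerance = 1e-9)
  expect_equal(r$mean_shape, Reduce(`+`, r$aligned) / length(r$aligned),
               tolerance = 1e-12)
  expect_equal(procrustes_distance_from_mean(r), r$distances)
  # brute-force distance recomputation
  d_brute <- vapply(r$aligned,
                    function(a) sqrt(sum((a - r$mean_shape)^2)), 0)
  expect_equal(r$distances, d_brute, tolerance = 1e-12)
})

test_that("gpa distances are invariant to rigid motion of any input", {
  set.seed(9)
  base <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  samples <- lapply(1:5, function(i) base + matrix(stats::rnorm(36), 12, 3))
  r1 <- gpa(samples)
  samples2 <- samples
  samples2[[3]] <- transform_points(samples2[[3]] * 1.7, random_rotation(),
                                    c(5, 5, 5))
  r2 <- gpa(samples2)
  expect_equal(r1$distances, r2$distances, tolerance = 1e-9)
})

test_that("gpa agrees with an independent reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  mean_true <- matrix(stats::rnorm(36, 0, 10), 12, 3)
  samples <- lapply(1:20, function(i)
    mean_true + matrix(stats::rnorm(36, 0, 0.8), 12, 3))
  ours <- gpa(samples)$distances
  ref <- oracle_gpa_distances(samples)
  expect_equal(mean(ours), mean(ref), tolerance = 0.1 * mean(ref))
})

test_that("gpa rejects mismatched label sets", {
  x <- matrix(stats::rnorm(36), 12, 3)
  rownames(x) <- landmark_names()
  y <- x
  rownames(y)[1] <- "nope"
  expect_error(gpa(list(x, y)), "label")
})

test_that("landmark_errors reports exact distances and summaries", {
  fx <- small_fixture()
  a <- list(fx$landmarks, fx$landmarks)
  rep0 <- landmark_errors(a, a)
  expect_true(all(rep0$distances == 0))
  expect_equal(rep0$overall$mean, 0)

  off <- landmark_set3d(unclass(fx$landmarks) +
                          matrix(rep(c(2.5, 0, 0), each = 12), 12, 3))
  rep1 <- landmark_errors(a, list(off, off))
  expect_true(all(abs(rep1$distances - 2.5) < 1e-12))
  expect_equal(rep1$per_landmark$mean, rep(2.5, 12))
  expect_equal(rep1$per_landmark$sd, rep(0, 12))
  expect_equal(rep1$overall$mean, 2.5)
  expect_equal(rep1$per_subject, rep(2.5, 2), ignore_attr = TRUE)

  # overall mean equals the mean of per-landmark means (equal subject counts)
  set.seed(12)
  b <- lapply(1:5, function(i) perturb_landmarks(fx$landmarks, 1, seed = i))
  rep2 <- landmark_errors(rep(list(fx$landmarks), 5), b)
  expect_equal(rep2$overall$mean, mean(rep2$per_landmark$mean))
  expect_equal(rep2$overall$sd, stats::sd(as.numeric(rep2$distances)))
})

test_that("Gaussian landmark noise yields the Maxwell mean distance", {
  fx <- small_fixture()
  n_sub <- 400  # 4800 landmark instances
  m <- rep(list(fx$landmarks), n_sub)
  obs <- lapply(seq_len(n_sub),
                function(i) perturb_landmarks(fx$landmarks, 1, seed = 1000 + i))
  rep <- landmark_errors(m, obs)
  expect_equal(rep$overall$mean, 2 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("average_over_observers averages per-pair distances", {
  fx <- small_fixture()
  m <- list(fx$landmarks)
  o1 <- list(perturb_landmarks(fx$landmarks, 1, seed = 1))
  o2 <- list(perturb_landmarks(fx$landmarks, 1, seed = 2))
  # identical observers reduce to landmark_errors
  same <- average_over_observers(m, o1, o1)
  expect_equal(same$distances, landmark_errors(m, o1)$distances)
  # averaged distances equal the brute-force mean of the two
  avg <- average_over_observers(m, o1, o2)
  d1 <- landmark_errors(m, o1)$distances
  d2 <- landmark_errors(m, o2)$distances
  expect_equal(avg$distances, (d1 + d2) / 2, tolerance = 1e-12)
})

test_that("error reports write CSV with an Overall row and JSON", {
  fx <- small_fixture()
  m <- list(fx$landmarks)
  o <- list(perturb_landmarks(fx$landmarks, 1, seed = 3))
  rep <- landmark_errors(m, o)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_error_report(rep, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 13)
  expect_equal(df$landmark[13], "Overall")
  expect_equal(df$mean_mm[13], rep$overall$mean, tolerance = 1e-6)
  js <- withr::local_tempfile(fileext = ".json")
  write_error_report(rep, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$overall$mean, rep$overall$mean, tolerance = 1e-9)
})
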