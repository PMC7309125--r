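# Shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

test_fixture <- function(key = "default", spec = fixture_spec()) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_face_fixture(spec)
  .fixture_cache[[key]]
}

# Small fixture for NICP / ray-cast tests (~2k vertices).
small_fixture <- function() {
  test_fixture("small", fixture_spec(n_lat = 45, n_mer = 45))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

landmark_dist <- function(a, b) {
  sqrt(rowSums((unclass(landmark_set3d(a)) - unclass(landmark_set3d(b)))^2))
}
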