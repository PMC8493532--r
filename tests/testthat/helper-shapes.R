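# Shared geometric fixtures, built in code.

raster_disk <- function(r, cx = 64.5, cy = 64.5, H = 128, W = 128) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  (i - cx)^2 + (j - cy)^2 <= r^2
}

raster_ellipse <- function(a, b, cx = 64.5, cy = 64.5, H = 128, W = 128) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((i - cx) / a)^2 + ((j - cy) / b)^2 <= 1
}

# star-shaped (spiky) mask: same rough area as a disk, much longer boundary
raster_star <- function(r, spikes = 8, cx = 64.5, cy = 64.5, H = 128, W = 128) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  th <- atan2(j - cy, i - cx)
  rr <- sqrt((i - cx)^2 + (j - cy)^2)
  rr <= r * (0.55 + 0.45 * cos(spikes * th))
}

rigid_move <- function(mesh, angle, axis = c(0, 0, 1), translation = c(0, 0, 0)) {
  R <- echoforge:::rotation_about(axis, angle)
  mesh$vertices <- mesh$vertices %*% t(R) +
    matrix(translation, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh$landmarks <- echoforge:::mesh_landmarks(mesh)
  mesh
}

# small toy blob domains for transform tests
toy_blob <- function(gray, seed, N = 32, rmin = N / 4, rmax = N / 2.4) {
  set.seed(seed)
  r <- stats::runif(1, rmin, rmax)
  cx <- stats::runif(1, 0.4 * N, 0.6 * N)
  cy <- stats::runif(1, 0.4 * N, 0.6 * N)
  i <- matrix(seq_len(N), N, N)
  j <- matrix(seq_len(N), N, N, byrow = TRUE)
  m <- matrix(0, N, N)
  m[(i - cx)^2 + (j - cy)^2 <= r^2] <- gray
  m
}

tissue_volumes <- function(mesh) {
  vapply(c("lv_pool", "lv_myo", "la", "rv", "ra", "aorta", "valve"),
         function(t) mesh_compartment_volume(mesh, t), numeric(1))
}
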