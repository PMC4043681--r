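# Small constructed masks and phantoms shared across tests.

# solid box of bone inside empty space
solid_box_mask <- function(box = 3, pad = 1) {
  n <- box + 2 * pad
  a <- array(FALSE, c(n, n, n))
  idx <- (pad + 1):(pad + box)
  a[idx, idx, idx] <- TRUE
  a
}

# square voxel ring (one independent loop) in a single slab
voxel_torus_mask <- function(side = 5, pad = 1) {
  n <- side + 2 * pad
  a <- array(FALSE, c(n, n, 3))
  idx <- (pad + 1):(pad + side)
  a[idx, idx, 2] <- TRUE
  inner <- (pad + 2):(pad + side - 1)
  a[inner, inner, 2] <- FALSE
  a
}

# k disjoint solid boxes along the first axis
disjoint_boxes_mask <- function(k, box = 2, gap = 2) {
  n1 <- k * box + (k + 1) * gap
  a <- array(FALSE, c(n1, box + 2 * gap, box + 2 * gap))
  for (i in seq_len(k)) {
    lo <- gap + (i - 1) * (box + gap) + 1
    a[lo:(lo + box - 1), (gap + 1):(gap + box), (gap + 1):(gap + box)] <- TRUE
  }
  a
}

# crossing vertical plate grid extruded along z: a plates normal x and
# b plates normal y spanning a box; independent loops = (a - 1) * (b - 1)
plate_grid_mask <- function(a_planes, b_planes, pitch = 6, thick = 2,
                            height = 8, pad = 2) {
  nx <- pad * 2 + (a_planes - 1) * pitch + thick
  ny <- pad * 2 + (b_planes - 1) * pitch + thick
  m <- array(FALSE, c(height, nx, ny))
  for (i in seq_len(a_planes)) {
    lo <- pad + (i - 1) * pitch + 1
    m[, lo:(lo + thick - 1), (pad + 1):(ny - pad)] <- TRUE
  }
  for (j in seq_len(b_planes)) {
    lo <- pad + (j - 1) * pitch + 1
    m[, (pad + 1):(nx - pad), lo:(lo + thick - 1)] <- TRUE
  }
  m
}

# voxelized sphere mask centered in a cube
sphere_mask <- function(radius, margin = 4) {
  n <- 2 * (radius + margin) + 1
  ctr <- radius + margin + 1
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  array((g$i - ctr)^2 + (g$j - ctr)^2 + (g$k - ctr)^2 <= radius^2, c(n, n, n))
}

# small metaphysis-like phantom arguments used in several tests;
# overrides merge over the defaults
small_meta_args <- function(...) {
  utils::modifyList(
    list(shape = c(40L, 64L, 64L), outer_radius = 21, inner_radius = 16),
    list(...)
  )
}

# a random 26-connected-ish blob mask (union of a few random boxes)
random_blob_mask <- function(seed, n = 16) {
  set.seed(seed)
  a <- array(FALSE, c(n, n, n))
  for (i in 1:5) {
    lo <- sample(2:(n - 6), 3, replace = TRUE)
    sz <- sample(2:4, 3, replace = TRUE)
    a[lo[1]:(lo[1] + sz[1]), lo[2]:(lo[2] + sz[2]), lo[3]:(lo[3] + sz[3])] <- TRUE
  }
  a
}
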