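# Brute-force oracles, independent of the package's C++ code paths.

ball_offsets_oracle <- function(radius) {
  r <- floor(radius + 1e-9)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  as.matrix(off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2 + 1e-9, ])
}

oracle_erode <- function(mask, radius) {
  d <- dim(mask)
  off <- ball_offsets_oracle(radius)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    keep <- TRUE
    for (q in seq_len(nrow(off))) {
      j <- p + off[q, ]
      if (any(j < 1) || any(j > d) || !mask[j[1], j[2], j[3]]) {
        keep <- FALSE
        break
      }
    }
    if (keep) out[p[1], p[2], p[3]] <- TRUE
  }
  out
}

oracle_dilate <- function(mask, radius) {
  d <- dim(mask)
  off <- ball_offsets_oracle(radius)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    for (q in seq_len(nrow(off))) {
      j <- p + off[q, ]
      if (all(j >= 1) && all(j <= d)) out[j[1], j[2], j[3]] <- TRUE
    }
  }
  out
}

# per-component opening mirroring the documented algorithm
oracle_opening_components <- function(mask, er, dr) {
  d <- dim(mask)
  lab <- array(pocketome:::cpp_label26(as.logical(mask), as.integer(d)), d)
  out <- array(FALSE, d)
  for (k in seq_len(max(lab, 0))) {
    comp <- lab == k
    e <- if (er > 0) oracle_erode(comp, er) else comp
    if (!any(e)) next
    out <- out | (if (dr > 0) oracle_dilate(e, dr) else e)
  }
  out
}

# exact ray-sphere burial, plain R triple loop
oracle_burial <- function(points, atoms, radii, dirs, cutoff) {
  apply(points, 1, function(p) {
    hits <- 0
    for (r in seq_len(nrow(dirs))) {
      u <- dirs[r, ]
      hit <- FALSE
      for (j in seq_len(nrow(atoms))) {
        v <- atoms[j, ] - p
        t <- sum(v * u)
        if (t > 0 && t <= cutoff && sum(v^2) - t^2 <= radii[j]^2) {
          hit <- TRUE
          break
        }
      }
      hits <- hits + hit
    }
    hits / nrow(dirs)
  })
}

oracle_rmsd <- function(P, Q, rotation, translation) {
  moved <- P %*% t(rotation) +
    matrix(translation, nrow(P), 3, byrow = TRUE)
  sqrt(mean(rowSums((moved - Q)^2)))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# voxelized ball: indices of grid points within r of the origin
make_voxel_sphere <- function(r, h, pad = 3) {
  centers <- seq(-(r + pad), r + pad, by = h)
  n <- length(centers)
  g <- expand.grid(x = centers, y = centers, z = centers)
  list(idx = which(g$x^2 + g$y^2 + g$z^2 <= r^2),
       dims = c(n, n, n), spacing = h)
}

# axis-aligned voxel box given index ranges in a dims grid
make_voxel_box <- function(dims, xr, yr, zr) {
  a <- array(FALSE, dims)
  a[xr, yr, zr] <- TRUE
  which(a)
}
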