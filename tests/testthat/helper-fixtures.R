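# Shared fixtures, all built in code at test time.

# Minimal single-adenosine PDB text (ribose atoms only, known coordinates).
minimal_adenosine_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  C1' A   A  12       1.000   2.000   3.000  1.00 10.00           C",
    "ATOM      2  C2' A   A  12       2.100   2.500   3.500  1.00 10.00           C",
    "ATOM      3  O2' A   A  12       2.600   3.800   3.200  1.00 10.00           O",
    "ATOM      4  C3' A   A  12       3.100   1.500   3.800  1.00 10.00           C",
    "END"), path)
  path
}

# Ramp-field map: f(x, y, z) = 2x + 3y - z sampled on a grid; trilinear
# interpolation is exact on affine fields, so f itself is the oracle.
ramp_map <- function(n = 11L, voxel = 0.5, origin = c(0, 0, 0)) {
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(n) - 1L) * voxel)
  g <- 2 * ax[[1]] %o% rep(1, n) %o% rep(1, n) +
       3 * rep(1, n) %o% ax[[2]] %o% rep(1, n) -
       1 * rep(1, n) %o% rep(1, n) %o% ax[[3]]
  density_map(g, voxel, origin)
}

ramp_f <- function(p) 2 * p[1] + 3 * p[2] - p[3]

# Independent brute-force trilinear interpolation, written from the textbook
# definition (fractional index, 8-corner weighted sum) without sharing code
# with the package implementation.
brute_trilinear <- function(map, p) {
  f <- (p - map$origin) / map$voxel
  n <- dim(map$grid)
  if (any(f < 0) || any(f > n - 1)) return(list(value = 0, inside = FALSE))
  i <- pmin(floor(f), n - 2)
  t <- f - i
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- abs(dx - (1 - t[1])) * abs(dy - (1 - t[2])) * abs(dz - (1 - t[3]))
    v <- v + w * map$grid[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
  }
  list(value = v, inside = TRUE)
}

# Isotropic Gaussian map of sd `sigma` centred at `centre` on a fine grid.
gaussian_map <- function(centre, sigma = 1.0, voxel = 0.2, half = 6) {
  ax <- lapply(1:3, function(k) seq(centre[k] - half, centre[k] + half, by = voxel))
  g <- exp(-outer(outer((ax[[1]] - centre[1])^2,
                        (ax[[2]] - centre[2])^2, "+"),
                  (ax[[3]] - centre[3])^2, "+") / (2 * sigma^2))
  density_map(g, voxel, vapply(ax, `[`, numeric(1), 1L))
}

model_coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

truth_keys <- function(truth)
  paste(truth$methylated_sites$chain, truth$methylated_sites$seq_id)

record_keys <- function(result)
  paste(result$records$chain, result$records$seq_id)
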