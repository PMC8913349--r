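# Geometry fixtures built in code: centred grids, spheres and ellipsoids.

centred_grid <- function(n, spacing = 1) {
  n <- rep(n, length.out = 3)
  sp <- rep(spacing, length.out = 3)
  voxel_grid(array(0, n), spacing = sp, origin = -(n - 1) / 2 * sp)
}

fill_mask <- function(grid, predicate) {
  pts <- grid_points(grid)
  grid_like(grid, array(predicate(pts) * 1, dim(grid$values)))
}

sphere_mask <- function(radius, n, spacing = 1, centre = c(0, 0, 0)) {
  fill_mask(centred_grid(n, spacing), function(p)
    sqrt(rowSums(sweep(p, 2, centre, "-")^2)) <= radius)
}

ellipsoid_mask <- function(radii, n, spacing = 1, centre = c(0, 0, 0),
                           rotation = diag(3)) {
  fill_mask(centred_grid(n, spacing), function(p) {
    u <- sweep(p, 2, centre, "-") %*% rotation
    rowSums(sweep(u, 2, radii, "/")^2) <= 1
  })
}

# warp a mask through a displacement field (nearest) onto the fixed grid
warp_mask <- function(mask, field, fixed) {
  pts <- grid_points(fixed)
  pts <- pts + prostatlas:::sample_displacement(field, pts)
  v <- prostatlas:::cpp_sample3(as.vector(mask$values), dim(mask$values),
                                prostatlas:::world_to_index(mask, pts) - 1,
                                FALSE, FALSE, 0)
  grid_like(fixed, array(v, dim(fixed$values)))
}

# fraction of in-gland points whose normalised depth is preserved by the
# field within `tol`
nd_preservation <- function(moving, fixed, field, tol = 0.1) {
  ndm <- normalised_distance_map(moving)$values
  ndf <- normalised_distance_map(fixed)$values
  ing <- which(fixed$values == 1)
  pts <- grid_points(fixed)[ing, , drop = FALSE]
  pts <- pts + prostatlas:::sample_displacement(field, pts)
  at <- prostatlas:::cpp_sample3(as.vector(ndm$values), dim(ndm$values),
                                 prostatlas:::world_to_index(ndm, pts) - 1,
                                 TRUE, TRUE, -1)
  mean(abs(at - ndf$values[ing]) <= tol)
}
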