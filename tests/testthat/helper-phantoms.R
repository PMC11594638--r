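# Shared fixtures built in code. Expensive phantom/vesselness objects are
# computed once per test run and cached here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# noiseless phantom with comfortably thick tubes (radius >= 1 voxel)
noiseless_phantom <- function() {
  fixture("noiseless_phantom", function() {
    spec <- phantom_spec(noise_sigma = 0, seed = 11,
                         tube_radius_mm_range = c(0.9, 1.5))
    generate_phantom(spec)
  })
}

noiseless_vesselness <- function() {
  fixture("noiseless_vesselness", function() {
    ph <- noiseless_phantom()
    list(t2 = frangi_filter(ph$t2, frangi_params()),
         flair = frangi_filter(ph$flair, frangi_params(polarity = "dark")))
  })
}

# brute-force capsule oracle: loop over all voxels, point-segment distance
capsule_oracle <- function(p0, p1, radius_mm, dm, voxel_mm) {
  out <- array(FALSE, dm)
  v <- p1 - p0
  L2 <- sum(v^2)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- (c(i, j, k) - 0.5) * voxel_mm
    t <- if (L2 > 0) min(1, max(0, sum((p - p0) * v) / L2)) else 0
    out[i, j, k] <- sum((p - p0 - t * v)^2) <= radius_mm^2
  }
  out
}

# recursive flood-fill labelling oracle (stack-based), any connectivity
floodfill_oracle <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  offs <- pvsmap:::connectivity_offsets(connectivity)
  labels <- array(0L, dm)
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(start, dm)[1, ])
    labels[start] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dm)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  labels
}

# do two labelings define the same partition of foreground voxels?
same_partition <- function(lab_a, lab_b) {
  fg <- lab_a > 0L
  if (!identical(fg, lab_b > 0L)) return(FALSE)
  pairs <- unique(cbind(lab_a[fg], lab_b[fg]))
  !any(duplicated(pairs[, 1])) && !any(duplicated(pairs[, 2]))
}

# analytic 3D Gaussian blob sampled at voxel centers (in voxel units)
gaussian_blob <- function(dm, center, sigma_vox, amplitude = 100) {
  g <- pvsmap:::index_grids(dm)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  amplitude * exp(-d2 / (2 * sigma_vox^2))
}

# straight bright tube along a grid axis
axis_tube <- function(dm, radius_vox, axis = 3, amplitude = 100, voxel_mm = 0.9) {
  g <- pvsmap:::index_grids(dm)
  c1 <- (dm[1] + 1) / 2; c2 <- (dm[2] + 1) / 2; c3 <- (dm[3] + 1) / 2
  r2 <- switch(axis,
               (g$y - c2)^2 + (g$z - c3)^2,
               (g$x - c1)^2 + (g$z - c3)^2,
               (g$x - c1)^2 + (g$y - c2)^2)
  as_volume(amplitude * exp(-r2 / (2 * (radius_vox / 1.5)^2)), voxel_mm)
}
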