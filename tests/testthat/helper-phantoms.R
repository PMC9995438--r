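# Shared fixtures: small phantoms and independent brute-force oracles.

# Compact phantom for fast unit tests (~2,700 brain voxels; penumbra ~260,
# core ~57 voxels, so tests sample with small n_per_class).
small_spec <- function(seed = 1L, ...) {
  args <- list(grid_shape = c(24, 24, 16),
               voxel_spacing_mm = c(2, 2, 4),
               brain_axes_mm = c(20, 20, 26),
               lesion_center_mm = c(-7, 0, 0),
               penumbra_radius_mm = 10,
               core_radius_mm = 6,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

# Remove all stochastic variation from a spec: compartment values become
# their exact means.
zero_noise <- function(spec) {
  zap <- function(p) lapply(p, function(v) c(mean = v[["mean"]], sd = 0))
  spec$healthy_params <- zap(spec$healthy_params)
  spec$penumbra_params <- zap(spec$penumbra_params)
  spec$core_params <- zap(spec$core_params)
  spec$noise_sd[] <- 0
  spec
}

scale_noise <- function(spec, f) {
  spec$noise_sd <- spec$noise_sd * f
  spec
}

# Independent flood-fill connected-component labeling (queue-based, voxel
# by voxel), used as the oracle for the graph-based implementation.
# Components come out numbered by their smallest linear voxel index.
bf_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue <- start
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        nc <- co + offs[k, ]
        if (any(nc < 1) || any(nc > d)) next
        j <- nc[1] + (nc[2] - 1) * d[1] + (nc[3] - 1) * d[1] * d[2]
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# A constructed patch matrix with four well-separated Gaussian classes.
# Class k has mean k * sep in every column of the named map blocks.
separable_patch_matrix <- function(n_per_class = 60, maps = c("dt", "cbf"),
                                   sep = 10, sd = 1, seed = 1,
                                   signal_maps = maps) {
  cols <- unlist(lapply(maps, function(m) sprintf("%s_%02d", m, 1:27)))
  n <- 4 * n_per_class
  labels <- rep(0:3, each = n_per_class)
  feats <- ctpseg:::with_seed(seed, {
    x <- matrix(rnorm(n * length(cols), 0, sd), n,
                dimnames = list(NULL, cols))
    for (m in signal_maps) {
      block <- grep(paste0("^", m, "_"), cols)
      x[, block] <- x[, block] + labels * sep
    }
    x
  })
  ctpseg:::new_patch_matrix(feats, labels,
                            data.frame(study_id = "synthetic",
                                       x = seq_len(n), y = 1L, z = 1L),
                            maps)
}
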