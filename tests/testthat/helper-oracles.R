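# Independent brute-force oracles and tiny fixtures shared across tests.
# The oracle deliberately uses naive per-point loops and fine sampling so it
# shares no code path with the vectorized implementation it checks.

# nearest-voxel label set of one streamline, sampled at `frac` times the
# smallest voxel edge
bf_streamline_labels <- function(sl, vol, frac = 0.01) {
  inv <- solve(vol$affine)
  edge <- min(sqrt(colSums(vol$affine[1:3, 1:3]^2)))
  step <- frac * edge
  g <- dim(vol$labels)
  labs <- integer(0)
  for (i in seq_len(nrow(sl) - 1)) {
    a <- sl[i, ]; b <- sl[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    for (tt in seq(0, 1, length.out = max(2, ceiling(len / step) + 1))) {
      p <- a + tt * (b - a)
      v <- (inv %*% c(p, 1))[1:3]
      v <- sign(v) * floor(abs(v) + 0.5)
      if (all(v >= 0) && all(v < g)) {
        l <- vol$labels[v[1] + 1, v[2] + 1, v[3] + 1]
        if (l > 0) labs <- union(labs, l)
      }
    }
  }
  sort(labs)
}

# exclusive-assignment decision, restated independently from the package
bf_assign <- function(tract, vol, table, frac = 0.01) {
  tg <- table$label[table$role == "target"]
  ex <- table$label[table$role == "exclusion"]
  vapply(tract$streamlines, function(sl) {
    if (nrow(sl) < 2) return("invalid")
    labs <- bf_streamline_labels(sl, vol, frac)
    if (length(intersect(labs, ex)) > 0) return("touches_exclusion")
    hit <- intersect(labs, tg)
    if (length(hit) >= 2) return("multiple_targets")
    if (length(hit) == 0) return("no_target")
    as.character(hit)
  }, character(1))
}

# minimal valid region table for hand-built grids
tiny_region_table <- function(n_targets = 2, exclusion = TRUE) {
  n <- n_targets
  region_table(data.frame(
    label = seq_len(1 + n + exclusion),
    name = c("Seed", paste("Midline Target", seq_len(n)),
             if (exclusion) "Avoid"),
    hemisphere = "midline",
    compartment = c("none", rep("posterior", n), if (exclusion) "none"),
    role = c("seed", rep("target", n), if (exclusion) "exclusion")))
}

# small, fast phantom configuration for pipeline-level tests
tiny_phantom_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(41L, 41L, 41L), n_streamlines = 300L,
         n_targets_bilateral = 2L, n_targets_midline = 1L, seed = 42L),
    list(...))
  do.call(phantom_config, args)
}
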