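#' Phantom configuration
#'
#' Parameters of the synthetic tractography phantom: a cuboid grid hosting
#' one midline seed ROI, `n_targets_bilateral` mirror-symmetric left/right
#' target pairs plus `n_targets_midline` midline targets (spheres of
#' `roi_radius` voxels), and one exclusion ROI sitting between the seed and a
#' decoy direction (emulating a region of avoidance adjacent to the seed).
#' Each subject receives `n_streamlines` polylines: valid streamlines run
#' from inside the seed into exactly one target with per-target counts drawn
#' multinomially around `true_weights`, perturbed per subject by a
#' multiplicative log-normal factor (`subject_sigma` on the log scale, which
#' keeps weights positive and produces the right-skewed between-subject
#' spread seen in real cohorts); `lateralization_shift` multiplies the left
#' member of every pair (1 = symmetric). The remaining fractions of
#' streamlines are constructed invalid: crossing the exclusion ROI, touching
#' two targets, or reaching no target at all.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size isotropic voxel edge, mm.
#' @param n_targets_bilateral number of left/right target pairs.
#' @param n_targets_midline number of midline targets.
#' @param roi_radius ROI sphere radius, voxels.
#' @param n_streamlines streamlines per subject.
#' @param true_weights ground-truth relative density per target, ordered
#'   (left 1, right 1, left 2, right 2, ..., midline 1, ...); default a
#'   right-skewed decreasing profile.
#' @param subject_sigma SD of the per-subject log-normal weight perturbation.
#' @param lateralization_shift multiplicative left/right asymmetry (1 = none).
#' @param noise_exclusion_frac,noise_multitarget_frac,noise_offtarget_frac
#'   fractions of streamlines made invalid in each way.
#' @param step_mm polyline vertex spacing, mm (default 0.2).
#' @param seed RNG seed for cohort generation.
#' @return validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(41L, 41L, 41L),
                           voxel_size = 1,
                           n_targets_bilateral = 3L,
                           n_targets_midline = 2L,
                           roi_radius = 3L,
                           n_streamlines = 2000L,
                           true_weights = NULL,
                           subject_sigma = 0.3,
                           lateralization_shift = 1,
                           noise_exclusion_frac = 0.05,
                           noise_multitarget_frac = 0.05,
                           noise_offtarget_frac = 0.05,
                           step_mm = 0.2,
                           seed = 1L) {
  nt <- 2L * n_targets_bilateral + n_targets_midline
  if (is.null(true_weights)) {
    pw <- 24 * 0.5^(seq_len(n_targets_bilateral) - 1)  # per-pair weight
    mw <- 16 * 0.5^(seq_len(n_targets_midline) - 1)    # per-midline weight
    true_weights <- c(rep(pw, each = 2L), mw)
  }
  cfg <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
              n_targets_bilateral = as.integer(n_targets_bilateral),
              n_targets_midline = as.integer(n_targets_midline),
              roi_radius = roi_radius, n_streamlines = as.integer(n_streamlines),
              true_weights = true_weights, subject_sigma = subject_sigma,
              lateralization_shift = lateralization_shift,
              noise_exclusion_frac = noise_exclusion_frac,
              noise_multitarget_frac = noise_multitarget_frac,
              noise_offtarget_frac = noise_offtarget_frac,
              step_mm = step_mm, seed = as.integer(seed))
  with(cfg, {
    stopifnot(length(grid_shape) == 3L, all(grid_shape >= 9L),
              voxel_size > 0, n_targets_bilateral >= 0L,
              n_targets_midline >= 0L, nt >= 1L, roi_radius >= 1,
              n_streamlines >= 1L, step_mm > 0, subject_sigma >= 0,
              lateralization_shift > 0)
    if (length(true_weights) != nt)
      stop("true_weights must have one entry per target (", nt, ")")
    if (any(true_weights < 0) || sum(true_weights) <= 0)
      stop("true_weights must be nonnegative with positive sum")
    fr <- c(noise_exclusion_frac, noise_multitarget_frac,
            noise_offtarget_frac)
    if (any(fr < 0 | fr > 1) || sum(fr) >= 1)
      stop("noise fractions must lie in [0, 1] with sum < 1")
  })
  structure(cfg, class = "phantom_config")
}

# deterministic child seed for subject k; stays below 2^31
child_seed <- function(seed, k) {
  m <- 2147483587
  as.integer((as.numeric(seed %% m) * 48271 + k * 8191 + 12345) %% m)
}

# voxel indices (0-based, n x 3) of a sphere of radius r voxels around centre
.sphere_voxels <- function(centre, r, grid) {
  rng <- lapply(1:3, function(a)
    max(0L, floor(centre[a] - r)):min(grid[a] - 1L, ceiling(centre[a] + r)))
  g <- as.matrix(expand.grid(rng))
  d2 <- (g[, 1L] - centre[1L])^2 + (g[, 2L] - centre[2L])^2 +
        (g[, 3L] - centre[3L])^2
  unname(g[d2 <= r^2, , drop = FALSE])
}

#' Build the phantom parcellation
#'
#' Places the seed, target, and exclusion ROIs on the grid and returns the
#' label volume (isotropic affine, origin 0) together with its region table.
#' The seed sits on the midline plane; bilateral pairs are mirror images of
#' one another about that plane; the exclusion ROI sits on the opposite side
#' of the seed from the targets (the decoy direction exercised by
#' exclusion-crossing noise streamlines). Target compartments are assigned
#' round-robin over the four cerebellar compartments.
#'
#' @param config a [phantom_config()].
#' @return list with elements `labels` (a [label_volume()]) and `table`
#'   (a [region_table()]).
#' @export
make_phantom_labels <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$grid_shape; v <- config$voxel_size; r <- config$roi_radius
  nb <- config$n_targets_bilateral; nm <- config$n_targets_midline
  cx <- (g[1L] - 1) / 2; cz <- (g[3L] - 1) / 2
  seed_c <- c(cx, r + 1, cz)
  excl_c <- c(cx, r + 1, max(0, cz - (2 * r + 2)))
  ty <- g[2L] - 1 - r - 1                       # target plane (y index)
  dx <- max(2 * r + 2, floor((g[1L] - 1) / 4))  # half-separation of a pair
  dz <- 2 * r + 2                               # z spacing between targets

  centres <- list(); names_ <- hemis <- character(0)
  comps4 <- c("anterior", "posterior", "flocculonodular", "nuclear")
  for (i in seq_len(nb)) {
    z <- cz + (i - (nb + 1) / 2) * dz
    comp <- comps4[(i - 1L) %% 4L + 1L]
    centres <- c(centres, list(c(cx - dx, ty, z), c(cx + dx, ty, z)))
    names_ <- c(names_, paste("Left Target", i), paste("Right Target", i))
    hemis <- c(hemis, "left", "right")
  }
  for (j in seq_len(nm)) {
    z <- cz + (j - (nm + 1) / 2) * dz
    centres <- c(centres, list(c(cx, ty, z)))
    names_ <- c(names_, paste("Midline Target", j))
    hemis <- c(hemis, "midline")
  }
  comp_of <- c(rep(comps4[(seq_len(nb) - 1L) %% 4L + 1L], each = 2L),
               comps4[(nb + seq_len(nm) - 1L) %% 4L + 1L])

  all_centres <- c(list(seed_c), centres, list(excl_c))
  arr <- array(0L, dim = g)
  for (k in seq_along(all_centres)) {
    vox <- .sphere_voxels(all_centres[[k]], r, g)
    if (nrow(vox) == 0L ||
        any(vox < 0L) || any(vox >= matrix(g, nrow(vox), 3L, byrow = TRUE)))
      stop("ROI ", k, " cannot be placed inside the grid; enlarge grid_shape")
    lin <- vox %*% c(1L, g[1L], g[1L] * g[2L]) + 1L
    if (any(arr[lin] != 0L))
      stop("ROIs overlap on this grid; enlarge grid_shape or shrink roi_radius")
    arr[lin] <- k
  }

  nt <- length(centres)
  table <- region_table(data.frame(
    label = seq_len(nt + 2L),
    name = c("Seed", names_, "Avoidance"),
    hemisphere = c("midline", hemis, "midline"),
    compartment = c("none", comp_of, "none"),
    role = c("seed", rep("target", nt), "exclusion"),
    stringsAsFactors = FALSE))
  labels <- label_volume(arr, diag(c(v, v, v, 1)))
  attr(labels, "roi_centres_vox") <- all_centres
  list(labels = labels, table = table)
}

#' Draw one subject's target weights
#'
#' Per-subject realized weights: `w_i = true_weight_i * exp(e_i)` with
#' `e_i ~ Normal(0, subject_sigma^2)` independently per target, and the left
#' member of every bilateral pair further multiplied by
#' `lateralization_shift`. Uses the current RNG state.
#'
#' @param config a [phantom_config()].
#' @return numeric vector of positive weights, one per target.
#' @export
sample_subject_weights <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  nt <- length(config$true_weights)
  w <- config$true_weights * exp(stats::rnorm(nt, 0, config$subject_sigma))
  if (config$n_targets_bilateral > 0L) {
    left <- seq(1L, 2L * config$n_targets_bilateral, by = 2L)
    w[left] <- w[left] * config$lateralization_shift
  }
  w
}

# intended per-category streamline counts for one subject
.intended_counts <- function(config, weights) {
  n <- config$n_streamlines
  na <- round(n * config$noise_exclusion_frac)
  nb <- round(n * config$noise_multitarget_frac)
  nc <- round(n * config$noise_offtarget_frac)
  nv <- n - na - nb - nc
  counts <- if (sum(weights) > 0 && nv > 0)
    as.vector(stats::rmultinom(1L, nv, weights)) else rep(0L, length(weights))
  list(valid = counts, excl = na, multi = nb, off = nc)
}

# straight polyline start -> end (world mm), resampled to ~step spacing,
# then jittered per vertex
.jittered_line <- function(waypoints, step, jitter_sd) {
  segs <- lapply(seq_len(nrow(waypoints) - 1L), function(i) {
    a <- waypoints[i, ]; b <- waypoints[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nv <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = nv)
    if (i > 1L) tt <- tt[-1L]
    cbind(a[1L] + tt * (b[1L] - a[1L]), a[2L] + tt * (b[2L] - a[2L]),
          a[3L] + tt * (b[3L] - a[3L]))
  })
  pts <- do.call(rbind, segs)
  pts + matrix(stats::rnorm(length(pts), 0, jitter_sd), nrow(pts), 3L)
}

#' Generate one subject's tractogram with ground truth
#'
#' Valid streamlines run from a uniformly sampled seed voxel centre into a
#' uniformly sampled voxel of their intended target (straight path, Gaussian
#' per-vertex jitter of SD 0.3 x voxel size, vertex spacing ~`step_mm`),
#' rejection-resampled (up to 100 retries) until the densified path touches
#' its target and avoids all exclusion ROIs and all other targets. Noise
#' streamlines are constructed to cross the exclusion ROI, to traverse two
#' distinct targets, or to end in background without touching any target, in
#' the configured fractions. Streamline order is shuffled. Uses the current
#' RNG state.
#'
#' @param labels,table phantom parcellation from [make_phantom_labels()].
#' @param weights per-target weights (e.g. [sample_subject_weights()]).
#' @param config a [phantom_config()].
#' @return list with `tractogram` (a [tractogram()]) and `ground_truth`:
#'   list with `weights`, `intended_counts` (named: per-target plus noise
#'   categories), and `intended` (per-streamline: target label id as
#'   character, or the discard reason the assignment stage should produce).
#' @export
generate_subject_tractogram <- function(labels, table, weights, config) {
  stopifnot(inherits(labels, "label_volume"), inherits(table, "region_table"),
            inherits(config, "phantom_config"))
  tg <- target_labels(table); ex <- exclusion_labels(table)
  sd_lab <- seed_label(table)
  if (length(weights) != length(tg)) stop("weights length must match targets")
  arr <- labels$labels; g <- dim(arr); A <- labels$affine
  vsize <- min_voxel_edge(A)
  jit <- 0.3 * vsize
  step <- config$step_mm
  need_densify <- step > 0.5 * vsize

  vox_world <- function(lab) {
    idx <- which(arr == lab)
    k0 <- (idx - 1L) %/% (g[1L] * g[2L])
    j0 <- ((idx - 1L) %% (g[1L] * g[2L])) %/% g[1L]
    i0 <- (idx - 1L) %% g[1L]
    cbind(i0, j0, k0) %*% t(A[1:3, 1:3]) +
      matrix(A[1:3, 4L], length(idx), 3L, byrow = TRUE)
  }
  seed_pts <- vox_world(sd_lab)
  tg_pts <- lapply(tg, vox_world)
  ex_centre <- colMeans(vox_world(ex[1L]))

  labs_of <- function(pts) {
    if (need_densify) pts <- densify_points(pts, 0.5 * vsize)$points
    idx <- world_to_voxel(pts, A, g)
    ok <- !is.na(idx[, 1L])
    if (!any(ok)) return(integer(0))
    l <- arr[idx[ok, , drop = FALSE] + 1L]
    unique(l[l > 0L])
  }
  draw <- function(make, accept, what) {
    for (try in 1:100) {
      s <- make()
      if (accept(labs_of(s))) return(s)
    }
    stop("phantom generation failed: could not construct a ", what,
         " streamline in 100 retries")
  }
  rrow <- function(m) m[sample.int(nrow(m), 1L), ]

  ic <- .intended_counts(config, weights)
  streamlines <- vector("list", config$n_streamlines)
  intended <- character(config$n_streamlines)
  pos <- 0L
  for (t_i in seq_along(tg)) {
    others <- setdiff(tg, tg[t_i])
    for (s_i in seq_len(ic$valid[t_i])) {
      sl <- draw(
        function() .jittered_line(rbind(rrow(seed_pts), rrow(tg_pts[[t_i]])),
                                  step, jit),
        function(l) tg[t_i] %in% l && !any(l %in% ex) && !any(l %in% others),
        "valid")
      pos <- pos + 1L
      streamlines[[pos]] <- sl; intended[pos] <- as.character(tg[t_i])
    }
  }
  for (s_i in seq_len(ic$excl)) {
    sl <- draw(
      function() {
        a <- rrow(seed_pts)
        .jittered_line(rbind(a, ex_centre, ex_centre + (ex_centre - a) * 0.3),
                       step, jit)
      },
      function(l) any(l %in% ex), "exclusion-crossing")
    pos <- pos + 1L
    streamlines[[pos]] <- sl; intended[pos] <- "touches_exclusion"
  }
  for (s_i in seq_len(ic$multi)) {
    sl <- draw(
      function() {
        ab <- sample.int(length(tg), 2L)
        .jittered_line(rbind(rrow(seed_pts), rrow(tg_pts[[ab[1L]]]),
                             rrow(tg_pts[[ab[2L]]])), step, jit)
      },
      function(l) sum(l %in% tg) >= 2L && !any(l %in% ex), "multi-target")
    pos <- pos + 1L
    streamlines[[pos]] <- sl; intended[pos] <- "multiple_targets"
  }
  if (ic$off > 0L) {
    # background end points in the corridor between seed and target planes
    bg <- which(arr == 0L)
    k0 <- (bg - 1L) %/% (g[1L] * g[2L])
    j0 <- ((bg - 1L) %% (g[1L] * g[2L])) %/% g[1L]
    i0 <- (bg - 1L) %% g[1L]
    ymid <- stats::quantile(j0, c(0.35, 0.6))
    sel <- j0 >= ymid[1L] & j0 <= ymid[2L]
    bg_pts <- cbind(i0, j0, k0)[sel, , drop = FALSE] %*% t(A[1:3, 1:3]) +
      matrix(A[1:3, 4L], sum(sel), 3L, byrow = TRUE)
    for (s_i in seq_len(ic$off)) {
      sl <- draw(
        function() .jittered_line(rbind(rrow(seed_pts), rrow(bg_pts)),
                                  step, jit),
        function(l) !any(l %in% tg) && !any(l %in% ex), "off-target")
      pos <- pos + 1L
      streamlines[[pos]] <- sl; intended[pos] <- "no_target"
    }
  }

  ord <- sample.int(pos)
  counts <- c(stats::setNames(ic$valid, tg),
              touches_exclusion = ic$excl, multiple_targets = ic$multi,
              no_target = ic$off)
  list(tractogram = tractogram(streamlines[ord],
                               header = list(phantom = "tractdensity")),
       ground_truth = list(weights = weights, intended_counts = counts,
                           intended = intended[ord]))
}

#' Generate a phantom cohort
#'
#' All subjects share the ROI geometry; subject k is generated under the
#' deterministic child seed `child_seed(config$seed, k)`, so cohorts are
#' bit-identical given the same configuration and reproducible across
#' platforms.
#'
#' @param config a [phantom_config()].
#' @param n_subjects number of subjects (>= 1).
#' @return list with `labels`, `table`, and `subjects` — a list of per-subject
#'   records, each with `tractogram` and `ground_truth`.
#' @export
generate_cohort <- function(config, n_subjects) {
  stopifnot(inherits(config, "phantom_config"), n_subjects >= 1L)
  ph <- make_phantom_labels(config)
  subjects <- lapply(seq_len(n_subjects), function(k) {
    set.seed(child_seed(config$seed, k))
    w <- sample_subject_weights(config)
    generate_subject_tractogram(ph$labels, ph$table, w, config)
  })
  list(labels = ph$labels, table = ph$table, subjects = subjects)
}

#' Profile-level phantom cohort
#'
#' Simulates per-subject delta_norm profiles directly from the phantom's
#' stochastic model — log-normal subject weights, multinomial streamline
#' counts, volume normalization against the phantom geometry — without
#' constructing streamline geometry. Distributionally this equals the
#' geometric phantom followed by noise-free assignment (border jitter aside)
#' and is the workhorse for replicate studies (type-I error, power,
#' p-value calibration) where thousands of cohorts are needed.
#'
#' @param config a [phantom_config()].
#' @param n_subjects cohort size.
#' @param geometry optional precomputed [make_phantom_labels()] result
#'   (rebuilt from `config` when NULL).
#' @return list with `profiles` (matrix, subjects x targets, delta_norm %),
#'   `table`, `target_volumes`, `seed_volume`.
#' @export
simulate_cohort_profiles <- function(config, n_subjects, geometry = NULL) {
  stopifnot(inherits(config, "phantom_config"), n_subjects >= 1L)
  if (is.null(geometry)) geometry <- make_phantom_labels(config)
  tab <- geometry$table
  tg <- target_labels(tab)
  vols <- region_volumes(geometry$labels, c(seed_label(tab), tg))
  seed_vol <- vols[1L]; tvols <- vols[-1L]
  prof <- matrix(NA_real_, n_subjects, length(tg),
                 dimnames = list(NULL, tg))
  for (k in seq_len(n_subjects)) {
    set.seed(child_seed(config$seed, k))
    w <- sample_subject_weights(config)
    nos <- .intended_counts(config, w)$valid
    prof[k, ] <- delta_norm(nos, tvols, seed_vol)
  }
  list(profiles = prof, table = tab, target_volumes = tvols,
       seed_volume = unname(seed_vol))
}

#' Expected volume-corrected density of a phantom
#'
#' The delta_norm profile implied by the ground-truth weights and the ROI
#' volumes: `100 * (w_i / vbar_i) / sum_j (w_j / vbar_j)` with
#' `vbar_i = (seed_volume + volume_i) / 2`. This is what the group mean
#' delta_norm recovers (up to sampling error) on a phantom cohort.
#'
#' @param config a [phantom_config()].
#' @param geometry optional precomputed [make_phantom_labels()] result.
#' @return named numeric vector (percent, sums to 100).
#' @export
expected_delta_norm <- function(config, geometry = NULL) {
  if (is.null(geometry)) geometry <- make_phantom_labels(config)
  tab <- geometry$table
  tg <- target_labels(tab)
  vols <- region_volumes(geometry$labels, c(seed_label(tab), tg))
  w <- config$true_weights / ((vols[1L] + vols[-1L]) / 2)
  stats::setNames(100 * w / sum(w), tg)
}
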