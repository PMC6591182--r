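#' Map world-mm points to voxel indices
#'
#' Applies the inverse affine and rounds each continuous index to the nearest
#' integer, half away from zero (voxel-centre convention, 0-based indices).
#' Points falling outside the grid are marked out-of-bounds (NA row), never
#' an error: streamlines may legitimately leave the field of view.
#'
#' @param points numeric matrix n x 3 of world coordinates (mm), or a single
#'   length-3 vector.
#' @param affine 4x4 voxel-to-world matrix.
#' @param dim grid dimensions (length 3); if supplied, indices outside
#'   `[0, dim)` become NA.
#' @return integer matrix n x 3 of 0-based voxel indices, NA rows where out
#'   of bounds.
#' @export
world_to_voxel <- function(points, affine, dim = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3L)
  inv <- tryCatch(solve(affine),
                  error = function(e) stop("affine is singular"))
  cont <- points %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(points), 3L, byrow = TRUE)
  idx <- sign(cont) * floor(abs(cont) + 0.5)  # half away from zero
  if (!is.null(dim)) {
    oob <- idx[, 1L] < 0 | idx[, 1L] >= dim[1L] |
           idx[, 2L] < 0 | idx[, 2L] >= dim[2L] |
           idx[, 3L] < 0 | idx[, 3L] >= dim[3L]
    idx[oob, ] <- NA_real_
  }
  storage.mode(idx) <- "integer"
  idx
}

# smallest voxel edge length in mm: minimum column norm of the 3x3 block
min_voxel_edge <- function(affine) min(sqrt(colSums(affine[1:3, 1:3]^2)))

# Insert evenly spaced intermediate samples so consecutive spacing <= max_step.
# Returns the resampled points plus, when id is given, the expanded id vector.
densify_points <- function(points, max_step, id = NULL) {
  n <- nrow(points)
  if (n < 2L) return(list(points = points, id = id))
  dx <- points[-1L, 1L] - points[-n, 1L]
  dy <- points[-1L, 2L] - points[-n, 2L]
  dz <- points[-1L, 3L] - points[-n, 3L]
  len2 <- dx * dx + dy * dy + dz * dz
  reps <- rep.int(1L, n - 1L)
  long <- len2 > max_step^2
  if (!is.null(id)) long <- long & id[-1L] == id[-n]  # never bridge streamlines
  if (!any(long)) return(list(points = points, id = id))
  reps[long] <- ceiling(sqrt(len2[long]) / max_step)
  # fractional positions along each segment (excluding its start point)
  segidx <- rep.int(seq_len(n - 1L), reps)
  frac <- sequence(reps) / rep.int(reps, reps)
  seg <- cbind(dx, dy, dz, deparse.level = 0)
  mid <- points[segidx, , drop = FALSE] + seg[segidx, , drop = FALSE] * frac
  out <- rbind(points[1L, , drop = FALSE], mid)
  outid <- if (!is.null(id)) c(id[1L], id[segidx + 1L]) else NULL
  list(points = out, id = outid)
}

#' Labels traversed by a streamline
#'
#' The set of nonzero parcellation labels hit by a streamline after
#' densifying its polyline so that consecutive sample spacing is at most half
#' the smallest voxel edge — a Nyquist-style guarantee that no voxel-thick
#' structure between vertices is skipped. Out-of-bounds samples contribute
#' nothing. Label membership is nearest-voxel (labels are categorical, never
#' interpolated).
#'
#' @param streamline n x 3 matrix of vertices (world mm).
#' @param labels a [label_volume()].
#' @return integer vector: the sorted set of distinct nonzero labels.
#' @export
streamline_labels <- function(streamline, labels) {
  stopifnot(inherits(labels, "label_volume"))
  max_step <- 0.5 * min_voxel_edge(labels$affine)
  pts <- densify_points(streamline, max_step)$points
  idx <- world_to_voxel(pts, labels$affine, dim(labels$labels))
  ok <- !is.na(idx[, 1L])
  if (!any(ok)) return(integer(0))
  lab <- labels$labels[idx[ok, , drop = FALSE] + 1L]
  sort(unique(lab[lab > 0L]))
}

#' Assign streamlines exclusively to target regions
#'
#' Implements the mutual-exclusion filtering used to extract single
#' seed-to-target connections: each target region acts as inclusion mask
#' while every other target acts as exclusion mask, and regions of avoidance
#' veto a streamline outright. For each streamline the set of traversed
#' labels is computed (see [streamline_labels()]); the streamline is then
#' \itemize{
#'   \item discarded `touches_exclusion` if any role = exclusion label is hit
#'     (checked first — an avoided streamline can never be assigned);
#'   \item discarded `multiple_targets` if two or more distinct targets are
#'     hit (it belongs to no single pathway);
#'   \item discarded `no_target` if no target is hit;
#'   \item otherwise assigned to the unique traversed target.
#' }
#' Traversal of the seed label is ignored for the decision; with
#' `strict_seed = TRUE` streamlines that never touch the seed are discarded
#' as `no_seed`. Streamlines with fewer than two vertices are counted under
#' `invalid`, never silently dropped.
#'
#' @param tractogram a [tractogram()].
#' @param labels a [label_volume()].
#' @param table a [region_table()].
#' @param strict_seed require seed traversal (default FALSE: the tractogram
#'   is already seeded in the seed region upstream).
#' @return An object of class `assignment_result`: list with
#'   `outcome` (character per streamline: the target label id as character,
#'   or a discard reason), `target` (integer per streamline, NA when
#'   discarded), `counts` (named integer: per-target assigned counts, names =
#'   target label ids), and `discards` (named integer counts by reason).
#' @export
assign_streamlines <- function(tractogram, labels, table,
                               strict_seed = FALSE) {
  stopifnot(inherits(tractogram, "tractogram"),
            inherits(labels, "label_volume"),
            inherits(table, "region_table"))
  tg <- target_labels(table)
  ex <- exclusion_labels(table)
  sd_lab <- seed_label(table)
  ns <- n_streamlines(tractogram)

  nv <- vapply(tractogram$streamlines, nrow, integer(1))
  valid <- nv >= 2L
  outcome <- character(ns)
  target <- rep(NA_integer_, ns)
  outcome[!valid] <- "invalid"

  if (any(valid)) {
    sl <- tractogram$streamlines[valid]
    pts <- do.call(rbind, sl)
    id <- rep.int(seq_along(sl), nv[valid])
    dd <- densify_points(pts, 0.5 * min_voxel_edge(labels$affine), id)
    idx <- world_to_voxel(dd$points, labels$affine, dim(labels$labels))
    ok <- !is.na(idx[, 1L])
    lab <- rep(0L, nrow(idx))
    lab[ok] <- labels$labels[idx[ok, , drop = FALSE] + 1L]
    keep <- lab > 0L
    sid <- dd$id[keep]; lb <- lab[keep]
    # distinct (streamline, label) pairs
    u <- !duplicated(as.numeric(sid) * (max(lb, 1L) + 1) + lb)
    sid <- sid[u]; lb <- lb[u]

    n_valid <- length(sl)
    hit_ex <- tabulate(sid[lb %in% ex], n_valid) > 0L
    is_tg <- lb %in% tg
    n_tg <- tabulate(sid[is_tg], n_valid)
    hit_seed <- tabulate(sid[lb == sd_lab], n_valid) > 0L

    res <- rep("no_target", n_valid)
    res[hit_ex] <- "touches_exclusion"
    res[!hit_ex & n_tg >= 2L] <- "multiple_targets"
    assigned <- !hit_ex & n_tg == 1L
    if (strict_seed) {
      res[!hit_ex & !hit_seed] <- "no_seed"
      assigned <- assigned & hit_seed
    }
    # the unique target of each assigned streamline
    one <- is_tg & assigned[sid]
    tgt <- rep(NA_integer_, n_valid)
    tgt[sid[one]] <- lb[one]
    res[assigned] <- as.character(tgt[assigned])
    outcome[valid] <- res
    target[valid] <- tgt
  }

  counts <- vapply(tg, function(t) sum(target == t, na.rm = TRUE), integer(1))
  names(counts) <- tg
  reasons <- c("touches_exclusion", "multiple_targets", "no_target",
               if (strict_seed) "no_seed", "invalid")
  discards <- vapply(reasons, function(r) sum(outcome == r), integer(1))
  structure(list(outcome = outcome, target = target,
                 counts = counts, discards = discards),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment_result:", sum(x$counts), "assigned /",
      length(x$outcome), "streamlines;",
      paste(names(x$discards), x$discards, collapse = ", "), "\n")
  invisible(x)
}
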