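#' Per-target streamline counts (NOS)
#'
#' Number of streamlines (NOS) connecting the seed to each target region,
#' counted over assigned streamlines only; discarded streamlines contribute
#' nothing and targets without streamlines get 0.
#'
#' @param assignment an `assignment_result` from [assign_streamlines()].
#' @param table a [region_table()].
#' @return named integer vector, one entry per target label.
#' @export
count_nos <- function(assignment, table) {
  stopifnot(inherits(assignment, "assignment_result"))
  tg <- target_labels(table)
  nos <- assignment$counts[as.character(tg)]
  nos[is.na(nos)] <- 0L
  names(nos) <- tg
  nos
}

#' Connectivity density (percent of total NOS)
#'
#' The contribution of each target region to the total assigned NOS:
#' `delta_i = 100 * nos_i / sum(nos)`.
#'
#' @param nos nonnegative per-target counts.
#' @return per-target percentages summing to 100.
#' @section Errors:
#' A profile with zero total NOS is undefined (there is no pathway to
#' apportion) and raises an error — distinct from an all-zero result.
#' @export
delta <- function(nos) {
  if (any(nos < 0)) stop("NOS counts must be nonnegative")
  tot <- sum(nos)
  if (tot == 0) stop("undefined connectivity profile: total NOS is zero")
  100 * nos / tot
}

#' Volume-normalized connectivity density
#'
#' Raw streamline counts are biased towards large regions, so each pathway's
#' NOS is scaled by the mean volume of its two endpoints (seed and target)
#' before being expressed as a percentage:
#' `w_i = nos_i / ((seed_volume + volume_i) / 2)`,
#' `delta_norm_i = 100 * w_i / sum(w)`.
#' The renormalization to percent makes profiles sum to 100 per subject and
#' leaves the measure invariant under a global rescaling of all volumes;
#' when all volumes are equal it reduces exactly to [delta()].
#'
#' @param nos per-target counts.
#' @param volumes per-target region volumes (mm^3), aligned with `nos`.
#' @param seed_volume seed region volume (mm^3).
#' @return per-target percentages summing to 100.
#' @export
delta_norm <- function(nos, volumes, seed_volume) {
  if (any(nos < 0)) stop("NOS counts must be nonnegative")
  if (length(volumes) != length(nos))
    stop("volumes and nos must align")
  if (!is.finite(seed_volume) || seed_volume <= 0)
    stop("seed volume must be positive")
  if (sum(nos) == 0) stop("undefined connectivity profile: total NOS is zero")
  if (any(volumes <= 0 & nos > 0))
    stop("target(s) with zero volume but nonzero NOS: ",
         paste(names(nos)[volumes <= 0 & nos > 0], collapse = ", "))
  w <- ifelse(nos > 0, nos / ((seed_volume + volumes) / 2), 0)
  100 * w / sum(w)
}

#' Per-subject connectivity profile
#'
#' Convenience constructor combining [count_nos()], [region_volumes()],
#' [delta()] and [delta_norm()] into the per-subject profile used by the
#' group summary: per-target NOS, delta (% of total NOS) and delta_norm
#' (volume-corrected %), plus the volumes that entered the normalization.
#'
#' @param assignment an `assignment_result`.
#' @param labels the subject's [label_volume()].
#' @param table a [region_table()].
#' @return object of class `subject_profile`: list with `nos`, `delta`,
#'   `delta_norm` (named by target label), `seed_volume`, `target_volumes`.
#' @export
subject_profile <- function(assignment, labels, table) {
  nos <- count_nos(assignment, table)
  tg <- target_labels(table)
  vols <- suppressWarnings(region_volumes(labels, c(seed_label(table), tg)))
  seed_vol <- vols[1L]
  tvols <- vols[-1L]
  structure(list(nos = nos,
                 delta = delta(nos),
                 delta_norm = delta_norm(nos, tvols, seed_vol),
                 seed_volume = unname(seed_vol),
                 target_volumes = tvols),
            class = "subject_profile")
}

#' Group summary of connectivity profiles
#'
#' Across-subject mean and sample SD (n - 1 denominator) of delta_norm per
#' target, the coefficient of variation COV = SD / mean (the between-subject
#' reliability screen; 0 when mean and SD are both 0), and the retention flag
#' `retained = mean > threshold` — the density threshold (default 1%) that
#' separates reliable pathways from likely false positives. With a single
#' profile the mean is still computed but SD and COV are NA.
#'
#' @param profiles list of [subject_profile()]s (or a numeric matrix,
#'   subjects x targets, of delta_norm values).
#' @param threshold retention threshold on the group mean delta_norm, in
#'   percent (default 1).
#' @return data.frame of class `group_summary`: `target` (label id or column
#'   name), `mean_delta_norm`, `sd`, `cov`, `retained`.
#' @export
summarize_group <- function(profiles, threshold = 1.0) {
  m <- if (is.matrix(profiles)) profiles
       else {
         stopifnot(length(profiles) >= 1L)
         tg <- names(profiles[[1L]]$delta_norm)
         do.call(rbind, lapply(profiles, function(p) {
           if (!identical(names(p$delta_norm), tg))
             stop("profiles have inconsistent target sets")
           p$delta_norm
         }))
       }
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  mu <- colMeans(m)
  sdv <- if (nrow(m) >= 2L) apply(m, 2L, stats::sd) else rep(NA_real_, ncol(m))
  cov <- ifelse(mu > 0, sdv / mu, ifelse(sdv == 0, 0, NA_real_))
  out <- data.frame(target = colnames(m),
                    mean_delta_norm = unname(mu),
                    sd = unname(sdv),
                    cov = unname(cov),
                    retained = unname(mu > threshold),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_summary", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "n_subjects") <- nrow(m)
  out
}

#' Aggregate densities into anatomical compartments
#'
#' Sums per-target density values into the four Stoodley-Schmahmann
#' cerebellar compartments (anterior, posterior, flocculonodular, nuclear).
#' Aggregation is linear, so summing group means per compartment equals the
#' group mean of per-subject compartment sums.
#'
#' @param values named numeric vector of per-target values (percent).
#' @param compartments character vector aligned with `values`, or a
#'   [region_table()] (matched to `values` by target label id).
#' @return named numeric vector of compartment sums.
#' @export
aggregate_compartments <- function(values, compartments) {
  if (inherits(compartments, "region_table")) {
    tab <- compartments
    comp <- tab$compartment[match(as.integer(names(values)), tab$label)]
    if (anyNA(comp))
      stop("value(s) for label(s) absent from the region table: ",
           paste(names(values)[is.na(comp)], collapse = ", "))
  } else {
    comp <- as.character(compartments)
    if (length(comp) != length(values))
      stop("compartments and values must align")
  }
  if (any(comp == "none"))
    stop("target(s) mapped to compartment 'none' cannot be aggregated")
  agg <- tapply(values, comp, sum)[unique(comp)]
  stats::setNames(as.numeric(agg), names(agg))
}

#' Round half away from zero
#'
#' Presentation rounding matching the published tables (R's `round()` rounds
#' half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
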