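#' Lateralization index
#'
#' `LI = (Left - Right) / (Left + Right)`, in [-1, 1]. Positive values
#' indicate left lateralization, negative values right lateralization;
#' |LI| > 0.1 is the conventional asymmetry cutoff. When both densities are
#' zero the index is undefined and returned as NA (such pathways are excluded
#' from testing).
#'
#' @param left,right nonnegative density values (vectorized).
#' @return dimensionless index in [-1, 1], NA where left + right = 0.
#' @export
li <- function(left, right) {
  if (any(left < 0 | right < 0)) stop("densities must be nonnegative")
  tot <- left + right
  ifelse(tot == 0, NA_real_, (left - right) / tot)
}

#' Paired t statistic of left-minus-right differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with sample SD. Degenerate cases are
#' defined rather than errors: all-zero differences give t = 0 (exact null);
#' constant nonzero differences give t = +/-Inf, which the permutation test
#' ranks maximally.
#'
#' @param diffs per-subject left - right values, n >= 2.
#' @return the t value.
#' @export
paired_tstat <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 subjects")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    if (m == 0) return(0)
    return(sign(m) * Inf)
  }
  m / (s / sqrt(n))
}

# t statistics for every column of D under every sign-flip column of S,
# exploiting that sum(d^2) is flip-invariant:
#   mean_b = (s_b' D) / n ;  var_b = (colSums(D^2) - n mean_b^2) / (n - 1)
.flip_tstats <- function(D, S) {
  n <- nrow(D)
  ss <- matrix(colSums(D^2), ncol(S), ncol(D), byrow = TRUE)
  mn <- crossprod(S, D) / n                       # B x P means
  vr <- (ss - n * mn^2) / (n - 1)
  vr[vr < 0] <- 0                                 # guard fp negatives
  t <- mn / sqrt(vr / n)
  t[is.nan(t)] <- 0                               # 0/0: all-zero rows
  t
}

# all 2^n sign patterns, generated in chunks to bound memory
.sign_patterns <- function(n, chunk = 2^14) {
  B <- 2^n
  starts <- seq(0, B - 1, by = chunk)
  lapply(starts, function(s0) {
    b <- s0 + seq_len(min(chunk, B - s0)) - 1
    vapply(seq_len(n) - 1L,
           function(bit) ifelse(bitwAnd(b %/% 2^bit, 1) == 1, -1, 1),
           numeric(length(b)))  # rows = patterns, cols = subjects
  })
}

#' Paired tmax permutation test of hemispheric lateralization
#'
#' Tests left/right asymmetry of every bilateral pathway pair simultaneously,
#' with family-wise error control by the tmax method: the null distribution
#' is generated by independent per-subject sign flips of the paired
#' differences (the exchangeability of a paired design), each permutation
#' records the t statistic of every pair plus `tmax`, the maximum |t| across
#' pairs, and each observed |t| is ranked against both. Sampled permutations
#' use the add-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)` so p is
#' never zero. With n <= `exhaustive_max` subjects all 2^n sign patterns are
#' enumerated instead, making the test exact with
#' `p = #{pattern >= obs} / 2^n` (the identity pattern keeps p positive).
#'
#' A pair is called lateralized left when its group-level LI exceeds 0.1 with
#' corrected p below `alpha`, lateralized right when LI < -0.1 likewise
#' (the cutoff is symmetric), otherwise none.
#'
#' @param left,right numeric matrices, subjects x pairs, of per-subject
#'   densities (delta_norm) for the left and right member of each pair.
#' @param n_perm number of sampled permutations (default 50000; ignored when
#'   enumeration is exhaustive).
#' @param alpha significance level (default 0.05).
#' @param seed optional RNG seed for the sampled permutations.
#' @param exhaustive_max enumerate all sign patterns when n <= this (default
#'   20).
#' @return data.frame of class `lateralization_result`: `pair`, `li_group`
#'   (LI of the group mean densities), `t_stat`, `p_uncorrected`, `p_tmax`,
#'   `lateralized` in {left, right, none} (NA LI rows are excluded from the
#'   family and get NA p values).
#' @export
tmax_permutation <- function(left, right, n_perm = 50000L, alpha = 0.05,
                             seed = NULL, exhaustive_max = 20L) {
  left <- as.matrix(left); right <- as.matrix(right)
  if (!all(dim(left) == dim(right)))
    stop("left and right matrices must have matching shapes")
  n <- nrow(left); P <- ncol(left)
  if (n < 2L) stop("need at least 2 subjects")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  pair <- colnames(left)
  if (is.null(pair)) pair <- paste0("pair", seq_len(P))

  D <- left - right
  li_group <- li(colMeans(left), colMeans(right))
  testable <- !is.na(li_group)  # both-zero pathways carry no information
  t_obs <- apply(D, 2L, paired_tstat)

  p_unc <- p_tmax <- rep(NA_real_, P)
  if (any(testable)) {
    Dt <- D[, testable, drop = FALSE]
    to <- abs(t_obs[testable])
    exhaustive <- n <= exhaustive_max
    if (exhaustive) {
      chunks <- .sign_patterns(n)
      B <- 2^n
      cnt_unc <- rep(0, sum(testable)); cnt_max <- rep(0, sum(testable))
      for (S in chunks) {
        tp <- abs(.flip_tstats(Dt, t(S)))
        tm <- do.call(pmax, as.data.frame(tp))
        cnt_unc <- cnt_unc + colSums(tp >= rep(to, each = nrow(tp)))
        cnt_max <- cnt_max + vapply(to, function(o) sum(tm >= o), numeric(1))
      }
    } else {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
        set.seed(seed)
      }
      B <- as.integer(n_perm)
      S <- matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
      tp <- abs(.flip_tstats(Dt, S))
      tm <- do.call(pmax, as.data.frame(tp))
      cnt_unc <- colSums(tp >= rep(to, each = B))
      cnt_max <- vapply(to, function(o) sum(tm >= o), numeric(1))
    }
    if (exhaustive) {
      p_unc[testable] <- cnt_unc / B
      p_tmax[testable] <- cnt_max / B
    } else {
      p_unc[testable] <- (1 + cnt_unc) / (1 + B)
      p_tmax[testable] <- (1 + cnt_max) / (1 + B)
    }
  }

  side <- rep("none", P)
  side[testable & li_group > 0.1 & p_tmax < alpha] <- "left"
  side[testable & li_group < -0.1 & p_tmax < alpha] <- "right"
  side[!testable] <- NA_character_

  out <- data.frame(pair = pair, li_group = li_group, t_stat = t_obs,
                    p_uncorrected = p_unc, p_tmax = p_tmax,
                    lateralized = side, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("lateralization_result", "data.frame")
  attr(out, "n_perm") <- if (any(testable)) B else NA_integer_
  attr(out, "exhaustive") <- n <= exhaustive_max
  attr(out, "alpha") <- alpha
  out
}
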