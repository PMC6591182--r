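pipeline_error <- function(msg, class) {
  stop(structure(class = c(class, "pipeline_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. Defaults are the study
#' constants: retention threshold 1% on the group mean delta_norm, 50,000
#' permutations, alpha 0.05. Inputs are either real data (vectors of TCK and
#' NIfTI paths plus a region-table path) or a phantom sub-configuration; with
#' a phantom, every random operation derives its seed from `seed`, so a rerun
#' with the same configuration is bit-identical.
#'
#' @param tck_paths character vector of per-subject TCK files (real-data
#'   mode).
#' @param label_paths per-subject NIfTI label volumes; a single path is
#'   recycled to all subjects.
#' @param region_table_path TSV region table.
#' @param phantom a [phantom_config()] (phantom mode).
#' @param n_subjects cohort size in phantom mode.
#' @param threshold retention threshold on mean delta_norm, percent.
#' @param n_perm permutations for the lateralization test.
#' @param alpha significance level.
#' @param seed master RNG seed (overrides the phantom's own seed).
#' @param strict_seed_traversal discard streamlines that never touch the
#'   seed region.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tck_paths = NULL, label_paths = NULL,
                            region_table_path = NULL, phantom = NULL,
                            n_subjects = NULL, threshold = 1.0,
                            n_perm = 50000L, alpha = 0.05, seed = 1L,
                            strict_seed_traversal = FALSE) {
  cfg <- list(tck_paths = tck_paths, label_paths = label_paths,
              region_table_path = region_table_path, phantom = phantom,
              n_subjects = n_subjects, threshold = threshold,
              n_perm = as.integer(n_perm), alpha = alpha,
              seed = as.integer(seed),
              strict_seed_traversal = isTRUE(strict_seed_traversal))
  if (is.null(phantom)) {
    if (is.null(tck_paths) || is.null(label_paths) ||
        is.null(region_table_path))
      pipeline_error(paste(
        "configuration needs either a phantom sub-config or all of",
        "tck_paths, label_paths and region_table_path"),
        "pipeline_config_error")
    missing <- c(tck_paths, label_paths, region_table_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      pipeline_error(paste0("input file(s) not found: ",
                            paste(missing, collapse = ", ")),
                     "pipeline_io_error")
    if (length(label_paths) == 1L)
      cfg$label_paths <- rep(label_paths, length(tck_paths))
    else if (length(label_paths) != length(tck_paths))
      pipeline_error("label_paths must have length 1 or length(tck_paths)",
                     "pipeline_config_error")
  } else {
    if (!inherits(phantom, "phantom_config"))
      pipeline_error("phantom must be a phantom_config",
                     "pipeline_config_error")
    if (is.null(n_subjects) || n_subjects < 2L)
      pipeline_error("phantom mode needs n_subjects >= 2",
                     "pipeline_config_error")
  }
  if (threshold < 0 || alpha <= 0 || alpha >= 1 || cfg$n_perm < 1L)
    pipeline_error("invalid threshold/alpha/n_perm",
                   "pipeline_config_error")
  structure(cfg, class = "pipeline_config")
}

.log_msg <- function(logcon, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [INFO] ", ...)
  message(line)
  if (!is.null(logcon)) writeLines(line, logcon)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full connectivity-density analysis
#'
#' Orchestrates phantom generation (or real-data loading), streamline
#' assignment, per-subject density profiles, the group summary with COV and
#' retention threshold, compartment aggregation, and the paired tmax
#' lateralization test, writing every table under `out_dir`:
#' `profile_subject<k>.tsv` (per-target NOS, delta, delta_norm),
#' `group_summary.tsv` (structure, mean, SD, COV, retained — the shape of the
#' published density table), `compartments.tsv`, `lateralization.tsv`, and
#' `manifest.json` recording the configuration, seeds, package version, and
#' full streamline accounting (assigned + discarded = input, per subject).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param log write a timestamped log to stderr and `pipeline.log`.
#' @return invisibly, a list with `profiles`, `summary`, `compartments`,
#'   `lateralization`, `manifest`, and the output `paths`.
#' @export
run_pipeline <- function(config, out_dir, log = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- NULL
  if (log) {
    logcon <- file(file.path(out_dir, "pipeline.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  }

  phantom_mode <- !is.null(config$phantom)
  if (phantom_mode) {
    pcfg <- config$phantom
    pcfg$seed <- config$seed
    .log_msg(logcon, "phantom mode: ", config$n_subjects, " subjects, ",
             pcfg$n_streamlines, " streamlines each")
    geom <- make_phantom_labels(pcfg)
    n_sub <- config$n_subjects
  } else {
    .log_msg(logcon, "real-data mode: ", length(config$tck_paths),
             " subjects")
    n_sub <- length(config$tck_paths)
    table <- read_region_table(config$region_table_path)
  }

  profiles <- vector("list", n_sub)
  accounting <- vector("list", n_sub)
  for (k in seq_len(n_sub)) {
    if (phantom_mode) {
      set.seed(child_seed(config$seed, k))
      w <- sample_subject_weights(pcfg)
      sub <- generate_subject_tractogram(geom$labels, geom$table, w, pcfg)
      tract <- sub$tractogram; labels <- geom$labels; table <- geom$table
    } else {
      tract <- read_tck(config$tck_paths[k])
      labels <- read_label_volume(config$label_paths[k])
    }
    asg <- assign_streamlines(tract, labels, table,
                              strict_seed = config$strict_seed_traversal)
    n_in <- n_streamlines(tract)
    stopifnot(sum(asg$counts) + sum(asg$discards) == n_in)
    accounting[[k]] <- c(list(subject = k, input = n_in,
                              assigned = sum(asg$counts)),
                         as.list(asg$discards))
    profiles[[k]] <- subject_profile(asg, labels, table)
    .log_msg(logcon, "subject ", k, ": ", n_in, " streamlines, ",
             sum(asg$counts), " assigned, ", sum(asg$discards), " discarded")
  }

  tg <- table[table$role == "target", ]
  prof_paths <- vapply(seq_len(n_sub), function(k) {
    p <- profiles[[k]]
    .write_tsv(data.frame(label = tg$label, structure = tg$name,
                          nos = unname(p$nos), delta = unname(p$delta),
                          delta_norm = unname(p$delta_norm)),
               file.path(out_dir, sprintf("profile_subject%03d.tsv", k)))
  }, character(1))

  summ <- summarize_group(profiles, threshold = config$threshold)
  summ_df <- data.frame(structure = tg$name[match(as.integer(summ$target),
                                                  tg$label)],
                        mean = round_half_up(summ$mean_delta_norm),
                        sd = round_half_up(summ$sd),
                        cov = round_half_up(summ$cov),
                        retained = summ$retained)
  summ_df <- summ_df[order(-summ_df$mean), ]
  summary_path <- .write_tsv(summ_df, file.path(out_dir, "group_summary.tsv"))

  comp <- aggregate_compartments(
    stats::setNames(summ$mean_delta_norm, summ$target), table)
  comp_path <- .write_tsv(
    data.frame(compartment = names(comp),
               mean_delta_norm = round_half_up(unname(comp))),
    file.path(out_dir, "compartments.tsv"))

  pairs <- bilateral_pairs(table)
  lat <- NULL; lat_path <- NULL
  if (nrow(pairs) > 0L && n_sub >= 2L) {
    dn <- do.call(rbind, lapply(profiles, function(p) p$delta_norm))
    left <- dn[, as.character(pairs$left), drop = FALSE]
    right <- dn[, as.character(pairs$right), drop = FALSE]
    colnames(left) <- colnames(right) <- pairs$base
    lat <- tmax_permutation(left, right, n_perm = config$n_perm,
                            alpha = config$alpha, seed = config$seed)
    lat_path <- .write_tsv(as.data.frame(lat),
                           file.path(out_dir, "lateralization.tsv"))
    .log_msg(logcon, "lateralization: ", sum(lat$lateralized != "none",
                                             na.rm = TRUE),
             " of ", nrow(lat), " pairs significant at alpha ", config$alpha)
  }

  manifest <- list(
    package = "tractdensity",
    version = as.character(utils::packageVersion("tractdensity")),
    mode = if (phantom_mode) "phantom" else "real",
    seed = config$seed,
    threshold = config$threshold, n_perm = config$n_perm,
    alpha = config$alpha,
    strict_seed_traversal = config$strict_seed_traversal,
    n_subjects = n_sub,
    streamline_accounting = accounting)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(profiles = profiles, summary = summ, compartments = comp,
                 lateralization = lat, manifest = manifest,
                 paths = list(profiles = prof_paths, summary = summary_path,
                              compartments = comp_path,
                              lateralization = lat_path,
                              manifest = manifest_path)))
}

#' Published-table pass-through report
#'
#' Renders the packaged published density table through the same report
#' shape as [run_pipeline()]'s group summary (structure, mean, SD, COV,
#' retained), applying the retention threshold to the printed means. Useful
#' as an end-to-end check that the reporting layer reproduces the printed
#' columns verbatim.
#'
#' @param threshold retention threshold, percent (default 1).
#' @param path optional output TSV path.
#' @return the report data.frame (written to `path` when given).
#' @export
table1_report <- function(threshold = 1.0, path = NULL) {
  t1 <- load_table1_fixture()
  df <- data.frame(structure = t1$structure,
                   mean = round_half_up(t1$mean_delta_norm),
                   sd = round_half_up(t1$sd),
                   cov = round_half_up(t1$cov),
                   retained = t1$mean_delta_norm > threshold)
  if (!is.null(path)) .write_tsv(df, path)
  df
}
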