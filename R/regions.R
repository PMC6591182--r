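#' Region tables
#'
#' A region table gives the semantics of each parcellation label: a display
#' name, a hemisphere (`left`, `right`, `midline`), a compartment for
#' aggregation (`anterior`, `posterior`, `flocculonodular`, `nuclear`, or
#' `none`), and a role in streamline filtering (`seed`, `target`,
#' `exclusion`). Exactly one seed is required; every target needs a
#' compartment. Bilateral targets are expected in left/right pairs sharing a
#' base name (name stripped of its `Left `/`Right ` prefix); unpaired
#' bilateral targets are accepted with a warning because lateralization
#' analysis will have to skip them.
#'
#' @param df data.frame with columns `label` (integer), `name`, `hemisphere`,
#'   `compartment`, `role`.
#' @return validated `region_table` (a data.frame subclass).
#' @export
region_table <- function(df) {
  req <- c("label", "name", "hemisphere", "compartment", "role")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("region table lacks column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$label <- as.integer(df$label)
  for (col in c("name", "hemisphere", "compartment", "role"))
    df[[col]] <- as.character(df[[col]])

  chk <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop("unknown ", col, " token(s): ", paste(bad, collapse = ", "))
  }
  chk("hemisphere", c("left", "right", "midline"))
  chk("compartment",
      c("anterior", "posterior", "flocculonodular", "nuclear", "none"))
  chk("role", c("seed", "target", "exclusion"))

  if (anyDuplicated(df$label))
    stop("duplicated label id(s): ",
         paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  n_seed <- sum(df$role == "seed")
  if (n_seed != 1L)
    stop("region table must have exactly one seed row, found ", n_seed)
  tg <- df[df$role == "target", ]
  if (nrow(tg) < 1L)
    stop("region table must have at least one target row")
  if (any(tg$compartment == "none"))
    stop("target region(s) with compartment 'none': ",
         paste(tg$name[tg$compartment == "none"], collapse = ", "))

  base <- base_name(tg$name)
  for (side in c("left", "right")) {
    other <- setdiff(c("left", "right"), side)
    unpaired <- setdiff(base[tg$hemisphere == side],
                        base[tg$hemisphere == other])
    if (length(unpaired))
      warning("unpaired ", side, " target(s) without a ", other,
              " counterpart: ", paste(unpaired, collapse = ", "),
              call. = FALSE)
  }
  class(df) <- c("region_table", "data.frame")
  df
}

# strip a leading Left/Right token so bilateral partners share a base name
base_name <- function(x) sub("^(Left|Right)[ _]", "", x)

#' Read a region table from TSV
#'
#' Expects a tab-separated file with header columns `label`, `name`,
#' `hemisphere`, `compartment`, `role`; validation as in [region_table()].
#'
#' @param path TSV file path.
#' @return a [region_table()].
#' @export
read_region_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  region_table(df)
}

#' Write a region table to TSV
#' @param x a [region_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

seed_label <- function(table) table$label[table$role == "seed"]
target_labels <- function(table) table$label[table$role == "target"]
exclusion_labels <- function(table) table$label[table$role == "exclusion"]

#' Bilateral target pairs of a region table
#'
#' @param table a [region_table()].
#' @return data.frame with one row per left/right target pair: `base`
#'   (shared base name), `left` and `right` (label ids).
#' @export
bilateral_pairs <- function(table) {
  tg <- table[table$role == "target", ]
  lt <- tg[tg$hemisphere == "left", ]
  rt <- tg[tg$hemisphere == "right", ]
  lb <- base_name(lt$name); rb <- base_name(rt$name)
  common <- intersect(lb, rb)
  data.frame(base = common,
             left = lt$label[match(common, lb)],
             right = rt$label[match(common, rb)],
             stringsAsFactors = FALSE)
}
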