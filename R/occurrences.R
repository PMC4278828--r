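#' Species occurrence records
#'
#' An `occurrence_set` is a data frame of presence points (`id`, `x`,
#' `y`, map units) tied to the study-region geometry. Points outside the
#' extent or on masked cells are dropped at construction with a message
#' reporting the count; record ids must be unique.
#'
#' @param records data frame with columns `id`, `x`, `y` (extra columns,
#'   e.g. `date`, are carried along but ignored by the models).
#' @param geometry the study-region `grid_geometry`.
#' @param region optional `grid_layer` whose mask defines valid cells;
#'   when given, points on masked cells are dropped.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, geometry, region = NULL) {
  stopifnot(is.data.frame(records), inherits(geometry, "grid_geometry"))
  for (f in c("id", "x", "y"))
    if (!f %in% names(records)) stop("occurrence records need a '", f, "' column")
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) stop("occurrence record ids must be unique")
  idx <- point_to_cell(geometry, records$x, records$y)
  keep <- !is.na(idx$row)
  if (!is.null(region)) {
    stopifnot(inherits(region, "grid_layer"))
    on_mask <- keep
    on_mask[keep] <- is.na(region$values[cbind(idx$row[keep], idx$col[keep])])
    keep <- keep & !on_mask
  }
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " occurrence record(s) outside the study region or on ",
            "masked cells were dropped")
  structure(list(records = records[keep, , drop = FALSE], geometry = geometry),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records on a %d x %d region\n",
              nrow(x$records), x$geometry$n_rows, x$geometry$n_cols))
  invisible(x)
}

#' Number of records in an occurrence set
#' @param occ an `occurrence_set`.
#' @export
n_occurrences <- function(occ) nrow(occ$records)

#' Read occurrence points from CSV
#'
#' The CSV must have a header with at least `id,x,y`; an optional `date`
#' column (or any other extras) is retained but unused by the core
#' models.
#'
#' @param path CSV file path.
#' @inheritParams occurrence_set
#' @return An `occurrence_set`.
#' @export
read_occurrences <- function(path, geometry, region = NULL) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  occurrence_set(df, geometry, region)
}

#' @rdname read_occurrences
#' @param occ an `occurrence_set`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# subset by record ids, keeping order of `ids`
occ_subset <- function(occ, ids) {
  structure(list(records = occ$records[match(ids, occ$records$id), , drop = FALSE],
                 geometry = occ$geometry),
            class = "occurrence_set")
}
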