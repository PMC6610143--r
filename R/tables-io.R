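#' Read and write the package's standard CSV tables
#'
#' Localization tables carry `(frame, channel, x_px, y_px, x_um, y_um, I,
#' I_BG, sigma_x, sigma_y, converged)`; track tables carry `(track_id,
#' frame, x_um, y_um, channel)`. Columns are written in this fixed order
#' (extra columns follow) so outputs are byte-stable across runs.
#'
#' @param tbl table to write.
#' @param path CSV path.
#' @return `path` invisibly (writers); a tibble (readers).
#' @name table-io
NULL

loc_cols <- c("frame", "channel", "x_px", "y_px", "x_um", "y_um",
              "I", "I_BG", "sigma_x", "sigma_y", "converged")
trk_cols <- c("track_id", "frame", "x_um", "y_um", "channel")

write_ordered_csv <- function(tbl, path, first) {
  first <- intersect(first, names(tbl))
  tbl <- tbl[, c(first, setdiff(names(tbl), first)), drop = FALSE]
  write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @export
write_localizations <- function(tbl, path) write_ordered_csv(tbl, path, loc_cols)

#' @rdname table-io
#' @export
read_localizations <- function(path) as_tibble(read.csv(path))

#' @rdname table-io
#' @export
write_tracks <- function(tbl, path) write_ordered_csv(tbl, path, trk_cols)

#' @rdname table-io
#' @export
read_tracks <- function(path) as_tibble(read.csv(path))
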