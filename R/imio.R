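# Tile container, pseudocolor packing, tile-scan splitting, and the per-cell
# data table reader/writer.

DATA_TABLE_COLS <- c("patient_id", "object_size_px", "ppix_total", "ppix_mean",
                     "mt_total", "mt_mean")

#' Construct a three-channel tile
#'
#' A tile is one confocal field of view with three registered channels:
#' MitoTracker fluorescence (`mt`), PpIX fluorescence (`ppix`) and
#' transmitted light (`trans`), each an unsigned 16-bit count matrix, plus
#' the physical pixel size.
#'
#' @param mt,ppix,trans Numeric matrices of identical dimensions with values
#'   in `[0, 65535]`.
#' @param subject_id Subject identifier (character scalar).
#' @param tile_index Zero-based tile index within the subject's tile scan.
#' @param um_per_px Physical scale, micrometres per pixel (`> 0`).
#' @return An object of class `mito_tile`.
#' @export
new_tile <- function(mt, ppix, trans, subject_id = "S1", tile_index = 0L,
                     um_per_px = 225 / 512) {
  stopifnot(is.matrix(mt), is.matrix(ppix), is.matrix(trans))
  if (!identical(dim(mt), dim(ppix)) || !identical(dim(mt), dim(trans)))
    stop("channel dimensions differ")
  if (um_per_px <= 0) stop("um_per_px must be > 0")
  structure(
    list(mt = mt, ppix = ppix, trans = trans,
         subject_id = as.character(subject_id),
         tile_index = as.integer(tile_index), um_per_px = um_per_px),
    class = "mito_tile")
}

#' @export
print.mito_tile <- function(x, ...) {
  cat(sprintf("<mito_tile> subject %s, tile %d, %d x %d px (%.4f um/px)\n",
              x$subject_id, x$tile_index, nrow(x$mt), ncol(x$mt), x$um_per_px))
  invisible(x)
}

#' Pack a tile into the RGB pseudocolor convention
#'
#' Maps MitoTracker to the red plane, PpIX to the green plane and transmitted
#' light to the blue plane of a 16-bit RGB image — the convention used when
#' tile scans of this kind are exported for object classification.
#'
#' @param tile A [new_tile()] object.
#' @return A `H x W x 3` numeric array (R, G, B) of 16-bit counts.
#' @seealso [unpack_pseudocolor()]
#' @export
pack_pseudocolor <- function(tile) {
  stopifnot(inherits(tile, "mito_tile"))
  h <- nrow(tile$mt); w <- ncol(tile$mt)
  rgb <- array(0, dim = c(h, w, 3L))
  rgb[, , 1L] <- tile$mt
  rgb[, , 2L] <- tile$ppix
  rgb[, , 3L] <- tile$trans
  rgb
}

#' Unpack an RGB pseudocolor image into a tile
#'
#' Inverse of [pack_pseudocolor()]: red plane becomes MitoTracker, green
#' PpIX, blue transmitted light.
#'
#' @param rgb A `H x W x 3` array of 16-bit counts.
#' @param subject_id,tile_index,um_per_px Tile metadata (not stored in the
#'   pixel array).
#' @return A `mito_tile`.
#' @export
unpack_pseudocolor <- function(rgb, subject_id = "S1", tile_index = 0L,
                               um_per_px = 225 / 512) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected an H x W x 3 array")
  if (any(rgb < 0 | rgb > 65535) || any(rgb != round(rgb)))
    stop("expected 16-bit integer counts in [0, 65535]")
  new_tile(mt = rgb[, , 1L], ppix = rgb[, , 2L], trans = rgb[, , 3L],
           subject_id = subject_id, tile_index = tile_index,
           um_per_px = um_per_px)
}

#' Split a tile-scan mosaic into individual tiles
#'
#' Cuts a large mosaic (as acquired in tile-scan mode) into `tile_px` square
#' tiles in row-major order. Dimensions must divide exactly; nothing is
#' cropped silently.
#'
#' @param mosaic A `mito_tile` whose channels hold the full mosaic.
#' @param tile_px Tile edge length in pixels.
#' @return List of `mito_tile`, row-major, with `tile_index` `0, 1, ...`.
#' @export
split_tilescan <- function(mosaic, tile_px) {
  stopifnot(inherits(mosaic, "mito_tile"))
  h <- nrow(mosaic$mt); w <- ncol(mosaic$mt)
  if (h %% tile_px != 0L || w %% tile_px != 0L)
    stop(sprintf("mosaic %d x %d is not divisible by tile_px = %d", h, w, tile_px))
  nr <- h %/% tile_px; nc <- w %/% tile_px
  out <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    ri <- ((r - 1L) * tile_px + 1L):(r * tile_px)
    ci <- ((cc - 1L) * tile_px + 1L):(cc * tile_px)
    out[[k + 1L]] <- new_tile(mosaic$mt[ri, ci], mosaic$ppix[ri, ci],
                              mosaic$trans[ri, ci],
                              subject_id = mosaic$subject_id, tile_index = k,
                              um_per_px = mosaic$um_per_px)
    k <- k + 1L
  }
  out
}

#' Tile file name for a subject/tile pair
#' @param subject_id Subject identifier.
#' @param tile_index Zero-based tile index.
#' @param ext File extension (default `"tif"`).
#' @return File name like `P11_T003.tif`.
#' @export
tile_filename <- function(subject_id, tile_index, ext = "tif") {
  sprintf("P%s_T%03d.%s", subject_id, as.integer(tile_index), ext)
}

#' Write / read a tile as 16-bit RGB TIFF with a JSON metadata sidecar
#'
#' The canonical on-disk form is the pseudocolor RGB TIFF (red = MitoTracker,
#' green = PpIX, blue = transmitted light) written by the package's own
#' baseline TIFF codec, plus `<file>.json` carrying `subject_id`,
#' `tile_index` and `um_per_px`.
#'
#' @param tile A `mito_tile`.
#' @param dir Output directory (created if missing).
#' @return `write_tile`: the TIFF path, invisibly. `read_tile`: a `mito_tile`.
#' @export
write_tile <- function(tile, dir) {
  stopifnot(inherits(tile, "mito_tile"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, tile_filename(tile$subject_id, tile$tile_index))
  rgb <- pack_pseudocolor(tile)
  write_tiff16(list(rgb[, , 1L], rgb[, , 2L], rgb[, , 3L]), path)
  meta <- list(subject_id = tile$subject_id, tile_index = tile$tile_index,
               um_per_px = tile$um_per_px)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tile
#' @param path Path to a tile TIFF written by [write_tile()].
#' @export
read_tile <- function(path) {
  chans <- read_tiff16(path)
  if (!is.list(chans) || length(chans) != 3L)
    stop("expected a 3-sample (RGB pseudocolor) TIFF: ", path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(subject_id = "S1", tile_index = 0L, um_per_px = 225 / 512)
  new_tile(mt = chans[[1L]], ppix = chans[[2L]], trans = chans[[3L]],
           subject_id = meta$subject_id, tile_index = meta$tile_index,
           um_per_px = meta$um_per_px)
}

#' Write / read the per-cell data table
#'
#' The per-cell measurement table: one row per retained singlet with patient
#' number, object size and total plus average-per-pixel fluorescence for both
#' channels. Column order is fixed
#' (`patient_id,object_size_px,ppix_total,ppix_mean,mt_total,mt_mean`); extra
#' measurement columns (e.g. `tile_index`, `granularity`) are appended after
#' the fixed block.
#'
#' @param records Data frame containing at least the fixed columns.
#' @param path CSV path.
#' @return `write_data_table`: `path` invisibly; `read_data_table`: the table.
#' @export
write_data_table <- function(records, path) {
  miss <- setdiff(DATA_TABLE_COLS, names(records))
  if (length(miss)) stop("missing data-table columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(records), DATA_TABLE_COLS)
  out <- records[, c(DATA_TABLE_COLS, extra), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_data_table
#' @export
read_data_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = c(patient_id = "character"))
  miss <- setdiff(DATA_TABLE_COLS, names(tab))
  if (length(miss)) stop("not a cell data table, missing: ",
                         paste(miss, collapse = ", "))
  tab
}
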