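#' Structure codes used in coded colonization grids
#'
#' Grid-intersect scoring assigns every cell of a 10 x 10 microscopic-field
#' grid one integer code: 0 marks a non-colonized (empty) cell, 1 hyphae,
#' 2 an arbuscule, 3 a vesicle, 4 a spore, 5 an auxiliary cell and
#' 6 an entry point. A cell holds exactly one code, so the structures
#' partition the occupied area of the field.
#'
#' @return Named integer vector mapping structure labels to codes.
#' @export
#' @examples
#' structure_codes()
structure_codes <- function() {
  c(empty = 0L, hyphae = 1L, arbuscule = 2L, vesicle = 3L,
    spore = 4L, auxiliary_cell = 5L, entry_point = 6L)
}

#' Colour legend for colonization maps
#'
#' Non-colonized cells render white, hyphae blue, arbuscules red, vesicles
#' green and entry points purple. Spores (orange) and auxiliary cells
#' (yellow) carry package-chosen colours.
#'
#' @return Named character vector mapping structure labels to colours.
#' @export
map_legend <- function() {
  c(empty = "white", hyphae = "blue", arbuscule = "red", vesicle = "green",
    spore = "orange", auxiliary_cell = "yellow", entry_point = "purple")
}

# one ASCII glyph per code 0..6, used by the text map format
.map_glyphs <- c(".", "H", "A", "V", "S", "X", "E")

#' @rdname structure_codes
#' @param code Integer vector of codes in 0..6.
#' @return `structure_label()` returns the label for each code.
#' @export
structure_label <- function(code) {
  codes <- structure_codes()
  if (!all(code %in% codes)) stop("structure code must be an integer in 0..6")
  names(codes)[match(code, codes)]
}

#' Construct a colonization grid for one microscopic field
#'
#' @param replication Replication number (1-based).
#' @param segment Segment number within the replication.
#' @param field Microscopic field number within the segment.
#' @param cells 10 x 10 integer matrix of structure codes (0..6). Rows are
#'   the transverse position; columns run along the root axis.
#'
#' @return An object of class `colonization_grid`: a list with elements
#'   `replication`, `segment`, `field` and `cells`.
#' @export
#' @examples
#' g <- colonization_grid(1, 1, 1)
#' g$cells[1, 1] <- 2L  # one arbuscule
colonization_grid <- function(replication, segment, field,
                              cells = matrix(0L, 10, 10)) {
  cells <- matrix(as.integer(cells), nrow = nrow(cells), ncol = ncol(cells))
  if (!identical(dim(cells), c(10L, 10L)))
    stop("`cells` must be a 10 x 10 matrix")
  if (anyNA(cells) || !all(cells %in% 0:6))
    stop("every cell must hold an integer structure code in 0..6")
  structure(
    list(replication = as.integer(replication),
         segment = as.integer(segment),
         field = as.integer(field),
         cells = cells),
    class = "colonization_grid"
  )
}

#' @export
print.colonization_grid <- function(x, ...) {
  cat(sprintf("<colonization_grid> replication %d, segment %d, field %d\n",
              x$replication, x$segment, x$field))
  cat(paste(apply(x$cells, 1, function(r) paste(.map_glyphs[r + 1L],
                                                collapse = "")),
            collapse = "\n"), "\n")
  invisible(x)
}

.grid_id <- function(g) sprintf("%d.%d.%d", g$replication, g$segment, g$field)

.grid_order <- function(grids) {
  order(vapply(grids, `[[`, 1L, "replication"),
        vapply(grids, `[[`, 1L, "segment"),
        vapply(grids, `[[`, 1L, "field"))
}

#' Read coded grids from a long-format table
#'
#' The on-disk format is a CSV with header
#' `replication,segment,field,row,col,code`, one row per (typically
#' non-empty) cell. Cells absent from the file default to code 0, so files
#' for lightly colonized roots stay sparse; dense files carrying explicit
#' code-0 rows are accepted. Indices are 1-based.
#'
#' @param path Path to the CSV file.
#' @return List of [colonization_grid()] objects, sorted by
#'   (replication, segment, field); empty list for a file with no data rows.
#' @export
read_grid_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("replication", "segment", "field", "row", "col", "code")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("grid table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(list())
  line <- seq_len(nrow(df)) + 1L  # file line numbers incl. header
  bad <- which(!(df$code %in% 0:6))
  if (length(bad))
    stop("structure code outside 0..6 at line(s) ",
         paste(line[bad], collapse = ", "))
  bad <- which(df$row < 1 | df$row > 10 | df$col < 1 | df$col > 10 |
                 df$row != as.integer(df$row) | df$col != as.integer(df$col))
  if (length(bad))
    stop("row/col outside 1..10 at line(s) ", paste(line[bad], collapse = ", "))
  key <- paste(df$replication, df$segment, df$field, df$row, df$col)
  if (anyDuplicated(key)) {
    first_dup <- key[duplicated(key)][1]
    at <- line[key == first_dup]
    stop("duplicate cell entry (replication segment field row col = ",
         first_dup, ") at lines ", paste(at, collapse = " and "))
  }
  pieces <- split(df, list(df$replication, df$segment, df$field), drop = TRUE)
  grids <- lapply(pieces, function(p) {
    cells <- matrix(0L, 10, 10)
    cells[cbind(p$row, p$col)] <- as.integer(p$code)
    colonization_grid(p$replication[1], p$segment[1], p$field[1], cells)
  })
  grids <- unname(grids)
  grids[.grid_order(grids)]
}

#' Write coded grids to a long-format table
#'
#' Inverse of [read_grid_table()]: only non-empty cells are written, except
#' that an entirely empty grid is represented by a single explicit code-0
#' row at (1, 1) so that it survives the round trip.
#'
#' @param grids Non-empty list of [colonization_grid()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(grids, path) {
  if (length(grids) == 0) stop("`grids` must be non-empty")
  grids <- grids[.grid_order(grids)]
  rows <- lapply(grids, function(g) {
    idx <- which(g$cells != 0L, arr.ind = TRUE)
    if (nrow(idx) == 0) idx <- cbind(row = 1L, col = 1L)
    data.frame(replication = g$replication, segment = g$segment,
               field = g$field, row = idx[, 1], col = idx[, 2],
               code = g$cells[idx])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$replication, out$segment, out$field,
                   out$col, out$row), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a colonization map from a coded grid
#'
#' Translates each structure code to its display colour, giving the
#' colour-coded 10 x 10 colonization map for the field; per-colour cell
#' counts equal per-code cell counts by construction.
#'
#' @param grid A [colonization_grid()].
#' @return An object of class `colonization_map`: list with `cell_colors`
#'   (10 x 10 character matrix), `legend`, `codes` (the source code matrix)
#'   and `id` fields.
#' @export
render_map <- function(grid) {
  stopifnot(inherits(grid, "colonization_grid"))
  legend <- map_legend()
  colors <- matrix(unname(legend[grid$cells + 1L]), 10, 10)
  structure(
    list(cell_colors = colors, legend = legend, codes = grid$cells,
         replication = grid$replication, segment = grid$segment,
         field = grid$field),
    class = "colonization_map"
  )
}

#' @export
print.colonization_map <- function(x, ...) {
  cat(sprintf("<colonization_map> replication %d, segment %d, field %d\n",
              x$replication, x$segment, x$field))
  tab <- table(factor(x$cell_colors, levels = unique(unname(x$legend))))
  cat(paste(sprintf("%s: %d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = ", "), "\n")
  invisible(x)
}

.draw_map_tiles <- function(codes_list, cell_px = 12) {
  n <- length(codes_list)
  legend <- map_legend()
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 10 * n), ylim = c(0, 10))
  for (i in seq_len(n)) {
    codes <- codes_list[[i]]
    xs <- rep(1:10, each = 10) + (i - 1) * 10
    ys <- rep(10:1, times = 10)
    graphics::rect(xs - 1, ys - 1, xs, ys,
                   col = unname(legend[codes + 1L]), border = "grey80",
                   lwd = 0.5)
  }
}

#' Export a colonization map as an image or text grid
#'
#' `text` writes one line per grid row with one glyph per cell
#' (`.` empty, `H` hyphae, `A` arbuscule, `V` vesicle, `S` spore,
#' `X` auxiliary cell, `E` entry point); this format round-trips exactly
#' via [read_map_text()]. `png` and `svg` draw the 10 x 10 colour tiles.
#'
#' @param map A `colonization_map` from [render_map()].
#' @param path Output file path.
#' @param format One of `"png"`, `"svg"`, `"text"`.
#' @param cell_px Pixel size of one cell for raster output.
#' @return `path`, invisibly.
#' @export
export_map_image <- function(map, path, format = c("png", "svg", "text"),
                             cell_px = 12) {
  stopifnot(inherits(map, "colonization_map"))
  format <- match.arg(format)
  if (format == "text") {
    lines <- apply(map$codes, 1, function(r)
      paste(.map_glyphs[r + 1L], collapse = ""))
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "png") {
    grDevices::png(path, width = 10 * cell_px, height = 10 * cell_px)
  } else {
    grDevices::svg(path, width = 10 * cell_px / 72, height = 10 * cell_px / 72)
  }
  on.exit(grDevices::dev.off())
  .draw_map_tiles(list(map$codes), cell_px)
  invisible(path)
}

#' Export several maps side by side as one composite image
#'
#' Concatenates the fields of one segment (or any set of maps) into a
#' single image strip, 10 rows high and `10 * length(maps)` cells wide.
#'
#' @param maps List of `colonization_map` objects.
#' @inheritParams export_map_image
#' @return `path`, invisibly.
#' @export
export_map_montage <- function(maps, path, format = c("png", "svg"),
                               cell_px = 12) {
  format <- match.arg(format)
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, TRUE, "colonization_map")))
  n <- length(maps)
  if (format == "png") {
    grDevices::png(path, width = 10 * n * cell_px, height = 10 * cell_px)
  } else {
    grDevices::svg(path, width = 10 * n * cell_px / 72,
                   height = 10 * cell_px / 72)
  }
  on.exit(grDevices::dev.off())
  .draw_map_tiles(lapply(maps, `[[`, "codes"), cell_px)
  invisible(path)
}

#' Parse a text-format colonization map back into a code matrix
#'
#' @param path Path to a text map written by
#'   `export_map_image(format = "text")`.
#' @return 10 x 10 integer matrix of structure codes.
#' @export
read_map_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) != 10 || any(nchar(lines) != 10))
    stop("text map must be 10 lines of 10 glyphs")
  chars <- do.call(rbind, strsplit(lines, ""))
  codes <- match(chars, .map_glyphs) - 1L
  if (anyNA(codes)) stop("unknown glyph in text map")
  matrix(codes, 10, 10)
}
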