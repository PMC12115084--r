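#' Environmental raster stack
#'
#' A lightweight in-memory container for a set of aligned environmental
#' layers (typically `bio1`...`bio19`, `elev`, `landcover`) sharing one
#' rectangular grid. Layers are stored as numeric matrices with row 1 at the
#' *top* of the map (the ESRI ASCII grid convention); `NA` marks nodata and
#' the nodata mask must be identical across layers.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param cell_size cell edge length in map units (e.g. km for synthetic
#'   metric grids).
#' @param origin numeric length-2, the (x, y) of the lower-left corner of
#'   the grid (ESRI `xllcorner`/`yllcorner`).
#' @param categorical character vector of layer names to treat as
#'   categorical (e.g. `"landcover"`).
#'
#' @return an object of class `env_stack` with elements `layers`,
#'   `n_rows`, `n_cols`, `cell_size`, `origin`, `categorical`.
#' @export
env_stack <- function(layers, cell_size = 1, origin = c(0, 0),
                      categorical = character()) {
  if (!is.list(layers) || length(layers) == 0L || is.null(names(layers)) ||
      any(names(layers) == "")) {
    stop("`layers` must be a non-empty named list of matrices", call. = FALSE)
  }
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share the same grid dimensions", call. = FALSE)
  }
  base_mask <- is.na(layers[[1]])
  for (nm in names(layers)) {
    if (!identical(is.na(layers[[nm]]), base_mask)) {
      stop("nodata mask of layer '", nm,
           "' differs from the other layers", call. = FALSE)
    }
  }
  if (!all(categorical %in% names(layers))) {
    stop("categorical names must match layer names", call. = FALSE)
  }
  structure(
    list(layers = layers,
         n_rows = dims[1, 1], n_cols = dims[2, 1],
         cell_size = cell_size,
         origin = as.numeric(origin),
         categorical = categorical),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> ", length(x$layers), " layers, ",
      x$n_rows, " x ", x$n_cols, " cells (cell size ", x$cell_size, ")\n",
      sep = "")
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat("  valid cells:", sum(!is.na(x$layers[[1]])), "\n")
  invisible(x)
}

# Linear indices (column-major over the matrix) of non-nodata cells.
valid_cells <- function(stack) which(!is.na(stack$layers[[1]]))

#' Cell-centre coordinates of grid cells
#'
#' @param stack an [env_stack()].
#' @param cells integer vector of linear (column-major) cell indices;
#'   defaults to all valid cells.
#' @return data.frame with columns `cell`, `x`, `y`.
#' @export
cell_coordinates <- function(stack, cells = valid_cells(stack)) {
  row <- (cells - 1L) %% stack$n_rows + 1L
  col <- (cells - 1L) %/% stack$n_rows + 1L
  data.frame(
    cell = cells,
    x = stack$origin[1] + (col - 0.5) * stack$cell_size,
    y = stack$origin[2] + (stack$n_rows - row + 0.5) * stack$cell_size
  )
}

#' Map (x, y) coordinates to linear cell indices
#'
#' Points outside the grid extent get `NA`.
#'
#' @param stack an [env_stack()].
#' @param x,y coordinate vectors in map units.
#' @return integer vector of column-major cell indices (`NA` outside).
#' @export
cell_index <- function(stack, x, y) {
  col <- floor((x - stack$origin[1]) / stack$cell_size) + 1L
  row <- stack$n_rows - floor((y - stack$origin[2]) / stack$cell_size)
  bad <- col < 1L | col > stack$n_cols | row < 1L | row > stack$n_rows |
    !is.finite(x) | !is.finite(y)
  idx <- (col - 1L) * stack$n_rows + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Extract layer values at cells or coordinates
#'
#' @param stack an [env_stack()].
#' @param cells linear cell indices, or `NULL` to use `x`/`y`.
#' @param x,y coordinates used when `cells` is `NULL`.
#' @param layers layer names (default all).
#' @return data.frame, one row per input location, one column per layer;
#'   nodata cells and out-of-extent points yield `NA` rows.
#' @export
extract_env <- function(stack, cells = NULL, x = NULL, y = NULL,
                        layers = names(stack$layers)) {
  if (is.null(cells)) {
    stopifnot(!is.null(x), !is.null(y), length(x) == length(y))
    cells <- cell_index(stack, x, y)
  }
  out <- lapply(layers, function(nm) {
    v <- rep(NA_real_, length(cells))
    ok <- !is.na(cells)
    v[ok] <- stack$layers[[nm]][cells[ok]]
    v
  })
  names(out) <- layers
  as.data.frame(out, optional = TRUE)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @return list with `matrix` (row 1 = top), `cell_size`, `origin`,
#'   `nodata_value`.
#' @export
read_asc <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  n_hdr <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      seek(con, pos)
      break
    }
  }
  for (req in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[req]])) {
      stop("malformed .asc header: missing '", req, "' in ", path,
           call. = FALSE)
    }
  }
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " cell values, got ", length(vals),
         " in ", path, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(matrix = m, cell_size = hdr$cellsize, origin = c(xll, yll),
       nodata_value = nodata)
}

#' Write a matrix as an ESRI ASCII grid (.asc)
#'
#' @param m numeric matrix, row 1 = top of the map; `NA` written as the
#'   nodata value.
#' @param path output file path.
#' @param cell_size,origin grid geometry as in [env_stack()].
#' @param nodata_value value used to encode `NA`.
#' @return `path`, invisibly.
#' @export
write_asc <- function(m, path, cell_size = 1, origin = c(0, 0),
                      nodata_value = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(origin[1], scientific = FALSE)),
    paste("yllcorner", format(origin[2], scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata_value)
  ), con)
  m[is.na(m)] <- nodata_value
  for (i in seq_len(nrow(m))) {
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE,
                            digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' Read a directory of .asc layers into an env_stack
#'
#' Layer names are taken from file names (`bio1.asc` -> `bio1`).
#'
#' @param dir directory containing `.asc` files.
#' @param categorical layer names to flag categorical.
#' @return an [env_stack()].
#' @export
read_env_dir <- function(dir, categorical = "landcover") {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (length(files) == 0L) stop("no .asc files in ", dir, call. = FALSE)
  grids <- lapply(files, read_asc)
  names(grids) <- sub("\\.asc$", "", basename(files))
  layers <- lapply(grids, `[[`, "matrix")
  env_stack(layers,
            cell_size = grids[[1]]$cell_size,
            origin = grids[[1]]$origin,
            categorical = intersect(categorical, names(layers)))
}

#' Write every layer of an env_stack to a directory of .asc files
#'
#' @param stack an [env_stack()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_env_dir <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_asc(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")),
              cell_size = stack$cell_size, origin = stack$origin)
  }
  invisible(dir)
}
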