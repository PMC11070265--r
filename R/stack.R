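#' In-memory raster stack of co-registered covariate layers
#'
#' A `layer_stack` holds named real-valued layers on one shared north-up grid
#' (row 1 is the northern edge; x grows with column, y grows southward to
#' northward with decreasing row). It is the package's stand-in for a
#' multi-band covariate raster: all layers share the grid shape, the affine
#' transform is `(xll, yll, pixel_size)` in metres, and an optional logical
#' `mask` marks valid pixels (`FALSE` = NoData).
#'
#' @param values named list of numeric matrices, all with identical dimensions.
#' @param pixel_size pixel edge length in metres (default 30, the resolution
#'   the covariate products are mapped at).
#' @param xll,yll x/y coordinate of the lower-left corner of the grid, metres.
#' @param mask optional logical matrix with the layer dimensions; `FALSE`
#'   pixels are treated as NoData everywhere downstream.
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(values, pixel_size = 30, xll = 0, yll = 0, mask = NULL) {
  if (!is.list(values) || length(values) == 0L)
    stop("`values` must be a non-empty named list of matrices")
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("layers must have unique names")
  dims <- lapply(values, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("all layers must be matrices")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all layers must share the same grid shape")
  if (any(d1 <= 0)) stop("grid dimensions must be positive")
  if (!is.null(mask) && !identical(dim(mask), d1))
    stop("mask must match the layer dimensions")
  structure(list(values = values, pixel_size = pixel_size,
                 xll = xll, yll = yll, mask = mask),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  d <- dim(x$values[[1]])
  cat(sprintf("layer_stack: %d x %d pixels, %d layer(s), %g m pixels\n",
              d[1], d[2], length(x$values), x$pixel_size))
  cat("layers:", paste(names(x$values), collapse = ", "), "\n")
  invisible(x)
}

stack_shape <- function(stack) dim(stack$values[[1]])

#' Pixel-centre coordinates of a stack, row-major order
#'
#' Returns the x/y centre coordinates (metres) of every pixel in row-major
#' order (row 1 first, i.e. from the northern edge), matching the flattening
#' used by [stack_to_matrix()].
#'
#' @param stack a [layer_stack()].
#' @return data.frame with columns `row`, `col`, `x`, `y`.
#' @export
pixel_centres <- function(stack) {
  d <- stack_shape(stack)
  rows <- rep(seq_len(d[1]), each = d[2])
  cols <- rep(seq_len(d[2]), times = d[1])
  data.frame(
    row = rows, col = cols,
    x = stack$xll + (cols - 0.5) * stack$pixel_size,
    y = stack$yll + (d[1] - rows + 0.5) * stack$pixel_size)
}

#' Flatten a stack to a pixels-by-layers matrix
#'
#' Row-major flattening (row 1 of the grid first). Masked pixels are kept in
#' place (their covariate values are returned as stored); use the `mask`
#' attribute to drop them.
#'
#' @param stack a [layer_stack()].
#' @return numeric matrix, `n_pixels x n_layers`, with an attribute `valid`
#'   (logical vector, `FALSE` for masked pixels).
#' @export
stack_to_matrix <- function(stack) {
  d <- stack_shape(stack)
  X <- vapply(stack$values, function(m) as.vector(t(m)),
              numeric(prod(d)))
  X <- matrix(X, ncol = length(stack$values),
              dimnames = list(NULL, names(stack$values)))
  valid <- if (is.null(stack$mask)) rep(TRUE, prod(d)) else as.vector(t(stack$mask))
  attr(X, "valid") <- valid
  X
}

#' Write / read a single layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows from north to south.
#' `NA` is written as the NoData value (-9999).
#'
#' @param m numeric matrix (row 1 = north).
#' @param path file path (`.asc`).
#' @param xll,yll lower-left corner, metres.
#' @param pixel_size cell size, metres.
#' @param nodata NoData sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, xll = 0, yll = 0, pixel_size = 30,
                             nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(pixel_size, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  writeLines(apply(formatC(mm, format = "g", digits = 9), 1, paste,
                   collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return for `read_ascii_grid`: a list with `values` (matrix, NoData as
#'   `NA`), `xll`, `yll`, `pixel_size`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  list(values = m, xll = h[["xllcorner"]], yll = h[["yllcorner"]],
       pixel_size = h[["cellsize"]])
}

#' Write / read a whole stack as one ASCII grid per layer
#'
#' Layer names become file names (`<name>.asc`); a mask, if present, is
#' written as `mask.asc` (1 valid / NoData elsewhere).
#'
#' @param stack a [layer_stack()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths (for `write_stack_asc`);
#'   a [layer_stack()] (for `read_stack_asc`).
#' @export
write_stack_asc <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(stack$values)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    m <- stack$values[[nm]]
    if (!is.null(stack$mask)) m[!stack$mask] <- NA
    write_ascii_grid(m, p, stack$xll, stack$yll, stack$pixel_size)
    paths <- c(paths, p)
  }
  paths
}

#' @rdname write_stack_asc
#' @param paths `.asc` files sharing one grid; layer names are taken from the
#'   file names.
#' @export
read_stack_asc <- function(paths) {
  gs <- lapply(paths, read_ascii_grid)
  ref <- gs[[1]]
  for (g in gs) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        g$xll != ref$xll || g$yll != ref$yll ||
        g$pixel_size != ref$pixel_size)
      stop("ASCII grids do not share one grid/transform: ",
           paste(basename(unlist(paths)), collapse = ", "))
  }
  vals <- lapply(gs, `[[`, "values")
  names(vals) <- sub("\\.asc$", "", basename(unlist(paths)))
  anyna <- Reduce(`|`, lapply(vals, is.na))
  mask <- if (any(anyna)) !anyna else NULL
  vals <- lapply(vals, function(m) { m[anyna] <- 0; m })
  layer_stack(vals, ref$pixel_size, ref$xll, ref$yll, mask)
}
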