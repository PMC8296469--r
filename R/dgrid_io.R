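#' Read a DGRID v1 text grid
#'
#' DGRID v1 is the package's plain-text exchange format for dose grids and
#' masks. Layout: line 1 `DGRID 1`; line 2 `dims nx ny nz`; line 3
#' `origin ox oy oz`; line 4 `spacing sx sy sz`; line 5 `unit Gy` or
#' `unit mask`; then whitespace-separated payload values in x-fastest order.
#'
#' @param path path to a DGRID v1 file.
#' @return A [dose_grid()] when the unit line is `Gy`, a [voxel_mask()] when
#'   it is `mask`.
#' @seealso [write_dgrid()]
#' @export
read_dgrid <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  lines <- character(5)
  for (i in 1:5) {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L)
      stop(sprintf("format error in %s: truncated header (line %d missing)", path, i),
           call. = FALSE)
    lines[i] <- ln
  }
  if (!identical(trimws(lines[1]), "DGRID 1"))
    stop(sprintf("format error in %s: line 1 must be 'DGRID 1', got '%s'", path, lines[1]),
         call. = FALSE)
  parse_triple <- function(line, key, lineno, integer = FALSE) {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) != 4L || tok[1] != key)
      stop(sprintf("format error in %s: line %d must be '%s a b c', got '%s'",
                   path, lineno, key, line), call. = FALSE)
    val <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(val))
      stop(sprintf("format error in %s: non-numeric %s on line %d", path, key, lineno),
           call. = FALSE)
    val
  }
  dims    <- parse_triple(lines[2], "dims", 2)
  origin  <- parse_triple(lines[3], "origin", 3)
  spacing <- parse_triple(lines[4], "spacing", 4)
  utok <- strsplit(trimws(lines[5]), "[[:space:]]+")[[1]]
  if (length(utok) != 2L || utok[1] != "unit" || !(utok[2] %in% c("Gy", "mask")))
    stop(sprintf("format error in %s: line 5 must be 'unit Gy' or 'unit mask', got '%s'",
                 path, lines[5]), call. = FALSE)
  header <- grid_header(dims, origin, spacing)
  values <- scan(con, what = numeric(), quiet = TRUE)
  if (length(values) != n_voxels(header))
    stop(sprintf("size error in %s: header promises %d values, payload has %d",
                 path, n_voxels(header), length(values)), call. = FALSE)
  if (utok[2] == "Gy") dose_grid(header, values) else voxel_mask(header, values)
}

#' Write a DGRID v1 text grid
#'
#' Doses are serialized with 17 significant digits so that a
#' write/read round trip reproduces the values bit-exactly at double
#' precision. Masks are written as 0/1 with unit line `mask`.
#'
#' @param grid a [dose_grid()] or [voxel_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dgrid <- function(grid, path) {
  if (inherits(grid, "dose_grid")) {
    unit <- "Gy"
    payload <- sprintf("%.17g", grid$values)
  } else if (inherits(grid, "voxel_mask")) {
    unit <- "mask"
    payload <- as.character(as.integer(grid$flags))
  } else {
    stop("`grid` must be a dose_grid or voxel_mask", call. = FALSE)
  }
  h <- grid$header
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("I/O error: cannot open '%s' for writing", path),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c("DGRID 1",
               sprintf("dims %d %d %d", h$dims[1], h$dims[2], h$dims[3]),
               sprintf("origin %.17g %.17g %.17g", h$origin[1], h$origin[2], h$origin[3]),
               sprintf("spacing %.17g %.17g %.17g", h$spacing[1], h$spacing[2], h$spacing[3]),
               sprintf("unit %s", unit)), con)
  # chunk the payload into lines of 8 values to keep files diffable
  idx <- seq_along(payload)
  rows <- split(payload, (idx - 1L) %/% 8L)
  writeLines(vapply(rows, paste, "", collapse = " "), con)
  invisible(path)
}
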