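#' Read and write hyperspectral cubes
#'
#' Two lossless on-disk layouts are supported:
#' \describe{
#'   \item{`"h5"`}{HDF5 with datasets `cube` (`H x W x C` float64) and
#'     `wavelengths_nm` (`C` float64), a root attribute `role`, and
#'     free-form metadata under the group `meta/`.}
#'   \item{`"hsz"`}{a single-file gzip-compressed array archive with the
#'     same keys: a JSON header (dims, role, metadata) followed by the
#'     wavelength grid and the cube values as little-endian float64.}
#' }
#' Both round-trip values bit-exactly together with grid, role and
#' metadata.
#'
#' @param cube A [hypercube].
#' @param path File path. With `format = "auto"`, `.h5`/`.hdf5` selects
#'   HDF5 and anything else the archive format.
#' @param format `"auto"`, `"h5"` or `"hsz"`.
#' @return `read_cube` returns a [hypercube]; `write_cube` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".hsz")
#' cube <- hypercube(array(runif(32), c(4, 4, 2)), c(500, 505))
#' write_cube(cube, f)
#' identical(read_cube(f)$values, cube$values)
#' @export
write_cube <- function(cube, path, format = c("auto", "h5", "hsz")) {
  stop_if_not_cube(cube)
  format <- resolve_format(match.arg(format), path)
  if (format == "h5") write_cube_h5(cube, path) else write_cube_hsz(cube, path)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, format = c("auto", "h5", "hsz")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  format <- resolve_format(match.arg(format), path)
  if (format == "h5") read_cube_h5(path) else read_cube_hsz(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) "h5" else "hsz"
}

write_cube_h5 <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$values, path, "cube")
  rhdf5::h5write(cube$wavelengths, path, "wavelengths_nm")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(cube$role, fid, "role")
  if (length(cube$metadata)) {
    rhdf5::h5createGroup(fid, "meta")
    for (key in names(cube$metadata))
      rhdf5::h5write(cube$metadata[[key]], fid, paste0("meta/", key))
  }
  invisible(path)
}

read_cube_h5 <- function(path) {
  contents <- rhdf5::h5ls(path)
  names_present <- contents$name[contents$group == "/"]
  if (!("wavelengths_nm" %in% names_present))
    stop(sprintf("format error in %s: missing dataset 'wavelengths_nm'", path))
  if (!("cube" %in% names_present))
    stop(sprintf("format error in %s: missing dataset 'cube'", path))
  values <- rhdf5::h5read(path, "cube")
  if (length(dim(values)) != 3L)
    stop(sprintf("format error in %s: dataset 'cube' is not 3-dimensional",
                 path))
  wavelengths <- as.numeric(rhdf5::h5read(path, "wavelengths_nm"))
  fid <- rhdf5::H5Fopen(path)
  attrs <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  role <- if (!is.null(attrs$role)) as.character(attrs$role) else
    stop(sprintf("format error in %s: missing attribute 'role'", path))
  metadata <- list()
  meta_rows <- contents[contents$group == "/meta", , drop = FALSE]
  if (nrow(meta_rows)) {
    for (key in meta_rows$name)
      metadata[[key]] <- drop_h5(rhdf5::h5read(path, paste0("meta/", key)))
  }
  hypercube(values, wavelengths, role = role, metadata = metadata)
}

drop_h5 <- function(x) if (is.array(x) && length(dim(x)) == 1L) as.vector(x) else x

HSZ_MAGIC <- "SPECCUBE1"

write_cube_hsz <- function(cube, path) {
  header <- jsonlite::toJSON(list(
    magic = HSZ_MAGIC,
    dims = dim(cube$values),
    role = cube$role,
    meta = cube$metadata
  ), auto_unbox = TRUE, digits = NA)
  con <- gzfile(path, "wb")
  on.exit(close(con), add = TRUE)
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(cube$wavelengths, con, size = 8L, endian = "little")
  writeBin(as.vector(cube$values), con, size = 8L, endian = "little")
  invisible(path)
}

read_cube_hsz <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(hlen) || is.na(hlen) || hlen <= 0 || hlen > 1e8)
    stop(sprintf("format error in %s: corrupt header length", path))
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(header$magic, HSZ_MAGIC))
    stop(sprintf("format error in %s: missing or wrong magic", path))
  if (is.null(header$dims) || length(header$dims) != 3L)
    stop(sprintf("format error in %s: missing field 'dims'", path))
  d <- as.integer(header$dims)
  wavelengths <- readBin(con, "double", d[3], size = 8L, endian = "little")
  if (length(wavelengths) != d[3])
    stop(sprintf("format error in %s: truncated field 'wavelengths_nm'", path))
  n <- prod(d)
  values <- readBin(con, "double", n, size = 8L, endian = "little")
  if (length(values) != n)
    stop(sprintf("format error in %s: truncated field 'cube'", path))
  meta <- header$meta
  if (is.null(meta) || !length(meta)) meta <- list()
  hypercube(array(values, d), wavelengths, role = header$role,
            metadata = as.list(meta))
}

#' Save and load an illumination library
#'
#' A library is persisted as a directory of cube files (`cube_0001.h5`,
#' ...) plus a `manifest.json` recording cluster labels, provenance, `K`
#' and the clustering seed.
#'
#' @param library An `illumination_library` (see [cluster_library()]).
#' @param dir Directory path (created if needed).
#' @param format Cube file format, `"h5"` or `"hsz"`.
#' @return `write_library` returns `dir` invisibly; `read_library` the
#'   restored library.
#' @export
write_library <- function(library, dir, format = c("h5", "hsz")) {
  format <- match.arg(format)
  if (!inherits(library, "illumination_library"))
    stop("library must be an illumination_library")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("cube_%04d.%s", seq_along(library$white_refs), format)
  for (i in seq_along(files))
    write_cube(library$white_refs[[i]], file.path(dir, files[i]), format)
  manifest <- list(files = files, labels = library$labels, K = library$K,
                   provenance = library$provenance, seed = library$seed)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf("format error: missing manifest.json in %s", dir))
  manifest <- jsonlite::fromJSON(mf)
  cubes <- lapply(file.path(dir, manifest$files), read_cube)
  new_illumination_library(cubes, as.integer(manifest$labels),
                           as.integer(manifest$K),
                           as.character(manifest$provenance),
                           manifest$seed)
}

#' Save and load a white-reference model checkpoint
#'
#' A checkpoint is a single gzip-compressed file: a JSON header (the model
#' configuration, training state, wavelength grid) followed by all
#' parameters as little-endian float64, restoring the model bit-exactly.
#'
#' @param model A `whiteref_model`.
#' @param path Checkpoint file path.
#' @return `write_model` returns `path` invisibly; `read_model` the
#'   restored `whiteref_model`.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "whiteref_model")) stop("model must be a whiteref_model")
  cfg <- model$config
  header <- jsonlite::toJSON(list(
    magic = "SPECCKPT1",
    mode = cfg$mode, channels = cfg$channels,
    input_kernel = cfg$input_kernel, kernel = cfg$kernel,
    downsample_every = cfg$downsample_every, normalize = cfg$normalize,
    trained = model$trained,
    grid = if (is.null(model$grid)) NULL else model$grid
  ), auto_unbox = TRUE, digits = NA, null = "null")
  theta <- coef(model)
  con <- gzfile(path, "wb")
  on.exit(close(con), add = TRUE)
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  writeBin(length(theta), con, size = 4L, endian = "little")
  writeBin(theta, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(header$magic, "SPECCKPT1"))
    stop(sprintf("format error in %s: not a model checkpoint", path))
  cfg <- model_config(header$mode, channels = header$channels,
                      input_kernel = header$input_kernel,
                      kernel = header$kernel,
                      downsample_every = header$downsample_every,
                      normalize = header$normalize)
  model <- build_model(cfg, seed = 1L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  theta <- readBin(con, "double", n, size = 8L, endian = "little")
  paths <- conv_paths(model$layers)
  model$layers <- unflatten_wb(model$layers, paths, theta)
  model$trained <- isTRUE(header$trained)
  if (!is.null(header$grid)) model$grid <- as.numeric(header$grid)
  model
}
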