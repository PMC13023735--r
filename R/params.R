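# Flat parameter vector with a shape registry: the unit exchanged between
# clients and the server. All aggregation rules operate on the `values`
# field; the registry maps layer names to array dimensions for the model
# forward/backward passes and for checkpoint round-trips.

#' Construct a parameter vector
#'
#' @param values numeric vector of parameter values (finite).
#' @param shapes named list mapping layer names to integer dimension vectors;
#'   the total number of elements must equal `length(values)`.
#' @return object of class `parameter_vector`.
#' @export
param_vector <- function(values, shapes) {
  sizes <- vapply(shapes, function(d) prod(d), numeric(1))
  if (sum(sizes) != length(values)) {
    stop("total registry size does not match length(values)")
  }
  if (any(!is.finite(values))) stop("parameter values must be finite")
  structure(list(values = as.numeric(values), shapes = shapes),
            class = "parameter_vector")
}

#' @export
length.parameter_vector <- function(x) length(x$values)

# Extract one layer as an array with its registered shape.
param_get <- function(pv, name) {
  shapes <- pv$shapes
  off <- 0L
  for (nm in names(shapes)) {
    sz <- prod(shapes[[nm]])
    if (nm == name) {
      v <- pv$values[(off + 1):(off + sz)]
      return(if (length(shapes[[nm]]) == 1) v else array(v, shapes[[nm]]))
    }
    off <- off + sz
  }
  stop("unknown layer: ", name)
}

# Unpack all layers into a named list of arrays.
param_unpack <- function(pv) {
  out <- list()
  off <- 0L
  for (nm in names(pv$shapes)) {
    d <- pv$shapes[[nm]]
    sz <- prod(d)
    v <- pv$values[(off + 1):(off + sz)]
    out[[nm]] <- if (length(d) == 1) v else array(v, d)
    off <- off + sz
  }
  out
}

# Pack a named list of arrays (in registry order) into a parameter vector.
param_pack <- function(layers, shapes) {
  param_vector(unlist(lapply(names(shapes), function(nm) as.numeric(layers[[nm]]))),
               shapes)
}

param_zeros_like <- function(pv) param_vector(numeric(length(pv$values)), pv$shapes)

#' Write / read a parameter checkpoint
#'
#' Checkpoints are stored as raw little-endian float32 values with a JSON
#' sidecar (`<path>.json`) recording the shape registry and byte order, so
#' they are portable and diffable without any binary container format.
#'
#' @param pv a [param_vector()].
#' @param path file path for the raw values.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the reconstructed `parameter_vector`.
#' @export
write_checkpoint <- function(pv, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pv$values, con, size = 4L, endian = "little")
  meta <- list(shapes = pv$shapes, n = length(pv$values),
               dtype = "float32", byte_order = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  values <- readBin(con, "numeric", n = meta$n, size = 4L, endian = "little")
  shapes <- lapply(meta$shapes, as.integer)
  param_vector(values, shapes)
}
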