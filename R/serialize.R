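#' Save and load models as JSON
#'
#' Plain-text serialization for networks and fitted pipelines: weight
#' matrices, factor matrices, centring data, partition, and provenance
#' (variant, seeds, control) are written as a documented JSON container so a
#' fitted model replays identically after a round trip.
#'
#' @param object an `elman_net` or `plsca_model`.
#' @param path output file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the restored object.
#' @export
write_model_json <- function(object, path) {
  kind <- class(object)[1]
  if (!kind %in% c("elman_net", "plsca_model")) {
    abort("only elman_net and plsca_model objects are serializable")
  }
  payload <- list(kind = kind, version = 1L, body = encode_node(object))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  decode_node(payload$body)
}

# recursive encoding: matrices keep their dimensions, classed lists their
# class; tibbles become column records
encode_node <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) {
    list(`_type` = "matrix", dim = dim(x), data = as.vector(x),
         dimnames = lapply(dimnames(x) %||% list(), identity))
  } else if (is.data.frame(x)) {
    list(`_type` = "tbl", class = class(x), columns = lapply(as.list(x), identity))
  } else if (is.list(x)) {
    out <- list(`_type` = "list", class = class(x),
                names = names(x) %||% character(),
                items = lapply(x, encode_node))
    out
  } else if (is.function(x)) {
    NULL
  } else {
    list(`_type` = "atomic", mode = typeof(x), data = x)
  }
}

decode_node <- function(node) {
  if (is.null(node)) return(NULL)
  type <- node$`_type`
  if (type == "matrix") {
    m <- matrix(unlist(node$data), unlist(node$dim)[1], unlist(node$dim)[2])
    if (length(node$dimnames) == 2) {
      dimnames(m) <- lapply(node$dimnames, function(d) unlist(d) %||% NULL)
    }
    m
  } else if (type == "tbl") {
    cols <- lapply(node$columns, unlist)
    out <- tibble::as_tibble(cols)
    class(out) <- unlist(node$class)
    out
  } else if (type == "list") {
    items <- lapply(node$items, decode_node)
    nm <- unlist(node$names)
    if (length(nm) == length(items)) names(items) <- nm
    cls <- unlist(node$class)
    if (!identical(cls, "list")) class(items) <- cls
    items
  } else {
    v <- unlist(node$data)
    if (is.null(v)) v <- vector(node$mode, 0)
    mode_target <- node$mode
    if (mode_target == "integer") v <- as.integer(v)
    if (mode_target == "double") v <- as.double(v)
    if (mode_target == "logical") v <- as.logical(v)
    if (mode_target == "character") v <- as.character(v)
    v
  }
}
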