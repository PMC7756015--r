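## Geometry JSON schema version written/accepted by this package.
GEOMETRY_SCHEMA <- "coaflow-geometry/1.0"

#' Write / read an aortic network as JSON
#'
#' Serializes an [aorta_network()] to a versioned JSON document with explicit
#' unit fields (`cm` for lengths and diameters).  `read_aorta_network()`
#' validates the document against the schema and reconstructs the network
#' through the ordinary constructors, so a file that violates a geometry
#' invariant is rejected rather than silently loaded.
#'
#' @param network an [aorta_network()]
#' @param path file path
#' @return `write_aorta_network()` returns `path` invisibly;
#'   `read_aorta_network()` returns an [aorta_network()].
#' @export
write_aorta_network <- function(network, path) {
  stopifnot(inherits(network, "aorta_network"))
  segs <- lapply(network$segments, function(s) {
    out <- list(id = s$id, length_cm = s$length,
                radius_profile = list(pos_cm = s$radius_profile$pos,
                                      radius_cm = s$radius_profile$radius),
                is_lesion = s$is_lesion)
    if (s$is_lesion) {
      out$lesion_start_cm <- s$lesion_start
      out$lesion_end_cm <- s$lesion_end
    }
    out
  })
  doc <- list(schema = GEOMETRY_SCHEMA, units = list(length = "cm"),
              inlet_node = network$inlet_node,
              segments = unname(segs),
              connections = network$connections,
              outlets = data.frame(id = network$outlets$id,
                                   node = network$outlets$node,
                                   diameter_cm = network$outlets$diameter),
              diaphragm_diameter_cm = network$diaphragm_diameter,
              lesion_k_e = network$lesion_k_e,
              lesion_transitional = network$lesion_transitional)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aorta_network
#' @export
read_aorta_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, GEOMETRY_SCHEMA))
    stop("unsupported geometry schema: ", doc$schema, call. = FALSE)
  segs <- doc$segments
  if (is.data.frame(segs)) segs <- split(segs, seq_len(nrow(segs)))
  segments <- lapply(segs, function(s) {
    if (is.data.frame(s)) s <- as.list(s)
    rp <- s$radius_profile
    if (is.list(rp) && !is.data.frame(rp) && length(rp) == 1L) rp <- rp[[1L]]
    vessel_segment(id = s$id[[1L]], length = s$length_cm[[1L]],
                   radius_profile = data.frame(pos = unlist(rp$pos_cm),
                                               radius = unlist(rp$radius_cm)),
                   is_lesion = isTRUE(s$is_lesion[[1L]]),
                   lesion_start = if (isTRUE(s$is_lesion[[1L]]))
                     s$lesion_start_cm[[1L]],
                   lesion_end = if (isTRUE(s$is_lesion[[1L]]))
                     s$lesion_end_cm[[1L]])
  })
  outlets <- data.frame(id = doc$outlets$id, node = doc$outlets$node,
                        diameter = doc$outlets$diameter_cm)
  aorta_network(segments = segments, connections = doc$connections,
                inlet_node = doc$inlet_node, outlets = outlets,
                diaphragm_diameter = doc$diaphragm_diameter_cm,
                lesion_k_e = doc$lesion_k_e %||% 1,
                lesion_transitional = doc$lesion_transitional %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
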