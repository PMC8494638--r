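#' @title SWC reconstruction input/output
#' @description Read and write 7-column SWC morphology files. Dialect:
#'   1-based node ids, type codes 1 = soma, 2 = axon, 3 = basal dendrite,
#'   4 = apical dendrite, coordinates in micrometres with y increasing toward
#'   the pia (aligned morphologies place the pia at y = 0, so somatic y is
#'   negative).
#' @name swc
NULL

.swc_types <- c("1" = "soma", "2" = "axon", "3" = "basal", "4" = "apical")

#' Construct a morphology object
#'
#' @param nodes data.frame with columns `id`, `type` (one of soma/axon/
#'   basal/apical, or a numeric code as character for unknown types), `x`,
#'   `y`, `z` (um), `radius` (um), `parent` (-1 for roots).
#' @param validate Check tree invariants: exactly one soma root, parents
#'   precede children, no cycles; extra roots are only permitted for axon
#'   fragments that could not be traced back to the main structure.
#' @return Object of class `morphology` (a data.frame of nodes).
#' @export
morphology <- function(nodes, validate = TRUE) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) stop("nodes missing required columns")
  nodes <- nodes[, need]
  if (validate) .validate_morphology(nodes)
  class(nodes) <- c("morphology", "data.frame")
  nodes
}

.validate_morphology <- function(nodes) {
  if (any(duplicated(nodes$id))) stop("duplicate node ids")
  if (any(nodes$parent == nodes$id)) stop("node is its own parent (cycle)")
  roots <- nodes$parent == -1
  if (sum(roots & nodes$type == "soma") != 1)
    stop("morphology must have exactly one soma root")
  if (any(roots & !nodes$type %in% c("soma", "axon")))
    stop("non-axon node disconnected from the tree")
  pos <- match(nodes$parent, nodes$id)
  bad <- !roots & is.na(pos)
  if (any(bad)) stop("malformed parent reference")
  if (any(!roots & pos >= seq_len(nrow(nodes))))
    stop("parent must precede child")
  invisible(TRUE)
}

#' @rdname swc
#' @param path File path.
#' @return `read_swc`: a [morphology()]. `write_swc`: `path`, invisibly.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty SWC file")
  m <- utils::read.table(text = lines, col.names =
                           c("id", "code", "x", "y", "z", "radius", "parent"))
  type <- unname(.swc_types[as.character(m$code)])
  if (any(is.na(type))) {
    warning("unknown SWC type codes preserved verbatim: ",
            paste(unique(m$code[is.na(type)]), collapse = ", "))
    type[is.na(type)] <- as.character(m$code[is.na(type)])
  }
  morphology(data.frame(id = m$id, type = type, x = m$x, y = m$y, z = m$z,
                        radius = m$radius, parent = m$parent))
}

#' @rdname swc
#' @param m A [morphology()].
#' @export
write_swc <- function(m, path) {
  code <- match(m$type, .swc_types)
  code[is.na(code)] <- suppressWarnings(as.integer(m$type[is.na(code)]))
  df <- data.frame(m$id, code, m$x, m$y, m$z, m$radius, m$parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent (um; y increases toward pia)",
             con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %d nodes (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$type)), table(x$type)),
                    collapse = ", ")))
  invisible(x)
}
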