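#' Helix/loop segment annotation with membrane topology
#'
#' @param name segment names (character)
#' @param start,end 1-based reference residue numbers, start <= end
#' @param kind one of \code{"TM"}, \code{"surface_helix"}, \code{"loop"}
#'   per segment
#' @param side one of \code{"cytoplasmic"}, \code{"periplasmic"},
#'   \code{"membrane"} per segment
#' @return object of class \code{helix_annotation} (a data frame)
#' @export
helix_annotation <- function(name, start, end, kind, side) {
  df <- data.frame(name = as.character(name), start = as.integer(start),
                   end = as.integer(end), kind = as.character(kind),
                   side = as.character(side), stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("segment start must be <= end")
  if (!all(df$kind %in% c("TM", "surface_helix", "loop")))
    stop("kind must be TM, surface_helix or loop")
  if (!all(df$side %in% c("cytoplasmic", "periplasmic", "membrane")))
    stop("side must be cytoplasmic, periplasmic or membrane")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)]))
    stop("segments must be non-overlapping")
  if (anyDuplicated(df$name)) stop("segment names must be unique")
  rownames(df) <- NULL
  class(df) <- c("helix_annotation", "data.frame")
  df
}

#' @export
print.helix_annotation <- function(x, ...) {
  cat("helix_annotation:\n")
  print.data.frame(x)
  invisible(x)
}

#' Segment lookup for a residue
#' @param ha a \code{helix_annotation}
#' @param res reference residue numbers
#' @return character segment name per residue (error if any residue is not
#'   covered by a segment)
#' @export
segment_of <- function(ha, res) {
  out <- vapply(res, function(r) {
    hit <- which(ha$start <= r & ha$end >= r)
    if (length(hit) == 0L)
      stop("residue ", r, " is not covered by the annotation")
    ha$name[hit[1L]]
  }, character(1))
  out
}

#' Helix segments of an annotation
#' @param ha a \code{helix_annotation}
#' @return the helical (TM or surface_helix) rows
#' @export
helices_of <- function(ha) {
  ha[ha$kind %in% c("TM", "surface_helix"), , drop = FALSE]
}

#' Residue numbers of a named segment
#' @param ha a \code{helix_annotation}
#' @param name segment name
#' @return integer residue numbers start..end
#' @export
segment_residues <- function(ha, name) {
  i <- match(name, ha$name)
  if (is.na(i)) stop("unknown segment: ", name)
  seq(ha$start[i], ha$end[i])
}

#' Read / write segment annotations as TSV
#'
#' Columns: name, start, end, kind, side.
#' @param path file path
#' @export
read_segments <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  helix_annotation(tab$name, tab$start, tab$end, tab$kind, tab$side)
}

#' @rdname read_segments
#' @param ha a \code{helix_annotation}
#' @export
write_segments <- function(ha, path) {
  utils::write.table(as.data.frame(unclass(ha)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
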