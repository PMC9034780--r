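# SWC input/output.
#
# Standard whitespace-separated SWC (id type x y z radius parent) with one
# convention: the y column stores depth below the pia in um (positive
# downward), and dendritic compartments are encoded in the type column as
# 1 = soma, 3 = basal, 4 = apical trunk + oblique, 5 = apical tuft (a
# custom extension of the SWC type set, declared in the header comment).

#' Write a morphology to an SWC file
#'
#' @param morph a `scracm_morphology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "scracm_morphology"))
  nd <- morph$nodes
  header <- c(
    "# SWC morphology; y = depth below pia (um)",
    "# type: 1 soma, 3 basal, 4 apical trunk + oblique, 5 apical tuft",
    sprintf("# soma_depth_um %.6f", morph$soma_depth_um),
    sprintf("# bifurcation_depth_um %.6f", morph$bifurcation_depth_um)
  )
  body <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                  nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an SWC morphology
#'
#' Accepts the compartment-typed files written by [write_swc()] as well as
#' plain SWC (types 1/3/4 only); in the latter case the tuft must be
#' recovered with [label_compartments()].
#'
#' @param path SWC file path.
#' @return A `scracm_morphology`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("no SWC records in ", path, call. = FALSE)
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                             as.numeric))
  if (ncol(m) != 7L) stop("malformed SWC: expected 7 columns", call. = FALSE)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  grab <- function(key) {
    ln <- grep(paste0("# ", key), hdr, value = TRUE, fixed = TRUE)
    if (length(ln)) as.numeric(sub(paste0(".*", key, " +"), "", ln[1])) else NA_real_
  }
  soma_depth <- grab("soma_depth_um")
  if (is.na(soma_depth)) soma_depth <- mean(nodes$y[nodes$type == 1L])
  comp <- rep(NA_character_, nrow(nodes))
  for (nm in names(SWC_TYPE)) comp[nodes$type == SWC_TYPE[[nm]]] <- nm
  structure(list(
    nodes = nodes,
    compartment = factor(comp, levels = names(SWC_TYPE)),
    soma_depth_um = soma_depth,
    bifurcation_depth_um = grab("bifurcation_depth_um")
  ), class = "scracm_morphology")
}
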