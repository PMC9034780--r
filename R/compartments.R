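# Compartment labeling from tree topology.

#' Label dendritic compartments of a morphology
#'
#' Re-derives basal / oblique / tuft labels from the tree structure alone:
#' subtrees rooted at the soma other than the apical one are basal; the
#' apical trunk is walked from its root along the heaviest daughter, and
#' the main bifurcation is the first node at which a second daughter
#' subtree holds at least `daughter_frac` of the remaining apical length.
#' The trunk and everything branching from it below the bifurcation are
#' oblique (the trunk itself counts as oblique); everything distal to the
#' bifurcation is tuft. A tree whose apical never bifurcates under the rule
#' is labeled all-oblique with a warning.
#'
#' @param morph a `scracm_morphology` (existing dendrite labels, if any,
#'   are ignored except that SWC types 4/5 mark the apical subtree).
#' @param daughter_frac minimum fraction of the remaining apical length a
#'   second daughter must carry to qualify as the main bifurcation.
#' @return The morphology with `compartment` relabeled and
#'   `bifurcation_depth_um` set from the detected bifurcation node.
#' @export
label_compartments <- function(morph, daughter_frac = 0.25) {
  stopifnot(inherits(morph, "scracm_morphology"))
  if (daughter_frac <= 0 || daughter_frac > 0.5)
    stop("'daughter_frac' must be in (0, 0.5]", call. = FALSE)
  nd <- morph$nodes
  n <- nrow(nd)
  if (!identical(nd$id, seq_len(n))) {
    remap <- match(nd$parent, nd$id)
    nd$parent <- ifelse(is.na(remap), -1L, remap)
    nd$id <- seq_len(n)
    morph$nodes <- nd
  }
  soma_ids <- nd$id[nd$type == 1L]
  if (!length(soma_ids)) stop("morphology has no soma node", call. = FALSE)

  children <- split(nd$id[nd$parent > 0], factor(nd$parent[nd$parent > 0],
                                                 levels = nd$id))
  elen <- numeric(n)  # length of edge into each node
  has_par <- nd$parent > 0
  p <- nd$parent[has_par]
  elen[has_par] <- sqrt((nd$x[has_par] - nd$x[p])^2 +
                          (nd$y[has_par] - nd$y[p])^2 +
                          (nd$z[has_par] - nd$z[p])^2)

  # subtree length below each node (edge into the node included),
  # computed children-first
  sub_len <- elen
  ord <- order(nd$id)  # ids are topologically ordered (parent < child)
  for (i in rev(seq_len(n))) {
    id <- nd$id[ord[i]]
    pid <- nd$parent[ord[i]]
    if (pid > 0) sub_len[pid] <- sub_len[pid] + sub_len[id]
  }

  descend_ids <- function(root) {
    out <- integer(0); stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      out <- c(out, v)
      stack <- c(stack, children[[as.character(v)]])
    }
    out
  }

  soma_children <- unlist(children[as.character(soma_ids)], use.names = FALSE)
  if (!length(soma_children))
    stop("morphology has no dendrites attached to the soma", call. = FALSE)

  # apical root: a type-4/5 child if typed, else the subtree reaching
  # most superficially (smallest depth)
  typed_apical <- soma_children[nd$type[soma_children] %in% c(4L, 5L)]
  if (length(typed_apical)) {
    apical_root <- typed_apical[which.max(sub_len[typed_apical])]
  } else {
    min_depth <- vapply(soma_children,
                        function(v) min(nd$y[descend_ids(v)]), numeric(1))
    apical_root <- soma_children[which.min(min_depth)]
  }
  if (!length(apical_root)) stop("no apical trunk found", call. = FALSE)

  comp <- rep(NA_character_, n)
  comp[nd$type == 1L] <- "soma"
  for (v in setdiff(soma_children, apical_root))
    comp[descend_ids(v)] <- "basal"

  apical_ids <- descend_ids(apical_root)
  comp[apical_ids] <- "oblique"

  # walk the trunk along the heaviest daughter until the first balanced split
  v <- apical_root
  bif <- NA_integer_
  repeat {
    kids <- children[[as.character(v)]]
    if (is.null(kids) || !length(kids)) break
    if (length(kids) >= 2L) {
      S <- sub_len[kids]
      if (sum(S >= daughter_frac * sum(S)) >= 2L) { bif <- v; break }
    }
    v <- kids[which.max(sub_len[kids])]
  }

  if (is.na(bif)) {
    warning("apical tree has no main bifurcation under the ",
            sprintf("%.0f%%", 100 * daughter_frac),
            " daughter rule; whole apical labeled oblique, tuft empty")
    bif_depth <- NA_real_
  } else {
    for (k in children[[as.character(bif)]]) comp[descend_ids(k)] <- "tuft"
    bif_depth <- nd$y[bif]
  }

  morph$compartment <- factor(comp, levels = names(SWC_TYPE))
  morph$nodes$type <- ifelse(comp == "soma", 1L,
                             unname(SWC_TYPE[comp]))
  morph$bifurcation_depth_um <- bif_depth
  morph
}
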