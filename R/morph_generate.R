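# Synthetic thick-tufted L5 pyramidal morphologies.
#
# Trees are generated in the slice plane (x = mediolateral um, y = depth
# below the pia in um, z = 0) as node tables in SWC form. Compartments
# follow the standard ttL5 definitions: basal dendrites originate at the
# soma; the apical trunk ascends to a main bifurcation; oblique dendrites
# branch from the trunk below the bifurcation (the trunk itself counts as
# oblique); the tuft is everything distal to the bifurcation. Depth bands
# are constructed so that compartment centroids order tuft < oblique <
# basal from the pia, as in real ttL5 reconstructions.

SWC_TYPE <- c(soma = 1L, basal = 3L, oblique = 4L, tuft = 5L)

#' Generate a synthetic ttL5 pyramidal morphology
#'
#' Builds a compartment-labeled dendritic tree for a thick-tufted layer 5
#' neuron: radiating basal dendrites around/below the soma, an apical trunk
#' ascending to a main bifurcation at ~45% of the soma depth, oblique
#' branches off the trunk, and a branching apical tuft reaching the pia.
#' Identical `(soma_depth_um, seed)` give byte-identical trees.
#'
#' @param soma_depth_um soma depth below the pia, um; must lie strictly
#'   between 200 and 800.
#' @param seed integer seed.
#' @return An object of class `scracm_morphology`: a list with `nodes`
#'   (SWC node table: id, type, x, y, z, radius, parent, with `y` = depth
#'   below the pia in um), `compartment` (factor per node), `soma_depth_um`
#'   and `bifurcation_depth_um`.
#' @export
generate_morphology <- function(soma_depth_um = 500, seed = 1L) {
  stopifnot_scalar(soma_depth_um, "soma_depth_um")
  if (soma_depth_um <= 200 || soma_depth_um >= 800)
    stop("'soma_depth_um' must lie strictly between 200 and 800 um",
         call. = FALSE)
  D <- soma_depth_um
  with_seed(seed, {
    env <- new.env()
    env$nodes <- list()
    env$n <- 0L
    add_node <- function(type, x, y, z, radius, parent) {
      env$n <- env$n + 1L
      env$nodes[[env$n]] <- c(id = env$n, type = type, x = x, y = y, z = z,
                              radius = radius, parent = parent)
      env$n
    }
    # path of ~step-um segments from the node `from` toward `dir` (unit-ish)
    add_path <- function(from, x0, y0, dir, length_um, type, step = 20,
                         wobble = 2, ymin = 5, ymax = 990, xmax = 240) {
      n_steps <- max(1L, ceiling(length_um / step))
      parent <- from
      x <- x0; y <- y0
      for (i in seq_len(n_steps)) {
        d <- dir + stats::rnorm(2, 0, wobble / 100)
        d <- d / sqrt(sum(d^2))
        x <- min(xmax, max(-xmax, x + d[1] * step))
        y <- min(ymax, max(ymin, y + d[2] * step))
        parent <- add_node(SWC_TYPE[[type]], x, y, 0, 0.6, parent)
      }
      parent
    }

    soma <- add_node(SWC_TYPE[["soma"]], 0, D, 0, 8, -1L)

    # apical trunk: ascend (decreasing depth) to the main bifurcation
    bif_depth <- 0.45 * D * stats::runif(1, 0.95, 1.05)
    trunk_len <- D - bif_depth
    n_tr <- ceiling(trunk_len / 20)
    trunk_ids <- integer(n_tr)
    parent <- soma; x <- 0
    ys <- seq(D, bif_depth, length.out = n_tr + 1L)[-1L]
    for (i in seq_len(n_tr)) {
      x <- x + stats::rnorm(1, 0, 2)
      parent <- add_node(SWC_TYPE[["oblique"]], x, ys[i], 0, 1.5, parent)
      trunk_ids[i] <- parent
    }
    bif_node <- parent
    bif_x <- x

    # obliques: branch off the trunk between bifurcation and soma,
    # slanting upward so their mass sits in the mid band
    elig <- trunk_ids[ys > bif_depth + 60 & ys < D - 50]
    n_obl <- sample(4:6, 1)
    origins <- elig[sample.int(length(elig), min(n_obl, length(elig)))]
    for (o in origins) {
      nd <- env$nodes[[o]]
      side <- sample(c(-1, 1), 1)
      ang <- stats::runif(1, 5, 20) * pi / 180   # mild upward tilt
      dir <- c(side * cos(ang), -sin(ang))
      tip <- add_path(o, nd[["x"]], nd[["y"]], dir, stats::runif(1, 150, 260),
                      "oblique")
      if (stats::runif(1) < 0.7) {
        nd2 <- env$nodes[[tip]]
        ang2 <- stats::runif(1, 5, 25) * pi / 180
        add_path(tip, nd2[["x"]], nd2[["y"]], c(side * cos(ang2), -sin(ang2)),
                 stats::runif(1, 60, 120), "oblique")
      }
    }

    # tuft: balanced binary tree from the bifurcation up to the pia
    grow_tuft <- function(from, x0, y0, depth_level) {
      for (side in c(-1, 1)) {
        ang <- stats::runif(1, 25, 60) * pi / 180
        len <- stats::runif(1, 80, 130)
        tip <- add_path(from, x0, y0, c(side * sin(ang), -cos(ang)), len,
                        "tuft", ymin = 10)
        nd <- env$nodes[[tip]]
        if (depth_level < 3L && nd[["y"]] > 60) {
          grow_tuft(tip, nd[["x"]], nd[["y"]], depth_level + 1L)
        } else if (nd[["y"]] > 40) {
          add_path(tip, nd[["x"]], nd[["y"]],
                   c(stats::rnorm(1, 0, 0.2), -1), nd[["y"]] - 25, "tuft",
                   ymin = 10)
        }
      }
    }
    grow_tuft(bif_node, bif_x, bif_depth, 1L)

    # basal dendrites: radiate into the deep band around/below the soma
    n_bas <- sample(5:7, 1)
    for (i in seq_len(n_bas)) {
      ang <- stats::runif(1, -75, 75) * pi / 180  # from straight down
      dir <- c(sin(ang), cos(ang))
      tip <- add_path(soma, 0, D, dir, stats::runif(1, 130, 220), "basal",
                      ymax = min(990, D + 260))
      if (stats::runif(1) < 0.8) {
        nd <- env$nodes[[tip]]
        ang2 <- ang + sample(c(-1, 1), 1) * stats::runif(1, 15, 50) * pi / 180
        add_path(tip, nd[["x"]], nd[["y"]], c(sin(ang2), cos(ang2)),
                 stats::runif(1, 50, 110), "basal",
                 ymax = min(990, D + 260))
      }
    }

    nodes <- as.data.frame(do.call(rbind, env$nodes))
    nodes$id <- as.integer(nodes$id)
    nodes$type <- as.integer(nodes$type)
    nodes$parent <- as.integer(nodes$parent)
    comp <- names(SWC_TYPE)[match(nodes$type, SWC_TYPE)]
    structure(list(
      nodes = nodes,
      compartment = factor(comp, levels = names(SWC_TYPE)),
      soma_depth_um = D,
      bifurcation_depth_um = bif_depth
    ), class = "scracm_morphology")
  })
}

#' @export
print.scracm_morphology <- function(x, ...) {
  len <- compartment_lengths(x)
  cat(sprintf(
    "ttL5 morphology: %d nodes, soma %.0f um, bifurcation %.0f um below pia\n",
    nrow(x$nodes), x$soma_depth_um, x$bifurcation_depth_um))
  cat(sprintf("  dendritic length (um): basal %.0f, oblique %.0f, tuft %.0f\n",
              len[["basal"]], len[["oblique"]], len[["tuft"]]))
  invisible(x)
}

# total dendritic length per compartment (um)
compartment_lengths <- function(morph) {
  ed <- morph_edges(morph)
  vapply(c("basal", "oblique", "tuft"),
         function(cc) sum(ed$length[ed$compartment == cc]), numeric(1))
}

# edge table: one row per parent->child dendritic segment
morph_edges <- function(morph) {
  nd <- morph$nodes
  child <- which(nd$parent > 0)
  p <- nd$parent[child]
  len <- sqrt((nd$x[child] - nd$x[p])^2 + (nd$y[child] - nd$y[p])^2 +
                (nd$z[child] - nd$z[p])^2)
  data.frame(
    child = nd$id[child], parent = p, length = len,
    d0 = pmin(nd$y[child], nd$y[p]), d1 = pmax(nd$y[child], nd$y[p]),
    x_mid = (nd$x[child] + nd$x[p]) / 2,
    compartment = as.character(morph$compartment[child]),
    stringsAsFactors = FALSE
  )
}
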