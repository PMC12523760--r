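#' Skeletonize a collagen mask into a junction/endpoint/path graph
#'
#' The mask is thinned to a 1-pixel, 8-connected skeleton (topology
#' preserving Guo-Hall thinning iterated to a fixed point). Skeleton
#' pixels are classified by degree: endpoints (degree 1), path pixels
#' (degree 2), and junction pixels (degree >= 3); 8-adjacent junction pixels
#' are merged into a single junction node, and simple pixel paths are traced
#' between nodes. Isolated cycles are represented by one edge anchored at a
#' synthetic node. Spur edges shorter than `prune_px` that end at an
#' endpoint are pruned before node counting (they are thinning artifacts),
#' and chains through junctions demoted by pruning are merged back together.
#'
#' Mask components that thinning erases completely (very small blobs) are
#' re-anchored by a single representative pixel so that every mask component
#' keeps exactly one skeleton component.
#'
#' @param cm a [collagen_mask()] (may be empty: returns an empty graph)
#' @param prune_px prune spur edges with geodesic length below this many
#'   pixels (default 3); set 0 to disable
#' @return an object of class `skeleton_graph` with elements `skeleton`
#'   (logical matrix), `deg` (integer matrix of skeleton degrees), `labels`
#'   (mask component labels), `nodes` (data.frame: id, px, type, comp),
#'   `edges` (data.frame: a, b, length_px, comp, plus a list column `path`
#'   of pixel indices), and `mpp`
#' @export
skeletonize_mask <- function(cm, prune_px = 3) {
  stopifnot(inherits(cm, "collagen_mask"))
  mask <- cm$mask
  h <- nrow(mask); w <- ncol(mask)
  empty <- function() {
    structure(list(skeleton = matrix(FALSE, h, w),
                   deg = matrix(0L, h, w),
                   labels = matrix(0L, h, w),
                   nodes = data.frame(id = integer(), px = integer(),
                                      type = character(), comp = integer(),
                                      npx_cluster = integer()),
                   edges = .empty_edges(),
                   mpp = cm$mpp, prune_px = prune_px),
              class = "skeleton_graph")
  }
  if (!any(mask)) return(empty())

  lab <- as_matrix(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  sk <- thin_mask_c(mask)

  # restore components fully erased by thinning with one anchor pixel each
  comp_ids <- seq_len(max(lab))
  present <- unique(lab[sk])
  lost <- setdiff(comp_ids, present)
  for (ci in lost) {
    px <- which(lab == ci)
    rs <- (px - 1) %% h + 1; cs <- (px - 1) %/% h + 1
    ctr <- c(mean(rs), mean(cs))
    sk[px[which.min((rs - ctr[1])^2 + (cs - ctr[2])^2)]] <- TRUE
  }

  tr <- trace_skeleton_c(sk)
  deg <- tr$deg
  storage.mode(deg) <- "integer"

  skel_px <- which(sk)
  # junction clustering: 8-adjacent junction pixels form one node
  jun <- matrix(FALSE, h, w); jun[skel_px[deg[skel_px] >= 3]] <- TRUE
  jlab <- if (any(jun)) as_matrix(EBImage::bwlabel(jun)) else matrix(0L, h, w)
  storage.mode(jlab) <- "integer"

  # node ids: junction clusters get positive ids (= cluster label);
  # endpoints, anchors and isolated pixels get the negative pixel index
  node_id_of_px <- function(px) {
    d <- deg[px]
    ifelse(d >= 3L, jlab[px], -px)
  }

  paths <- tr$paths
  n_e <- length(paths)
  if (n_e > 0) {
    a <- integer(n_e); b <- integer(n_e); len <- numeric(n_e); comp <- integer(n_e)
    crn <- integer(n_e)
    for (i in seq_len(n_e)) {
      p <- paths[[i]]
      rs <- (p - 1L) %% h + 1L; cs <- (p - 1L) %/% h + 1L
      a[i] <- node_id_of_px(p[1])
      b[i] <- node_id_of_px(p[length(p)])
      len[i] <- path_length_px(rs, cs)
      crn[i] <- path_corners(rs, cs)
      comp[i] <- lab[p[1]]
    }
    edges <- data.frame(a = a, b = b, length_px = len, corners = crn,
                        comp = comp)
    edges$path <- paths
    # collapse edges internal to one junction cluster (adjacent junction px)
    edges <- edges[!(edges$a == edges$b & edges$a > 0 & edges$length_px <= 2), ,
                   drop = FALSE]
  } else {
    edges <- .empty_edges()
  }

  # node table: every referenced node plus isolated pixels
  iso_px <- skel_px[deg[skel_px] == 0]
  ids <- unique(c(edges$a, edges$b, -iso_px))
  px_of_id <- function(id) {
    if (id < 0) return(-id)
    which(jlab == id)[1]  # representative pixel of the cluster
  }
  npx <- vapply(ids, px_of_id, integer(1))
  ntype <- ifelse(ids > 0, "junction",
                  ifelse(deg[npx] == 1L, "endpoint",
                         ifelse(deg[npx] == 0L, "isolated", "anchor")))
  jsizes <- if (any(jun)) tabulate(jlab[jlab > 0]) else integer(0)
  nodes <- data.frame(id = ids, px = npx, type = ntype, comp = lab[npx],
                      npx_cluster = ifelse(ids > 0, jsizes[pmax(ids, 1)], 1L))

  g <- structure(list(skeleton = sk, deg = deg, labels = lab,
                      nodes = nodes, edges = edges,
                      mpp = cm$mpp, prune_px = prune_px),
                 class = "skeleton_graph")
  if (prune_px > 0) g <- .prune_and_simplify(g, prune_px)
  g
}

.empty_edges <- function() {
  e <- data.frame(a = integer(), b = integer(), length_px = numeric(),
                  corners = integer(), comp = integer())
  e$path <- list()
  e
}

# degree of each node id in the edge table (self-loops count twice)
.node_degree <- function(edges, ids) {
  d <- tabulate(match(c(edges$a, edges$b), ids), nbins = length(ids))
  names(d) <- ids
  d
}

# remove short spurs ending at endpoints, then merge edge chains through
# nodes whose degree fell to 2; operates on plain vectors for speed
.prune_and_simplify <- function(g, prune_px) {
  ea <- g$edges$a; eb <- g$edges$b
  elen <- g$edges$length_px; ecomp <- g$edges$comp
  ecrn <- g$edges$corners
  epath <- g$edges$path
  nodes <- g$nodes
  ids <- nodes$id
  is_end <- nodes$type == "endpoint"
  alive <- rep(TRUE, length(ea))
  deg_of <- function() tabulate(match(c(ea[alive], eb[alive]), ids),
                                nbins = length(ids))
  repeat {
    if (!any(alive)) break
    degs <- deg_of()
    da <- degs[match(ea, ids)]; db <- degs[match(eb, ids)]
    enda <- is_end[match(ea, ids)]; endb <- is_end[match(eb, ids)]
    spur <- alive & elen < prune_px &
      ((enda & da == 1L & db >= 2L) | (endb & db == 1L & da >= 2L))
    spur[is.na(spur)] <- FALSE
    if (!any(spur)) break
    alive[spur] <- FALSE
  }
  # merge through junction nodes demoted to degree 2
  is_junction <- nodes$type == "junction"
  repeat {
    if (!any(alive)) break
    degs <- deg_of()
    cand <- which(is_junction & degs == 2L)
    merged_any <- FALSE
    for (ni in cand) {
      id <- ids[ni]
      ei <- which(alive & (ea == id | eb == id))
      if (length(ei) != 2L) next  # one self-loop: leave as a cycle
      i1 <- ei[1]; i2 <- ei[2]
      o1 <- if (ea[i1] == id) eb[i1] else ea[i1]
      o2 <- if (ea[i2] == id) eb[i2] else ea[i2]
      p1 <- epath[[i1]]; if (ea[i1] != id) p1 <- rev(p1)  # starts at id
      p2 <- epath[[i2]]; if (ea[i2] != id) p2 <- rev(p2)  # starts at id
      ea[i1] <- o1; eb[i1] <- o2
      elen[i1] <- elen[i1] + elen[i2]
      ecrn[i1] <- ecrn[i1] + ecrn[i2]
      epath[[i1]] <- c(rev(p1), p2[-1])
      alive[i2] <- FALSE
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  keep_e <- which(alive)
  edges <- data.frame(a = ea[keep_e], b = eb[keep_e],
                      length_px = elen[keep_e], corners = ecrn[keep_e],
                      comp = ecomp[keep_e])
  edges$path <- epath[keep_e]
  # drop nodes no longer referenced, but keep isolated markers
  keep <- nodes$id %in% c(edges$a, edges$b) | nodes$type == "isolated"
  g$nodes <- nodes[keep, , drop = FALSE]
  g$edges <- edges
  g
}

#' Per-component skeleton statistics
#'
#' Summarizes a [skeletonize_mask()] graph per mask component: total
#' geodesic length, junction and endpoint counts, and the longest
#' unbranched (single-edge) path.
#'
#' @param g a `skeleton_graph`
#' @return data.frame with one row per component: `comp`, `length_px`,
#'   `n_junctions`, `n_endpoints`, `longest_path_px`, `longest_chord_px`
#' @export
skeleton_component_stats <- function(g) {
  stopifnot(inherits(g, "skeleton_graph"))
  comps <- sort(unique(c(g$nodes$comp, g$edges$comp)))
  if (length(comps) == 0) {
    return(data.frame(comp = integer(), length_px = numeric(),
                      n_junctions = integer(), n_endpoints = integer(),
                      longest_path_px = numeric(), longest_chord_px = numeric()))
  }
  degs <- .node_degree(g$edges, g$nodes$id)
  h <- nrow(g$skeleton)
  out <- lapply(comps, function(ci) {
    ei <- which(g$edges$comp == ci)
    ni <- which(g$nodes$comp == ci)
    # junction clusters spanning several pixels contribute their internal
    # extent (unit steps between the cluster's pixels)
    intra <- sum(pmax(g$nodes$npx_cluster[ni] - 1L, 0L))
    # corner-count corrected chain length: the (1, sqrt 2) metric
    # overestimates digital lines between the axis and diagonal directions
    len_corr <- g$edges$length_px[ei] - 0.091 * g$edges$corners[ei]
    tot <- sum(len_corr) + intra
    nj <- sum(g$nodes$type[ni] == "junction" & degs[match(g$nodes$id[ni], g$nodes$id)] >= 3L)
    ne <- sum(g$nodes$type[ni] == "endpoint" &
                degs[match(g$nodes$id[ni], g$nodes$id)] >= 1L)
    if (any(g$nodes$type[ni] == "isolated")) ne <- ne + sum(g$nodes$type[ni] == "isolated")
    lp <- 0; lc <- 0
    if (length(ei)) {
      k <- ei[which.max(len_corr)]
      lp <- len_corr[which.max(len_corr)]
      p <- g$edges$path[[k]]
      r1 <- (p[1] - 1L) %% h + 1L; c1 <- (p[1] - 1L) %/% h + 1L
      r2 <- (p[length(p)] - 1L) %% h + 1L; c2 <- (p[length(p)] - 1L) %/% h + 1L
      lc <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
    }
    data.frame(comp = ci, length_px = tot, n_junctions = nj, n_endpoints = ne,
               longest_path_px = lp, longest_chord_px = lc)
  })
  do.call(rbind, out)
}
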