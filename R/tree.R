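#' Construct a dendrite tree from a node table
#'
#' A `dendrite_tree` is a rooted 3D morphology: a node table in SWC order
#' plus derived structure (children lists, branch labels, arc lengths).
#' Node positions are in micrometres; arc length along the tree is the sum
#' of straight parent-child steps.
#'
#' @param nodes data.frame with columns `node_id`, `parent_id` (`-1` for the
#'   root), `x`, `y`, `z` (um), `radius` (um) and optionally `type` (SWC
#'   structure code; defaults to 3 = dendrite, 1 for the root).
#' @return An object of class `dendrite_tree` with elements `nodes` (the
#'   validated table with a `branch_id` column), `root_id`, `edge_length`
#'   (named by child node id) and `branches` (list of node-id vectors, each a
#'   maximal unbranched path ordered root-side to tip, starting at its
#'   parent bifurcation/root node).
#' @export
dendrite_tree <- function(nodes) {
  required <- c("node_id", "parent_id", "x", "y", "z", "radius")
  if (!all(required %in% names(nodes))) {
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids")
  if (any(nodes$radius <= 0)) stop("all radii must be > 0")
  if (!"type" %in% names(nodes)) {
    nodes$type <- ifelse(nodes$parent_id == -1L, 1L, 3L)
  }

  root <- nodes$node_id[nodes$parent_id == -1L]
  if (length(root) != 1L) stop("tree must have exactly one root, found ", length(root))

  idx <- match(nodes$parent_id, nodes$node_id)
  bad <- nodes$parent_id != -1L & is.na(idx)
  if (any(bad)) {
    stop("node(s) reference missing parent: ",
         paste(nodes$node_id[bad], collapse = ", "))
  }

  n <- nrow(nodes)
  # cycle / connectivity check: walk each node to the root
  depth <- rep(NA_integer_, n)
  depth[nodes$parent_id == -1L] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- integer(0)
    j <- i
    while (is.na(depth[j])) {
      if (j %in% chain) stop("cyclic parent references detected")
      chain <- c(chain, j)
      j <- idx[j]
    }
    d <- depth[j]
    for (k in rev(chain)) {
      d <- d + 1L
      depth[k] <- d
    }
  }

  pid <- idx # parent row index (NA for root)
  dx <- nodes$x - nodes$x[pid]
  dy <- nodes$y - nodes$y[pid]
  dz <- nodes$z - nodes$z[pid]
  edge_length <- sqrt(dx^2 + dy^2 + dz^2)
  edge_length[is.na(edge_length)] <- 0
  names(edge_length) <- nodes$node_id

  children <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  n_children <- lengths(children)[as.character(nodes$node_id)]
  n_children[is.na(n_children)] <- 0L
  names(n_children) <- nodes$node_id

  # branch decomposition: the root and every node with >= 2 children start
  # new branches at each of their children
  branch_id <- rep(NA_integer_, n)
  names(branch_id) <- nodes$node_id
  branches <- list()
  bid <- 0L
  is_split <- n_children >= 2L | nodes$node_id == root
  start_children <- unlist(children[as.character(nodes$node_id[is_split])],
                           use.names = FALSE)
  for (st in start_children) {
    bid <- bid + 1L
    path <- st
    cur <- st
    while (n_children[as.character(cur)] == 1L) {
      cur <- children[[as.character(cur)]]
      path <- c(path, cur)
    }
    branch_id[as.character(path)] <- bid
    parent_node <- nodes$parent_id[match(st, nodes$node_id)]
    branches[[bid]] <- c(parent_node, path)
  }
  # root inherits the branch of its first child (pure labelling convention)
  if (is.na(branch_id[as.character(root)])) {
    kids <- children[[as.character(root)]]
    branch_id[as.character(root)] <-
      if (length(kids)) branch_id[as.character(kids[1])] else 1L
  }
  nodes$branch_id <- as.integer(branch_id[as.character(nodes$node_id)])

  structure(list(nodes = nodes, root_id = root, edge_length = edge_length,
                 children = children, n_children = n_children,
                 branches = branches),
            class = "dendrite_tree")
}

#' @export
print.dendrite_tree <- function(x, ...) {
  cat("dendrite_tree:", nrow(x$nodes), "nodes,", length(x$branches),
      "branches, total length", round(sum(x$edge_length), 1), "um\n")
  invisible(x)
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, `#` comments).
#'
#' @param path path to an SWC file.
#' @return a [dendrite_tree()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node_id", "type", "x", "y", "z",
                                         "radius", "parent_id"))
  dendrite_tree(tab[, c("node_id", "parent_id", "x", "y", "z", "radius", "type")])
}

#' Write a morphology to an SWC file
#'
#' @param tree a [dendrite_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  nd <- tree$nodes
  tab <- data.frame(nd$node_id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent_id)
  writeLines(c("# SWC export", "# id type x y z radius parent"), path)
  utils::write.table(tab, path, append = TRUE, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# node-to-node tree distance matrix (um), rows/cols named by node id
node_distances <- function(tree) {
  nd <- tree$nodes
  has_parent <- nd$parent_id != -1L
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(nd$parent_id[has_parent]),
               to = as.character(nd$node_id[has_parent])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$node_id)))
  igraph::distances(g, weights = tree$edge_length[as.character(nd$node_id[has_parent])])
}

# resolve a mask attachment to (edge child node, offset toward parent,
# 3D point). offset 0 means exactly at node_id.
resolve_attachment <- function(tree, node_id, offset = 0) {
  nd <- tree$nodes
  i <- match(node_id, nd$node_id)
  if (is.na(i)) stop("attachment node ", node_id, " not in tree")
  if (offset < 0) stop("attachment offset must be >= 0")
  if (offset == 0) {
    return(list(node = node_id, parent = nd$parent_id[i], offset = 0,
                edge_len = unname(tree$edge_length[as.character(node_id)]),
                pos = c(nd$x[i], nd$y[i], nd$z[i])))
  }
  len <- unname(tree$edge_length[as.character(node_id)])
  if (nd$parent_id[i] == -1L || offset > len + 1e-9) {
    stop("offset ", offset, " exceeds edge above node ", node_id)
  }
  j <- match(nd$parent_id[i], nd$node_id)
  w <- offset / len
  pos <- c(nd$x[i], nd$y[i], nd$z[i]) * (1 - w) +
    c(nd$x[j], nd$y[j], nd$z[j]) * w
  list(node = node_id, parent = nd$parent_id[i], offset = offset,
       edge_len = len, pos = pos)
}

mask_row <- function(masks, mask_id) {
  i <- match(mask_id, masks$mask_id)
  if (is.na(i)) stop("unknown mask: ", mask_id)
  masks[i, ]
}

#' Traversal distance between two masks
#'
#' Length of the shortest path through the dendritic tree between the two
#' mask attachment points, in micrometres.
#'
#' @param tree a [dendrite_tree()].
#' @param masks mask table (see [generate_synthetic_tree()] for the format).
#' @param mask_a,mask_b mask ids.
#' @param D optional precomputed [node_distance_matrix()] output for speed.
#' @return distance in um.
#' @export
traversal_distance <- function(tree, masks, mask_a, mask_b, D = NULL) {
  if (is.null(D)) D <- node_distances(tree)
  a <- mask_row(masks, mask_a)
  b <- mask_row(masks, mask_b)
  point_tree_distance(tree, D,
                      resolve_attachment(tree, a$node_id, a$offset),
                      resolve_attachment(tree, b$node_id, b$offset))$d
}

#' Node distance matrix of a dendrite tree
#'
#' @param tree a [dendrite_tree()].
#' @return symmetric matrix of tree distances (um) named by node id.
#' @export
node_distance_matrix <- function(tree) node_distances(tree)

# tree-metric distance between two resolved attachment points; also reports
# the edge endpoints through which the shortest path exits each mask point.
point_tree_distance <- function(tree, D, pa, pb) {
  na_ <- as.character(pa$node); nb_ <- as.character(pb$node)
  if (pa$node == pb$node && pa$offset > 0 && pb$offset > 0) {
    return(list(d = abs(pa$offset - pb$offset), exit_a = NA, exit_b = NA))
  }
  cand_a <- list(list(node = na_, add = pa$offset))
  if (pa$offset > 0) {
    cand_a <- c(cand_a, list(list(node = as.character(pa$parent),
                                  add = pa$edge_len - pa$offset)))
  }
  cand_b <- list(list(node = nb_, add = pb$offset))
  if (pb$offset > 0) {
    cand_b <- c(cand_b, list(list(node = as.character(pb$parent),
                                  add = pb$edge_len - pb$offset)))
  }
  best <- Inf; ea <- NA; eb <- NA
  for (ca in cand_a) for (cb in cand_b) {
    d <- ca$add + D[ca$node, cb$node] + cb$add
    if (d < best) { best <- d; ea <- ca$node; eb <- cb$node }
  }
  list(d = best, exit_a = ea, exit_b = eb)
}

#' Euclidean distance between two masks
#'
#' Straight-line 3D distance between the mask attachment points; always
#' less than or equal to the traversal distance.
#'
#' @inheritParams traversal_distance
#' @return distance in um.
#' @export
euclidean_distance <- function(tree, masks, mask_a, mask_b) {
  a <- mask_row(masks, mask_a)
  b <- mask_row(masks, mask_b)
  pa <- resolve_attachment(tree, a$node_id, a$offset)
  pb <- resolve_attachment(tree, b$node_id, b$offset)
  sqrt(sum((pa$pos - pb$pos)^2))
}

#' Branch relation of a mask pair
#'
#' Classifies a pair by the number of bifurcation nodes (nodes with two or
#' more children) strictly interior to the tree path connecting the two
#' attachment points: `"within"` (0), `"across_one"` (1), or
#' `"across_multiple"` (2+).
#'
#' @inheritParams traversal_distance
#' @return character scalar.
#' @export
branch_relation <- function(tree, masks, mask_a, mask_b, D = NULL) {
  if (is.null(D)) D <- node_distances(tree)
  a <- mask_row(masks, mask_a)
  b <- mask_row(masks, mask_b)
  pa <- resolve_attachment(tree, a$node_id, a$offset)
  pb <- resolve_attachment(tree, b$node_id, b$offset)
  pt <- point_tree_distance(tree, D, pa, pb)
  if (is.na(pt$exit_a)) return("within") # same edge
  path <- node_path(tree, as.integer(pt$exit_a), as.integer(pt$exit_b))
  # the exit node itself lies strictly between the points only when the mask
  # sits off-node (offset > 0); an offset-0 mask point IS its node
  interior <- path
  if (pa$offset == 0) interior <- setdiff(interior, pa$node)
  if (pb$offset == 0) interior <- setdiff(interior, pb$node)
  nbif <- sum(tree$n_children[as.character(interior)] >= 2L)
  if (nbif == 0) "within" else if (nbif == 1) "across_one" else "across_multiple"
}

# unique path between two nodes via walking to the root (LCA)
node_path <- function(tree, a, b) {
  nd <- tree$nodes
  up <- function(v) {
    out <- v
    while (TRUE) {
      p <- nd$parent_id[match(v, nd$node_id)]
      if (p == -1L) break
      out <- c(out, p)
      v <- p
    }
    out
  }
  pa <- up(a); pb <- up(b)
  common <- intersect(pa, pb)
  lca <- common[1]
  c(pa[seq_len(match(lca, pa))], rev(pb[seq_len(match(lca, pb) - 1L)]))
}

# arc length from the branch start node to each node of a branch
branch_arc <- function(tree, branch_nodes) {
  el <- tree$edge_length[as.character(branch_nodes[-1])]
  c(0, cumsum(el))
}

# place a point at arc position s (from branch start) on a branch:
# returns (node_id, offset toward parent)
branch_point_at <- function(tree, branch_nodes, s) {
  arc <- branch_arc(tree, branch_nodes)
  k <- which(arc >= s - 1e-9)[1]
  if (is.na(k)) k <- length(arc)
  if (k == 1) {
    return(list(node_id = branch_nodes[2], offset = tree$edge_length[as.character(branch_nodes[2])]))
  }
  list(node_id = branch_nodes[k], offset = max(0, arc[k] - s))
}

#' Divide the dendrite into equal-length shaft segments
#'
#' Each branch (maximal unbranched path) is tiled with
#' `max(1, round(length / target_length))` segments of equal length, so the
#' realized segment length approximates the target (e.g. 30 um or ~3 um).
#'
#' @param tree a [dendrite_tree()].
#' @param target_length_um target segment length in um.
#' @return mask table (data.frame) with columns `mask_id`, `kind`
#'   (`"dendrite_segment"`), `node_id`, `offset`, `segment_length`,
#'   `branch_id`.
#' @export
segment_dendrite <- function(tree, target_length_um) {
  if (target_length_um <= 0) stop("target_length_um must be > 0")
  if (length(tree$branches) == 0) stop("tree has no branches to segment")
  out <- list()
  k <- 0L
  for (bi in seq_along(tree$branches)) {
    bn <- tree$branches[[bi]]
    len <- sum(tree$edge_length[as.character(bn[-1])])
    if (len <= 0) next
    nseg <- max(1L, round(len / target_length_um))
    seg_len <- len / nseg
    for (s in seq_len(nseg)) {
      k <- k + 1L
      pt <- branch_point_at(tree, bn, (s - 0.5) * seg_len)
      out[[k]] <- data.frame(
        mask_id = sprintf("dend_%03d", k), kind = "dendrite_segment",
        node_id = pt$node_id, offset = pt$offset,
        segment_length = seg_len, branch_id = bi)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic dendritic tree with spine masks
#'
#' Builds a random rooted morphology: a soma at the origin, a first branch
#' growing away from it, and subsequent branches sprouting from uniformly
#' chosen points of the existing tree (each sprout creates a bifurcation, so
#' the number of maximal unbranched paths can exceed `n_branches`). Spines
#' are placed uniformly along the dendrite at the requested density with
#' zero arc extent.
#'
#' @param n_branches number of grown paths (>= 1).
#' @param branch_length_range length range (um) each grown path is drawn from.
#' @param spine_density_per_um expected spines per um of dendrite.
#' @param seed integer RNG seed.
#' @param step node spacing along branches (um).
#' @return list with `tree` (a [dendrite_tree()]) and `masks` (mask table
#'   with one `soma` mask at the root plus `spine` masks).
#' @export
generate_synthetic_tree <- function(n_branches = 6,
                                    branch_length_range = c(40, 70),
                                    spine_density_per_um = 0.22,
                                    seed = 1L, step = 2) {
  if (n_branches < 1) stop("n_branches must be >= 1")
  if (any(branch_length_range <= 0) || spine_density_per_um < 0) {
    stop("branch lengths and spine density must be positive")
  }
  rng <- local_rng(seed)
  nodes <- data.frame(node_id = 1L, parent_id = -1L, x = 0, y = 0, z = 0,
                      radius = 5, type = 1L)
  nid <- 1L
  rand_dir <- function() {
    v <- rng$norm(3)
    v / sqrt(sum(v^2))
  }
  for (b in seq_len(n_branches)) {
    len <- rng$unif(1, branch_length_range[1], branch_length_range[2])
    nsteps <- max(2L, ceiling(len / step))
    anchor <- if (b == 1) 1L else nodes$node_id[1L + rng$int(nrow(nodes) - 1L)]
    dir <- rand_dir()
    pos <- as.numeric(nodes[match(anchor, nodes$node_id), c("x", "y", "z")])
    parent <- anchor
    for (s in seq_len(nsteps)) {
      dir <- dir + 0.15 * rng$norm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir * (len / nsteps)
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(node_id = nid, parent_id = parent,
                                       x = pos[1], y = pos[2], z = pos[3],
                                       radius = 0.5, type = 3L))
      parent <- nid
    }
  }
  tree <- dendrite_tree(nodes)

  masks <- data.frame(mask_id = "soma", kind = "soma",
                      node_id = tree$root_id, offset = 0,
                      segment_length = 0,
                      branch_id = tree$nodes$branch_id[match(tree$root_id, tree$nodes$node_id)])
  k <- 0L
  for (bi in seq_along(tree$branches)) {
    bn <- tree$branches[[bi]]
    len <- sum(tree$edge_length[as.character(bn[-1])])
    nsp <- rng$pois(len * spine_density_per_um)
    if (nsp == 0) next
    for (s in sort(rng$unif(nsp, 0, len))) {
      k <- k + 1L
      pt <- branch_point_at(tree, bn, s)
      masks <- rbind(masks, data.frame(
        mask_id = sprintf("spine_%03d", k), kind = "spine",
        node_id = pt$node_id, offset = pt$offset,
        segment_length = 0, branch_id = bi))
    }
  }
  rownames(masks) <- NULL
  list(tree = tree, masks = masks)
}

#' Pairwise mask distance table
#'
#' Traversal and Euclidean distances plus branch relation for every
#' unordered pair of the given masks (bouton masks are dropped).
#'
#' @param tree a [dendrite_tree()].
#' @param masks mask table.
#' @return data.frame with `mask_a`, `mask_b`, `traversal`, `euclidean`,
#'   `branch_relation`, `kind_a`, `kind_b`.
#' @export
mask_pair_distances <- function(tree, masks) {
  masks <- masks[masks$kind != "bouton", , drop = FALSE]
  D <- node_distances(tree)
  ids <- masks$mask_id
  n <- length(ids)
  if (n < 2) stop("need at least two masks")
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- data.frame(mask_a = ids[pairs[1, ]], mask_b = ids[pairs[2, ]],
                    traversal = numeric(m), euclidean = numeric(m),
                    branch_relation = character(m),
                    kind_a = masks$kind[pairs[1, ]],
                    kind_b = masks$kind[pairs[2, ]])
  pts <- lapply(seq_len(n), function(i)
    resolve_attachment(tree, masks$node_id[i], masks$offset[i]))
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    out$traversal[j] <- point_tree_distance(tree, D, pts[[i1]], pts[[i2]])$d
    out$euclidean[j] <- sqrt(sum((pts[[i1]]$pos - pts[[i2]]$pos)^2))
    out$branch_relation[j] <- branch_relation(tree, masks, ids[i1], ids[i2], D)
  }
  out
}
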