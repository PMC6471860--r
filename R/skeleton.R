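#' Skeletonize a binary airway mask
#'
#' Topology-preserving sequential 3-D thinning (simple-point deletion with
#' endpoint preservation over six directional sub-iterations) reduces the
#' mask to a one-voxel-wide centerline with the same connectivity.
#'
#' @param mask a [binary_mask()], non-empty and connected.
#' @return A [binary_mask()] holding the centerline voxels.
#' @export
skeletonize_mask <- function(mask) {
  if (!any(mask$values)) stop("empty-input error: empty mask", call. = FALSE)
  sk <- cpp_thin3d(as.logical(mask$values), dim(mask$values))
  binary_mask(array(sk, dim(mask$values)), mask$spacing, mask$origin)
}

# 26-neighbour offsets as an integer matrix
offsets26_r <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Build a labelled branch graph from a centerline voxel set
#'
#' Skeleton voxels with 26-neighbourhood degree other than 2 become nodes
#' (endpoints and bifurcations); mutually adjacent junction voxels are merged
#' into a single node.  Each maximal degree-2 chain becomes one branch whose
#' length is the polyline length in mm.
#'
#' @param centerline a [binary_mask()] of skeleton voxels (or a logical
#'   array).
#' @param spacing voxel spacing in mm (taken from the mask if omitted).
#' @param largest_only if the centerline has several connected components,
#'   keep the largest instead of erroring.
#' @return An `airway_graph`: list with `nodes` and `branches` data frames,
#'   `centerlines` (list of voxel-index matrices, one per branch) and
#'   `spacing`.
#' @export
build_branch_graph <- function(centerline, spacing = NULL,
                               largest_only = FALSE) {
  if (inherits(centerline, "binary_mask")) {
    arr <- centerline$values
    if (is.null(spacing)) spacing <- centerline$spacing
  } else arr <- centerline
  dm <- dim(arr)
  idx <- which(arr)
  if (length(idx) == 0) stop("empty-input error", call. = FALSE)
  lab <- cpp_label_components(as.logical(arr), dm, 26L)
  ncomp <- max(lab)
  if (ncomp > 1) {
    if (!largest_only)
      stop("multiple-components error: centerline has ", ncomp,
           " components (set largest_only = TRUE to keep the largest)",
           call. = FALSE)
    keep <- which.max(tabulate(lab[idx]))
    arr <- lab == keep
    idx <- which(arr)
  }
  co <- arrayInd(idx, dm)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  kset <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(idx)) assign(key(co[i, , drop = FALSE]), i, kset)
  off <- offsets26_r()
  nb_of <- function(i) {
    p <- co[i, ]
    nb <- integer(0)
    for (k in seq_len(nrow(off))) {
      q <- p + off[k, ]
      j <- mget(paste(q[1], q[2], q[3]), kset, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) nb <- c(nb, j)
    }
    nb
  }
  nbs <- lapply(seq_along(idx), nb_of)
  deg <- lengths(nbs)

  is_node_vox <- deg != 2L
  if (!any(is_node_vox)) {
    # a pure cycle cannot occur in a tree-shaped mask; treat as error
    stop("centerline is a closed loop; not a tree", call. = FALSE)
  }
  # merge 26-adjacent junction voxels (degree >= 3) into one node each;
  # endpoints stay individual nodes so one-voxel spurs remain visible
  node_vox <- which(is_node_vox)
  junction_vox <- which(deg >= 3L)
  vox2node <- integer(length(idx))
  node_id <- 0L
  for (v in junction_vox) {
    if (vox2node[v] != 0L) next
    node_id <- node_id + 1L
    stack <- v
    while (length(stack)) {
      c0 <- stack[[1]]; stack <- stack[-1]
      if (vox2node[c0] != 0L) next
      vox2node[c0] <- node_id
      adjn <- intersect(nbs[[c0]], junction_vox)
      stack <- c(stack, adjn[vox2node[adjn] == 0L])
    }
  }
  for (v in setdiff(node_vox, junction_vox)) {
    node_id <- node_id + 1L
    vox2node[v] <- node_id
  }
  n_nodes <- node_id

  # trace branches: from each node voxel, follow each non-node neighbour
  # through degree-2 voxels until another node voxel
  visited_edge <- new.env(hash = TRUE, parent = emptyenv())
  branches <- list(); centerlines <- list(); bid <- 0L
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  for (v in node_vox) {
    for (s in nbs[[v]]) {
      if (is_node_vox[s]) {
        # node-to-node adjacency: a zero-interior branch between clusters
        if (vox2node[s] == vox2node[v]) next
        ek <- edge_key(v, s)
        if (!is.null(mget(ek, visited_edge, ifnotfound = list(NULL))[[1]]))
          next
        assign(ek, TRUE, visited_edge)
        chain <- c(v, s)
      } else {
        ek <- edge_key(v, s)
        if (!is.null(mget(ek, visited_edge, ifnotfound = list(NULL))[[1]]))
          next
        chain <- c(v, s)
        prev <- v; cur <- s
        while (!is_node_vox[cur]) {
          nxt <- setdiff(nbs[[cur]], prev)
          if (length(nxt) == 0) break            # dangling (shouldn't happen)
          # prefer continuing to an unvisited voxel
          prev <- cur; cur <- nxt[1]
          chain <- c(chain, cur)
        }
        assign(ek, TRUE, visited_edge)
        assign(edge_key(chain[length(chain) - 1L], chain[length(chain)]),
               TRUE, visited_edge)
        if (vox2node[chain[1]] != 0L && vox2node[cur] != 0L &&
            vox2node[chain[1]] == vox2node[cur] && length(chain) <= 3)
          next   # tiny loop within one junction cluster
      }
      bid <- bid + 1L
      pts <- co[chain, , drop = FALSE]
      seglen <- sqrt(rowSums((sweep(diff(pts), 2, spacing, "*"))^2))
      branches[[bid]] <- data.frame(
        id = bid, node_from = vox2node[chain[1]],
        node_to = vox2node[chain[length(chain)]],
        length_mm = sum(seglen), generation = NA_integer_,
        parent = NA_integer_, label = "unassigned",
        stringsAsFactors = FALSE)
      centerlines[[bid]] <- pts
    }
  }
  br <- if (bid == 0L) {
    data.frame(id = integer(0), node_from = integer(0), node_to = integer(0),
               length_mm = numeric(0), generation = integer(0),
               parent = integer(0), label = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, branches)
  node_rows <- lapply(seq_len(n_nodes), function(nid) {
    vs <- which(vox2node == nid)
    cen <- round(colMeans(co[vs, , drop = FALSE]))
    data.frame(id = nid, x = cen[1], y = cen[2], z = cen[3],
               degree = sum(br$node_from == nid) + sum(br$node_to == nid),
               kind = NA_character_, stringsAsFactors = FALSE)
  })
  nodes <- do.call(rbind, node_rows)
  nodes$kind <- ifelse(nodes$degree <= 1, "endpoint", "bifurcation")
  g <- structure(list(nodes = nodes, branches = br,
                      centerlines = centerlines, spacing = spacing),
                 class = "airway_graph")
  assign_generations(g)
}

#' @export
print.airway_graph <- function(x, ...) {
  cat(sprintf("<airway_graph> %d branches, %d nodes, total length %.1f mm\n",
              nrow(x$branches), nrow(x$nodes), sum(x$branches$length_mm)))
  if (any(x$branches$label != "unassigned"))
    print(table(x$branches$label))
  invisible(x)
}

# orient the graph from the most cranial endpoint (root), set generations
# and parent branch ids, and flip centerlines proximal -> distal
assign_generations <- function(graph, root_node = NULL) {
  nodes <- graph$nodes; br <- graph$branches
  if (nrow(br) == 0) return(graph)
  if (is.null(root_node)) {
    ep <- nodes[nodes$degree <= 1, ]
    if (nrow(ep) == 0) ep <- nodes
    root_node <- ep$id[which.max(ep$z)]
  }
  nodes$kind[nodes$id == root_node] <- "root"
  br$generation <- NA_integer_; br$parent <- NA_integer_
  # BFS over branches
  queue <- list()
  for (i in which(br$node_from == root_node | br$node_to == root_node))
    queue[[length(queue) + 1L]] <- list(b = i, from = root_node, gen = 0L,
                                        parent = NA_integer_)
  seen <- rep(FALSE, nrow(br))
  while (length(queue)) {
    q <- queue[[1]]; queue <- queue[-1]
    i <- q$b
    if (seen[i]) next
    seen[i] <- TRUE
    br$generation[i] <- q$gen
    br$parent[i] <- q$parent
    if (br$node_from[i] != q$from) {
      # flip orientation so node_from is proximal
      tmp <- br$node_from[i]; br$node_from[i] <- br$node_to[i]
      br$node_to[i] <- tmp
      graph$centerlines[[br$id[i]]] <-
        graph$centerlines[[br$id[i]]][rev(seq_len(nrow(graph$centerlines[[br$id[i]]]))), , drop = FALSE]
    }
    distal <- br$node_to[i]
    nxt <- which(!seen & (br$node_from == distal | br$node_to == distal))
    for (j in nxt)
      queue[[length(queue) + 1L]] <- list(b = j, from = distal,
                                          gen = q$gen + 1L,
                                          parent = br$id[i])
  }
  graph$nodes <- nodes; graph$branches <- br
  graph
}

#' Remove terminal spur branches shorter than a minimum length
#'
#' Terminal branches (one endpoint node) shorter than `min_length_mm` are
#' removed and any node left with exactly two incident branches is merged so
#' adjacent chains re-join.  The operation is iterated to a fixed point and
#' is therefore idempotent.
#'
#' @param graph an `airway_graph`.
#' @param min_length_mm spur threshold in mm (default 2, removing
#'   voxelization artifacts smaller than any genuine branch).
#' @return The pruned `airway_graph`.
#' @export
prune_spurs <- function(graph, min_length_mm = 2) {
  if (min_length_mm < 0) stop("min_length must be >= 0", call. = FALSE)
  repeat {
    br <- graph$branches
    if (nrow(br) <= 1) break
    ndeg <- table(factor(c(br$node_from, br$node_to),
                         levels = graph$nodes$id))
    terminal <- vapply(seq_len(nrow(br)), function(i)
      ndeg[as.character(br$node_to[i])] == 1 ||
        ndeg[as.character(br$node_from[i])] == 1, TRUE)
    drop <- which(terminal & br$length_mm < min_length_mm)
    # never drop the root-containing branch
    rootn <- graph$nodes$id[graph$nodes$kind == "root"]
    if (length(rootn))
      drop <- drop[!(br$node_from[drop] %in% rootn |
                       br$node_to[drop] %in% rootn)]
    if (length(drop) == 0) break
    drop <- drop[1]
    keep <- setdiff(seq_len(nrow(br)), drop)
    graph$branches <- br[keep, , drop = FALSE]
    graph <- merge_degree2(graph)
  }
  rootn <- graph$nodes$id[graph$nodes$kind == "root"]
  graph <- assign_generations(graph, if (length(rootn)) rootn[1] else NULL)
  graph
}

# merge nodes with exactly two incident branches into a single branch
merge_degree2 <- function(graph) {
  repeat {
    br <- graph$branches
    cnt <- table(factor(c(br$node_from, br$node_to), levels = graph$nodes$id))
    rootn <- graph$nodes$id[graph$nodes$kind == "root"]
    mid <- as.integer(names(cnt)[cnt == 2])
    mid <- setdiff(mid, rootn)
    if (length(mid) == 0) break
    n <- mid[1]
    inc <- which(br$node_from == n | br$node_to == n)
    if (length(inc) != 2) break
    a <- inc[1]; b <- inc[2]
    # orient a: ... -> n ; b: n -> ...
    ca <- graph$centerlines[[br$id[a]]]
    cb <- graph$centerlines[[br$id[b]]]
    if (br$node_from[a] == n) { br[a, c("node_from", "node_to")] <-
      br[a, c("node_to", "node_from")]; ca <- ca[rev(seq_len(nrow(ca))), , drop = FALSE] }
    if (br$node_to[b] == n) { br[b, c("node_from", "node_to")] <-
      br[b, c("node_to", "node_from")]; cb <- cb[rev(seq_len(nrow(cb))), , drop = FALSE] }
    newc <- rbind(ca, cb[-1, , drop = FALSE])
    br$node_to[a] <- br$node_to[b]
    br$length_mm[a] <- br$length_mm[a] + br$length_mm[b]
    graph$centerlines[[br$id[a]]] <- newc
    graph$branches <- br[-b, , drop = FALSE]
    graph$nodes <- graph$nodes[graph$nodes$id != n, , drop = FALSE]
  }
  # refresh node degrees, drop orphaned nodes
  br <- graph$branches
  cnt <- table(factor(c(br$node_from, br$node_to), levels = graph$nodes$id))
  graph$nodes$degree <- as.integer(cnt[as.character(graph$nodes$id)])
  if (nrow(br) > 0)
    graph$nodes <- graph$nodes[graph$nodes$degree > 0, , drop = FALSE]
  graph
}

#' Partition the airway graph into RUL and RMLL subtrees
#'
#' Labels every branch in the subtree rooted at `rul_root` (inclusive) as
#' `"RUL"` and at `rmll_root` as `"RMLL"`; the remaining branches keep the
#' label `"trachea"` (generation 0) or `"other"`.
#'
#' @param graph an `airway_graph` with generations assigned.
#' @param rul_root,rmll_root branch ids of the two lobe roots; must be
#'   distinct and neither an ancestor of the other.
#' @return The labelled `airway_graph`.
#' @export
partition_subtrees <- function(graph, rul_root, rmll_root) {
  br <- graph$branches
  if (!(rul_root %in% br$id) || !(rmll_root %in% br$id))
    stop("unknown branch id", call. = FALSE)
  anc <- function(id) {
    out <- integer(0)
    cur <- br$parent[br$id == id]
    while (!is.na(cur)) { out <- c(out, cur); cur <- br$parent[br$id == cur] }
    out
  }
  if (rul_root == rmll_root || rul_root %in% anc(rmll_root) ||
      rmll_root %in% anc(rul_root))
    stop("invalid-partition error: lobe roots overlap (ancestor/descendant)",
         call. = FALSE)
  desc <- function(id) {
    out <- id
    repeat {
      more <- br$id[!is.na(br$parent) & br$parent %in% out & !(br$id %in% out)]
      if (length(more) == 0) break
      out <- c(out, more)
    }
    out
  }
  br$label <- ifelse(br$generation == 0, "trachea", "other")
  br$label[br$id %in% desc(rul_root)] <- "RUL"
  br$label[br$id %in% desc(rmll_root)] <- "RMLL"
  graph$branches <- br
  graph
}

#' Total airway count (TAC)
#'
#' Number of branches labelled RUL plus those labelled RMLL.  The trachea /
#' unlabelled branches are not counted.
#'
#' @param graph a partitioned `airway_graph`.
#' @return Integer TAC.
#' @export
total_airway_count <- function(graph) {
  lab <- graph$branches$label
  if (!any(lab %in% c("RUL", "RMLL")))
    stop("missing-labels error: run partition_subtrees() first",
         call. = FALSE)
  sum(lab == "RUL") + sum(lab == "RMLL")
}

#' Pick the two lobe-root branches automatically
#'
#' Returns the ids of the children of the root (generation-1) branches,
#' ordered by subtree size; suitable for phantoms whose main bifurcation
#' splits the tree into the two lobe surrogates.
#'
#' @param graph an `airway_graph` with generations.
#' @return Integer vector of two branch ids.
#' @export
auto_lobe_roots <- function(graph) {
  g1 <- graph$branches$id[graph$branches$generation == 1]
  if (length(g1) < 2)
    stop("graph has fewer than two generation-1 branches", call. = FALSE)
  g1[1:2]
}
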