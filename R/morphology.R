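#' Neuron trees
#'
#' A `neuron_tree` is a tibble in standard SWC column order — `id`, `type`,
#' `x`, `y`, `z`, `radius`, `parent` — holding a rooted tree or forest of
#' traced nodes. Roots have `parent = -1`; every other node's parent
#' appears earlier in the table (topological order). Type codes follow the
#' SWC convention (1 = soma, 3 = dendrite/neurite).
#'
#' @param nodes data frame with the seven SWC columns.
#' @return A validated `neuron_tree` tibble.
#' @export
neuron_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("`nodes` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  nodes <- nodes[, need]
  validate_tree(nodes)
  class(nodes) <- c("neuron_tree", class(tibble::tibble()))
  nodes
}

validate_tree <- function(nodes) {
  if (nrow(nodes) == 0L) return(invisible(nodes))
  if (anyDuplicated(nodes$id))
    stop("node ids must be unique", call. = FALSE)
  if (any(nodes$id <= 0))
    stop("node ids must be positive", call. = FALSE)
  if (any(nodes$radius <= 0))
    stop("node radii must be positive", call. = FALSE)
  nonroot <- nodes$parent != -1
  if (any(nodes$parent[nonroot] == nodes$id[nonroot]))
    stop("a node cannot be its own parent", call. = FALSE)
  pos <- match(nodes$parent[nonroot], nodes$id)
  if (anyNA(pos))
    stop("dangling parent reference: parent id ",
         nodes$parent[nonroot][which(is.na(pos))[1]], " not found",
         call. = FALSE)
  if (any(pos >= which(nonroot)))
    stop("parent must precede child in node order", call. = FALSE)
  invisible(nodes)
}

#' @export
print.neuron_tree <- function(x, ...) {
  g <- glance(x)
  cat("<neuron_tree> ", g$n_nodes, " nodes, ", g$n_roots, " root(s), ",
      g$n_bifurcations, " bifurcation(s), total path length ",
      format(g$total_length, digits = 6), " voxels\n", sep = "")
  NextMethod()
}

#' @rdname neuron_tree
#' @param x a `neuron_tree`.
#' @param ... unused.
#' @method glance neuron_tree
#' @export
glance.neuron_tree <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x),
    n_roots = sum(x$parent == -1),
    n_bifurcations = n_bifurcations(x),
    n_tips = if (nrow(x)) sum(!(x$id %in% x$parent)) else 0L,
    total_length = total_path_length(x),
    mean_radius = if (nrow(x)) mean(x$radius) else NA_real_)
}

#' @rdname neuron_tree
#' @method tidy neuron_tree
#' @export
tidy.neuron_tree <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_children <- child_counts(x)
  out$degree <- out$n_children + as.integer(out$parent != -1)
  out$depth <- node_depths(x)
  out
}

# children per node, aligned with row order
child_counts <- function(tree) {
  cc <- integer(nrow(tree))
  pos <- match(tree$parent, tree$id)
  pos <- pos[!is.na(pos)]
  if (length(pos)) {
    t <- tabulate(pos, nbins = nrow(tree))
    cc <- t
  }
  cc
}

node_depths <- function(tree) {
  depth <- integer(nrow(tree))
  pos <- match(tree$parent, tree$id)
  for (i in seq_len(nrow(tree)))
    depth[i] <- if (is.na(pos[i])) 0L else depth[pos[i]] + 1L
  depth
}

#' Total path length of a tree
#'
#' Polyline length through node centers: the sum of parent-to-child
#' segment lengths, in voxels.
#'
#' @param tree a [neuron_tree()].
#' @return numeric scalar.
#' @export
total_path_length <- function(tree) {
  if (nrow(tree) == 0L) return(0)
  pos <- match(tree$parent, tree$id)
  ok <- !is.na(pos)
  if (!any(ok)) return(0)
  sum(sqrt((tree$x[ok] - tree$x[pos[ok]])^2 +
           (tree$y[ok] - tree$y[pos[ok]])^2 +
           (tree$z[ok] - tree$z[pos[ok]])^2))
}

#' Number of bifurcation nodes (two or more children)
#' @param tree a [neuron_tree()].
#' @return integer count of nodes with out-degree >= 2.
#' @export
n_bifurcations <- function(tree) sum(child_counts(tree) >= 2L)

#' Read and write SWC morphology files
#'
#' Standard 7-column SWC text format (`id type x y z radius parent`, `#`
#' comments). Writing uses 4 decimal places, so a write/read round trip
#' preserves coordinates and radii to 1e-4. Reading validates structure:
#' parents must exist and precede their children.
#'
#' @param tree a [neuron_tree()].
#' @param path file path.
#' @return `read_swc` returns a [neuron_tree()]; `write_swc` returns the
#'   path invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  lines <- c("# SWC reconstruction (rayburst)",
             "# id type x y z radius parent",
             sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                     tree$id, tree$type, tree$x, tree$y, tree$z,
                     tree$radius, tree$parent))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  if (!file.exists(path))
    stop("no such SWC file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", rows[bad[1]], " in ", path, call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    stop("non-numeric SWC field at line ",
         rows[which(rowSums(is.na(m)) > 0)[1]], " in ", path, call. = FALSE)
  neuron_tree(tibble::tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])))
}

# Reindex a node table (possibly unordered, arbitrary ids) into a valid
# neuron_tree: topological order, contiguous ids from 1.
compact_tree <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(neuron_tree(df))
  pos_parent <- match(df$parent, df$id)
  children <- split(seq_len(n), factor(pos_parent, levels = seq_len(n)))
  order_out <- integer(n)
  k <- 0L
  queue <- which(is.na(pos_parent) | df$parent == -1)
  visited <- logical(n)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (visited[cur]) next
    visited[cur] <- TRUE
    k <- k + 1L
    order_out[k] <- cur
    queue <- c(queue, children[[cur]])
  }
  if (k < n)
    stop("tree contains a cycle or unreachable nodes", call. = FALSE)
  df <- df[order_out, , drop = FALSE]
  new_id <- seq_len(n)
  old_id <- df$id
  df$id <- new_id
  pp <- match(df$parent, old_id)
  df$parent <- ifelse(is.na(pp), -1L, new_id[pp])
  neuron_tree(df)
}

#' Merge redundant paths
#'
#' Traces run from multiple seeds (or through crossings) can cover the
#' same neurite twice. Working from the roots toward the endpoints, any
#' pair of nodes that are not directly connected, have similar direction
#' (angle below `max_angle`) and lie within each other's radius (Cartesian
#' distance below the larger of the two radii) is merged: the merged node
#' sits at the pair midpoint with the mean radius, and both nodes'
#' children are re-parented to it. Passes repeat until no pair qualifies,
#' so the operation is idempotent.
#'
#' @param tree a [neuron_tree()].
#' @param max_angle direction-similarity gate in radians (default `pi/4`).
#' @param max_passes safety cap on merge passes.
#' @return A merged, re-compacted [neuron_tree()].
#' @export
merge_redundant_paths <- function(tree, max_angle = pi / 4,
                                  max_passes = 50L) {
  stopifnot(inherits(tree, "neuron_tree"))
  df <- tibble::as_tibble(tree)
  for (pass in seq_len(max_passes)) {
    n <- nrow(df)
    if (n < 2L) break
    pos_parent <- match(df$parent, df$id)
    depth <- integer(n)
    ord <- order(ifelse(is.na(pos_parent), 0L, 1L))  # roots first
    # depths via repeated propagation (rows may be unordered mid-pass)
    for (rep_i in seq_len(n)) {
      new_depth <- ifelse(is.na(pos_parent), 0L, depth[pos_parent] + 1L)
      if (identical(new_depth, depth)) break
      depth <- new_depth
    }
    dirs <- node_direction_matrix(df, pos_parent)
    Pm <- cbind(df$x, df$y, df$z)
    D <- as.matrix(stats::dist(Pm))
    thr <- outer(df$radius, df$radius, pmax)
    qual <- D < thr
    diag(qual) <- FALSE
    # exclude directly connected pairs
    edge <- which(!is.na(pos_parent))
    qual[cbind(edge, pos_parent[edge])] <- FALSE
    qual[cbind(pos_parent[edge], edge)] <- FALSE
    # direction-similarity gate (NA direction passes)
    cosang <- dirs %*% t(dirs)
    ang_ok <- is.na(cosang) | cosang > cos(max_angle)
    qual <- qual & ang_ok
    if (!any(qual)) break
    consumed <- logical(n)
    merges <- list()
    for (i in order(depth)) {
      if (consumed[i]) next
      js <- which(qual[i, ] & !consumed)
      js <- js[js != i]
      if (length(js) == 0L) next
      j <- js[which.min(D[i, js])]
      consumed[c(i, j)] <- TRUE
      a <- if (depth[i] <= depth[j]) i else j
      merges[[length(merges) + 1L]] <- list(i = i, j = j, keep_parent_of = a)
    }
    if (length(merges) == 0L) break
    new_rows <- list()
    remap <- integer(0)  # old id -> new id
    next_id <- max(df$id) + 1L
    for (m in merges) {
      new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
        id = next_id,
        type = df$type[m$keep_parent_of],
        x = (df$x[m$i] + df$x[m$j]) / 2,
        y = (df$y[m$i] + df$y[m$j]) / 2,
        z = (df$z[m$i] + df$z[m$j]) / 2,
        radius = (df$radius[m$i] + df$radius[m$j]) / 2,
        parent = df$parent[m$keep_parent_of])
      remap[as.character(df$id[m$i])] <- next_id
      remap[as.character(df$id[m$j])] <- next_id
      next_id <- next_id + 1L
    }
    df <- dplyr::bind_rows(df[!consumed, , drop = FALSE],
                           dplyr::bind_rows(new_rows))
    hit <- as.character(df$parent) %in% names(remap)
    df$parent[hit] <- remap[as.character(df$parent[hit])]
    # guard: a merge that produced a cycle would make compacting fail
    ok <- tryCatch({ compact_tree(df); TRUE }, error = function(e) FALSE)
    if (!ok) {
      warning("merge pass produced an inconsistent tree; stopping early")
      break
    }
  }
  compact_tree(df)
}

# Unit direction per node: from parent to node; roots use the direction to
# their first child; isolated nodes get NA.
node_direction_matrix <- function(df, pos_parent) {
  n <- nrow(df)
  dirs <- matrix(NA_real_, n, 3)
  Pm <- cbind(df$x, df$y, df$z)
  has_par <- !is.na(pos_parent)
  d <- Pm[has_par, , drop = FALSE] - Pm[pos_parent[has_par], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  good <- len > 1e-9
  dirs[which(has_par)[good], ] <- d[good, , drop = FALSE] / len[good]
  # roots: direction to first child
  for (i in which(!has_par)) {
    ch <- which(pos_parent == i)[1]
    if (!is.na(ch)) {
      d1 <- Pm[ch, ] - Pm[i, ]
      if (vnorm(d1) > 1e-9) dirs[i, ] <- d1 / vnorm(d1)
    }
  }
  dirs
}

#' Prune short terminal branches
#'
#' A branch is the path from the last bifurcation to an endpoint; its
#' length is the polyline length of that path. Terminal branches shorter
#' than `abs_min_length` voxels, or shorter than `rel_min_length` times
#' the radius at their bifurcation, are removed. Removal is applied
#' iteratively until stable, so cascades (a bifurcation whose branches are
#' all pruned becomes part of a longer branch) are handled. An unbranched
#' root-to-tip path is never a candidate and is never emptied.
#'
#' @param tree a [neuron_tree()].
#' @param abs_min_length absolute threshold in voxels (default 5).
#' @param rel_min_length threshold in multiples of the bifurcation radius
#'   (default 2).
#' @return A pruned, re-compacted [neuron_tree()].
#' @export
prune_short_branches <- function(tree, abs_min_length = 5,
                                 rel_min_length = 2) {
  stopifnot(inherits(tree, "neuron_tree"),
            abs_min_length >= 0, rel_min_length >= 0)
  df <- tibble::as_tibble(tree)
  repeat {
    n <- nrow(df)
    if (n == 0L) break
    pos_parent <- match(df$parent, df$id)
    cc <- tabulate(pos_parent[!is.na(pos_parent)], nbins = n)
    tips <- which(cc == 0L)
    drop <- logical(n)
    for (tip in tips) {
      path <- tip
      cur <- tip
      repeat {
        par <- pos_parent[cur]
        if (is.na(par)) { par <- NA_integer_; break }
        if (cc[par] >= 2L) break
        path <- c(path, par)
        cur <- par
      }
      if (is.na(par)) next  # reaches a root with no bifurcation: exempt
      pts <- rbind(c(df$x[par], df$y[par], df$z[par]),
                   cbind(df$x[rev(path)], df$y[rev(path)], df$z[rev(path)]))
      seg <- diff(pts)
      len <- sum(sqrt(rowSums(seg^2)))
      if (len < abs_min_length || len < rel_min_length * df$radius[par])
        drop[path] <- TRUE
    }
    if (!any(drop)) break
    df <- df[!drop, , drop = FALSE]
  }
  compact_tree(df)
}
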