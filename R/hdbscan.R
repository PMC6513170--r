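## Hierarchical density-based clustering (HDBSCAN) implemented from
## scratch: mutual-reachability distances, a Prim minimum spanning tree,
## single-linkage hierarchy, condensed tree and excess-of-mass cluster
## selection. O(n^2) memory/time, intended for the 2-D embeddings this
## pipeline clusters (thousands of points). A single root-level cluster is
## never selected, so a dataset with one diffuse blob comes back as noise.

#' Density-based clustering of 2-D coordinates
#'
#' HDBSCAN with the classical single-parameter form: `min_pts` acts as both
#' the minimum cluster size and the core-distance neighbourhood size
#' (min samples). Cluster labels are dense integers assigned in decreasing
#' cluster-size order; 0 labels noise points.
#'
#' @param x numeric matrix of coordinates (one row per point).
#' @param min_pts minimum number of cluster points (>= 2).
#' @return integer vector of labels (0 = noise), one per row of `x`.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(60, 0), ncol = 2),
#'              matrix(rnorm(60, 8), ncol = 2))
#' table(hdbscanLabels(pts, min_pts = 10))
#' @export
hdbscanLabels <- function(x, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  min_pts <- as.integer(min_pts)
  if (min_pts < 2L) .stopf("min_pts must be >= 2")
  if (min_pts > n) {
    .warnf("min_pts (%d) exceeds the number of points (%d): all noise",
           min_pts, n)
    return(rep(0L, n))
  }
  D <- as.matrix(dist(x))
  core <- apply(D, 1L, function(r) sort(r, partial = min_pts)[min_pts])
  mrd <- pmax(D, matrix(pmax(rep(core, times = n), rep(core, each = n)), n))

  ## Prim MST over the mutual-reachability graph
  inmst <- logical(n); inmst[1L] <- TRUE
  key <- mrd[, 1L]; from <- rep(1L, n)
  ea <- eb <- integer(n - 1L); ew <- numeric(n - 1L)
  for (e in seq_len(n - 1L)) {
    rest <- which(!inmst)
    v <- rest[which.min(key[rest])]
    ea[e] <- from[v]; eb[e] <- v; ew[e] <- key[v]
    inmst[v] <- TRUE
    rest <- rest[rest != v]
    imp <- mrd[rest, v] < key[rest]
    key[rest[imp]] <- mrd[rest[imp], v]
    from[rest[imp]] <- v
  }

  ## single-linkage hierarchy: nodes 1..n are leaves, n+1..2n-1 merges
  o <- order(ew)
  uf <- seq_len(n)
  find <- function(i) {
    while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }
    i
  }
  node_of <- seq_len(n)                 # union-find root -> SL node id
  n_nodes <- 2L * n - 1L
  left <- right <- integer(n_nodes); height <- numeric(n_nodes)
  size <- c(rep(1L, n), integer(n - 1L))
  for (e in seq_len(n - 1L)) {
    i <- o[e]
    ra <- find(ea[i]); rb <- find(eb[i])
    id <- n + e
    left[id] <- node_of[ra]; right[id] <- node_of[rb]; height[id] <- ew[i]
    size[id] <- size[left[id]] + size[right[id]]
    uf[ra] <- rb
    node_of[rb] <- id
  }

  .condensed_labels(n, min_pts, left, right, height, size)
}

## leaves of an SL subtree, iteratively
.sl_leaves <- function(node, left, right, n) {
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= n) out[length(out) + 1L] <- v
    else stack <- c(stack, left[v], right[v])
  }
  out
}

.condensed_labels <- function(n, mcs, left, right, height, size) {
  root <- 2L * n - 1L
  if (n < 2L) return(rep(0L, n))
  ## condensed clusters: 1 is the root cluster
  birth <- 0; cparent <- 0L; n_cond <- 1L
  pt_cluster <- integer(n); pt_lambda <- numeric(n)
  row_parent <- integer(0); row_child <- integer(0)
  row_lambda <- numeric(0); row_size <- integer(0)
  stack_node <- root; stack_cl <- 1L
  while (length(stack_node)) {
    k <- length(stack_node)
    node <- stack_node[k]; cl <- stack_cl[k]
    stack_node <- stack_node[-k]; stack_cl <- stack_cl[-k]
    if (node <= n) {   # singleton continuation (only possible when mcs == 1)
      pt_cluster[node] <- cl; pt_lambda[node] <- Inf
      next
    }
    lam <- if (height[node] > 0) 1 / height[node] else Inf
    l <- left[node]; r <- right[node]
    ls <- size[l]; rs <- size[r]
    if (ls >= mcs && rs >= mcs) {
      for (ch in c(l, r)) {
        n_cond <- n_cond + 1L
        birth[n_cond] <- lam; cparent[n_cond] <- cl
        row_parent <- c(row_parent, cl); row_child <- c(row_child, n_cond)
        row_lambda <- c(row_lambda, lam); row_size <- c(row_size, size[ch])
        stack_node <- c(stack_node, ch); stack_cl <- c(stack_cl, n_cond)
      }
    } else if (ls >= mcs || rs >= mcs) {
      big <- if (ls >= mcs) l else r
      small <- if (ls >= mcs) r else l
      lv <- .sl_leaves(small, left, right, n)
      pt_cluster[lv] <- cl; pt_lambda[lv] <- lam
      stack_node <- c(stack_node, big); stack_cl <- c(stack_cl, cl)
    } else {
      lv <- .sl_leaves(node, left, right, n)
      pt_cluster[lv] <- cl; pt_lambda[lv] <- lam
    }
  }

  if (n_cond == 1L) return(rep(0L, n))   # no split survived: all noise

  ## stability = sum over members of (lambda_leave - lambda_birth)
  stab <- numeric(n_cond)
  for (p in seq_len(n)) {
    c0 <- pt_cluster[p]
    if (c0 > 0L) stab[c0] <- stab[c0] + (pt_lambda[p] - birth[c0])
  }
  if (length(row_parent)) {
    for (k in seq_along(row_parent)) {
      stab[row_parent[k]] <- stab[row_parent[k]] +
        (row_lambda[k] - birth[row_parent[k]]) * row_size[k]
    }
  }

  ## excess-of-mass selection, root excluded (no single-cluster solutions)
  children <- split(row_child, row_parent)
  sel <- logical(n_cond)
  for (cl in seq.int(n_cond, 2L)) {
    ch <- children[[as.character(cl)]]
    if (is.null(ch)) { sel[cl] <- TRUE; next }
    sub <- sum(stab[ch])
    if (stab[cl] < sub) {
      stab[cl] <- sub
      sel[cl] <- FALSE
    } else {
      sel[cl] <- TRUE
      ## deselect the whole subtree below cl
      q <- ch
      while (length(q)) {
        sel[q] <- FALSE
        q <- unlist(children[as.character(q)], use.names = FALSE)
      }
    }
  }
  sel[1L] <- FALSE

  ## a point belongs to the selected ancestor of its condensed cluster
  sel_anc <- integer(n_cond)            # 0 = none
  for (cl in seq_len(n_cond)) {
    a <- cl
    while (a > 0L && !sel[a]) a <- cparent[a]
    sel_anc[cl] <- a
  }
  raw <- ifelse(pt_cluster > 0L, sel_anc[pmax(pt_cluster, 1L)], 0L)

  ## dense labels in decreasing size order
  picked <- which(sel)
  if (!length(picked)) return(rep(0L, n))
  sizes <- vapply(picked, function(cl) sum(raw == cl), 1L)
  picked <- picked[order(-sizes, picked)]
  out <- integer(n)
  for (j in seq_along(picked)) out[raw == picked[j]] <- j
  out
}
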