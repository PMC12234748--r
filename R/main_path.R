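#' Downstream and successor nodes along a partially built path
#'
#' For the last node `i` of `path_so_far` (which must start at the origin),
#' `down(i)` is the set of nodes directly connected to `i` that are not on
#' the origin-to-`i` path, and `successor(i')` for a candidate `i'` is
#' every node reachable from `i'` excluding all nodes on the path.
#' Reachability uses breadth-first search, so cyclic cluster graphs are
#' handled (each node visited once).
#'
#' @param g A `tivelo_cluster_graph` (pruned; only retained nodes are
#'   considered).
#' @param path_so_far Character vector of nodes, starting at the origin.
#' @return A list with `down` (character vector) and `successor` (named
#'   list mapping each down-node to its successor set).
#' @export
down_and_successors <- function(g, path_so_far) {
  nodes <- g$retained
  w <- g$weights[nodes, nodes, drop = FALSE]
  i <- path_so_far[length(path_so_far)]
  down <- setdiff(nodes[w[i, ] > 0], path_so_far)
  succ <- lapply(down, function(d) {
    reachable_excluding(w, nodes, start = d, excluded = path_so_far)
  })
  names(succ) <- down
  list(down = down, successor = succ)
}

# BFS from `start` over positive weights, never entering `excluded`;
# returns reached nodes except `start` itself
reachable_excluding <- function(w, nodes, start, excluded) {
  visited <- start
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(nd) nodes[w[nd, ] > 0])))
    nxt <- setdiff(nxt, c(visited, excluded))
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  setdiff(visited, start)
}

#' Select the main path of the cluster graph
#'
#' Starting at the origin the path is grown greedily: from the current node
#' the next node is the downstream node whose own cell count plus the cell
#' count of all its successors is maximal (ties break by ascending node
#' id). Growth stops when no downstream node remains. All off-path nodes
#' are collected into branches — maximal simple sub-paths attached to the
#' main path — so that every retained node lies on the main path or on
#' exactly one branch.
#'
#' @param g A `tivelo_cluster_graph` with the origin set.
#' @return An object of class `tivelo_main_path` with fields `nodes`
#'   (ordered, starting at the origin), `branches` (list of lists with
#'   `attach` node and ordered `nodes`), and the per-step decision log.
#' @export
select_main_path <- function(g) {
  if (is.null(g$origin)) abort("origin not set: run select_origin() first")
  sizes <- setNames(g$nodes$n_cells, g$nodes$node)
  path <- g$origin
  log <- character()
  repeat {
    ds <- down_and_successors(g, path)
    if (length(ds$down) == 0) break
    mass <- vapply(ds$down, function(d) {
      sizes[[d]] + sum(sizes[ds$successor[[d]]])
    }, 0)
    best <- max(mass)
    cand <- sort(ds$down[mass == best])
    if (length(cand) > 1) {
      # mass ties resolve toward the strongest edge (spurious weak edges
      # can reach the same successor set), then by node id
      wts <- g$weights[path[length(path)], cand]
      cand <- cand[order(-wts, cand)]
      log <- c(log, sprintf(
        "tie at %s (mass %g): chose %s by edge weight", path[length(path)], best, cand[1]
      ))
    }
    path <- c(path, cand[1])
  }
  if (length(path) == 1) {
    warn("origin is isolated; main path contains only the origin")
  }
  branches <- collect_branches(g, path, sizes)
  structure(
    list(nodes = path, branches = branches, log = log),
    class = "tivelo_main_path"
  )
}

# off-path nodes grouped into maximal sub-paths, each attached to the node
# (on the main path or an earlier branch) it hangs off
collect_branches <- function(g, path, sizes) {
  nodes <- g$retained
  w <- g$weights[nodes, nodes, drop = FALSE]
  remaining <- setdiff(nodes, path)
  branches <- list()
  assigned <- path
  while (length(remaining) > 0) {
    # grow a branch from the first remaining node adjacent to the assigned set
    seed <- NULL
    for (nd in sort(remaining)) {
      att <- sort(assigned[w[nd, assigned] > 0])
      if (length(att) > 0) {
        seed <- nd
        attach <- att[1]
        break
      }
    }
    if (is.null(seed)) {
      # disconnected leftovers become their own branch without attachment
      seed <- sort(remaining)[1]
      attach <- NA_character_
    }
    branch <- seed
    repeat {
      nxt <- setdiff(sort(nodes[w[branch[length(branch)], ] > 0]), c(assigned, branch))
      nxt <- intersect(nxt, remaining)
      if (length(nxt) == 0) break
      # follow the heaviest continuation; siblings start their own branch
      mass <- vapply(nxt, function(d) sizes[[d]], 0)
      branch <- c(branch, nxt[which.max(mass)])
    }
    branches[[length(branches) + 1]] <- list(attach = attach, nodes = branch)
    assigned <- c(assigned, branch)
    remaining <- setdiff(remaining, branch)
  }
  branches
}

#' @export
print.tivelo_main_path <- function(x, ...) {
  cat("<tivelo_main_path>", paste(x$nodes, collapse = " -> "), "\n")
  for (b in x$branches) {
    cat(sprintf(
      "  branch at %s: %s\n", b$attach, paste(b$nodes, collapse = " -> ")
    ))
  }
  invisible(x)
}
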