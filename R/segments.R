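#' Decompose an arbor into branch segments
#'
#' A segment is a maximal unbranched run of edges between the soma or a
#' branch point and the next branch point or terminal tip.  Segments carry
#' a centrifugal order: primaries leaving the soma have order 1, and a
#' daughter's order is its parent's order plus one.  The soma itself is
#' never a branch point, so a multipolar soma yields several order-1
#' primaries rather than a bifurcation.
#'
#' @param cell A [cell_morphology()].
#' @return A tibble of class `segment_decomposition` with columns
#'   `segment_id`, `parent_segment` (`NA` for primaries), `order`,
#'   `is_terminal` and the list-column `nodes` (node ids from the proximal
#'   anchor to the distal end).  Attributes: `primary_count`,
#'   `terminal_orders`, `n_branch_points`, `cell_id`.
#' @export
decompose <- function(cell) {
  nodes <- tibble::as_tibble(cell)
  root_row <- which(nodes$parent_id == -1L)
  if (length(root_row) != 1L) {
    stop("cell must have exactly one root", call. = FALSE)
  }
  root <- nodes$node_id[root_row]
  # children as row indices, via a dense node-id -> row map
  parent_row <- match(nodes$parent_id, nodes$node_id)
  kids_of <- split(seq_len(nrow(nodes))[-root_row],
                   factor(parent_row[-root_row], levels = seq_len(nrow(nodes))))
  n_kids <- lengths(kids_of)

  seg_parent <- integer(0); seg_order <- integer(0)
  seg_terminal <- logical(0); seg_nodes <- list()
  # stack of (first child row, anchor row, order, parent segment)
  stack <- lapply(kids_of[[root_row]],
                  function(ch) list(ch, root_row, 1L, NA_integer_))
  while (length(stack) > 0) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    cur <- item[[1]]
    path <- c(item[[2]], cur)
    while (n_kids[cur] == 1L) {
      cur <- kids_of[[cur]]
      path <- c(path, cur)
    }
    sid <- length(seg_nodes) + 1L
    seg_nodes[[sid]] <- nodes$node_id[path]
    seg_parent[sid] <- item[[4]]
    seg_order[sid] <- item[[3]]
    seg_terminal[sid] <- n_kids[cur] == 0L
    if (n_kids[cur] > 0L) {
      for (c2 in kids_of[[cur]]) {
        stack[[length(stack) + 1]] <- list(c2, cur, item[[3]] + 1L, sid)
      }
    }
  }
  if (length(seg_nodes) == 0L) stop("cell has no branches", call. = FALSE)
  out <- tibble::tibble(
    segment_id = seq_along(seg_nodes),
    parent_segment = seg_parent,
    order = seg_order,
    is_terminal = seg_terminal,
    nodes = seg_nodes)
  # the soma is never a branch point, however many primaries it bears
  non_root_parents <- nodes$parent_id[nodes$parent_id != -1L &
                                        nodes$parent_id != root]
  branch_pts <- sum(table(non_root_parents) >= 2L)
  structure(out,
            class = c("segment_decomposition", class(tibble::tibble())),
            primary_count = sum(is.na(seg_parent)),
            terminal_orders = seg_order[seg_terminal],
            n_branch_points = as.integer(branch_pts),
            cell_id = cell_id(cell))
}

#' Composite branching-complexity score
#'
#' The complexity of an arbor is
#' `(sum of terminal centrifugal orders + number of terminals) *
#'  (total branch length / number of primary branches)`,
#' in micrometres.  It grows with both topological depth (terminal orders)
#' and metric extent (length per primary tree), and is the key screening
#' variable for astrocyte morphotypes.
#'
#' @param decomp A [decompose()] result.
#' @param total_length Total branch length of the same cell in micrometres.
#' @return Complexity in micrometres.
#' @export
complexity <- function(decomp, total_length) {
  np <- attr(decomp, "primary_count", exact = TRUE)
  if (is.null(np) || np < 1L) {
    stop("complexity undefined: no primary branches", call. = FALSE)
  }
  term_orders <- attr(decomp, "terminal_orders", exact = TRUE)
  (sum(term_orders) + length(term_orders)) * (total_length / np)
}

#' Complexity straight from a cell
#'
#' Convenience wrapper around [decompose()], [path_metrics()] and
#' [complexity()].
#'
#' @param cell A [cell_morphology()].
#' @return Complexity in micrometres.
#' @export
cell_complexity <- function(cell) {
  decomp <- decompose(cell)
  complexity(decomp, path_metrics(cell)$total_branch_length)
}
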