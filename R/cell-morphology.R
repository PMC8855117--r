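#' Construct a cell morphology object
#'
#' A `cell_morphology` is a tibble of measured nodes (one row per node of the
#' reconstructed arbor) carrying the cell's identity as attributes.  Columns
#' are `node_id`, `parent_id` (`-1` marks the root/soma), `x`, `y`, `z`
#' (micrometres), `radius` (micrometres) and `type_tag` (the SWC structure
#' code, passed through uninterpreted so astrocyte reconstructions with
#' custom tags are accepted).
#'
#' @param nodes A data frame with columns `node_id`, `parent_id`, `x`, `y`,
#'   `z`, `radius` and optionally `type_tag` (defaults to 7, the SWC
#'   "custom" code often used for glia).
#' @param cell_id Identifier of the cell.
#' @param species,individual Optional labels carried through the pipeline.
#' @param validate If `TRUE` (default), reject nodes violating the tree
#'   invariants (see [validate_tree()]).
#'
#' @return A tibble of class `cell_morphology`.
#' @export
cell_morphology <- function(nodes, cell_id, species = NA_character_,
                            individual = NA_character_, validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  if (!"type_tag" %in% names(nodes)) nodes$type_tag <- 7L
  required <- c("node_id", "parent_id", "x", "y", "z", "radius", "type_tag")
  missing <- setdiff(required, names(nodes))
  if (length(missing) > 0) {
    stop("nodes is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nodes <- nodes[required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$type_tag <- as.integer(nodes$type_tag)
  cell <- structure(
    nodes,
    class = c("cell_morphology", class(tibble::tibble())),
    cell_id = as.character(cell_id),
    species = as.character(species),
    individual = as.character(individual)
  )
  if (validate) {
    rep <- validate_tree(cell)
    if (!rep$ok) {
      stop("invalid cell morphology '", cell_id, "': ",
           paste(rep$issues$message, collapse = "; "), call. = FALSE)
    }
  }
  cell
}

#' @export
print.cell_morphology <- function(x, ...) {
  cat("<cell_morphology> ", cell_id(x), ": ", nrow(x), " nodes",
      if (!is.na(attr(x, "species"))) paste0(" (", attr(x, "species"), ")"),
      "\n", sep = "")
  NextMethod()
}

#' Accessors for cell identity
#'
#' @param cell A [cell_morphology()] object.
#' @return A character scalar.
#' @export
cell_id <- function(cell) attr(cell, "cell_id", exact = TRUE)

#' Validate the tree invariants of a reconstruction
#'
#' Checks that a node table encodes a single rooted tree: exactly one root
#' (`parent_id == -1`), unique node ids, every parent defined before its
#' child, no self-referencing nodes, and strictly positive radii.  All
#' violations are enumerated rather than raised.
#'
#' @param cell A `cell_morphology` or a bare node data frame.
#' @return A list of class `validation_report` with elements `ok` (logical)
#'   and `issues`, a tibble with columns `code`, `node_id`, `message`.
#' @export
validate_tree <- function(cell) {
  nodes <- tibble::as_tibble(cell)
  issues <- list()
  add <- function(code, node_id, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      code = code, node_id = as.integer(node_id), message = message)
  }

  dup <- nodes$node_id[duplicated(nodes$node_id)]
  for (id in unique(dup)) {
    add("duplicate-id", id, sprintf("node id %d occurs more than once", id))
  }

  roots <- which(nodes$parent_id == -1L)
  if (length(roots) == 0L) {
    add("no-root", NA, "no node has parent_id -1")
  } else if (length(roots) > 1L) {
    for (i in roots[-1]) {
      add("multi-root", nodes$node_id[i],
          sprintf("node %d is a second root", nodes$node_id[i]))
    }
  }

  self <- which(nodes$parent_id == nodes$node_id)
  for (i in self) {
    add("cycle", nodes$node_id[i],
        sprintf("node %d is its own parent", nodes$node_id[i]))
  }

  seen <- character(0)
  for (i in seq_len(nrow(nodes))) {
    pid <- nodes$parent_id[i]
    nid <- nodes$node_id[i]
    if (pid != -1L && pid != nid) {
      if (!pid %in% nodes$node_id) {
        add("orphan-parent", nid,
            sprintf("node %d references missing parent %d", nid, pid))
      } else if (!as.character(pid) %in% seen) {
        add("parent-after-child", nid,
            sprintf("node %d appears before its parent %d", nid, pid))
      }
    }
    seen <- c(seen, as.character(nid))
  }

  bad_r <- which(!is.finite(nodes$radius) | nodes$radius <= 0)
  for (i in bad_r) {
    add("bad-radius", nodes$node_id[i],
        sprintf("node %d has non-positive radius", nodes$node_id[i]))
  }

  issues <- if (length(issues) > 0) dplyr::bind_rows(issues) else
    tibble::tibble(code = character(), node_id = integer(),
                   message = character())
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ok =", x$ok, "\n")
  if (!x$ok) print(x$issues)
  invisible(x)
}

#' Read a digital reconstruction from an SWC file
#'
#' Parses the standard 7-column whitespace-delimited SWC interchange format
#' (`id type x y z radius parent`); `#` starts a comment.  Coordinates are
#' kept at full precision.
#'
#' @param path Path to the SWC file.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extension.
#' @param species,individual Optional labels.
#' @return A [cell_morphology()].
#' @export
read_swc <- function(path, cell_id = NULL, species = NA_character_,
                     individual = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(cell_id)) cell_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    fields <- strsplit(trimws(stripped[i]), "[[:space:]]+")[[1]]
    if (length(fields) != 7L) {
      stop(sprintf("%s:%d: malformed SWC line (%d fields, expected 7)",
                   path, i, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("%s:%d: non-numeric field in SWC line", path, i),
           call. = FALSE)
    }
    rows[[j]] <- vals
  }
  m <- do.call(rbind, rows)
  nodes <- tibble::tibble(
    node_id = as.integer(m[, 1]), type_tag = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent_id = as.integer(m[, 7]))
  cell <- cell_morphology(nodes, cell_id = cell_id, species = species,
                          individual = individual, validate = FALSE)
  rep <- validate_tree(cell)
  if (!rep$ok) {
    stop("structure error in ", path, ": ",
         paste(rep$issues$message, collapse = "; "), call. = FALSE)
  }
  cell
}

#' Write a reconstruction to an SWC file
#'
#' @param cell A [cell_morphology()].
#' @param path Output path.  The root's parent is written as `-1`.
#' @return `path`, invisibly.
#' @export
write_swc <- function(cell, path) {
  nodes <- tibble::as_tibble(cell)
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   nodes$node_id, nodes$type_tag, nodes$x, nodes$y,
                   nodes$z, nodes$radius, nodes$parent_id)
  header <- sprintf("# SWC export of cell %s", cell_id(cell))
  ok <- tryCatch({
    writeLines(c(header, lines), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write SWC file: ", path, call. = FALSE)
  invisible(path)
}

#' Correct z-axis tissue shrinkage
#'
#' Histological processing shrinks sections along the slicing axis while
#' leaving the section plane essentially unaffected, so the correction is
#' applied exclusively to z: every z coordinate is multiplied by `factor`
#' (default 1.75, restoring the pre-processing section thickness); x, y and
#' radii are untouched.
#'
#' @param cell A [cell_morphology()].
#' @param factor Positive multiplicative correction, default 1.75.
#' @return The corrected `cell_morphology`.
#' @export
correct_z_shrinkage <- function(cell, factor = 1.75) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("shrinkage factor must be a single positive number", call. = FALSE)
  }
  cell$z <- cell$z * factor
  cell
}
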