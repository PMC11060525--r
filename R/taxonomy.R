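# Taxonomy tree: the classifier hierarchy as configurable data.
#
# A hierarchy is a tree of classifier nodes. Each node owns a set of output
# slots; a slot either carries a terminal class label or descends into a
# child node. Abstention at a node emits the node's fallback label (the class
# the node represents in its parent), or the tree-wide unknown label at the
# root.

#' Build and validate a classifier hierarchy
#'
#' Turns a parsed taxonomy description (a list, typically read from YAML with
#' [read_taxonomy()]) into a validated `hierarchy_tree` object. The
#' description lists nodes with their id, display name, level, architecture
#' variant, training epochs, output slots and fallback label. An output slot
#' is terminal unless it names a `child` node id, in which case an image
#' routed to that slot descends into the child classifier.
#'
#' Validation enforces: unique node ids, exactly one root, every non-root
#' node referenced by exactly one parent slot, child level = parent level + 1,
#' no cycles, non-empty outputs, terminal labels unique across the tree and
#' distinct from fallback labels, and each non-root node's fallback equal to
#' the label of the parent slot that points to it.
#'
#' @param config A list with elements `nodes` (list of node descriptions),
#'   optional `unknown_label` (default `"Unknown"`) and optional `aliases`
#'   (named list mapping alias labels, e.g. species folded into a class, to
#'   terminal labels).
#' @return A `hierarchy_tree` object: list with `nodes` (named by id),
#'   `root`, `unknown_label`, `aliases`.
#' @seealso [default_taxonomy()], [enumerate_labels()], [read_taxonomy()]
#' @export
#' @examples
#' tree <- build_hierarchy(default_taxonomy())
#' tree
build_hierarchy <- function(config) {
  if (is.null(config$nodes) || length(config$nodes) == 0L) {
    stop("taxonomy config must list at least one node", call. = FALSE)
  }
  unknown_label <- config$unknown_label %||% "Unknown"
  aliases <- config$aliases %||% list()

  nodes <- lapply(config$nodes, normalize_node)
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate node id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(nodes) <- ids

  ## children referenced by descend slots
  child_refs <- unlist(lapply(nodes, function(nd) {
    vapply(nd$outputs, function(s) s$child %||% NA_character_, character(1))
  }))
  child_refs <- child_refs[!is.na(child_refs)]
  missing <- setdiff(child_refs, ids)
  if (length(missing)) {
    stop("dangling child reference: node '", missing[1], "' does not exist",
         call. = FALSE)
  }
  if (anyDuplicated(child_refs)) {
    stop("node '", child_refs[duplicated(child_refs)][1],
         "' is referenced by more than one parent output", call. = FALSE)
  }
  roots <- setdiff(ids, child_refs)
  if (length(roots) != 1L) {
    stop("hierarchy must have exactly one root; found: ",
         paste(roots, collapse = ", "), call. = FALSE)
  }
  root <- roots[[1]]

  ## walk from root: cycles, levels, fallback consistency
  seen <- character(0)
  walk <- function(id, level, expected_fallback) {
    if (id %in% seen) stop("cycle detected at node '", id, "'", call. = FALSE)
    seen <<- c(seen, id)
    nd <- nodes[[id]]
    if (nd$level != level) {
      stop("node '", id, "': level must be ", level, " (parent level + 1), got ",
           nd$level, call. = FALSE)
    }
    if (!is.null(expected_fallback) && !identical(nd$fallback, expected_fallback)) {
      stop("node '", id, "': fallback label must equal the class it represents ",
           "in its parent ('", expected_fallback, "'), got '", nd$fallback, "'",
           call. = FALSE)
    }
    for (slot in nd$outputs) {
      if (!is.null(slot$child)) walk(slot$child, level + 1L, slot$label)
    }
  }
  ## root's fallback is the unknown label
  if (!identical(nodes[[root]]$fallback, unknown_label)) {
    nodes[[root]]$fallback <- unknown_label
  }
  walk(root, nodes[[root]]$level, NULL)
  unreachable <- setdiff(ids, seen)
  if (length(unreachable)) {
    stop("node '", unreachable[1], "' is not reachable from the root",
         call. = FALSE)
  }

  terminals <- unlist(lapply(nodes, function(nd) {
    vapply(Filter(function(s) is.null(s$child), nd$outputs), `[[`,
           character(1), "label")
  }), use.names = FALSE)
  if (anyDuplicated(terminals)) {
    stop("duplicate terminal label: '", terminals[duplicated(terminals)][1],
         "'", call. = FALSE)
  }
  fallbacks <- vapply(nodes[setdiff(ids, root)], `[[`, character(1), "fallback")
  clash <- intersect(terminals, c(fallbacks, unknown_label))
  if (length(clash)) {
    stop("label '", clash[1],
         "' is used both as a terminal and as a fallback/unknown label",
         call. = FALSE)
  }
  bad_alias <- setdiff(unlist(aliases, use.names = FALSE), terminals)
  if (length(bad_alias)) {
    stop("alias target '", bad_alias[1], "' is not a terminal label",
         call. = FALSE)
  }

  structure(
    list(nodes = nodes, root = root, unknown_label = unknown_label,
         aliases = aliases),
    class = "hierarchy_tree"
  )
}

normalize_node <- function(nd) {
  for (field in c("id", "name", "level", "outputs", "fallback")) {
    if (is.null(nd[[field]])) {
      stop("node ", nd$id %||% "<unnamed>", ": missing field '", field, "'",
           call. = FALSE)
    }
  }
  if (length(nd$outputs) == 0L) {
    stop("node '", nd$id, "': outputs must be nonempty", call. = FALSE)
  }
  nd$level <- as.integer(nd$level)
  if (nd$level < 1L) stop("node '", nd$id, "': level must be >= 1", call. = FALSE)
  nd$architecture <- match.arg(nd$architecture %||% "deep", c("shallow", "deep"))
  nd$epochs <- as.integer(nd$epochs %||% 1L)
  nd$outputs <- lapply(nd$outputs, function(s) {
    if (is.null(s$label)) {
      stop("node '", nd$id, "': output slot without a label", call. = FALSE)
    }
    list(label = s$label, child = s$child)
  })
  nd[c("id", "name", "level", "architecture", "epochs", "outputs", "fallback")]
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  labs <- enumerate_labels(x)
  cat("<hierarchy_tree> ", length(x$nodes), " classifier nodes, depth ",
      tree_depth(x), "\n", sep = "")
  cat("  terminal labels:  ", length(terminal_labels(x)), "\n", sep = "")
  cat("  total labels:     ", length(labs), " (incl. fallbacks and '",
      x$unknown_label, "')\n", sep = "")
  for (id in names(x$nodes)) {
    nd <- x$nodes[[id]]
    cat(sprintf("  [%d] %-14s %-8s outputs: %s\n", nd$level, nd$id,
                nd$architecture,
                paste(vapply(nd$outputs, function(s) {
                  if (is.null(s$child)) s$label else paste0(s$label, " -> ", s$child)
                }, character(1)), collapse = ", ")))
  }
  invisible(x)
}

#' Terminal class labels of a hierarchy
#'
#' @param tree A `hierarchy_tree`.
#' @return Character vector of terminal labels in depth-first node order.
#' @export
terminal_labels <- function(tree) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  out <- character(0)
  walk <- function(id) {
    for (slot in tree$nodes[[id]]$outputs) {
      if (is.null(slot$child)) out <<- c(out, slot$label) else walk(slot$child)
    }
  }
  walk(tree$root)
  out
}

#' Enumerate every label a classification can produce
#'
#' The label set is the union of terminal labels, the fallback labels of all
#' non-root nodes (emitted on abstention below the root) and the unknown
#' label (emitted on abstention at the root), in that order. The order is
#' deterministic: depth-first terminals, then depth-first fallbacks, then the
#' unknown label.
#'
#' @param tree A `hierarchy_tree`.
#' @return Character vector of labels.
#' @export
#' @examples
#' length(enumerate_labels(build_hierarchy(default_taxonomy())))  # 21
enumerate_labels <- function(tree) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  fallbacks <- character(0)
  walk <- function(id) {
    for (slot in tree$nodes[[id]]$outputs) {
      if (!is.null(slot$child)) {
        fallbacks <<- c(fallbacks, tree$nodes[[slot$child]]$fallback)
        walk(slot$child)
      }
    }
  }
  walk(tree$root)
  c(terminal_labels(tree), fallbacks, tree$unknown_label)
}

#' Maximum level of any node in the tree
#' @param tree A `hierarchy_tree`.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  max(vapply(tree$nodes, `[[`, integer(1), "level"))
}

#' Parent node id of each node
#' @keywords internal
node_parents <- function(tree) {
  parents <- stats::setNames(rep(NA_character_, length(tree$nodes)),
                             names(tree$nodes))
  for (id in names(tree$nodes)) {
    for (slot in tree$nodes[[id]]$outputs) {
      if (!is.null(slot$child)) parents[slot$child] <- id
    }
  }
  parents
}

#' Default north-eastern American taxonomy
#'
#' The default seven-node hierarchy used throughout the package: a main
#' classifier separating the gross morphotypes (aporate Juniperus/Thuja,
#' vesiculate Abies/Picea and Pinus groups, triporate and tricolpate mixes,
#' and a non-pollen palynomorph/minerals class), second-level classifiers
#' resolving the vesiculate and (tri)porate/colpate groups, and third-level
#' classifiers splitting Alnus and Acer to species. Alnus, though
#' stephanoporate, sits under the triporate node: its grains share the size
#' and gross shape of the triporates apart from the pore count. Species
#' routinely folded into a class by analysts (e.g. Pinus resinosa counted as
#' Pinus banksiana) are listed as label aliases rather than extra outputs.
#'
#' 14 terminal labels, 6 intermediate fallback labels and the unknown label
#' give 21 possible classification outcomes.
#'
#' @return A taxonomy config list suitable for [build_hierarchy()].
#' @export
default_taxonomy <- function() {
  list(
    unknown_label = "Unknown",
    aliases = list(
      "Pinus resinosa"    = "Pinus banksiana",
      "Acer pensylvanicum" = "Acer rubrum",
      "Juniperus communis" = "Juniperus/Thuja",
      "Thuja occidentalis" = "Juniperus/Thuja",
      "Picea glauca"       = "Picea",
      "Picea rubens"       = "Picea",
      "Betula alleghaniensis" = "Betula",
      "Betula papyrifera"  = "Betula"
    ),
    nodes = list(
      list(id = "main", name = "Main", level = 1,
           architecture = "deep", epochs = 200,
           fallback = "Unknown",
           outputs = list(
             list(label = "Juniperus/Thuja"),
             list(label = "Abies/Picea mix", child = "abies_picea"),
             list(label = "Pinus mix", child = "pinus"),
             list(label = "Triporate mix", child = "triporate"),
             list(label = "Tricolpate mix", child = "tricolpate"),
             list(label = "NPP/Minerals")
           )),
      list(id = "abies_picea", name = "Abies/Picea", level = 2,
           architecture = "deep", epochs = 250,
           fallback = "Abies/Picea mix",
           outputs = list(
             list(label = "Abies balsamea"),
             list(label = "Picea")
           )),
      list(id = "pinus", name = "Pinus", level = 2,
           architecture = "deep", epochs = 200,
           fallback = "Pinus mix",
           outputs = list(
             list(label = "Pinus banksiana"),
             list(label = "Pinus strobus")
           )),
      list(id = "triporate", name = "Triporate", level = 2,
           architecture = "deep", epochs = 600,
           fallback = "Triporate mix",
           outputs = list(
             list(label = "Betula"),
             list(label = "Corylus cornuta"),
             list(label = "Eucalyptus"),
             list(label = "Alnus", child = "alnus")
           )),
      list(id = "tricolpate", name = "Tricolpate", level = 2,
           architecture = "deep", epochs = 550,
           fallback = "Tricolpate mix",
           outputs = list(
             list(label = "Quercus"),
             list(label = "Acer", child = "acer")
           )),
      list(id = "alnus", name = "Alnus", level = 3,
           architecture = "shallow", epochs = 170,
           fallback = "Alnus",
           outputs = list(
             list(label = "Alnus crispa"),
             list(label = "Alnus rugosa")
           )),
      list(id = "acer", name = "Acer", level = 3,
           architecture = "deep", epochs = 280,
           fallback = "Acer",
           outputs = list(
             list(label = "Acer rubrum"),
             list(label = "Acer saccharum")
           ))
    )
  )
}

#' Read a taxonomy config from YAML
#'
#' Reads and structurally validates a YAML taxonomy description. The schema
#' is `unknown_label`, optional `aliases` (map), and `nodes`, a sequence of
#' maps with keys `id`, `name`, `level`, `architecture`, `epochs`, `fallback`
#' and `outputs` (sequence of maps with `label` and optional `child`).
#' Schema violations raise errors naming the offending node and field.
#'
#' @param path Path to a YAML file.
#' @return A validated `hierarchy_tree` (via [build_hierarchy()]).
#' @export
read_taxonomy <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$nodes)) {
    stop("taxonomy YAML must contain a 'nodes' sequence: ", path, call. = FALSE)
  }
  build_hierarchy(cfg)
}

#' Write a taxonomy config to YAML
#' @param config A taxonomy config list (not a built tree).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Resolve label aliases
#'
#' Maps alias labels (species folded into a coarser class) to their terminal
#' labels; labels without an alias entry pass through unchanged.
#' @param labels Character vector.
#' @param tree A `hierarchy_tree`.
#' @return Character vector of the same length.
#' @export
resolve_aliases <- function(labels, tree) {
  if (!length(tree$aliases)) return(labels)
  map <- unlist(tree$aliases)
  hit <- labels %in% names(map)
  labels[hit] <- map[labels[hit]]
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
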