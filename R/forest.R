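#' @importFrom dplyr filter mutate arrange group_by summarise ungroup bind_rows
#'   left_join pull n
#' @importFrom tibble tibble as_tibble
NULL

# Internal constructor for the FHLCM forest object. Everything user-facing
# goes through cfhlc() or read_forest().
new_fhlc_forest <- function(nodes, edges, priors, cpts, imputed, n_individuals,
                            config = list()) {
  structure(list(
    nodes = nodes, # tibble: id, type, layer, cardinality, window
    edges = edges, # tibble: parent, child, scaled_mi
    priors = priors, # named list: root id -> probability vector
    cpts = cpts, # named list: child id -> (child_card x parent_card) matrix
    imputed = imputed, # integer matrix n x #latents (colnames = latent ids)
    n_individuals = n_individuals,
    config = config
  ), class = "fhlc_forest")
}

#' @export
print.fhlc_forest <- function(x, ...) {
  obs <- sum(x$nodes$type == "observed")
  lat <- sum(x$nodes$type == "latent")
  cat(sprintf(
    "<fhlc_forest> %d observed + %d latent variables, %d trees, max layer %d\n",
    obs, lat, tree_count(x), max(x$nodes$layer)
  ))
  invisible(x)
}

# parent lookup: named character vector child -> parent (roots absent)
parent_map <- function(forest) {
  setNames(forest$edges$parent, forest$edges$child)
}

#' Root nodes of a forest
#'
#' Nodes without a parent; each corresponds to one tree (isolated observed
#' variables count as single-node trees).
#'
#' @param forest an `fhlc_forest`.
#' @return Character vector of node ids.
#' @export
forest_roots <- function(forest) {
  setdiff(forest$nodes$id, forest$edges$child)
}

# tree membership: named vector node id -> root id
tree_assignment <- function(forest) {
  pm <- parent_map(forest)
  vapply(forest$nodes$id, function(id) {
    while (id %in% names(pm)) id <- pm[[id]]
    id
  }, character(1))
}

# observed leaves under each node (a leaf's own set is itself)
subtree_leaves <- function(forest, node_id) {
  kids <- split(forest$edges$child, forest$edges$parent)
  walk <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch)) return(id)
    unlist(lapply(ch, walk), use.names = FALSE)
  }
  obs <- forest$nodes$id[forest$nodes$type == "observed"]
  intersect(walk(node_id), obs)
}

# structural sanity: single parent, acyclic, layer rule, CPT normalization
validate_forest <- function(forest, tol = 1e-6) {
  if (anyDuplicated(forest$edges$child)) {
    abort("a node has more than one parent")
  }
  pm <- parent_map(forest)
  for (id in forest$nodes$id) {
    seen <- character(0)
    cur <- id
    while (cur %in% names(pm)) {
      if (cur %in% seen) abort("cycle detected in forest edges")
      seen <- c(seen, cur)
      cur <- pm[[cur]]
    }
  }
  layer <- setNames(forest$nodes$layer, forest$nodes$id)
  lat <- forest$nodes$id[forest$nodes$type == "latent"]
  for (h in lat) {
    ch <- forest$edges$child[forest$edges$parent == h]
    if (length(ch) < 2L) abort(sprintf("latent node %s has < 2 children", h))
    if (layer[[h]] != 1L + max(layer[ch])) {
      abort(sprintf("layer of %s violates 1 + max(child layers)", h))
    }
  }
  for (r in forest_roots(forest)) {
    if (forest$nodes$type[forest$nodes$id == r] == "latent" &&
        abs(sum(forest$priors[[r]]) - 1) > tol) {
      abort(sprintf("prior of %s does not sum to 1", r))
    }
  }
  for (id in names(forest$cpts)) {
    if (any(abs(colSums(forest$cpts[[id]]) - 1) > tol)) {
      abort(sprintf("CPT columns of %s do not sum to 1", id))
    }
  }
  invisible(forest)
}
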