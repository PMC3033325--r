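#' Serialize a forest to GraphML, JSON or DOT
#'
#' JSON stores the complete object (structure, parameters at full precision,
#' imputed latent data) and round-trips losslessly. GraphML stores the
#' structure as a directed graph with node attributes plus the parameters as
#' an embedded JSON payload, and also round-trips. DOT is a write-only export
#' for graph viewers.
#'
#' @param forest an `fhlc_forest`.
#' @param path output path.
#' @param dialect `"json"`, `"graphml"` or `"dot"`; defaults to the file
#'   extension.
#' @export
write_forest <- function(forest, path,
                         dialect = c("auto", "json", "graphml", "dot")) {
  stopifnot(inherits(forest, "fhlc_forest"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      json = "json", graphml = "graphml", dot = "dot", gv = "dot",
      abort(sprintf("cannot infer dialect from extension '%s'", ext))
    )
  }
  switch(dialect,
    json = write_forest_json(forest, path),
    graphml = write_forest_graphml(forest, path),
    dot = write_forest_dot(forest, path)
  )
  invisible(path)
}

forest_payload <- function(forest) {
  list(
    format = "fhlc_forest",
    version = 1L,
    n_individuals = forest$n_individuals,
    nodes = as.list(forest$nodes),
    edges = as.list(forest$edges),
    priors = forest$priors,
    cpts = lapply(forest$cpts, function(m) {
      list(dim = dim(m), values = as.vector(m))
    }),
    imputed = list(
      latent_ids = as.list(colnames(forest$imputed)),
      values = if (ncol(forest$imputed)) unname(apply(forest$imputed, 2,
                                                      as.list)) else list()
    ),
    config = forest$config
  )
}

payload_to_forest <- function(pl) {
  nodes <- as_tibble(lapply(pl$nodes, unlist))
  nodes$layer <- as.integer(nodes$layer)
  nodes$cardinality <- as.integer(nodes$cardinality)
  nodes$window <- as.integer(nodes$window)
  edges <- if (length(pl$edges$parent)) {
    tibble(
      parent = unlist(pl$edges$parent), child = unlist(pl$edges$child),
      scaled_mi = as.numeric(unlist(pl$edges$scaled_mi))
    )
  } else {
    tibble(parent = character(), child = character(), scaled_mi = numeric())
  }
  cpts <- lapply(pl$cpts, function(e) {
    matrix(as.numeric(unlist(e$values)), nrow = unlist(e$dim)[1])
  })
  lat_ids <- unlist(pl$imputed$latent_ids)
  imputed <- if (length(lat_ids)) {
    m <- do.call(cbind, lapply(pl$imputed$values, function(col) {
      as.integer(unlist(col))
    }))
    colnames(m) <- lat_ids
    m
  } else {
    matrix(integer(0), nrow = as.integer(pl$n_individuals), ncol = 0)
  }
  new_fhlc_forest(
    nodes, edges,
    priors = lapply(pl$priors, function(v) as.numeric(unlist(v))),
    cpts = cpts, imputed = imputed,
    n_individuals = as.integer(pl$n_individuals),
    config = pl$config
  )
}

write_forest_json <- function(forest, path) {
  json <- jsonlite::toJSON(forest_payload(forest),
    auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  writeLines(json, path)
}

read_forest_json <- function(path) {
  payload_to_forest(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

write_forest_graphml <- function(forest, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keydefs <- list(
    c("d_type", "node", "type", "string"),
    c("d_layer", "node", "layer", "int"),
    c("d_card", "node", "cardinality", "int"),
    c("d_window", "node", "window", "int"),
    c("d_smi", "edge", "scaled_mi", "double"),
    c("d_params", "graph", "parameters_json", "string")
  )
  for (k in keydefs) {
    xml2::xml_add_child(doc, "key",
      id = k[1], `for` = k[2], attr.name = k[3], attr.type = k[4]
    )
  }
  g <- xml2::xml_add_child(doc, "graph", id = "fhlcm", edgedefault = "directed")
  params <- forest_payload(forest)
  params$nodes <- NULL
  params$edges <- NULL
  pd <- xml2::xml_add_child(g, "data", key = "d_params")
  xml2::xml_text(pd) <- as.character(jsonlite::toJSON(params,
    auto_unbox = TRUE, digits = NA
  ))
  for (i in seq_len(nrow(forest$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = forest$nodes$id[i])
    vals <- c(
      d_type = forest$nodes$type[i], d_layer = forest$nodes$layer[i],
      d_card = forest$nodes$cardinality[i], d_window = forest$nodes$window[i]
    )
    for (key in names(vals)) {
      d <- xml2::xml_add_child(nd, "data", key = key)
      xml2::xml_text(d) <- as.character(vals[[key]])
    }
  }
  for (i in seq_len(nrow(forest$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
      source = forest$edges$parent[i], target = forest$edges$child[i]
    )
    d <- xml2::xml_add_child(ed, "data", key = "d_smi")
    xml2::xml_text(d) <- sprintf("%.17g", forest$edges$scaled_mi[i])
  }
  xml2::write_xml(doc, path)
}

read_forest_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  g <- xml2::xml_find_first(doc, ".//g:graph", ns)
  pjson <- xml2::xml_text(
    xml2::xml_find_first(g, "./g:data[@key='d_params']", ns)
  )
  params <- jsonlite::fromJSON(pjson, simplifyVector = FALSE)
  nodes_xml <- xml2::xml_find_all(g, "./g:node", ns)
  get_data <- function(node, key) {
    xml2::xml_text(xml2::xml_find_first(
      node, sprintf("./g:data[@key='%s']", key), ns
    ))
  }
  nodes <- tibble(
    id = xml2::xml_attr(nodes_xml, "id"),
    type = vapply(nodes_xml, get_data, character(1), key = "d_type"),
    layer = as.integer(vapply(nodes_xml, get_data, character(1),
                              key = "d_layer")),
    cardinality = as.integer(vapply(nodes_xml, get_data, character(1),
                                    key = "d_card")),
    window = as.integer(vapply(nodes_xml, get_data, character(1),
                               key = "d_window"))
  )
  edges_xml <- xml2::xml_find_all(g, "./g:edge", ns)
  edges <- tibble(
    parent = xml2::xml_attr(edges_xml, "source"),
    child = xml2::xml_attr(edges_xml, "target"),
    scaled_mi = as.numeric(vapply(edges_xml, get_data, character(1),
                                  key = "d_smi"))
  )
  params$nodes <- as.list(nodes)
  params$edges <- as.list(edges)
  payload_to_forest(params)
}

write_forest_dot <- function(forest, path) {
  lines <- c("digraph fhlcm {", "  rankdir=BT;")
  for (i in seq_len(nrow(forest$nodes))) {
    shape <- if (forest$nodes$type[i] == "latent") "ellipse" else "box"
    lines <- c(lines, sprintf(
      "  \"%s\" [shape=%s, label=\"%s\\nlayer %d\"];",
      forest$nodes$id[i], shape, forest$nodes$id[i], forest$nodes$layer[i]
    ))
  }
  for (i in seq_len(nrow(forest$edges))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\";", forest$edges$parent[i], forest$edges$child[i]
    ))
  }
  writeLines(c(lines, "}"), path)
}

#' Read a forest from GraphML or JSON
#'
#' @param path file written by [write_forest()].
#' @param dialect `"json"` or `"graphml"`; defaults to the file extension.
#' @return An `fhlc_forest`.
#' @export
read_forest <- function(path, dialect = c("auto", "json", "graphml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      json = "json", graphml = "graphml",
      abort(sprintf("cannot infer dialect from extension '%s'", ext))
    )
  }
  f <- switch(dialect,
    json = read_forest_json(path),
    graphml = read_forest_graphml(path)
  )
  validate_forest(f)
  f
}

#' Write the imputed latent-variable matrix as TSV
#'
#' One column per latent variable (named by its `H<layer>_<i>` id), one row
#' per individual.
#'
#' @param forest an `fhlc_forest` with imputed data.
#' @param path output path.
#' @export
write_imputed <- function(forest, path) {
  stopifnot(inherits(forest, "fhlc_forest"))
  lat <- forest$nodes$id[forest$nodes$type == "latent"]
  if (!setequal(colnames(forest$imputed), lat)) {
    abort("imputed columns do not match the forest's latent variables")
  }
  m <- forest$imputed
  if (ncol(m) == 0L) {
    writeLines("", path)
    return(invisible(path))
  }
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an imputed latent-variable matrix written by [write_imputed()]
#'
#' @param path TSV path.
#' @return Integer matrix with latent ids as column names.
#' @export
read_imputed <- function(path) {
  first <- readLines(path, n = 1L)
  if (!nzchar(first)) return(matrix(integer(0), 0, 0))
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  m
}
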