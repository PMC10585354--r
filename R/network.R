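#' Declare a cell differentiation network
#'
#' A differentiation network is a directed graph over cell lineages. Each
#' node may carry a duplication and a death reaction; each edge `i -> j` is a
#' differentiation reaction `x_i -> 2 x_j` with rate `lambda_ij > 0`. Nodes
#' are annotated with an observability flag (whether the assay measures that
#' lineage), a branch label (`"myeloid"`, `"lymphoid"` or `"none"`) and an
#' optional ancestor, both of which drive the identifiability constraints for
#' unobserved compartments (see [build_constraint_map()]).
#'
#' Node order is fixed at construction and defines the coordinates of the
#' state vector everywhere else in the package.
#'
#' @param nodes character vector of lineage names (defines state order).
#' @param edges two-column matrix or data.frame of directed edges
#'   (source, target), or a list of length-2 character vectors.
#' @param observed logical vector (recycled) flagging measured lineages.
#' @param branch character vector (recycled) with values
#'   `"myeloid"`, `"lymphoid"` or `"none"`.
#' @param ancestor character vector (recycled) naming each node's parent
#'   lineage, or `NA` for the root.
#' @param dup,death logical vectors (recycled): does the node carry a
#'   duplication / death reaction?
#' @return An object of class `diffnet`.
#' @examples
#' net <- differentiation_network(
#'   nodes = c("A", "B"),
#'   edges = rbind(c("A", "B"))
#' )
#' net
#' @export
differentiation_network <- function(nodes, edges = NULL, observed = TRUE,
                                    branch = "none", ancestor = NA_character_,
                                    dup = TRUE, death = TRUE) {
  stopifnot(is.character(nodes), length(nodes) >= 1L)
  if (anyDuplicated(nodes)) stop("duplicated node names: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  n <- length(nodes)
  edges <- normalize_edges(edges)
  net <- structure(list(
    nodes    = nodes,
    observed = setNames(rep_len(as.logical(observed), n), nodes),
    branch   = setNames(rep_len(as.character(branch), n), nodes),
    ancestor = setNames(rep_len(as.character(ancestor), n), nodes),
    dup      = setNames(rep_len(as.logical(dup), n), nodes),
    death    = setNames(rep_len(as.logical(death), n), nodes),
    edges    = edges
  ), class = "diffnet")
  validate_network(net)
}

normalize_edges <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L)) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) c(e[[1]], e[[2]])))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns (from, to)")
  storage.mode(edges) <- "character"
  dimnames(edges) <- list(NULL, c("from", "to"))
  edges
}

validate_network <- function(net) {
  nodes <- net$nodes
  e <- net$edges
  bad <- setdiff(c(e[, "from"], e[, "to"]), nodes)
  if (length(bad)) {
    stop("topology error: edge endpoint(s) not declared as nodes: ",
         paste(unique(bad), collapse = ", "))
  }
  if (nrow(e) && any(e[, "from"] == e[, "to"])) {
    stop("topology error: self-loop edges are not allowed")
  }
  if (nrow(e) && anyDuplicated(paste(e[, "from"], e[, "to"]))) {
    stop("topology error: duplicated edges")
  }
  badb <- setdiff(net$branch, c("myeloid", "lymphoid", "none"))
  if (length(badb)) stop("branch labels must be myeloid/lymphoid/none, got: ",
                         paste(badb, collapse = ", "))
  banc <- setdiff(net$ancestor[!is.na(net$ancestor)], nodes)
  if (length(banc)) stop("ancestor(s) not declared as nodes: ",
                         paste(banc, collapse = ", "))
  net
}

#' @export
print.diffnet <- function(x, ...) {
  cat("Cell differentiation network:", length(x$nodes), "lineages,",
      nrow(x$edges), "differentiation edges\n")
  obs <- ifelse(x$observed, "", " (unobserved)")
  cat("  nodes:", paste0(x$nodes, obs, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    cat("  edges:", paste(x$edges[, 1], "->", x$edges[, 2], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Offspring set of a lineage
#'
#' Lineages reachable from `node` by a single differentiation step.
#'
#' @param net a `diffnet`.
#' @param node lineage name.
#' @return Character vector of offspring lineage names (edge declaration order).
#' @export
offspring <- function(net, node) {
  stopifnot(inherits(net, "diffnet"), node %in% net$nodes)
  net$edges[net$edges[, "from"] == node, "to"]
}

#' Read a network configuration file
#'
#' Reads a YAML (or JSON) network declaration of the form
#' ```
#' nodes:
#'   - {name: HSC, observed: false, branch: none, dup: true, death: true}
#'   - ...
#' edges:
#'   - [HSC, MPP]
#' ```
#' Missing per-node fields default to `observed: true`, `branch: none`,
#' `ancestor: null`, `dup: true`, `death: true`. The optional argument
#' `observed_override` re-flags observability per dataset: a lineage measured
#' in one study may be missing in another without editing the config.
#'
#' @param path file path to a `.yaml`/`.yml` or `.json` network config.
#' @param observed_override optional named logical vector, e.g.
#'   `c(NK = FALSE)`, applied on top of the file's `observed` flags.
#' @return A `diffnet`.
#' @export
read_network <- function(path, observed_override = NULL) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$nodes)) stop("network config has no 'nodes' section: ", path)
  grab <- function(nd, field, default) {
    v <- nd[[field]]
    if (is.null(v)) default else v
  }
  nodes    <- vapply(cfg$nodes, function(nd) as.character(nd$name), "")
  observed <- vapply(cfg$nodes, grab, TRUE, field = "observed", default = TRUE)
  branch   <- vapply(cfg$nodes, function(nd) as.character(grab(nd, "branch", "none")), "")
  ancestor <- vapply(cfg$nodes, function(nd) {
    a <- nd$ancestor
    if (is.null(a)) NA_character_ else as.character(a)
  }, "")
  dup   <- vapply(cfg$nodes, grab, TRUE, field = "dup", default = TRUE)
  death <- vapply(cfg$nodes, grab, TRUE, field = "death", default = TRUE)
  edges <- if (length(cfg$edges)) {
    do.call(rbind, lapply(cfg$edges, function(e) c(as.character(e[[1]]),
                                                   as.character(e[[2]]))))
  } else NULL
  net <- differentiation_network(nodes, edges, observed, branch, ancestor,
                                 dup, death)
  if (!is.null(observed_override)) {
    bad <- setdiff(names(observed_override), net$nodes)
    if (length(bad)) stop("observed_override names unknown lineages: ",
                          paste(bad, collapse = ", "))
    net$observed[names(observed_override)] <- as.logical(observed_override)
  }
  net
}

#' Bundled network topologies
#'
#' Returns the path of (or loads) one of the network configurations shipped
#' with the package. Four are the candidate haematopoietic models compared on
#' in vivo studies: `"single-branch"` (one common progenitor chain),
#' `"dichotomic"` (the classical myeloid/lymphoid split), `"myeloid-based"`
#' (myeloid progenitors also produce NK cells) and `"nk-branch"` (NK cells
#' develop through a dedicated progenitor). Four are in-silico validation
#' nets: `"insilico-small"` (HSC -> P1 -> P2 -> {T, B, G}),
#' `"insilico-branching"`, `"insilico-myeloid"` and `"insilico-deep"` (the
#' dichotomic tree with HSC and every progenitor unobserved).
#'
#' @param name one of the scenario names above; `shipped_networks()` lists them.
#' @param load if `TRUE` (default) return the parsed `diffnet`, else the path.
#' @return A `diffnet` or a file path.
#' @export
shipped_network <- function(name, load = TRUE) {
  path <- system.file("extdata", "networks", paste0(name, ".yaml"),
                      package = "clonenet")
  if (identical(path, "")) {
    stop("unknown network scenario '", name, "'; available: ",
         paste(shipped_networks(), collapse = ", "))
  }
  if (load) read_network(path) else path
}

#' @rdname shipped_network
#' @export
shipped_networks <- function() {
  files <- list.files(system.file("extdata", "networks", package = "clonenet"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' Export a network (with optional fitted weights) to GraphML or DOT
#'
#' Writes a machine-readable graph with the edge attribute
#' `transition_probability` when rates are supplied.
#'
#' @param net a `diffnet`.
#' @param path output file; extension `.graphml` or `.dot`/`.gv` picks the
#'   format unless `format` is given.
#' @param theta optional full rate vector (see [rate_parameters()]); when
#'   present, [transition_probabilities()] annotates the edges.
#' @param format `"graphml"` or `"dot"`; inferred from `path` by default.
#' @return Invisibly, the igraph object written.
#' @export
write_network <- function(net, path, theta = NULL, format = NULL) {
  stopifnot(inherits(net, "diffnet"))
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "dot"
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes,
                          observed = ifelse(net$observed, "true", "false"),
                          branch = unname(net$branch),
                          stringsAsFactors = FALSE))
  if (!is.null(theta)) {
    tp <- transition_probabilities(net, theta)
    key <- paste(tp$from, tp$to)
    ekey <- paste(net$edges[, "from"], net$edges[, "to"])
    igraph::E(g)$transition_probability <- tp$probability[match(ekey, key)]
  }
  igraph::write_graph(g, path, format = format)
  invisible(g)
}
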