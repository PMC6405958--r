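# Compartment-level spatial organization mapping: each compartment of a
# diffusion-coupled compartment graph is assigned the organization
# generated by the species present in its graph neighborhood.

#' Build a compartment graph
#'
#' Space is modelled as a set of well-stirred compartments interconnected
#' by diffusion links.  Each compartment holds a set of present species;
#' with `kinetochore_exclusive = TRUE` a compartment may contain at most
#' one of `KinU`/`KinA` (one kinetochore per compartment).
#'
#' @param compartments Named list (or list) of character vectors: species
#'   present in each compartment.
#' @param edges Two-column matrix or data frame of undirected links between
#'   compartment indices (or names).
#' @param net Optional `reaction_network`; when given, compartment species
#'   are checked against it.
#' @param kinetochore_exclusive Enforce the one-kinetochore constraint
#'   (default `TRUE` when both `KinU` and `KinA` are network species).
#' @return A `compartment_graph`.
#' @export
compartment_graph <- function(compartments, edges, net = NULL,
                              kinetochore_exclusive = NULL) {
  nc <- length(compartments)
  nm <- names(compartments) %||% as.character(seq_len(nc))
  edges <- as.matrix(edges)
  if (is.character(edges)) edges <- matrix(match(edges, nm), ncol = 2)
  storage.mode(edges) <- "integer"
  if (nrow(edges) && (anyNA(edges) || any(edges < 1) || any(edges > nc)))
    abort("edge endpoints must reference compartments")
  if (!is.null(net)) {
    bad <- setdiff(unique(unlist(compartments)), net$species)
    if (length(bad))
      abort(paste0("compartment species not in network: ",
                   paste(bad, collapse = ", ")))
  }
  kin <- c("KinU", "KinA")
  if (is.null(kinetochore_exclusive))
    kinetochore_exclusive <- !is.null(net) && all(kin %in% net$species)
  if (kinetochore_exclusive) {
    both <- map_lgl(compartments, function(s) all(kin %in% s))
    if (any(both))
      abort(paste0("compartment ", nm[which(both)[1]],
                   " holds both an attached and an unattached kinetochore"))
  }
  structure(list(compartments = setNames(map(compartments, as.character), nm),
                 edges = edges),
            class = "compartment_graph")
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat(sprintf("<compartment_graph> %d compartments, %d edges\n",
              length(x$compartments), nrow(x$edges)))
  for (i in seq_along(x$compartments))
    cat(sprintf("  %s: {%s}\n", names(x$compartments)[i],
                paste(x$compartments[[i]], collapse = ", ")))
  invisible(x)
}

graph_distances <- function(graph) {
  nc <- length(graph$compartments)
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nc - igraph::vcount(g)))
  igraph::distances(g)
}

#' Species in a compartment's neighborhood
#'
#' Union of the species over all compartments within graph (hop) distance
#' `radius` of the given compartment, including the compartment itself.
#'
#' @param graph A `compartment_graph`.
#' @param compartment Compartment index or name.
#' @param radius Non-negative integer hop radius.
#' @return Character vector of species.
#' @export
neighborhood_species <- function(graph, compartment, radius = 1) {
  stopifnot(inherits(graph, "compartment_graph"), radius >= 0)
  nm <- names(graph$compartments)
  i <- if (is.character(compartment)) match(compartment, nm)
       else as.integer(compartment)
  if (is.na(i) || i < 1 || i > length(nm))
    abort(paste0("unknown compartment: ", compartment))
  d <- graph_distances(graph)[i, ]
  sort(unique(unlist(graph$compartments[d <= radius])))
}

#' Map compartments to their spatial organizations
#'
#' The spatial organization of a compartment is the organization generated
#' (closure followed by self-maintaining reduction) by the species found in
#' its radius-`radius` neighborhood, including the compartment itself.
#' Compartments with identical contents can map to different organizations
#' when their neighborhoods differ.
#'
#' @param graph A `compartment_graph`.
#' @param net The `reaction_network` used for generation (for checkpoint
#'   models typically the short-timescale variant).
#' @param radius Hop radius (default 1).
#' @return A tibble with `compartment`, `own_species`, `neighborhood`
#'   (list columns) and `organization` (list column of member vectors),
#'   plus display strings `neighborhood_species` and `organization_species`.
#' @examples
#' fx <- sac_compartment_fixture()
#' spatial_organization_map(fx, sac_model("model3b"))
#' @export
spatial_organization_map <- function(graph, net, radius = 1) {
  stopifnot(inherits(graph, "compartment_graph"),
            inherits(net, "reaction_network"))
  bad <- setdiff(unique(unlist(graph$compartments)), net$species)
  if (length(bad))
    abort(paste0("compartment species not in network: ",
                 paste(bad, collapse = ", ")))
  nm <- names(graph$compartments)
  nbhd <- map(nm, function(cmp) neighborhood_species(graph, cmp, radius))
  orgs <- map(nbhd, function(s) generate_organization(net, s)$members)
  tibble(
    compartment = nm,
    own_species = unname(graph$compartments),
    neighborhood = nbhd,
    organization = orgs,
    neighborhood_species = map_chr(nbhd, paste, collapse = ", "),
    organization_species = map_chr(orgs, paste, collapse = ", ")
  )
}
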