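#' Regulation-graph export
#'
#' Builds a directed graph view of a network: operator and gene-product
#' nodes, production edges (operator → product, one per declared
#' output) and regulation edges (regulator → operator, with a `sign`
#' attribute, `activation` or `repression`, derived from the operator
#' parameters). Receiver inputs appear as supplement nodes. With
#' `operators_only = TRUE` the product nodes are contracted away and
#' operators are connected directly by edges labelled with the mediating
#' regulator — the compact network view.
#'
#' Node order follows declaration order, so the export is deterministic.
#'
#' @param net A valid `genetic_network`.
#' @param operators_only Contract product nodes?
#' @return An `igraph` graph with node attributes `type`
#'   (`operator`/`regulator`/`reporter`/`supplement`), `kind` and
#'   `logic`, and edge attributes `type` (`production`/`regulation`),
#'   `sign` and `regulator`.
#' @export
to_graph <- function(net, operators_only = FALSE) {
  v <- validate_network(net)
  if (length(v))
    stop("invalid network:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  signs <- lapply(net$operators, input_signs)
  op_logic <- vapply(net$operators, function(op)
    if (op$kind %in% c("hill1", "hill2")) classify_logic(op) else NA_character_,
    character(1))
  on <- vapply(net$operators, `[[`, character(1), "name")
  if (operators_only) {
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, length(on), name = on, type = "operator",
                              kind = vapply(net$operators, `[[`,
                                            character(1), "kind"),
                              logic = op_logic)
    for (li in seq_along(net$operators)) {
      op <- net$operators[[li]]
      if (!op$kind %in% c("hill1", "hill2")) next
      for (j in seq_along(op$inputs)) {
        reg <- op$inputs[[j]]
        src <- which(vapply(net$operators, function(o)
          reg %in% o$outputs, logical(1)))
        for (s in src)
          g <- igraph::add_edges(g, c(on[s], op$name), type = "regulation",
                                 sign = signs[[li]][j], regulator = reg)
      }
    }
    return(g)
  }
  pn <- product_names(net)
  ptype <- vapply(net$products, `[[`, character(1), "kind")
  sups <- unique(unlist(lapply(net$operators, function(op)
    if (op$kind == "receiver") op$inputs else character())))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(on), name = on, type = "operator",
                            kind = vapply(net$operators, `[[`, character(1),
                                          "kind"),
                            logic = op_logic)
  g <- igraph::add_vertices(g, length(pn), name = pn, type = ptype,
                            kind = ptype, logic = NA_character_)
  if (length(sups))
    g <- igraph::add_vertices(g, length(sups), name = sups,
                              type = "supplement", kind = "supplement",
                              logic = NA_character_)
  for (li in seq_along(net$operators)) {
    op <- net$operators[[li]]
    for (o in op$outputs)
      g <- igraph::add_edges(g, c(op$name, o), type = "production",
                             sign = NA_character_, regulator = NA_character_)
    for (j in seq_along(op$inputs))
      g <- igraph::add_edges(g, c(op$inputs[[j]], op$name),
                             type = "regulation", sign = signs[[li]][j],
                             regulator = op$inputs[[j]])
  }
  g
}

# per-input regulation sign from the operator parameters: input j
# stimulates when its regulated rate exceeds the basal rate alpha0.
input_signs <- function(op) {
  p <- op$params
  switch(op$kind,
    source = character(),
    hill1 = ,
    receiver = sign_of(p$alpha1, p$alpha0, op$name, op$inputs[[1]]),
    hill2 = c(sign_of(p$alpha1, p$alpha0, op$name, op$inputs[[1]]),
              sign_of(p$alpha2, p$alpha0, op$name, op$inputs[[2]])))
}

sign_of <- function(a_reg, a0, opname, input) {
  if (a_reg > a0) "activation"
  else if (a_reg < a0) "repression"
  else {
    warning(sprintf(
      "operator '%s': regulated and basal rates tie for input '%s'; defaulting to activation",
      opname, input), call. = FALSE)
    "activation"
  }
}

#' Write a regulation graph to GraphML or DOT
#'
#' @param g An igraph graph from [to_graph()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(drop_na_attrs(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_dot <- function(g, path) {
  igraph::write_graph(drop_na_attrs(g), path, format = "dot")
  invisible(path)
}

# igraph serializers reject NA character attributes; blank them out
drop_na_attrs <- function(g) {
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.character(v)) igraph::vertex_attr(g, at) <-
        ifelse(is.na(v), "", v)
  }
  for (at in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, at)
    if (is.character(v)) igraph::edge_attr(g, at) <- ifelse(is.na(v), "", v)
  }
  g
}
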