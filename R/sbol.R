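#' SBOL3-style design document export
#'
#' Renders a network as a hierarchical SBOL3-style design document: the
#' network maps to a top-level component; each operator together with its
#' outputs maps to a transcriptional-unit component of type DNA with role
#' engineered region, whose part subcomponents (promoter/operator region,
#' RBS, one CDS per output, terminator — placeholders when no sequences
#' are provided) are kept in order by precedes constraints; each gene
#' product has a genetic-production interaction from its unit, and each
#' regulator (or receiver supplement) an inhibition or stimulation
#' interaction on its target operator, the direction chosen from the
#' operator parameters (regulated rate below the basal rate ⇒
#' inhibition; an exact tie warns and defaults to stimulation). One model
#' reference (source, language, framework) is attached.
#'
#' The document is a plain R list; [write_sbol()] serializes it as JSON
#' with the same structure an RDF serializer would encode.
#'
#' @param net A valid `genetic_network`.
#' @param include_sequences Attach product/part sequences when present?
#' @return A list of class `sbol_design`.
#' @export
to_sbol <- function(net, include_sequences = TRUE) {
  v <- validate_network(net)
  if (length(v))
    stop("invalid network:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  species <- lapply(net$products, function(p) {
    comp <- list(id = p$name, type = "Protein",
                 role = if (p$kind == "reporter") "Reporter" else "Regulator")
    if (include_sequences && !is.null(p$sequence))
      comp$sequence <- p$sequence
    comp
  })
  sups <- unique(unlist(lapply(net$operators, function(op)
    if (op$kind == "receiver") op$inputs else character())))
  species <- c(species, lapply(sups, function(s)
    list(id = s, type = "SimpleChemical", role = "Supplement")))

  units <- list()
  interactions <- list()
  for (op in net$operators) {
    uid <- paste0(op$name, "_unit")
    parts <- list(list(id = paste0(op$name, "_promoter"),
                       role = "Promoter"),
                  list(id = paste0(op$name, "_rbs"),
                       role = "RBS"))
    for (o in op$outputs) {
      cds <- list(id = paste0(uid, "_", o, "_cds"), role = "CDS",
                  encodes = o)
      prod <- net$products[[match(o, product_names(net))]]
      if (include_sequences && !is.null(prod$sequence))
        cds$sequence <- prod$sequence
      parts <- c(parts, list(cds))
    }
    parts <- c(parts, list(list(id = paste0(op$name, "_terminator"),
                                role = "Terminator")))
    ids <- vapply(parts, `[[`, character(1), "id")
    constraints <- lapply(seq_len(length(ids) - 1L), function(i)
      list(restriction = "precedes", subject = ids[i], object = ids[i + 1L]))
    units[[length(units) + 1L]] <- list(
      id = uid, type = "DNA", role = "EngineeredRegion",
      operator = op$name, operator_kind = op$kind,
      subcomponents = parts, constraints = constraints)
    for (o in op$outputs)
      interactions[[length(interactions) + 1L]] <- list(
        type = "GeneticProduction",
        participants = list(template = uid, product = o))
    signs <- input_signs(op)
    for (j in seq_along(op$inputs))
      interactions[[length(interactions) + 1L]] <- list(
        type = if (signs[j] == "repression") "Inhibition" else "Stimulation",
        participants = list(regulator = op$inputs[[j]], target = uid))
  }
  structure(list(
    format = "sbol3-style-json", format_version = DESIGN_FORMAT_VERSION,
    network = list(id = net$name, type = "FunctionalEntity",
                   members = c(vapply(units, `[[`, character(1), "id"),
                               vapply(species, `[[`, character(1), "id"))),
    components = c(list(), units, species),
    interactions = interactions,
    model = list(source = paste0(net$name, ".json"),
                 language = "design-json",
                 framework = "ODE/SSA kinetic")),
    class = "sbol_design")
}

#' @export
print.sbol_design <- function(x, ...) {
  nu <- sum(vapply(x$components, function(c)
    identical(c$type, "DNA"), logical(1)))
  cat(sprintf(
    "<sbol_design> %s: %d components (%d transcriptional units), %d interactions\n",
    x$network$id, length(x$components), nu, length(x$interactions)))
  invisible(x)
}

#' @rdname to_sbol
#' @param doc An `sbol_design`.
#' @param path Output file.
#' @export
write_sbol <- function(doc, path) {
  stopifnot(inherits(doc, "sbol_design"))
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Structural validation of an SBOL-style design document
#'
#' Checks the document invariants: every transcriptional unit's
#' constraints form a total order over its subcomponents, every
#' regulator species participates in at least one regulatory
#' (inhibition/stimulation) interaction, every interaction participant
#' resolves to a declared component, and exactly one model reference with
#' source, language and framework is present.
#'
#' @param doc An `sbol_design` (or equivalent list).
#' @return Character vector of violations; empty when valid.
#' @export
validate_sbol <- function(doc) {
  out <- character()
  ids <- vapply(doc$components, `[[`, character(1), "id")
  for (comp in doc$components) {
    if (!identical(comp$type, "DNA")) next
    sub <- vapply(comp$subcomponents, `[[`, character(1), "id")
    cons <- comp$constraints
    nxt <- vapply(cons, `[[`, character(1), "subject")
    obj <- vapply(cons, `[[`, character(1), "object")
    chain <- length(cons) == length(sub) - 1L &&
      all(nxt %in% sub) && all(obj %in% sub) &&
      !anyDuplicated(nxt) && !anyDuplicated(obj) &&
      length(setdiff(sub, obj)) == 1L && length(setdiff(sub, nxt)) == 1L
    if (!chain)
      out <- c(out, sprintf(
        "unit '%s': constraints do not form a total part order", comp$id))
  }
  regs <- ids[vapply(doc$components, function(c)
    identical(c$role, "Regulator"), logical(1))]
  regulated <- unlist(lapply(doc$interactions, function(i)
    if (i$type %in% c("Inhibition", "Stimulation"))
      i$participants$regulator))
  for (r in setdiff(regs, regulated))
    out <- c(out, sprintf(
      "regulator '%s' has no regulatory interaction", r))
  for (i in doc$interactions) {
    refs <- unlist(i$participants)
    miss <- setdiff(refs, ids)
    if (length(miss))
      out <- c(out, sprintf("interaction %s references unknown component(s): %s",
                            i$type, paste(miss, collapse = ", ")))
  }
  m <- doc$model
  if (is.null(m) || !all(c("source", "language", "framework") %in% names(m)))
    out <- c(out, "missing or incomplete model reference")
  out
}
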