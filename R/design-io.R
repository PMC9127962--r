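DESIGN_FORMAT_VERSION <- "1.0"

#' Save and load design documents
#'
#' A design document is a JSON rendering of a [genetic_network()]: a
#' top-level object with `format_version`, `name`, `products` and
#' `operators`, field names matching the constructors. `load_design()`
#' of a saved file reproduces the network exactly, including all
#' parameters.
#'
#' @param net A `genetic_network`.
#' @param path File path (conventionally `*.json`).
#' @return `save_design()` the path, invisibly; `load_design()` the
#'   reconstructed `genetic_network`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' save_design(network_oscillator(), f)
#' identical(load_design(f), network_oscillator())
#' @export
save_design <- function(net, path) {
  stopifnot(inherits(net, "genetic_network"))
  doc <- list(
    format_version = DESIGN_FORMAT_VERSION,
    name = net$name,
    products = lapply(net$products, function(p)
      Filter(Negate(is.null),
             p[c("name", "kind", "degradation_rate", "init_concentration",
                 "signal_id", "sequence")])),
    operators = lapply(net$operators, function(op)
      list(name = op$name, kind = op$kind,
           inputs = as.list(op$inputs), outputs = as.list(op$outputs),
           params = unclass(op$params))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_design
#' @export
load_design <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("malformed design JSON at ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$format_version) ||
      doc$format_version != DESIGN_FORMAT_VERSION)
    stop(sprintf("unsupported design format_version '%s' (expected '%s')",
                 doc$format_version %||% "<missing>",
                 DESIGN_FORMAT_VERSION), call. = FALSE)
  products <- lapply(doc$products, function(p)
    gene_product(name = p$name,
                 degradation_rate = as.numeric(p$degradation_rate),
                 init_concentration = as.numeric(p$init_concentration),
                 kind = p$kind,
                 signal_id = p$signal_id, sequence = p$sequence))
  operators <- lapply(doc$operators, function(o) {
    inputs <- unlist(o$inputs)
    outputs <- unlist(o$outputs)
    pr <- lapply(o$params, as.numeric)
    switch(o$kind,
      source = op_source(o$name, outputs, alpha = pr$alpha),
      hill1 = op_hill1(o$name, inputs, outputs, pr$alpha0, pr$alpha1,
                       pr$K, pr$n),
      receiver = op_receiver(o$name, inputs, outputs, pr$alpha0,
                             pr$alpha1, pr$K, pr$n),
      hill2 = op_hill2(o$name, inputs, outputs, pr$alpha0, pr$alpha1,
                       pr$alpha2, pr$alpha3, pr$K1, pr$K2, pr$n1, pr$n2),
      stop("unknown operator kind '", o$kind, "' in ", path,
           call. = FALSE))
  })
  genetic_network(doc$name, products, operators)
}
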