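#' Gene products: regulators and reporters
#'
#' A gene product is an expressed molecular species \eqn{p_i} with a
#' first-order degradation rate \eqn{\gamma_i} (per hour). Regulators feed
#' operator inputs; reporters are measurable outputs linked to a signal
#' (e.g. a fluorescence channel).
#'
#' @param name Identifier, unique within a network.
#' @param degradation_rate Degradation rate \eqn{\gamma \ge 0} (1/h).
#' @param init_concentration Initial concentration (molecules per cell
#'   equivalents), \eqn{\ge 0}.
#' @param kind `"regulator"` or `"reporter"`.
#' @param signal_id Optional measured-signal identifier (reporters only).
#' @param sequence Optional nucleotide sequence, used only by exporters.
#' @return An object of class `gene_product`.
#' @examples
#' lacI <- regulator("LacI", degradation_rate = 1)
#' cfp  <- reporter("CFP", degradation_rate = 1, signal_id = "CFP")
#' @export
gene_product <- function(name, degradation_rate = 1, init_concentration = 0,
                         kind = c("regulator", "reporter"), signal_id = NULL,
                         sequence = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(degradation_rate) || length(degradation_rate) != 1L ||
      is.na(degradation_rate) || degradation_rate < 0)
    stop("degradation_rate must be a single number >= 0", call. = FALSE)
  if (!is.numeric(init_concentration) || length(init_concentration) != 1L ||
      is.na(init_concentration) || init_concentration < 0)
    stop("init_concentration must be a single number >= 0", call. = FALSE)
  if (!is.null(signal_id) && kind != "reporter")
    stop("signal_id is only meaningful for reporters", call. = FALSE)
  structure(
    list(name = name, degradation_rate = degradation_rate,
         init_concentration = init_concentration, kind = kind,
         signal_id = signal_id, sequence = sequence),
    class = "gene_product"
  )
}

#' @rdname gene_product
#' @param ... Passed on to [gene_product()].
#' @export
regulator <- function(name, ...) gene_product(name, ..., kind = "regulator")

#' @rdname gene_product
#' @export
reporter <- function(name, ..., signal_id = name)
  gene_product(name, ..., kind = "reporter", signal_id = signal_id)

#' @export
print.gene_product <- function(x, ...) {
  cat(sprintf("<%s> %s  gamma=%g/h  p(0)=%g%s\n", x$kind, x$name,
              x$degradation_rate, x$init_concentration,
              if (!is.null(x$signal_id)) paste0("  signal=", x$signal_id) else ""))
  invisible(x)
}

is_gene_product <- function(x) inherits(x, "gene_product")
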