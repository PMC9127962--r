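#' Single-call operator parametrization from stored data
#'
#' Pulls the relevant measurements from a datastore by selector query,
#' assembles the dose-response dataset (dose annotations come from the
#' stored sample supplement metadata; replicate assays are combined as
#' separate blocks so every row contributes residuals), reconstructs the
#' growth profile from the biomass channel when none is given, and
#' dispatches to the matching fit: [fit_source()], [fit_receiver()],
#' [fit_hill1()] or [fit_hill2()].
#'
#' @param kind Operator kind to characterize: `"source"`, `"receiver"`,
#'   `"hill1"` or `"hill2"`.
#' @param store A `datastore`.
#' @param selectors Named list of [store_query()] selectors locating the
#'   assay data; `signal` must name the measured reporter signal.
#' @param gamma Reporter degradation rate (1/h); for the cascade kinds
#'   this is the downstream reporter's rate.
#' @param gamma_regulator,gamma_regulator2 Regulator degradation rates
#'   for the `hill1` / `hill2` cascades.
#' @param receiver,receiver2 Fixed upstream receiver parameters
#'   (`hill1_params` or `operator_fit`s) for the cascade kinds.
#' @param supplements Character vector naming the supplement input
#'   axis/axes, in the order matching `receiver`/`receiver2`; defaults
#'   to the names found in the sample metadata (alphabetical).
#' @param growth Growth profile; `NULL` reconstructs it from biomass.
#' @param ... Passed to the dispatched fit (`n_restarts`, `seed`, `m`).
#' @return An [operator_fit].
#' @export
characterize <- function(kind = c("source", "receiver", "hill1", "hill2"),
                         store, selectors, gamma,
                         gamma_regulator = gamma, gamma_regulator2 = gamma,
                         receiver = NULL, receiver2 = NULL,
                         supplements = NULL, growth = NULL, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(store, "datastore"), is.list(selectors))
  if (is.null(selectors$signal))
    stop("selectors must include the reporter 'signal'", call. = FALSE)
  qsel <- selectors[setdiff(names(selectors), "signal")]
  tab <- do.call(store_query, c(list(store), qsel))
  sig <- tab[tab$signal %in% selectors$signal, , drop = FALSE]
  if (!nrow(sig))
    stop("no data matched selectors: ",
         paste(sprintf("%s=%s", names(selectors),
                       vapply(selectors, paste, "", collapse = "|")),
               collapse = ", "), call. = FALSE)

  if (kind == "source") {
    gp <- growth
    if (is.null(gp)) {
      bio <- tab[tab$signal == "biomass", , drop = FALSE]
      if (!nrow(bio))
        stop("no growth profile supplied and no biomass channel stored",
             call. = FALSE)
      b1 <- bio[bio$sample == bio$sample[1] & bio$assay == bio$assay[1], ]
      gp <- fit_growth(b1$time, b1$value, duration = max(b1$time) * 1.5)
    }
    s1 <- sig[sig$sample == sig$sample[1] & sig$assay == sig$assay[1], ]
    return(fit_source(s1[c("time", "value")], gamma = gamma, growth = gp,
                      ...))
  }

  if (is.list(receiver) && inherits(receiver, "operator_fit"))
    receiver <- receiver$params
  if (is.list(receiver2) && inherits(receiver2, "operator_fit"))
    receiver2 <- receiver2$params

  meta <- store_samples(store)
  n_axes <- if (kind == "hill2") 2L else 1L
  data <- assemble_dose_response(tab, meta, selectors$signal, supplements,
                                 n_axes)
  switch(kind,
    receiver = fit_receiver(data, gamma = gamma, growth = growth, ...),
    hill1 = fit_hill1(data, receiver = receiver,
                      gamma_regulator = gamma_regulator,
                      gamma_reporter = gamma, growth = growth, ...),
    hill2 = fit_hill2(data, receiver1 = receiver, receiver2 = receiver2,
                      gamma_regulator1 = gamma_regulator,
                      gamma_regulator2 = gamma_regulator2,
                      gamma_reporter = gamma, growth = growth, ...))
}

# Build a dose_response from a queried measurement table plus stored
# sample metadata: one block per assay (assays share a time grid), one
# condition per sample, concentrations from the supplements metadata.
assemble_dose_response <- function(tab, meta, signal, supplements, n_axes) {
  sig <- tab[tab$signal %in% signal, , drop = FALSE]
  bio <- tab[tab$signal == "biomass", , drop = FALSE]
  meta <- meta[paste(meta$assay, meta$sample) %in%
                 unique(paste(sig$assay, sig$sample)), , drop = FALSE]
  if (is.null(supplements)) {
    supplements <- sort(unique(unlist(lapply(meta$supplements, names))))
    if (length(supplements) > n_axes)
      stop("samples carry supplements ",
           paste(supplements, collapse = ", "),
           "; pass `supplements` to pick the ", n_axes, " input axis/axes",
           call. = FALSE)
  }
  if (length(supplements) != n_axes)
    stop(sprintf("expected %d supplement axis/axes, got %d", n_axes,
                 length(supplements)), call. = FALSE)
  blocks <- lapply(unique(sig$assay), function(an) {
    s <- sig[sig$assay == an, , drop = FALSE]
    ids <- unique(s$sample)
    times <- sort(unique(s$time))
    vals <- vapply(ids, function(id) {
      r <- s[s$sample == id, , drop = FALSE]
      r$value[match(times, r$time)]
    }, numeric(length(times)))
    if (anyNA(vals))
      stop("assay '", an, "': samples do not share a common time grid",
           call. = FALSE)
    conc <- t(vapply(ids, function(id) {
      sup <- meta$supplements[[which(meta$assay == an &
                                       meta$sample == id)[1]]]
      vapply(supplements, function(nm)
        if (nm %in% names(sup)) unname(sup[[nm]]) else 0, numeric(1))
    }, numeric(n_axes)))
    bio_series <- NULL
    b <- bio[bio$assay == an & bio$sample == ids[1], , drop = FALSE]
    if (nrow(b)) bio_series <- b$value[match(times, b$time)]
    list(conc = matrix(conc, ncol = n_axes), times = times,
         values = matrix(vals, ncol = length(ids)), biomass = bio_series)
  })
  ds <- structure(list(blocks = blocks), class = "dose_response")
  check_design(ds)
  ds
}
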