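#' Local measurement datastore
#'
#' A desk-scale, file-based store for assays and their kinetic
#' measurements, mirroring the study → assay → sample → measurement data
#' model (and the selector vocabulary) of web-based measurement
#' databases, so characterization can pull data by query instead of
#' being handed files. The backing format is a directory containing
#' `manifest.json` (studies, assays, sample metadata, signal registry)
#' plus one measurement CSV per assay — plain text, diffable, and
#' lossless for the measured values.
#'
#' Sample metadata records the *vector* (the genetic-network design id),
#' strain, media, and the supplement concentrations of each sample;
#' signals are registered with id, name and units.
#'
#' @param path Store directory.
#' @param name Store display name.
#' @return A `datastore` handle.
#' @export
store_create <- function(path, name = "local-store") {
  if (dir.exists(path) && file.exists(file.path(path, "manifest.json")))
    stop("a store already exists at ", path, call. = FALSE)
  dir.create(file.path(path, "measurements"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list(format_version = "1.0", name = name,
                   signals = list(), studies = list())
  write_manifest(path, manifest)
  structure(list(path = path), class = "datastore")
}

#' @rdname store_create
#' @export
store_open <- function(path) {
  if (!file.exists(file.path(path, "manifest.json")))
    stop("no store manifest found at ", path, call. = FALSE)
  structure(list(path = path), class = "datastore")
}

#' @export
print.datastore <- function(x, ...) {
  m <- read_manifest(x$path)
  nass <- sum(vapply(m$studies, function(s) length(s$assays), integer(1)))
  cat(sprintf("<datastore> %s at %s: %d study(ies), %d assay(s), %d signal(s)\n",
              m$name, x$path, length(m$studies), nass, length(m$signals)))
  invisible(x)
}

write_manifest <- function(path, manifest) {
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_manifest <- function(path) {
  jsonlite::read_json(file.path(path, "manifest.json"))
}

#' Upload an assay and its measurements
#'
#' Persists a measurement table and the assay's sample metadata. The
#' vector id of each sample is its network's name and the supplement
#' concentrations are taken from the sample conditions; reporter signals
#' are registered on first sight. Re-uploading an assay with the same
#' name and study replaces it (with a warning), leaving the row count
#' unchanged.
#'
#' @param store A `datastore`.
#' @param assay The [assay()] that produced the table.
#' @param table Its measurement table; defaults to [run_assay()] output.
#' @param metadata List with optional entries `study`, `strain`, `media`
#'   and `units` (a named list signal → unit string).
#' @return The assigned identifiers, invisibly:
#'   `list(study, assay, samples)`.
#' @export
upload_assay <- function(store, assay, table = NULL,
                         metadata = list()) {
  stopifnot(inherits(store, "datastore"), inherits(assay, "assay"))
  if (is.null(table)) table <- run_assay(assay)
  check_measurements(table)
  study <- metadata$study %||% "study1"
  strain <- metadata$strain %||% "unknown"
  media <- metadata$media %||% "unknown"

  known <- unlist(lapply(assay$samples, function(s) c(
    vapply(Filter(function(p) p$kind == "reporter", s$network$products),
           function(p) p$signal_id %||% p$name, character(1)), "biomass")))
  stray <- setdiff(unique(table$signal), known)
  if (length(stray))
    stop("integrity error: signal(s) not registered by any sample network: ",
         paste(stray, collapse = ", "), call. = FALSE)
  stray_s <- setdiff(unique(table$sample), names(assay$samples))
  if (length(stray_s))
    stop("integrity error: table rows reference unknown sample(s): ",
         paste(stray_s, collapse = ", "), call. = FALSE)

  m <- read_manifest(store$path)
  for (sig in unique(table$signal)) {
    ids <- vapply(m$signals, `[[`, character(1), "id")
    if (!sig %in% ids)
      m$signals <- c(m$signals, list(list(
        id = sig, name = sig,
        units = metadata$units[[sig]] %||% "arbitrary")))
  }
  si <- which(vapply(m$studies, `[[`, character(1), "name") == study)
  if (!length(si)) {
    m$studies <- c(m$studies, list(list(name = study, assays = list())))
    si <- length(m$studies)
  }
  samples <- lapply(names(assay$samples), function(id) {
    smp <- assay$samples[[id]]
    list(id = id, vector = smp$network$name, strain = strain,
         media = media, supplements = as.list(smp$supplements))
  })
  entry <- list(name = assay$name, method = assay$method,
                file = paste0(assay$name, ".csv"), samples = samples)
  ai <- which(vapply(m$studies[[si]]$assays, `[[`, character(1), "name") ==
                assay$name)
  if (length(ai)) {
    warning(sprintf("assay '%s' already in study '%s'; replacing it",
                    assay$name, study), call. = FALSE)
    m$studies[[si]]$assays[[ai]] <- entry
  } else m$studies[[si]]$assays <- c(m$studies[[si]]$assays, list(entry))
  tab <- table[table$assay == assay$name, , drop = FALSE]
  if (!nrow(tab))
    stop("integrity error: table contains no rows for assay '",
         assay$name, "'", call. = FALSE)
  write_measurements(tab, file.path(store$path, "measurements", entry$file))
  write_manifest(store$path, m)
  invisible(list(study = study, assay = assay$name,
                 samples = names(assay$samples)))
}

#' Sample metadata held in a store
#'
#' @param store A `datastore`.
#' @return Data frame with one row per stored sample: `study`, `assay`,
#'   `sample`, `vector`, `strain`, `media`, and a list-column
#'   `supplements` of named concentration vectors.
#' @export
store_samples <- function(store) {
  m <- read_manifest(store$path)
  rows <- list()
  for (st in m$studies) for (a in st$assays) for (s in a$samples) {
    rows[[length(rows) + 1L]] <- data.frame(
      study = st$name, assay = a$name, sample = s$id, vector = s$vector,
      strain = s$strain, media = s$media, stringsAsFactors = FALSE)
    rows[[length(rows)]]$supplements <-
      list(unlist(s$supplements) %||% numeric())
  }
  if (!length(rows))
    return(data.frame(study = character(), assay = character(),
                      sample = character(), vector = character(),
                      strain = character(), media = character()))
  do.call(rbind, rows)
}

#' Query measurements from a store
#'
#' Conjunctive exact-match filtering over the stored measurements. The
#' selector vocabulary mirrors the usual measurement-database filter
#' fields: `study`, `assay`, `vector` (network design id), `signal`,
#' `media`, `strain`, `supplement` (samples whose conditions include
#' that supplement name). Empty selectors return everything. Rows are
#' sorted by (sample, signal, time).
#'
#' @param store A `datastore`.
#' @param ... Named selectors from the vocabulary above; each may be a
#'   character vector (rows matching any value are kept).
#' @return A measurement table (possibly with zero rows).
#' @export
store_query <- function(store, ...) {
  stopifnot(inherits(store, "datastore"))
  sel <- list(...)
  allowed <- c("study", "assay", "vector", "signal", "media", "strain",
               "supplement")
  bad <- setdiff(names(sel), allowed)
  if (length(bad) || (length(sel) && is.null(names(sel))))
    stop("unknown selector key(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  meta <- store_samples(store)
  empty <- data.frame(assay = character(), sample = character(),
                      signal = character(), time = numeric(),
                      value = numeric())
  if (!nrow(meta)) return(empty)
  keep <- rep(TRUE, nrow(meta))
  for (key in c("study", "assay", "vector", "media", "strain"))
    if (!is.null(sel[[key]])) keep <- keep & meta[[key]] %in% sel[[key]]
  if (!is.null(sel$supplement))
    keep <- keep & vapply(meta$supplements, function(s)
      any(sel$supplement %in% names(s)), logical(1))
  meta <- meta[keep, , drop = FALSE]
  if (!nrow(meta)) return(empty)
  parts <- lapply(unique(meta$assay), function(an) {
    f <- file.path(store$path, "measurements", paste0(an, ".csv"))
    tab <- read_measurements(f)
    ids <- meta$sample[meta$assay == an]
    tab[tab$sample %in% ids, , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  if (!is.null(sel$signal)) out <- out[out$signal %in% sel$signal, ,
                                       drop = FALSE]
  out <- out[order(out$sample, out$signal, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
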