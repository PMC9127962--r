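# shared helpers: turn a dose-response assay + its measurement table into
# the dataset object the fit functions consume (without going through a
# datastore), and small convenience wrappers used across test files.

dr_from_assay <- function(a, tab, signal, n_axes = 1L) {
  ids <- names(a$samples)
  times <- sort(unique(tab$time[tab$signal == signal]))
  vals <- vapply(ids, function(id) {
    r <- tab[tab$sample == id & tab$signal == signal, ]
    r$value[match(times, r$time)]
  }, numeric(length(times)))
  conc <- matrix(unlist(lapply(ids, function(id)
    unname(a$samples[[id]]$supplements)[seq_len(n_axes)])),
    ncol = n_axes, byrow = TRUE)
  bio <- tab[tab$sample == ids[1] & tab$signal == "biomass", ]
  dose_response_data(if (n_axes == 1L) conc[, 1] else conc, times,
                     matrix(vals, ncol = length(ids)),
                     biomass = bio$value[match(times, bio$time)])
}

rel_err <- function(fit, truth) {
  tv <- unlist(truth)
  max(abs(coef(fit) - tv) / abs(tv))
}

pure_death_sample <- function(p0 = 100, gamma = 1) {
  circuit_sample(
    genetic_network("pure_death",
                    list(gene_product("X", gamma, p0, "reporter", "X")),
                    list(op_source("off", "X", 0))),
    growth_constant(mu0 = 0))
}

const_growth <- function(mu0 = 0.5) growth_constant(mu0 = mu0)
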