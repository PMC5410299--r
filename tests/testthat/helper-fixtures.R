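# Small study configurations used across the suite. All fixtures are built
# in code at test time; nothing is read from disk except what a test writes.

# a compact study with all plant types present
small_config <- function(seed = 7, ...) {
  defaults <- list(
    n_case = 5, n_control = 3,
    n_lnc = 40, n_mrna = 160,
    de_fraction = 0.3, effect_log2fc = 2, noise_sd = 0.5,
    module_specs = list(list(lnc = 1, n = 6, r = 0.95),
                        list(lnc = 2, n = 6, r = -0.9)),
    n_terms = 20, term_size_range = c(8, 20),
    cis_per_module = 2,
    n_tf = 4, motif_length = 8, promoter_length_bp = 300,
    tf_lnc_specs = list(list(tf = 1, lnc = 1, r = 0.9),
                        list(tf = 2, lnc = 3, r = 0.9)),
    n_site_only_pairs = 10,
    seed = seed)
  dots <- list(...)
  defaults[names(dots)] <- dots # plain replacement, no recursive merging
  do.call(sim_config, defaults)
}

# a null study: nothing planted
null_config <- function(seed = 1, n_lnc = 40, n_mrna = 160, ...) {
  sim_config(n_lnc = n_lnc, n_mrna = n_mrna, de_fraction = 0,
             module_specs = list(), tf_lnc_specs = list(),
             n_site_only_pairs = 0, seed = seed, ...)
}

# an expression matrix with hand-set values
tiny_em <- function(values, n_case = 2, n_control = 2,
                    scale = "linear") {
  n <- n_case + n_control
  stopifnot(ncol(values) == n)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(n))
  expression_matrix(
    values,
    groups = rep(c("case", "control"), c(n_case, n_control)),
    biotypes = rep(c("lncRNA", "mRNA"), length.out = nrow(values)),
    scale = scale)
}

# quadratic reference for window_neighbors built directly on interval_gap
brute_force_neighbors <- function(lnc_coords, gene_coords, window) {
  out <- list()
  for (i in seq_len(nrow(lnc_coords))) {
    for (j in seq_len(nrow(gene_coords))) {
      g <- interval_gap(lnc_coords[i, ], gene_coords[j, ])
      if (!is.na(g) && g <= window)
        out[[length(out) + 1]] <- data.frame(
          lnc_id = lnc_coords$feature_id[i],
          gene_id = gene_coords$feature_id[j],
          distance = g, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(lnc_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  do.call(rbind, out)
}

pair_key <- function(df, a = 1, b = 2) sort(paste(df[[a]], df[[b]]))
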