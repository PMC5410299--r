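#' Configuration for the synthetic two-group expression study
#'
#' Defines a desk-scale stand-in for a case-vs-control lncRNA/mRNA microarray
#' study: a 5-case vs 3-control design by default, log-normal intensities
#' (Gaussian in log2 space), planted differentially expressed features at a
#' fixed signed log2 effect, planted lncRNA-to-mRNA coexpression modules at
#' target pooled Pearson correlations, planted TF-lncRNA couplings, term sets
#' enriched for the modules, cis neighbors inside a genomic window, promoter
#' motif plants, and qPCR Ct tables.
#'
#' Module and TF plants are specified as lists of `list(lnc=, n=, r=)` and
#' `list(tf=, lnc=, r=)` respectively, indexing lncRNAs 1..`n_lnc` and TFs
#' 1..`n_tf` (TFs are the first `n_tf` mRNA features; a TF's expression proxy
#' is its own mRNA row). All planted module members and TF partner mRNAs are
#' forced into the planted-DE set, so `de_fraction * (n_lnc + n_mrna)` must
#' cover them.
#'
#' @param n_case,n_control sample counts (>= 2 each).
#' @param n_lnc,n_mrna feature counts per biotype.
#' @param de_fraction proportion of features planted as differentially
#'   expressed, in \[0, 1\].
#' @param effect_log2fc planted |log2 fold change| (log2 units, > 0).
#' @param noise_sd within-group standard deviation of log2 intensities.
#' @param baseline_mean,baseline_sd mean and between-feature spread of
#'   baseline log2 intensity.
#' @param module_specs list of `list(lnc, n, r)`: lncRNA index, number of
#'   coexpressed mRNA members, target pooled Pearson correlation in (-1, 1)
#'   (or exactly +/-1 for degenerate noise-free tests).
#' @param n_terms number of background annotation terms (planted terms, one
#'   per module, come on top).
#' @param term_size_range integer pair, admissible term sizes.
#' @param cis_window_bp cis window in base pairs (default 300000).
#' @param cis_per_module number of each module's mRNAs placed within the cis
#'   window of their lncRNA.
#' @param n_tf number of transcription factors (first `n_tf` mRNAs).
#' @param motif_length consensus motif length in bp.
#' @param promoter_length_bp synthetic promoter length per lncRNA.
#' @param tf_lnc_specs list of `list(tf, lnc, r)` expression-coupled
#'   TF-lncRNA plants; each also receives a promoter motif site.
#' @param n_site_only_pairs number of decoy TF-lncRNA pairs that receive a
#'   motif site but no expression coupling (they are tested by the motif
#'   gate but should not pass the correlation filter).
#' @param seed integer seed; identical configs give bit-identical outputs.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_case = 5, n_control = 3,
                       n_lnc = 500, n_mrna = 2000,
                       de_fraction = 0.1,
                       effect_log2fc = 2,
                       noise_sd = 0.5,
                       baseline_mean = 8, baseline_sd = 1.5,
                       module_specs = default_module_specs(),
                       n_terms = 50,
                       term_size_range = c(15, 40),
                       cis_window_bp = 300000L,
                       cis_per_module = 2L,
                       n_tf = 10L,
                       motif_length = 8L,
                       promoter_length_bp = 1000L,
                       tf_lnc_specs = default_tf_lnc_specs(),
                       n_site_only_pairs = 200L,
                       seed = 1L) {
  cfg <- list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_lnc = as.integer(n_lnc), n_mrna = as.integer(n_mrna),
    de_fraction = de_fraction, effect_log2fc = effect_log2fc,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    module_specs = module_specs, n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    cis_window_bp = as.integer(cis_window_bp),
    cis_per_module = as.integer(cis_per_module),
    n_tf = as.integer(n_tf), motif_length = as.integer(motif_length),
    promoter_length_bp = as.integer(promoter_length_bp),
    tf_lnc_specs = tf_lnc_specs,
    n_site_only_pairs = as.integer(n_site_only_pairs),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_module_specs <- function() {
  list(list(lnc = 1, n = 10, r = 0.95),
       list(lnc = 2, n = 10, r = 0.90),
       list(lnc = 3, n = 10, r = 0.85),
       list(lnc = 4, n = 10, r = -0.90),
       list(lnc = 5, n = 10, r = -0.85))
}

#' @rdname sim_config
#' @export
default_tf_lnc_specs <- function() {
  # five TFs, two coupled lncRNAs each (module hubs 1..5 plus lncRNAs 6..10)
  specs <- list()
  for (i in 1:5) {
    specs[[length(specs) + 1]] <- list(tf = i, lnc = i, r = 0.9)
    specs[[length(specs) + 1]] <- list(tf = i, lnc = i + 5, r = 0.9)
  }
  specs
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) config_error(msg)
  chk(cfg$n_case >= 2 && cfg$n_control >= 2,
      "n_case and n_control must both be >= 2 (tests and correlations need >= 2 per group)")
  chk(cfg$n_lnc >= 1 && cfg$n_mrna >= 1, "n_lnc and n_mrna must be >= 1")
  chk(cfg$de_fraction >= 0 && cfg$de_fraction <= 1,
      "de_fraction must lie in [0, 1]")
  chk(cfg$effect_log2fc > 0, "effect_log2fc must be positive")
  chk(cfg$noise_sd > 0, "noise_sd must be positive")
  for (m in cfg$module_specs) {
    chk(all(c("lnc", "n", "r") %in% names(m)),
        "each module spec needs fields lnc, n, r")
    chk(m$lnc >= 1 && m$lnc <= cfg$n_lnc, "module lnc index out of range")
    chk(m$n >= 1 && m$n <= cfg$n_mrna, "module member count out of range")
    chk(abs(m$r) <= 1, "module target correlation must lie in [-1, 1]")
  }
  for (s in cfg$tf_lnc_specs) {
    chk(all(c("tf", "lnc", "r") %in% names(s)),
        "each TF-lncRNA spec needs fields tf, lnc, r")
    chk(s$tf >= 1 && s$tf <= cfg$n_tf, "tf index out of range")
    chk(s$lnc >= 1 && s$lnc <= cfg$n_lnc, "tf-paired lnc index out of range")
    chk(abs(s$r) <= 1, "TF-lncRNA target correlation must lie in [-1, 1]")
  }
  if (length(cfg$tf_lnc_specs)) {
    lncs <- vapply(cfg$tf_lnc_specs, function(s) s$lnc, 1)
    chk(!anyDuplicated(lncs),
        "each lncRNA may be expression-coupled to at most one TF")
  }
  n_planted <- n_planted_features(cfg)
  chk(round(cfg$de_fraction * (cfg$n_lnc + cfg$n_mrna)) >= n_planted,
      sprintf(paste0("de_fraction * (n_lnc + n_mrna) must cover the %d planted",
                     " module/TF features (planted features must be DE-eligible)"),
              n_planted))
  chk(length(cfg$term_size_range) == 2 &&
        cfg$term_size_range[1] <= cfg$term_size_range[2],
      "term_size_range must be an ordered integer pair")
  if (length(cfg$module_specs))
    chk(cfg$term_size_range[2] >= max(vapply(cfg$module_specs, `[[`, 1, "n")),
        "term_size_range upper bound is smaller than a module (planted term cannot hold it)")
  chk(cfg$cis_window_bp > 0, "cis_window_bp must be positive")
  chk(cfg$cis_per_module >= 0, "cis_per_module must be >= 0")
  if (length(cfg$module_specs))
    chk(cfg$cis_per_module <= min(vapply(cfg$module_specs, `[[`, 1, "n")),
        "cis_per_module exceeds the smallest module size")
  chk(cfg$n_tf >= 0, "n_tf must be >= 0")
  chk(cfg$motif_length >= 4, "motif_length must be >= 4")
  chk(cfg$motif_length <= cfg$promoter_length_bp,
      "motif_length must not exceed promoter_length_bp")
  invisible(cfg)
}

# distinct features referenced by module and TF plants (hubs, members, TF mRNAs)
n_planted_features <- function(cfg) {
  n_mod <- sum(vapply(cfg$module_specs, `[[`, 1, "n"))
  hubs <- unique(c(vapply(cfg$module_specs, `[[`, 1, "lnc"),
                   vapply(cfg$tf_lnc_specs, `[[`, 1, "lnc")))
  tfs <- unique(vapply(cfg$tf_lnc_specs, `[[`, 1, "tf"))
  n_mod + length(hubs) + length(tfs)
}

lnc_ids  <- function(cfg) sprintf("LNC%04d",  seq_len(cfg$n_lnc))
mrna_ids <- function(cfg) sprintf("MRNA%04d", seq_len(cfg$n_mrna))
tf_ids   <- function(cfg) mrna_ids(cfg)[seq_len(cfg$n_tf)]

#' Generate the synthetic expression matrix with planted ground truth
#'
#' Intensities are log-normal: log2 intensity = feature baseline + group
#' effect + Gaussian noise. Planted DE features shift the case mean by
#' `+/- effect_log2fc`; module mRNAs (and TF mRNAs of expression-coupled
#' TF-lncRNA plants) share their lncRNA's latent noise profile, with the
#' latent correlation solved so the *expected pooled* Pearson correlation —
#' group-shift component included — equals the target. A target of exactly
#' +/-1 yields an affine relation and a sample correlation of exactly +/-1.
#'
#' @param config a [sim_config()].
#' @return list with elements `em` (a linear-scale [expression_matrix()]) and
#'   `truth` (ground-truth record; see [simulate_all()]).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  n <- cfg$n_case + cfg$n_control
  feat <- c(lnc_ids(cfg), mrna_ids(cfg))
  n_feat <- length(feat)
  samples <- c(sprintf("CASE%02d", seq_len(cfg$n_case)),
               sprintf("CTRL%02d", seq_len(cfg$n_control)))
  groups <- stats::setNames(rep(c("case", "control"),
                                c(cfg$n_case, cfg$n_control)), samples)
  biotypes <- stats::setNames(rep(c("lncRNA", "mRNA"),
                                  c(cfg$n_lnc, cfg$n_mrna)), feat)

  # centered group indicator: fixed regressor shared by coupled features
  p_case <- cfg$n_case / n
  gc_vec <- ifelse(groups == "case", 1 - p_case, -p_case)
  v_g <- p_case * (1 - p_case) # population variance of gc over sample index

  # --- planted DE set ---------------------------------------------------
  n_de <- round(cfg$de_fraction * n_feat)
  mod_lnc <- vapply(cfg$module_specs, `[[`, 1, "lnc")
  tf_lnc  <- vapply(cfg$tf_lnc_specs, function(s) s$lnc, 1)
  tf_idx  <- vapply(cfg$tf_lnc_specs, function(s) s$tf, 1)

  dir_vec <- stats::setNames(integer(n_feat), feat) # 0 = not DE

  # module membership: consecutive blocks of mRNAs after the TF block
  member_pool <- setdiff(seq_len(cfg$n_mrna), seq_len(cfg$n_tf))
  members <- list()
  cursor <- 1
  for (i in seq_along(cfg$module_specs)) {
    m <- cfg$module_specs[[i]]
    if (cursor + m$n - 1 > length(member_pool))
      config_error("not enough non-TF mRNAs for the requested modules")
    members[[i]] <- member_pool[cursor:(cursor + m$n - 1)]
    cursor <- cursor + m$n
  }

  # forced plants: module hubs, module members, coupled lncRNAs, TF mRNAs
  forced_lnc <- unique(c(mod_lnc, tf_lnc))
  forced_mrna <- unique(c(unlist(members), tf_idx))
  forced <- c(lnc_ids(cfg)[forced_lnc], mrna_ids(cfg)[forced_mrna])
  if (n_de < length(forced) && n_de > 0)
    config_error("de_fraction too small for the planted features")
  if (n_de > 0) {
    free_pool <- setdiff(feat, forced)
    extra <- sample(free_pool, n_de - length(forced))
    de_set <- c(forced, extra)
    dir_vec[de_set] <- sample(c(-1L, 1L), length(de_set), replace = TRUE)
    # direction constraints propagate along the coupling chain:
    # TF (random) -> coupled lncRNA (sign of target) -> module members
    for (s in cfg$tf_lnc_specs) {
      td <- dir_vec[mrna_ids(cfg)[s$tf]]
      dir_vec[lnc_ids(cfg)[s$lnc]] <- as.integer(sign(s$r) * td)
    }
    for (i in seq_along(cfg$module_specs)) {
      m <- cfg$module_specs[[i]]
      hd <- dir_vec[lnc_ids(cfg)[m$lnc]]
      dir_vec[mrna_ids(cfg)[members[[i]]]] <- as.integer(sign(m$r) * hd)
    }
  }

  # --- log2 intensities -------------------------------------------------
  # Each feature is baseline + group shift + noise_sd * residual, where the
  # residual is standard normal. Coupled features mix the *realized*
  # residual of their source row with fresh noise, in dependency order
  # (TF -> coupled lncRNA -> module member), so one source can drive many
  # partners and chains stay consistent.
  baseline <- stats::rnorm(n_feat, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- feat
  sdn <- cfg$noise_sd
  E <- matrix(stats::rnorm(n_feat * n, 0, 1), n_feat, n,
              dimnames = list(feat, samples))

  couple_residual <- function(row_id, src_id, target_r) {
    d_y <- dir_vec[row_id] * cfg$effect_log2fc
    d_x <- dir_vec[src_id] * cfg$effect_log2fc
    if (abs(target_r) == 1) return(sign(target_r) * E[src_id, ])
    rho <- solve_latent_rho(target_r, d_x, d_y, v_g, sdn)
    rho * E[src_id, ] + sqrt(1 - rho^2) * stats::rnorm(n)
  }

  tf_lnc_pairs <- NULL
  for (s in cfg$tf_lnc_specs) {
    src <- mrna_ids(cfg)[s$tf] # the TF's own mRNA row is the source
    rid <- lnc_ids(cfg)[s$lnc]
    E[rid, ] <- couple_residual(rid, src, s$r)
    tf_lnc_pairs <- rbind(tf_lnc_pairs,
      data.frame(tf_id = src, lnc_id = rid, target_r = s$r,
                 stringsAsFactors = FALSE))
  }
  coexpression_pairs <- NULL
  for (i in seq_along(cfg$module_specs)) {
    m <- cfg$module_specs[[i]]
    hub <- lnc_ids(cfg)[m$lnc]
    for (j in members[[i]]) {
      rid <- mrna_ids(cfg)[j]
      E[rid, ] <- couple_residual(rid, hub, m$r)
      coexpression_pairs <- rbind(coexpression_pairs,
        data.frame(lnc_id = hub, mrna_id = rid, target_r = m$r,
                   module = i, stringsAsFactors = FALSE))
    }
  }
  Y <- baseline + outer(dir_vec * cfg$effect_log2fc, gc_vec) + sdn * E

  em <- expression_matrix(2^Y, groups, biotypes, scale = "linear")
  de_idx <- dir_vec != 0
  truth <- list(
    de_features = data.frame(
      feature_id = feat[de_idx],
      direction = ifelse(dir_vec[de_idx] > 0, "up", "down"),
      true_fc = signed_ratio(2^(dir_vec[de_idx] * cfg$effect_log2fc)),
      stringsAsFactors = FALSE, row.names = NULL),
    coexpression_pairs = coexpression_pairs,
    tf_lnc_pairs = tf_lnc_pairs,
    module_members = stats::setNames(
      lapply(members, function(ix) mrna_ids(cfg)[ix]),
      if (length(members)) lnc_ids(cfg)[mod_lnc] else NULL))
  list(em = em, truth = truth)
}

# latent correlation giving a target *pooled* Pearson correlation when both
# features carry fixed group shifts d_x, d_y over a regressor of variance v_g
solve_latent_rho <- function(target, d_x, d_y, v_g, s) {
  if (abs(target) == 1) return(sign(target))
  var_x <- d_x^2 * v_g + s^2
  var_y <- d_y^2 * v_g + s^2
  rho <- (target * sqrt(var_x * var_y) - d_x * d_y * v_g) / s^2
  if (abs(rho) > 1)
    config_error(sprintf(
      "target correlation %.3f is unreachable given the group shifts (max latent |rho| exceeded; achievable pooled r in [%.3f, %.3f])",
      target,
      (-s^2 + d_x * d_y * v_g) / sqrt(var_x * var_y),
      (s^2 + d_x * d_y * v_g) / sqrt(var_x * var_y)))
  rho
}
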