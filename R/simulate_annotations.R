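#' Generate genomic coordinates with planted cis pairs
#'
#' Every feature receives a (chromosome, start, end, strand) interval. For
#' each coexpression module, `cis_per_module` of its mRNA members are placed
#' on the lncRNA's chromosome at a planted boundary gap inside the cis
#' window; all other features are separated by more than the window (or sit
#' on other chromosomes), so only planted pairs are window neighbors.
#'
#' @param config a [sim_config()].
#' @param feature_ids character vector of unique feature ids to place.
#' @param truth optional ground-truth record from [generate_expression()];
#'   needed for cis plants (module membership). Without it all features are
#'   decoys.
#' @return list with `coords` (coordinate data.frame, BED convention) and
#'   `cis_pairs` (data.frame `lnc_id`, `gene_id`, `distance`).
#' @export
generate_coordinates <- function(config, feature_ids, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (anyDuplicated(feature_ids)) input_error("duplicate feature ids")
  set.seed(config$seed + 1L)
  w <- config$cis_window_bp
  margin <- w + 50000L

  # planted units: lncRNA hub flanked by cis members, one side each,
  # stacked outward in slots so members never collide
  cis_pairs <- NULL
  units <- list()
  placed <- character(0)
  if (!is.null(truth) && length(truth$module_members) && config$cis_per_module > 0) {
    for (hub in names(truth$module_members)) {
      if (!hub %in% feature_ids) next
      mem <- intersect(truth$module_members[[hub]], feature_ids)
      mem <- utils::head(mem, config$cis_per_module)
      if (!length(mem)) next
      side <- rep(c("right", "left"), length.out = length(mem))
      gaps <- integer(length(mem))
      for (s in c("right", "left")) {
        ix <- which(side == s)
        q <- length(ix)
        if (!q) next
        lo <- 10000; hi <- w - 10000
        slot <- (hi - lo) / q
        gaps[ix] <- round(lo + (seq_len(q) - 1) * slot + 6000 +
                            stats::runif(q, 0, slot - 12000))
      }
      units[[length(units) + 1]] <-
        list(hub = hub, members = mem, side = side, gaps = gaps)
      cis_pairs <- rbind(cis_pairs, data.frame(
        lnc_id = hub, gene_id = mem, distance = gaps,
        stringsAsFactors = FALSE))
      placed <- c(placed, hub, mem)
    }
  }
  decoys <- setdiff(feature_ids, placed)

  n_chrom <- 12L
  cursor <- stats::setNames(rep(1L, n_chrom), paste0("chr", seq_len(n_chrom)))
  rows <- list()
  widths <- function(k) round(stats::runif(k, 500, 5000))
  add_row <- function(id, chrom, start, width, strand) {
    rows[[length(rows) + 1]] <<- data.frame(
      feature_id = id, chrom = chrom, start = as.integer(start),
      end = as.integer(start + width), strand = strand,
      stringsAsFactors = FALSE)
  }

  # interleave units and decoys round-robin over chromosomes
  blocks <- c(units, as.list(decoys))
  blocks <- blocks[sample(length(blocks))]
  for (i in seq_along(blocks)) {
    chrom <- paste0("chr", ((i - 1L) %% n_chrom) + 1L)
    b <- blocks[[i]]
    if (is.character(b)) { # decoy feature
      wdt <- widths(1)
      add_row(b, chrom, cursor[chrom], wdt, sample(c("+", "-"), 1))
      cursor[chrom] <- cursor[chrom] + wdt + margin +
        round(stats::runif(1, 0, 50000))
    } else { # planted unit: left members, hub, right members
      hub_w <- widths(1)
      mem_w <- widths(length(b$members))
      left <- which(b$side == "left"); right <- which(b$side == "right")
      left_extent <- if (length(left)) max(b$gaps[left] + mem_w[left]) else 0
      hub_start <- cursor[chrom] + left_extent
      for (j in left)  # member end sits b$gaps[j] to the left of hub start
        add_row(b$members[j], chrom, hub_start - b$gaps[j] - mem_w[j],
                mem_w[j], sample(c("+", "-"), 1))
      add_row(b$hub, chrom, hub_start, hub_w, sample(c("+", "-"), 1))
      for (j in right) # member start sits b$gaps[j] to the right of hub end
        add_row(b$members[j], chrom, hub_start + hub_w + b$gaps[j],
                mem_w[j], sample(c("+", "-"), 1))
      unit_end <- hub_start + hub_w +
        (if (length(right)) max(b$gaps[right] + mem_w[right]) else 0)
      cursor[chrom] <- unit_end + margin + round(stats::runif(1, 0, 50000))
    }
  }
  coords <- do.call(rbind, rows)
  coords <- coords[match(feature_ids, coords$feature_id), , drop = FALSE]
  rownames(coords) <- NULL
  list(coords = coords, cis_pairs = cis_pairs)
}

#' Generate annotation term sets with planted module enrichment
#'
#' One planted term per coexpression module containing every module mRNA
#' (padded with random background genes up to a size inside
#' `term_size_range`), plus `n_terms` background terms drawn uniformly from
#' non-module genes. The universe is the full mRNA id set.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth record from [generate_expression()].
#' @return list with `sets` (named list, GMT-serializable), `universe`
#'   (character) and `enriched_terms` (data.frame `lnc_id`, `term_id`).
#' @export
generate_term_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  universe <- mrna_ids(config)
  module_genes <- unique(unlist(truth$module_members))
  background <- setdiff(universe, module_genes)
  lo <- config$term_size_range[1]; hi <- config$term_size_range[2]

  sets <- list(); enriched <- NULL
  hubs <- names(truth$module_members)
  for (i in seq_along(hubs)) {
    mem <- truth$module_members[[i]]
    if (hi < length(mem))
      config_error("term_size_range upper bound smaller than a module")
    size <- sample(seq(max(lo, length(mem)), hi), 1)
    term_id <- sprintf("TERM_P%02d", i)
    sets[[term_id]] <- sort(c(mem, sample(background, size - length(mem))))
    enriched <- rbind(enriched, data.frame(
      lnc_id = hubs[i], term_id = term_id, stringsAsFactors = FALSE))
  }
  for (i in seq_len(config$n_terms)) {
    size <- sample(seq(lo, hi), 1)
    sets[[sprintf("TERM_B%02d", i)]] <- sort(sample(background, size))
  }
  list(sets = sets, universe = universe, enriched_terms = enriched)
}

#' Generate promoter sequences and TF consensus motifs with planted sites
#'
#' Each lncRNA gets one synthetic promoter of `promoter_length_bp`; each TF
#' one random consensus of `motif_length`. Expression-coupled TF-lncRNA
#' plants and `n_site_only_pairs` site-only decoy pairs get at least one
#' exact motif occurrence embedded in the promoter; every other promoter is
#' rejection-sampled until it carries zero occurrences of *any* motif on
#' either strand, so unplanted (TF, lncRNA) pairs are guaranteed site-free.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth record from [generate_expression()].
#' @return list with `promoters` (named character), `motifs` (data.frame
#'   `tf_id`, `consensus`) and `site_pairs` (data.frame `tf_id`, `lnc_id`,
#'   `coupled` logical — TRUE for expression-coupled plants).
#' @export
generate_promoters_and_motifs <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tf < 1) config_error("n_tf must be >= 1 to generate motifs")
  if (config$motif_length > config$promoter_length_bp)
    config_error("motif_length exceeds promoter_length_bp")
  set.seed(config$seed + 3L)

  tfs <- tf_ids(config)
  lncs <- lnc_ids(config)
  motifs <- data.frame(
    tf_id = tfs,
    consensus = vapply(seq_along(tfs), function(i)
      paste(sample(c("A", "C", "G", "T"), config$motif_length, replace = TRUE),
            collapse = ""), character(1)),
    stringsAsFactors = FALSE)

  coupled <- if (!is.null(truth$tf_lnc_pairs))
    truth$tf_lnc_pairs[, c("tf_id", "lnc_id")] else
    data.frame(tf_id = character(0), lnc_id = character(0))
  # site-only decoys go to promoters of *uncoupled* lncRNAs, so a decoy's
  # binding site is never confounded with a planted expression correlation
  open <- expand.grid(tf_id = tfs, lnc_id = setdiff(lncs, coupled$lnc_id),
                      stringsAsFactors = FALSE)
  n_decoy <- min(config$n_site_only_pairs, nrow(open))
  decoy <- open[sample(nrow(open), n_decoy), , drop = FALSE]
  site_pairs <- rbind(
    cbind(coupled, coupled = TRUE),
    cbind(decoy, coupled = FALSE))
  rownames(site_pairs) <- NULL

  cons <- stats::setNames(motifs$consensus, motifs$tf_id)
  plant_map <- split(site_pairs$tf_id, site_pairs$lnc_id)

  random_clean_seq <- function(len) {
    for (try in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      if (all(vapply(cons, function(m) scan_motif(s, m) == 0L, logical(1))))
        return(s)
    }
    config_error("could not sample a motif-free promoter; motifs too permissive")
  }

  promoters <- stats::setNames(character(length(lncs)), lncs)
  for (lnc in lncs) {
    planted_tfs <- plant_map[[lnc]]
    if (is.null(planted_tfs)) {
      promoters[[lnc]] <- random_clean_seq(config$promoter_length_bp)
      next
    }
    ok <- FALSE
    for (try in 1:200) {
      s <- random_clean_seq(config$promoter_length_bp)
      # embed one site per planted TF at non-overlapping random offsets
      slots <- sort(sample(
        seq(1, config$promoter_length_bp - config$motif_length + 1),
        length(planted_tfs)))
      if (length(slots) > 1 && any(diff(slots) < config$motif_length)) next
      for (j in seq_along(planted_tfs)) {
        m <- cons[[planted_tfs[j]]]
        substr(s, slots[j], slots[j] + nchar(m) - 1) <- m
      }
      counts <- vapply(cons, function(m) scan_motif(s, m), integer(1))
      want <- names(cons) %in% planted_tfs
      if (all(counts[want] >= 1L) && all(counts[!want] == 0L)) {
        promoters[[lnc]] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) config_error("could not embed planted motif sites cleanly")
  }
  list(promoters = promoters, motifs = motifs, site_pairs = site_pairs)
}

#' Generate TF-to-target-gene assignments
#'
#' Each TF's target set is the union of the module members of its
#' expression-coupled lncRNAs (so planted TF-lncRNA-gene triples exist)
#' plus `n_extra` random mRNAs.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth record from [generate_expression()].
#' @param n_extra random extra targets per TF.
#' @return named list: TF id -> character vector of gene ids.
#' @export
generate_tf_targets <- function(config, truth, n_extra = 20) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  pool <- setdiff(mrna_ids(config), tf_ids(config))
  targets <- list()
  for (tf in tf_ids(config)) {
    lncs <- if (!is.null(truth$tf_lnc_pairs))
      truth$tf_lnc_pairs$lnc_id[truth$tf_lnc_pairs$tf_id == tf] else character(0)
    mod <- unique(unlist(truth$module_members[
      intersect(lncs, names(truth$module_members))]))
    targets[[tf]] <- sort(unique(c(mod, sample(pool, n_extra))))
  }
  targets
}

#' Generate a qPCR Ct table from true relative expressions
#'
#' For each sample, the reference-gene Ct is drawn near a baseline and the
#' target Ct is `Ct_reference - log2(relative expression) + noise`, so the
#' 2^-deltaCt estimator recovers the planted relative expression.
#'
#' @param config a [sim_config()] (used for the seed).
#' @param true_relative_expression data.frame with columns `target_id`,
#'   `rel_case`, `rel_control` (positive relative quantities vs the
#'   reference gene in each group).
#' @param n_case,n_control qPCR cohort sizes (default 20 vs 10).
#' @param ct_ref_baseline,ct_ref_sd reference-gene Ct distribution (cycles).
#' @param noise_sd Gaussian noise on the target Ct (cycles).
#' @return data.frame `sample_id`, `group`, `target_id`, `ct_target`,
#'   `ct_reference`.
#' @export
generate_ct_table <- function(config, true_relative_expression,
                              n_case = 20, n_control = 10,
                              ct_ref_baseline = 20, ct_ref_sd = 0.3,
                              noise_sd = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  tre <- true_relative_expression
  if (!all(c("target_id", "rel_case", "rel_control") %in% names(tre)))
    input_error("true_relative_expression needs target_id, rel_case, rel_control")
  if (any(tre$rel_case <= 0) || any(tre$rel_control <= 0))
    input_error("relative expressions must be positive")
  set.seed(config$seed + 5L)
  samples <- data.frame(
    sample_id = c(sprintf("TUMOR%02d", seq_len(n_case)),
                  sprintf("RLN%02d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE)
  out <- merge(samples, tre, by = NULL) # cartesian: every sample x target
  rel <- ifelse(out$group == "case", out$rel_case, out$rel_control)
  out$ct_reference <- stats::rnorm(nrow(out), ct_ref_baseline, ct_ref_sd)
  out$ct_target <- out$ct_reference - log2(rel) +
    stats::rnorm(nrow(out), 0, noise_sd)
  out <- out[order(out$target_id, out$group, out$sample_id),
             c("sample_id", "group", "target_id", "ct_target", "ct_reference")]
  rownames(out) <- NULL
  out
}

#' Serialize and restore the ground-truth record
#'
#' The ground truth — planted DE features, coexpression pairs, enriched
#' terms, cis pairs, TF-lncRNA plants, TF target sets — is stored as a
#' single YAML file (key/value plus list syntax) so every plant can be
#' verified from the generated files without running the pipeline.
#'
#' @param truth ground-truth list as assembled by [simulate_all()].
#' @param file path to a YAML file.
#' @return `write_ground_truth` returns `truth` invisibly;
#'   `read_ground_truth` the restored list.
#' @export
write_ground_truth <- function(truth, file) {
  ser <- lapply(truth, function(x) {
    if (is.data.frame(x)) c(list(.df = TRUE), as.list(x)) else x
  })
  yaml::write_yaml(ser, file)
  invisible(truth)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(file) {
  raw <- yaml::read_yaml(file)
  lapply(raw, function(x) {
    if (is.list(x) && isTRUE(x$.df)) {
      x$.df <- NULL
      data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
    } else x
  })
}
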