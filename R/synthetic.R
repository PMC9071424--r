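# Seeded synthetic-data generators emulating the statistical structure of
# each assay: duplicate-spot arrays with print-tip/spatial bias, triplicate
# footprinting areas, titration intensity decay, motif-planted proteomes,
# and depletion-isotherm binding curves.

#' Generate a synthetic bound/mock microarray scan pair
#'
#' Emulates a duplicate-spot protein array: per-feature log-normal signal,
#' per-scan additive print-tip (block) offsets and a smooth 2-D spatial
#' gradient on the log2 scale, per-spot log-normal noise, and a configured
#' log2 spike effect added to selected features in the bound channel only.
#' Control spots carry a fixed signal and `Control_*` protein ids.
#'
#' @param seed Integer seed (mandatory; the generator is a pure function of
#'   its configuration).
#' @param n_features Number of distinct (non-control) features (default 2000;
#'   the emulated design is a scaled-down >21000-spot proteome array).
#' @param duplicate Spot multiplicity per feature (default 2).
#' @param n_blocks Number of print-tip blocks (default 8).
#' @param n_controls Number of control features (default 32).
#' @param n_spikes Number of spiked true binders (default 0).
#' @param spike_log2fc Log2 effect added to spiked features in the bound
#'   channel; default `3.5 * noise_sd`, comfortably above the 3-SD
#'   detectability floor.
#' @param noise_sd Per-spot log2 noise SD (default 0.1).
#' @param printtip_sd SD of per-block additive log2 offsets, drawn
#'   independently per scan (default 0.3).
#' @param spatial_grad Length-2 log2 gradient coefficients across the array
#'   in x and y, per scan (default `c(0.4, 0.25)`).
#' @param bg_median,bg_sd Constant local-background median and SD applied
#'   to every spot (defaults 400 and 50 intensity units).
#' @return List with `bound` and `mock` (`array_scan` objects) and `truth`
#'   (data frame `feature_id, spiked, log2fc`).
#' @export
gen_array <- function(seed, n_features = 2000L, duplicate = 2L,
                      n_blocks = 8L, n_controls = 32L, n_spikes = 0L,
                      spike_log2fc = 3.5 * noise_sd, noise_sd = 0.1,
                      printtip_sd = 0.3, spatial_grad = c(0.4, 0.25),
                      bg_median = 400, bg_sd = 50) {
  stopifnot(n_spikes <= n_features, noise_sd >= 0)
  set.seed(seed)
  feat_ids <- sprintf("FT%05d", seq_len(n_features))
  ctrl_ids <- sprintf("CT%03d", seq_len(n_controls))
  ids <- c(feat_ids, ctrl_ids)
  n_all <- length(ids)
  is_ctrl <- c(rep(FALSE, n_features), rep(TRUE, n_controls))
  protein <- c(sprintf("PROT%05d", seq_len(n_features)),
               sprintf("Control_%03d", seq_len(n_controls)))
  base_log2 <- c(stats::rnorm(n_features, mean = 6, sd = 1),
                 rep(6, n_controls))
  spiked <- rep(FALSE, n_all)
  if (n_spikes > 0L) spiked[sample.int(n_features, n_spikes)] <- TRUE

  # grid layout: features (x duplicate) dealt into blocks row-major,
  # duplicates adjacent so they share a print-tip block
  n_spots <- n_all * duplicate
  per_block <- ceiling(n_spots / n_blocks)
  ncol_block <- ceiling(sqrt(per_block))
  spot_feature <- rep(seq_len(n_all), each = duplicate)
  spot_idx <- seq_len(n_spots)
  block <- ((spot_idx - 1L) %/% per_block) + 1L
  within <- (spot_idx - 1L) %% per_block
  row <- within %/% ncol_block + 1L
  col <- within %% ncol_block + 1L
  block_col <- (block - 1L) %% 4L
  block_row <- (block - 1L) %/% 4L
  x <- block_col * (ncol_block + 4L) * 100 + col * 100
  y <- block_row * (ceiling(per_block / ncol_block) + 4L) * 100 + row * 100

  make_scan <- function(condition) {
    tip <- stats::rnorm(n_blocks, 0, printtip_sd)
    gx <- spatial_grad[[1L]] * stats::runif(1, 0.5, 1.5)
    gy <- spatial_grad[[2L]] * stats::runif(1, 0.5, 1.5)
    xs <- (x - min(x)) / (max(x) - min(x))
    ys <- (y - min(y)) / (max(y) - min(y))
    l2 <- base_log2[spot_feature] + tip[block] + gx * xs + gy * ys +
      stats::rnorm(n_spots, 0, noise_sd)
    if (condition == "bound") l2 <- l2 + spike_log2fc * spiked[spot_feature]
    fg <- bg_median + 2^l2
    spots <- data.frame(
      block_id = block, row = row, col = col, x = x, y = y,
      feature_id = ids[spot_feature], protein_id = protein[spot_feature],
      is_control = is_ctrl[spot_feature],
      fg_median = round(fg, 1), bg_median = bg_median, bg_sd = bg_sd,
      flag = 0L, stringsAsFactors = FALSE
    )
    array_scan(spots, condition = condition,
               channel_label = paste0("synthetic-", condition),
               header = c(paste0("Synthetic=", condition),
                          paste0("Seed=", seed)))
  }
  bound <- make_scan("bound")
  mock <- make_scan("mock")
  truth <- data.frame(feature_id = ids, protein_id = protein,
                      is_control = is_ctrl, spiked = spiked,
                      log2fc = ifelse(spiked, spike_log2fc, 0),
                      stringsAsFactors = FALSE)
  list(bound = bound, mock = mock, truth = truth)
}

#' Generate synthetic carbene-footprinting peak-area records
#'
#' Digests the target sequence, assigns each peptide a baseline fractional
#' modification, shifts peptides overlapping planted spans by the
#' configured masking/unmasking effect in the bound condition, and converts
#' fractional modifications to labelled/unlabelled peak-area pairs with
#' multiplicative log-normal replicate noise.
#'
#' @param seed Integer seed.
#' @param sequence Target amino-acid sequence; `NULL` draws a random
#'   164-residue sequence (the emulated head-domain construct length).
#' @param masked_spans,unmasked_spans Lists of `c(start, end)` residue
#'   spans planted as masked / unmasked (defaults: masked 66-71, none
#'   unmasked).
#' @param effect_masked,effect_unmasked Planted change in fractional
#'   modification (defaults -0.3 and +0.3).
#' @param baseline_range Range of per-peptide baseline fractional
#'   modification (default `c(0.35, 0.6)`).
#' @param n_reps Replicates per condition (default 3, the triplicate design).
#' @param noise_sd SD of the multiplicative log-normal noise on each peak
#'   area (default 0.02).
#' @param area_scale Median total peak area (default 1e6, arbitrary units).
#' @param max_missed Missed cleavages enumerated by the digest (default 0).
#' @return List with `records` (data frame `peptide_start, peptide_end,
#'   condition, replicate, area_labelled, area_unlabelled`), `truth`
#'   (peptide table with planted class), and `sequence`.
#' @export
gen_footprint <- function(seed, sequence = NULL,
                          masked_spans = list(c(66, 71)),
                          unmasked_spans = list(),
                          effect_masked = -0.3, effect_unmasked = 0.3,
                          baseline_range = c(0.35, 0.6), n_reps = 3L,
                          noise_sd = 0.02, area_scale = 1e6,
                          max_missed = 0L) {
  set.seed(seed)
  if (is.null(sequence)) {
    sequence <- paste(sample(.aa_standard, 164, replace = TRUE,
                             prob = ifelse(.aa_standard %in% c("K", "R"), 2, 1)),
                      collapse = "")
  }
  peps <- digest(sequence, max_missed = max_missed)
  overlaps <- function(p, spans) any(vapply(spans, function(s)
    p[["start"]] <= s[[2L]] && p[["end"]] >= s[[1L]], logical(1)))
  p_apo <- stats::runif(nrow(peps), baseline_range[[1L]], baseline_range[[2L]])
  planted <- character(nrow(peps))
  p_bound <- p_apo
  for (i in seq_len(nrow(peps))) {
    if (length(masked_spans) && overlaps(peps[i, ], masked_spans)) {
      p_bound[[i]] <- p_apo[[i]] + effect_masked; planted[[i]] <- "masked"
    } else if (length(unmasked_spans) && overlaps(peps[i, ], unmasked_spans)) {
      p_bound[[i]] <- p_apo[[i]] + effect_unmasked; planted[[i]] <- "unmasked"
    } else planted[[i]] <- "unchanged"
  }
  p_bound <- pmin(pmax(p_bound, 0.01), 0.99)
  grid <- expand.grid(pep = seq_len(nrow(peps)),
                      condition = c("apo", "bound"),
                      replicate = seq_len(n_reps),
                      stringsAsFactors = FALSE)
  p_true <- ifelse(grid$condition == "apo", p_apo[grid$pep], p_bound[grid$pep])
  total <- area_scale * exp(stats::rnorm(nrow(grid), 0, 0.2))
  lab <- p_true * total * exp(stats::rnorm(nrow(grid), 0, noise_sd))
  unlab <- (1 - p_true) * total * exp(stats::rnorm(nrow(grid), 0, noise_sd))
  records <- data.frame(peptide_start = peps$start[grid$pep],
                        peptide_end = peps$end[grid$pep],
                        condition = grid$condition,
                        replicate = grid$replicate,
                        area_labelled = lab, area_unlabelled = unlab,
                        stringsAsFactors = FALSE)
  truth <- cbind(peps, p_apo = p_apo, p_bound = p_bound, planted = planted)
  list(records = records, truth = truth, sequence = sequence)
}

#' Generate a synthetic NMR titration peak table
#'
#' Residues in the planted binding site lose intensity with single-site
#' saturation occupancy theta(e) = e / (Kapp + e) at each titration point;
#' non-site residues keep their reference intensity. All intensities carry
#' multiplicative Gaussian noise. Prolines are emitted unassigned.
#'
#' @param seed Integer seed.
#' @param n_residues Residues in the construct (default 120).
#' @param site Integer vector of planted binding-site residues (default
#'   `c(56:60, 101:111)`, two short surface stretches).
#' @param equivalents Titration points in molar equivalents (default
#'   `c(0.1, 0.5, 1, 4)`; the 0 reference point is added automatically).
#' @param kapp Apparent binding constant in equivalents units (default
#'   0.05; small = tight, site saturates early).
#' @param depth_range Range of maximal fractional intensity loss of site
#'   residues at saturation (default `c(0.85, 1)`).
#' @param noise_frac SD of multiplicative intensity noise as a fraction of
#'   signal (default 0.02).
#' @param i0 Reference intensity (default 100, arbitrary units).
#' @return List with `peaks` (long data frame `residue, aa, equivalents,
#'   intensity, assigned`) and `truth` (the site residues).
#' @export
gen_nmr_titration <- function(seed, n_residues = 120L,
                              site = c(56:60, 101:111),
                              equivalents = c(0.1, 0.5, 1, 4),
                              kapp = 0.05, depth_range = c(0.85, 1),
                              noise_frac = 0.02, i0 = 100) {
  stopifnot(all(site >= 1L), all(site <= n_residues), all(equivalents > 0))
  set.seed(seed)
  aa <- sample(.aa_standard, n_residues, replace = TRUE)
  aa[site][aa[site] == "P"] <- "A"   # planted site must be observable
  depth <- stats::runif(n_residues, depth_range[[1L]], depth_range[[2L]])
  eqs <- c(0, sort(equivalents))
  theta <- eqs / (kapp + eqs)
  rows <- expand.grid(residue = seq_len(n_residues), eq_idx = seq_along(eqs))
  is_site <- rows$residue %in% site
  clean <- i0 * ifelse(is_site, 1 - depth[rows$residue] * theta[rows$eq_idx], 1)
  noisy <- clean * (1 + stats::rnorm(nrow(rows), 0, noise_frac))
  peaks <- data.frame(residue = rows$residue, aa = aa[rows$residue],
                      equivalents = eqs[rows$eq_idx],
                      intensity = pmax(noisy, 0),
                      assigned = aa[rows$residue] != "P",
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$residue, peaks$equivalents), ]
  row.names(peaks) <- NULL
  list(peaks = peaks, truth = sort(site))
}

#' Generate a synthetic proteome with planted SIM-like motifs
#'
#' Random sequences (uniform residue frequencies) with motif instances
#' spliced in at recorded positions; a receptor set is constructed with a
#' configured overlap with the motif-positive proteins so enrichment tests
#' have known structure. The emitted truth list contains every match
#' (planted or arising by chance), found by brute-force window checking.
#'
#' @param seed Integer seed.
#' @param n_proteins Number of proteins (default 50).
#' @param length_range Sequence length range (default `c(200, 600)`).
#' @param n_planted Number of proteins receiving one planted motif
#'   (default 15).
#' @param pattern Motif planted/scanned (default XRCC4-like SIM).
#' @param n_receptors Size of the receptor set (default 10).
#' @param receptor_motif_frac Fraction of receptors drawn from
#'   motif-positive proteins (default 0.8).
#' @param fasta Optional path; when given the proteome is also written as
#'   an (uncompressed) FASTA file.
#' @return List with `sequences` (named character), `truth_hits` (brute
#'   force hit table `protein_id, start, matched`), `receptor_ids`,
#'   `universe_ids`, and `fasta` (path or `NULL`).
#' @export
gen_proteome <- function(seed, n_proteins = 50L, length_range = c(200L, 600L),
                         n_planted = 15L, pattern = NULL,
                         n_receptors = 10L, receptor_motif_frac = 0.8,
                         fasta = NULL) {
  stopifnot(n_planted <= n_proteins)
  pattern <- motif_pattern(if (is.null(pattern)) "K[SDE][VLI][DES][FVLI]" else pattern)
  set.seed(seed)
  width <- length(pattern)
  ids <- sprintf("SYN%04d", seq_len(n_proteins))
  lens <- sample(length_range[[1L]]:length_range[[2L]], n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(.aa_standard, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- ids
  planted_idx <- if (n_planted > 0L) sample.int(n_proteins, n_planted) else integer()
  for (i in planted_idx) {
    inst <- paste(vapply(pattern, function(s) sample(s, 1L), character(1)),
                  collapse = "")
    pos <- sample.int(lens[[i]] - width + 1L, 1L)
    substr(seqs[[i]], pos, pos + width - 1L) <- inst
  }
  # brute-force truth: every window checked position set by position set
  truth <- do.call(rbind, lapply(ids, function(id) {
    chars <- strsplit(seqs[[id]], "")[[1]]
    starts <- Filter(function(s) all(vapply(seq_len(width), function(j)
      chars[[s + j - 1L]] %in% pattern[[j]], logical(1))),
      seq_len(length(chars) - width + 1L))
    if (length(starts) == 0L) return(NULL)
    data.frame(protein_id = id, start = as.integer(unlist(starts)),
               matched = substring(seqs[[id]], unlist(starts),
                                   unlist(starts) + width - 1L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(protein_id = character(), start = integer(),
                        matched = character(), stringsAsFactors = FALSE)
  motif_pos <- unique(truth$protein_id)
  n_from_pos <- min(round(n_receptors * receptor_motif_frac), length(motif_pos))
  receptors <- c(sample(motif_pos, n_from_pos),
                 sample(setdiff(ids, motif_pos),
                        min(n_receptors - n_from_pos,
                            length(setdiff(ids, motif_pos)))))
  if (!is.null(fasta)) {
    writeLines(paste0(">", ids, "\n", seqs), fasta)
  }
  list(sequences = seqs, truth_hits = truth, receptor_ids = sort(receptors),
       universe_ids = ids, fasta = fasta)
}

#' Generate synthetic single-site binding curves
#'
#' Emulates an MST-style design: a fixed labelled target titrated with a
#' doubling-dilution ligand series, responses from the ligand-depletion
#' isotherm with multiplicative Gaussian noise.
#'
#' @param seed Integer seed.
#' @param kd True dissociation constant in nM (default 3.2).
#' @param bmax Response amplitude (default 100 signal units).
#' @param offset Baseline response (default 0).
#' @param target_conc Fixed labelled-target concentration in nM (default 5).
#' @param top_conc Highest ligand concentration in nM (default 500).
#' @param n_dilutions Number of doubling dilutions (default 16).
#' @param n_reps Replicates (default 3).
#' @param noise_frac SD of multiplicative response noise (default 0.02).
#' @return List with `curve` (data frame `conc, response, replicate`) and
#'   `truth` (the generating parameters).
#' @export
gen_binding_curve <- function(seed, kd = 3.2, bmax = 100, offset = 0,
                              target_conc = 5, top_conc = 500,
                              n_dilutions = 16L, n_reps = 3L,
                              noise_frac = 0.02) {
  set.seed(seed)
  conc <- top_conc / 2^(seq_len(n_dilutions) - 1L)
  grid <- expand.grid(conc = conc, replicate = seq_len(n_reps))
  clean <- offset + bmax * fraction_bound_depletion(grid$conc, kd, target_conc)
  resp <- clean * (1 + stats::rnorm(nrow(grid), 0, noise_frac))
  list(curve = data.frame(conc = grid$conc, response = resp,
                          replicate = grid$replicate),
       truth = list(kd = kd, bmax = bmax, offset = offset,
                    target_conc = target_conc, noise_frac = noise_frac))
}
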