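# NMR titration analysis: intensity-ratio ladders and chemical shift
# perturbation (CSP) classification for binding-surface mapping.

# Build an intensity ladder: for each titration point (molar equivalents),
# a set of half-open intensity-ratio intervals [lo, hi), ordered from most
# to least affected; residues matching no bin fall through to the
# "unaffected" rank. Boundary convention: "<45%" is [0, 0.45); "45-66%" is
# [0.45, 0.66).
.intensity_ladder <- function(equivalents, breaks, name) {
  bins <- do.call(rbind, lapply(equivalents, function(e) {
    data.frame(equivalents = e,
               lo = breaks[-length(breaks)], hi = breaks[-1L])
  }))
  bins$rank <- seq_len(nrow(bins)) - 1L
  n_rank <- nrow(bins) + 1L
  pal <- grDevices::colorRampPalette(c("#FF0000", "#FFFFFF", "#0000FF"))(n_rank)
  bins$colour <- pal[bins$rank + 1L]
  structure(list(type = "intensity", name = name, bins = bins,
                 unaffected_rank = nrow(bins),
                 unaffected_colour = pal[n_rank]),
            class = "gradient_ladder")
}

.csp_ladder <- function(thresholds, name) {
  # thresholds in SD multiples, descending; top bin is [thresholds[1], Inf)
  lo <- thresholds
  hi <- c(Inf, thresholds[-length(thresholds)])
  bins <- data.frame(equivalents = NA_real_, lo = lo, hi = hi,
                     rank = seq_along(thresholds) - 1L)
  n_rank <- nrow(bins) + 1L
  pal <- grDevices::colorRampPalette(c("#FF0000", "#FFFFFF", "#0000FF"))(n_rank)
  bins$colour <- pal[bins$rank + 1L]
  structure(list(type = "csp", name = name, bins = bins,
                 unaffected_rank = nrow(bins),
                 unaffected_colour = pal[n_rank]),
            class = "gradient_ladder")
}

# The eight built-in colour-gradient ladders (titrant-specific designs).
.builtin_ladders <- list(
  # head-domain target + SUMO2 monomer: 45%/66% cuts at 0.1/0.5/1/4 eq
  xrcc4_msumo2  = .intensity_ladder(c(0.1, 0.5, 1, 4), c(0, 0.45, 0.66),
                                    "xrcc4_msumo2"),
  # + SUMO2 dimer: 20/30/45/66% cuts at 0.125/0.25 eq
  xrcc4_disumo2 = .intensity_ladder(c(0.125, 0.25), c(0, 0.2, 0.3, 0.45, 0.66),
                                    "xrcc4_disumo2"),
  # + tetraSUMO2: 20/30/45/66% cuts at 0.1/0.67 eq
  xrcc4_4xsumo2 = .intensity_ladder(c(0.1, 0.67), c(0, 0.2, 0.3, 0.45, 0.66),
                                    "xrcc4_4xsumo2"),
  # SUMO2 target + head domain: 20/30/40/66% cuts at 0.25/0.5 eq
  msumo2_xrcc4  = .intensity_ladder(c(0.25, 0.5), c(0, 0.2, 0.3, 0.4, 0.66),
                                    "msumo2_xrcc4"),
  # SUMO2 target + full-length partner: single point at 0.33 eq
  msumo2_xrcc4fl = .intensity_ladder(0.33, c(0, 0.2, 0.3, 0.4, 0.66),
                                     "msumo2_xrcc4fl"),
  # SUMO2 target + PIAS2 SIM peptide: single point at 0.5 eq
  msumo2_pias2  = .intensity_ladder(0.5, c(0, 0.2, 0.3, 0.4, 0.66),
                                    "msumo2_pias2"),
  # CSP ladders (SD multiples): weak-binding titrations scored by shifts
  xrcc4_msumo1_csp = .csp_ladder(c(5, 4, 3, 2, 1), "xrcc4_msumo1_csp"),
  msumo1_xrcc4_csp = .csp_ladder(c(4, 2, 1), "msumo1_xrcc4_csp")
)

#' Retrieve a built-in gradient ladder
#'
#' The package ships the eight titration-specific colour-gradient ladders as
#' named configurations: `xrcc4_msumo2`, `xrcc4_disumo2`, `xrcc4_4xsumo2`,
#' `msumo2_xrcc4`, `msumo2_xrcc4fl`, `msumo2_pias2` (intensity-ratio type)
#' and `xrcc4_msumo1_csp`, `msumo1_xrcc4_csp` (CSP type, bins in SD
#' multiples).
#'
#' @param name Ladder name (see above).
#' @return A `gradient_ladder` object.
#' @export
gradient_ladder <- function(name) {
  if (inherits(name, "gradient_ladder")) return(name)
  if (!name %in% names(.builtin_ladders))
    stop("unknown ladder '", name, "'; available: ",
         paste(names(.builtin_ladders), collapse = ", "))
  .builtin_ladders[[name]]
}

#' @export
print.gradient_ladder <- function(x, ...) {
  cat(sprintf("<gradient_ladder> %s (%s), %d bins + unaffected rank %d\n",
              x$name, x$type, nrow(x$bins), x$unaffected_rank))
  invisible(x)
}

#' Read a custom intensity ladder from a key-value text file
#'
#' One bin per non-comment line, ordered from most to least affected:
#' `equivalents<whitespace>lo<whitespace>hi`.
#'
#' @param path Path to the ladder file.
#' @param name Name recorded on the returned ladder.
#' @return A `gradient_ladder` object.
#' @export
read_ladder <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  if (length(lines) == 0L) stop("no bins in ladder file: ", path)
  parts <- lapply(strsplit(lines, "\\s+"), as.numeric)
  if (any(lengths(parts) != 3L) || anyNA(unlist(parts)))
    stop("each ladder line must be: equivalents lo hi")
  bins <- data.frame(equivalents = vapply(parts, `[[`, 0, 1L),
                     lo = vapply(parts, `[[`, 0, 2L),
                     hi = vapply(parts, `[[`, 0, 3L))
  bins$rank <- seq_len(nrow(bins)) - 1L
  n_rank <- nrow(bins) + 1L
  pal <- grDevices::colorRampPalette(c("#FF0000", "#FFFFFF", "#0000FF"))(n_rank)
  bins$colour <- pal[bins$rank + 1L]
  structure(list(type = "intensity", name = name, bins = bins,
                 unaffected_rank = nrow(bins), unaffected_colour = pal[n_rank]),
            class = "gradient_ladder")
}

#' Per-point intensity ratios of a titration series
#'
#' Ratio at each titration point is I(e) / I(0), where the reference is the
#' 0-equivalents point. A non-positive reference marks the residue
#' unmeasurable (all ratios `NA`).
#'
#' @param intensities Numeric vector of peak intensities, one per point.
#' @param equivalents Numeric vector of molar equivalents, same length,
#'   starting at 0 and strictly increasing.
#' @return Named numeric vector of ratios at the non-zero equivalents
#'   (names are the equivalents); all-`NA` when the reference is unusable.
#' @export
intensity_ratios <- function(intensities, equivalents) {
  stopifnot(length(intensities) == length(equivalents))
  if (is.unsorted(equivalents, strictly = TRUE))
    stop("equivalents must be strictly increasing")
  if (equivalents[[1L]] != 0) stop("first titration point must be 0 equivalents")
  i0 <- intensities[[1L]]
  ratios <- if (is.na(i0) || i0 <= 0) {
    rep(NA_real_, length(intensities) - 1L)
  } else {
    intensities[-1L] / i0
  }
  names(ratios) <- equivalents[-1L]
  ratios
}

#' Classify a residue's ratio vector against a gradient ladder
#'
#' Bins are scanned from most-affected (rank 0) upward; the first bin whose
#' condition holds wins. Bins whose titration point is missing from the
#' ratio vector are skipped. Residues satisfying no bin get the unaffected
#' rank; if every bin had to be skipped the residue is unclassified (`NA`).
#'
#' @param ratios Named numeric vector as returned by [intensity_ratios()]
#'   (names = equivalents).
#' @param ladder A `gradient_ladder` (intensity type) or its name.
#' @return Integer rank (0 = most affected, `unaffected_rank` = unaffected),
#'   or `NA` if unclassifiable.
#' @export
classify_ladder <- function(ratios, ladder) {
  ladder <- gradient_ladder(ladder)
  if (ladder$type != "intensity")
    stop("classify_ladder needs an intensity-type ladder; use classify_csp")
  if (all(is.na(ratios))) return(NA_integer_)
  eqs <- as.numeric(names(ratios))
  any_evaluated <- FALSE
  for (i in seq_len(nrow(ladder$bins))) {
    b <- ladder$bins[i, ]
    j <- which(abs(eqs - b$equivalents) < 1e-9)
    if (length(j) == 0L || is.na(ratios[[j[[1L]]]])) next
    any_evaluated <- TRUE
    r <- ratios[[j[[1L]]]]
    if (r >= b$lo && r < b$hi) return(b$rank)
  }
  if (!any_evaluated) return(NA_integer_)
  ladder$unaffected_rank
}

#' Combined chemical shift perturbation
#'
#' CSP = sqrt(ddH^2 + (alpha * ddN)^2) with the community-standard 15N
#' scaling alpha = 0.14.
#'
#' @param delta_h,delta_n Amide 1H and 15N shift changes (ppm), vectorised.
#' @param alpha 15N scaling factor (default 0.14).
#' @return Combined shift in ppm (>= 0).
#' @export
csp <- function(delta_h, delta_n, alpha = 0.14) {
  sqrt(delta_h^2 + (alpha * delta_n)^2)
}

#' Classify residues by CSP in SD multiples
#'
#' Each residue's CSP is divided by the dataset SD and ranked against a
#' CSP-type ladder (bins in SD multiples, lower bound inclusive so that a
#' CSP of exactly 5 SD lands in the ">5 SD" top rank of the 5/4/3/2/1
#' ladder).
#'
#' @param csps Numeric vector of combined CSPs (ppm), `NA` = unassigned.
#' @param sd Dataset SD in ppm, or `"auto"` for a robust estimate
#'   (1.4826 x median absolute deviation; needs >= 5 non-`NA` residues).
#' @param ladder CSP-type `gradient_ladder` or name
#'   (default `"xrcc4_msumo1_csp"`).
#' @return Data frame with columns `csp, sd_multiple, rank, colour`;
#'   attribute `sd` records the SD used.
#' @export
classify_csp <- function(csps, sd = "auto", ladder = "xrcc4_msumo1_csp") {
  ladder <- gradient_ladder(ladder)
  if (ladder$type != "csp") stop("classify_csp needs a CSP-type ladder")
  if (any(csps < 0, na.rm = TRUE)) stop("CSPs must be non-negative")
  if (identical(sd, "auto")) {
    obs <- csps[!is.na(csps)]
    if (length(obs) < 5L) stop("need >= 5 residues for auto SD estimation")
    sd <- stats::mad(obs)           # 1.4826 * median absolute deviation
  }
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive (got ", sd, ")")
  mult <- csps / sd
  rank <- rep(ladder$unaffected_rank, length(csps))
  for (i in rev(seq_len(nrow(ladder$bins)))) {   # top bin assigned last, wins
    b <- ladder$bins[i, ]
    rank[!is.na(mult) & mult >= b$lo & mult < b$hi] <- b$rank
  }
  rank[is.na(mult)] <- NA_integer_
  pal <- c(ladder$bins$colour, ladder$unaffected_colour)
  structure(data.frame(csp = csps, sd_multiple = mult, rank = rank,
                       colour = ifelse(is.na(rank), "#808080", pal[rank + 1L]),
                       stringsAsFactors = FALSE),
            sd = sd)
}

#' Classify a whole titration peak table into a binding-surface map
#'
#' Applies [intensity_ratios()] + [classify_ladder()] residue by residue.
#' Residues flagged unassigned (e.g. prolines) are carried through with
#' `NA` rank and grey colour, never classified.
#'
#' @param peaks Long-format data frame with columns `residue, aa,
#'   equivalents, intensity` (one row per residue per titration point);
#'   optional logical column `assigned`.
#' @param ladder Intensity-type `gradient_ladder` or name.
#' @return Data frame `residue, aa, rank, colour, klass` (klass is
#'   `"rank<k>"`, `"unaffected"` or `"unassigned"`).
#' @export
classify_titration <- function(peaks, ladder) {
  ladder <- gradient_ladder(ladder)
  needed <- c("residue", "aa", "equivalents", "intensity")
  missing_cols <- setdiff(needed, names(peaks))
  if (length(missing_cols) > 0L)
    stop("peak table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"assigned" %in% names(peaks)) peaks$assigned <- TRUE
  res_ids <- unique(peaks$residue)
  rows <- lapply(res_ids, function(r) {
    g <- peaks[peaks$residue == r, , drop = FALSE]
    g <- g[order(g$equivalents), , drop = FALSE]
    aa <- g$aa[[1L]]
    if (!all(g$assigned) || aa == "P") {
      return(data.frame(residue = r, aa = aa, rank = NA_integer_,
                        colour = "#808080", klass = "unassigned",
                        stringsAsFactors = FALSE))
    }
    rk <- classify_ladder(intensity_ratios(g$intensity, g$equivalents), ladder)
    pal <- c(ladder$bins$colour, ladder$unaffected_colour)
    klass <- if (is.na(rk)) "unassigned"
             else if (rk == ladder$unaffected_rank) "unaffected"
             else paste0("rank", rk)
    data.frame(residue = r, aa = aa, rank = rk,
               colour = if (is.na(rk)) "#808080" else pal[rk + 1L],
               klass = klass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
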