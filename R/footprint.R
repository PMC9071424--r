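# Carbene footprinting: tryptic digestion, fractional modification,
# masking/unmasking classification, residue painting.

.aa_standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the following residue is
#' proline. Peptides with up to `max_missed` missed cleavages are
#' additionally enumerated (as concatenations of adjacent fully-cleaved
#' peptides). Spans are 1-based inclusive.
#'
#' @param sequence Amino-acid string (standard one-letter codes).
#' @param max_missed Maximum number of missed cleavages (default 1).
#' @return Data frame with columns `start, end, sequence, missed_cleavages`.
#' @export
digest <- function(sequence, max_missed = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% .aa_standard)
  if (length(bad) > 0L)
    stop("non-standard amino-acid letter(s) at position(s): ",
         paste(bad, collapse = ", "))
  n <- length(chars)
  # cut after position i when chars[i] in K/R and chars[i+1] != P
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts == n | chars[pmin(cuts + 1L, n)] != "P"]
  bounds <- unique(c(0L, cuts, n))         # peptide i spans bounds[i]+1 .. bounds[i+1]
  starts0 <- bounds[-length(bounds)] + 1L
  ends0 <- bounds[-1L]
  out <- list()
  for (mc in 0:max_missed) {
    if (length(starts0) <= mc && mc > 0L) break
    s <- starts0[seq_len(length(starts0) - mc)]
    e <- ends0[seq_len(length(ends0) - mc) + mc]
    out[[mc + 1L]] <- data.frame(
      start = s, end = e,
      sequence = substring(sequence, s, e),
      missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Fractional modification of a peptide
#'
#' P = A(labelled) / (A(labelled) + A(unlabelled)), the fraction of a
#' peptide's population carrying the carbene label. Returns `NA`
#' (undetected) where both areas are zero.
#'
#' @param area_labelled,area_unlabelled Non-negative peak areas (vectorised).
#' @return Numeric vector of fractional modifications in \[0, 1\].
#' @export
fractional_modification <- function(area_labelled, area_unlabelled) {
  if (any(area_labelled < 0, na.rm = TRUE) || any(area_unlabelled < 0, na.rm = TRUE))
    stop("peak areas must be non-negative")
  tot <- area_labelled + area_unlabelled
  ifelse(tot > 0, area_labelled / tot, NA_real_)
}

# Welch t-test p-value tolerant of zero-variance groups: identical constant
# groups are maximally unsurprising (p = 1), distinct constant groups are
# maximally surprising (p = 0).
.welch_p <- function(a, b) {
  tryCatch(stats::t.test(a, b)$p.value,
           error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
}

#' Classify peptides as masked / unmasked / unchanged
#'
#' Computes per-replicate fractional modifications, condition means and SDs,
#' and a two-sided Welch t-test between the apo and bound conditions.
#' A peptide is `masked` when bound labelling is significantly lower than
#' apo (partner occludes the surface) and `unmasked` when significantly
#' higher; otherwise `unchanged`. Peptides with fewer than two usable
#' replicates in either condition are `undetected`.
#'
#' @param records Data frame with columns `peptide_start, peptide_end,
#'   condition` (`"apo"`/`"bound"`), `replicate, area_labelled,
#'   area_unlabelled`.
#' @param alpha Per-peptide significance level (default 0.05).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`, matching a per-peptide alpha; `"BH"` available).
#' @return Data frame with one row per peptide: `peptide_start, peptide_end,
#'   p_apo_mean, p_bound_mean, p_apo_sd, p_bound_sd, effect, t_pvalue,
#'   klass`.
#' @export
classify_peptides <- function(records, alpha = 0.05, p_adjust = "none") {
  needed <- c("peptide_start", "peptide_end", "condition", "replicate",
              "area_labelled", "area_unlabelled")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L)
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(records$condition %in% c("apo", "bound")))
    stop("condition must be 'apo' or 'bound'")
  records$P <- fractional_modification(records$area_labelled,
                                       records$area_unlabelled)
  key <- paste(records$peptide_start, records$peptide_end, sep = "-")
  groups <- split(records, factor(key, levels = unique(key)))
  rows <- lapply(groups, function(g) {
    pa <- g$P[g$condition == "apo" & !is.na(g$P)]
    pb <- g$P[g$condition == "bound" & !is.na(g$P)]
    out <- data.frame(peptide_start = g$peptide_start[[1L]],
                      peptide_end = g$peptide_end[[1L]],
                      p_apo_mean = NA_real_, p_bound_mean = NA_real_,
                      p_apo_sd = NA_real_, p_bound_sd = NA_real_,
                      effect = NA_real_, t_pvalue = NA_real_,
                      klass = "undetected", stringsAsFactors = FALSE)
    if (length(pa) < 2L || length(pb) < 2L) return(out)
    out$klass <- "unchanged"
    out$p_apo_mean <- mean(pa); out$p_bound_mean <- mean(pb)
    out$p_apo_sd <- stats::sd(pa); out$p_bound_sd <- stats::sd(pb)
    out$effect <- out$p_bound_mean - out$p_apo_mean
    out$t_pvalue <- .welch_p(pa, pb)
    out
  })
  res <- do.call(rbind, rows)
  row.names(res) <- NULL
  res$t_pvalue_adj <- stats::p.adjust(res$t_pvalue, method = p_adjust)
  signif <- !is.na(res$t_pvalue_adj) & res$t_pvalue_adj < alpha
  res$klass[signif & res$effect < 0] <- "masked"
  res$klass[signif & res$effect > 0] <- "unmasked"
  res
}

#' Map peptide-level footprinting classes onto residues
#'
#' Each residue inherits the class of its covering peptide. Where peptides
#' overlap (missed cleavages), significant calls (masked/unmasked) win over
#' non-significant ones, larger absolute effects win among significant
#' peptides, and `unchanged` beats `undetected`. Uncovered residues are
#' `undetected`.
#'
#' @param results Output of [classify_peptides()].
#' @param length Length of the parent sequence (residues).
#' @return Data frame with columns `residue, klass`.
#' @export
map_to_residues <- function(results, length) {
  stopifnot(length >= 1L)
  if (nrow(results) > 0 &&
      (any(results$peptide_start < 1L) || any(results$peptide_end > length)))
    stop("peptide span outside [1, ", length, "]")
  klass <- rep("undetected", length)
  score <- rep(-Inf, length)   # current precedence score per residue
  # precedence: significant |effect| (score = 1 + |effect|) > unchanged (0)
  # > undetected (-1); undetected peptides never overwrite anything.
  for (i in seq_len(nrow(results))) {
    k <- results$klass[[i]]
    if (k == "undetected") next
    s <- if (k %in% c("masked", "unmasked")) 1 + abs(results$effect[[i]]) else 0
    span <- results$peptide_start[[i]]:results$peptide_end[[i]]
    take <- s > score[span]
    klass[span][take] <- k
    score[span][take] <- s
  }
  data.frame(residue = seq_len(length), klass = klass, stringsAsFactors = FALSE)
}

.footprint_colours <- c(masked = "#FF0000", unmasked = "#FFFF00",
                        unchanged = "#0000FF", undetected = "#ADD8E6",
                        unassigned = "#808080")

#' Write a per-residue attribute script for structure colouring
#'
#' Emits a plain-text file with one line per residue (`residue<TAB>class
#' <TAB>RGB hex`), plus `#`-prefixed header lines, consumable by molecular
#' viewers for painting footprinting or NMR classes onto a structure.
#'
#' @param residue_map Data frame with columns `residue` and `klass` (or
#'   `rank`-style labels); classes outside the built-in palette get black.
#' @param path Output path.
#' @param chain Chain identifier recorded in the header (default `"A"`).
#' @param colours Named vector mapping class labels to RGB hex strings.
#' @return `path`, invisibly.
#' @export
write_attribute_script <- function(residue_map, path, chain = "A",
                                   colours = .footprint_colours) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# per-residue class attribute script",
               paste0("# chain: ", chain),
               "# residue\tclass\tcolour"), con)
  if (nrow(residue_map) > 0L) {
    col <- colours[residue_map$klass]
    col[is.na(col)] <- "#000000"
    writeLines(paste(residue_map$residue, residue_map$klass, col, sep = "\t"), con)
  }
  invisible(path)
}

#' Read back an attribute script written by [write_attribute_script()]
#'
#' @param path Path to the attribute file.
#' @return Data frame with columns `residue, klass, colour`.
#' @export
read_attribute_script <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(residue = integer(), klass = character(),
                      colour = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(residue = as.integer(vapply(parts, `[[`, "", 1L)),
             klass = vapply(parts, `[[`, "", 2L),
             colour = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}
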