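# Microarray screen: GPR input, S/N normalisation, two-stage loess M-values,
# population-SD hit calling.

.gpr_required_cols <- c("Block", "Row", "Column", "X", "Y", "ID", "Name",
                        "F median", "B median", "B SD", "Flags")

#' Read a GenePix-dialect (GPR/ATF) microarray scan
#'
#' Parses a tab-delimited ATF-style file: an `ATF` signature line, a
#' `<n_headers> <n_cols>` line, `n_headers` optional metadata records, then a
#' column-header row followed by one record per spot. The mandatory columns
#' are `Block, Row, Column, X, Y, ID, Name, F median, B median, B SD, Flags`.
#'
#' @param path Path to the scan file.
#' @param condition Condition label for this scan, one of `"bound"` or
#'   `"mock"` (the probe-incubated array vs. the dye-only reference array).
#' @param channel_label Free-text channel annotation stored with the scan.
#' @return An object of class `array_scan`: a list with `spots` (a data frame
#'   with columns `block_id, row, col, x, y, feature_id, protein_id,
#'   is_control, fg_median, bg_median, bg_sd, flag`), `condition`,
#'   `channel_label` and `header` (the raw ATF metadata lines).
#' @export
read_gpr <- function(path, condition = c("bound", "mock"), channel_label = "") {
  condition <- match.arg(condition)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("empty or truncated scan file: ", path)
  if (!grepl("^ATF", lines[[1L]])) stop("not an ATF/GPR file (missing ATF signature): ", path)
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[[2L]]), "\\s+")[[1L]]))
  n_head <- if (length(counts) >= 1L && !is.na(counts[[1L]])) counts[[1L]] else 0L
  header <- if (n_head > 0L) gsub("\"", "", lines[seq_len(n_head) + 2L]) else character()
  body_start <- 3L + n_head
  if (body_start > length(lines)) stop("empty data section in scan file: ", path)
  tab <- utils::read.delim(text = lines[body_start:length(lines)],
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"")
  missing_cols <- setdiff(.gpr_required_cols, names(tab))
  if (length(missing_cols) > 0L) {
    stop("scan file ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("empty data section in scan file: ", path)
  spots <- data.frame(
    block_id  = as.integer(tab[["Block"]]),
    row       = as.integer(tab[["Row"]]),
    col       = as.integer(tab[["Column"]]),
    x         = as.numeric(tab[["X"]]),
    y         = as.numeric(tab[["Y"]]),
    feature_id = as.character(tab[["ID"]]),
    protein_id = as.character(tab[["Name"]]),
    fg_median = as.numeric(tab[["F median"]]),
    bg_median = as.numeric(tab[["B median"]]),
    bg_sd     = as.numeric(tab[["B SD"]]),
    flag      = as.integer(tab[["Flags"]]),
    stringsAsFactors = FALSE
  )
  spots$is_control <- if ("Control" %in% names(tab)) {
    as.logical(tab[["Control"]])
  } else {
    grepl("^control", spots$protein_id, ignore.case = TRUE)
  }
  array_scan(spots, condition = condition, channel_label = channel_label,
             header = header)
}

#' Construct an array scan object
#'
#' @param spots Data frame of spots (see [read_gpr()] for columns).
#' @param condition `"bound"` or `"mock"`.
#' @param channel_label Free-text channel annotation.
#' @param header Character vector of metadata lines.
#' @return An `array_scan` object.
#' @export
array_scan <- function(spots, condition = c("bound", "mock"),
                       channel_label = "", header = character()) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(spots))
  needed <- c("block_id", "row", "col", "x", "y", "feature_id", "protein_id",
              "is_control", "fg_median", "bg_median", "bg_sd", "flag")
  missing_cols <- setdiff(needed, names(spots))
  if (length(missing_cols) > 0L)
    stop("spot table missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("block_id", "row", "col", "flag"))
    spots[[col]] <- as.integer(spots[[col]])
  key <- paste(spots$block_id, spots$row, spots$col)
  if (anyDuplicated(key)) stop("duplicate (block,row,col) grid addresses in scan")
  if (any(spots$fg_median < 0, na.rm = TRUE)) stop("negative foreground intensities")
  if (any(spots$bg_sd < 0, na.rm = TRUE)) stop("negative background SD")
  structure(list(spots = spots[, needed], condition = condition,
                 channel_label = channel_label, header = header),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("<array_scan> condition=%s, %d spots, %d unique features, %d control spots\n",
              x$condition, nrow(x$spots), length(unique(x$spots$feature_id)),
              sum(x$spots$is_control)))
  invisible(x)
}

#' Write an array scan as a GPR/ATF-dialect file
#'
#' Inverse of [read_gpr()]; used for fixture round-trips and by the
#' synthetic-array generator.
#'
#' @param scan An `array_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(scan, path) {
  stopifnot(inherits(scan, "array_scan"))
  sp <- scan$spots
  tab <- data.frame(sp$block_id, sp$row, sp$col, sp$x, sp$y,
                    sp$feature_id, sp$protein_id, sp$fg_median, sp$bg_median,
                    sp$bg_sd, sp$flag, sp$is_control,
                    stringsAsFactors = FALSE)
  names(tab) <- c(.gpr_required_cols, "Control")
  con <- file(path, "w")
  on.exit(close(con))
  header <- scan$header
  if (length(header) == 0L)
    header <- c(paste0("Condition=", scan$condition),
                paste0("Channel=", scan$channel_label))
  writeLines(c("ATF\t1.0", paste0(length(header), "\t", ncol(tab)),
               paste0("\"", header, "\"")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spot signal-to-noise ratio
#'
#' S/N = (foreground median - background median) / background SD, the GenePix
#' convention. May be negative for spots dimmer than their local background.
#' Spots with zero background SD fall back to the scan-wide median background
#' SD (with a warning); if that too is zero the scan is degenerate.
#'
#' @param fg_median,bg_median,bg_sd Numeric vectors of per-spot foreground
#'   median, local background median and local background SD.
#' @return Numeric vector of S/N values.
#' @export
snr <- function(fg_median, bg_median, bg_sd) {
  zero <- !is.na(bg_sd) & bg_sd == 0
  if (any(zero)) {
    fallback <- stats::median(bg_sd[!zero], na.rm = TRUE)
    if (!is.finite(fallback) || fallback == 0)
      stop_degenerate("degenerate scan: all background SDs are zero")
    warning(sum(zero), " spot(s) with zero background SD; ",
            "substituting the scan-wide median background SD")
    bg_sd[zero] <- fallback
  }
  (fg_median - bg_median) / bg_sd
}

#' Normalise spot S/N to the biological controls of a scan
#'
#' Divides every spot's S/N by the median S/N of the non-flagged control
#' spots on the same array (within-array biological-control normalisation).
#'
#' @param scan An `array_scan`.
#' @param control_median Optional explicit control-median override for scans
#'   without usable control spots.
#' @return Data frame with the spot columns plus `snr` and `norm_value`;
#'   attribute `control_median` records the divisor.
#' @export
normalize_to_controls <- function(scan, control_median = NULL) {
  stopifnot(inherits(scan, "array_scan"))
  sp <- scan$spots
  sp$snr <- snr(sp$fg_median, sp$bg_median, sp$bg_sd)
  if (is.null(control_median)) {
    usable <- sp$is_control & sp$flag == 0L
    if (!any(usable))
      stop("no usable (non-flagged) control spots in scan; ",
           "pass an explicit control_median override")
    control_median <- stats::median(sp$snr[usable])
  }
  if (!is.finite(control_median) || control_median == 0)
    stop("control median S/N is zero or non-finite; cannot normalise")
  sp$norm_value <- sp$snr / control_median
  attr(sp, "control_median") <- control_median
  sp
}

#' Average duplicate features of a normalised spot table
#'
#' Per `feature_id`, takes the arithmetic mean of the non-flagged duplicates'
#' normalised values. Features whose duplicates are all flagged are dropped
#' and reported via the `dropped` attribute. Grid position of a summarised
#' feature is the mean (x, y) of its surviving spots and the block of its
#' first surviving spot (duplicates share a print-tip block in this design).
#'
#' @param norm_table Output of [normalize_to_controls()].
#' @return Data frame with one row per surviving feature: `feature_id,
#'   protein_id, is_control, block_id, x, y, value, n_spots`; attribute
#'   `dropped` lists all-flagged feature ids.
#' @export
summarize_duplicates <- function(norm_table) {
  ok <- norm_table$flag == 0L
  kept <- norm_table[ok, , drop = FALSE]
  dropped <- setdiff(unique(norm_table$feature_id), unique(kept$feature_id))
  if (nrow(kept) == 0L) stop("all spots flagged; nothing to summarise")
  idx <- split(seq_len(nrow(kept)), kept$feature_id)
  out <- data.frame(
    feature_id = names(idx),
    protein_id = vapply(idx, function(i) kept$protein_id[i[[1L]]], character(1)),
    is_control = vapply(idx, function(i) kept$is_control[i[[1L]]], logical(1)),
    block_id   = vapply(idx, function(i) kept$block_id[i[[1L]]], integer(1)),
    x          = vapply(idx, function(i) mean(kept$x[i]), numeric(1)),
    y          = vapply(idx, function(i) mean(kept$y[i]), numeric(1)),
    value      = vapply(idx, function(i) mean(kept$norm_value[i]), numeric(1)),
    n_spots    = vapply(idx, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(match(out$feature_id, norm_table$feature_id)), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

# Robust loess detrend of y on the given covariates; returns residuals.
# Groups too small for the local fit at this span are passed through
# unchanged (with a warning) rather than fitted.
.loess_residuals <- function(y, covars, span, min_points = 10L, what = "loess") {
  n <- length(y)
  if (n < min_points) {
    warning("skipping ", what, " fit: only ", n, " points (need >= ", min_points, ")")
    return(y)
  }
  if (stats::sd(y) == 0) return(y - mean(y))   # constant trend: exact fit
  covars <- covars[, vapply(covars, stats::sd, 0) > 0, drop = FALSE]
  if (ncol(covars) == 0L) return(y - mean(y))  # no usable covariate
  df <- cbind(data.frame(.y = y), covars)
  fml <- stats::as.formula(paste(".y ~", paste(names(covars), collapse = " + ")))
  fit <- tryCatch(
    stats::loess(fml, data = df, span = span, degree = 1,
                 family = "symmetric", surface = "direct",
                 normalize = ncol(covars) > 1L),
    error = function(e) {
      warning("skipping ", what, " fit: ", conditionMessage(e))
      NULL
    })
  if (is.null(fit)) return(y)
  stats::residuals(fit)
}

#' Compute twice-normalised M-values from a bound/mock scan pair
#'
#' Per feature, computes the bound-minus-mock difference of
#' control-normalised, duplicate-averaged log2 S/N, then removes technical
#' trends in two loess stages: (1) a robust local regression of the
#' difference D on the mean log-signal A within each print-tip group
#' (block), and (2) a 2-D local regression of the stage-1 residuals on the
#' spot centre coordinates (x, y) across the whole array. The stage-2
#' residual is the M-value.
#'
#' @param bound,mock `array_scan` objects sharing the same feature layout
#'   (`"bound"` = probe-incubated, `"mock"` = dye-only reference).
#' @param span_printtip Loess span for the per-block M-vs-A fit (default 0.75).
#' @param span_spatial Loess span for the whole-array spatial fit (default 0.3).
#' @param epsilon Floor applied to non-positive normalised values before
#'   taking log2 (default `1e-6`).
#' @param control_median_bound,control_median_mock Optional control-median
#'   overrides forwarded to [normalize_to_controls()].
#' @return Data frame (`m_table`) with one row per feature common to both
#'   scans: `feature_id, protein_id, is_control, block_id, x, y, a_value,
#'   d_raw, m_value`.
#' @export
compute_m_values <- function(bound, mock, span_printtip = 0.75,
                             span_spatial = 0.3, epsilon = 1e-6,
                             control_median_bound = NULL,
                             control_median_mock = NULL) {
  stopifnot(inherits(bound, "array_scan"), inherits(mock, "array_scan"))
  b <- summarize_duplicates(normalize_to_controls(bound, control_median_bound))
  m <- summarize_duplicates(normalize_to_controls(mock, control_median_mock))
  common <- intersect(b$feature_id, m$feature_id)
  if (length(common) == 0L) stop("no features shared between the two scans")
  b <- b[match(common, b$feature_id), ]
  m <- m[match(common, m$feature_id), ]
  lb <- log2(pmax(b$value, epsilon))
  lm_ <- log2(pmax(m$value, epsilon))
  tab <- data.frame(
    feature_id = common, protein_id = b$protein_id,
    is_control = b$is_control, block_id = b$block_id,
    x = b$x, y = b$y,
    a_value = (lb + lm_) / 2, d_raw = lb - lm_,
    stringsAsFactors = FALSE
  )
  # stage 1: print-tip M-vs-A loess within each block
  r1 <- tab$d_raw
  for (blk in unique(tab$block_id)) {
    i <- which(tab$block_id == blk)
    r1[i] <- .loess_residuals(tab$d_raw[i], data.frame(a = tab$a_value[i]),
                              span = span_printtip,
                              what = sprintf("print-tip (block %s)", blk))
  }
  # stage 2: spatial loess on (x, y) across the whole array
  tab$m_value <- .loess_residuals(r1, data.frame(x = tab$x, y = tab$y),
                                  span = span_spatial, what = "spatial")
  tab
}

#' Call receptor-candidate hits from an M-value table
#'
#' The hit threshold is `mean(M) + k * SD(M)` computed over the non-control
#' feature population with the sample (n-1) standard deviation; features at
#' or above the threshold are hits. Hits are reported sorted by decreasing
#' M-value, and isoforms are collapsed to unique protein identifiers for the
#' unique-candidate count.
#'
#' @param m_table Output of [compute_m_values()].
#' @param k SD multiplier above the population mean (default 1).
#' @param isoform_regex Regex removed from `protein_id` (first match onward)
#'   to collapse isoforms, default `"[.-].*$"`.
#' @return List with `table` (the m_table plus `is_hit`), `hits` (hit rows
#'   sorted by decreasing M), `unique_candidates` (collapsed protein ids),
#'   `threshold`, `mean`, `sd`, `k`.
#' @export
call_hits <- function(m_table, k = 1, isoform_regex = "[.-].*$") {
  pop <- m_table$m_value[!m_table$is_control]
  if (length(pop) < 2L) stop("need at least 2 non-control features to call hits")
  mu <- mean(pop)
  sdev <- stats::sd(pop)
  if (!is.finite(sdev) || sdev == 0) {
    warning("zero variance in M-values; no hits called")
    m_table$is_hit <- FALSE
    return(list(table = m_table, hits = m_table[0, ],
                unique_candidates = character(),
                threshold = Inf, mean = mu, sd = sdev, k = k))
  }
  thr <- mu + k * sdev
  m_table$is_hit <- !m_table$is_control & m_table$m_value >= thr
  hits <- m_table[m_table$is_hit, , drop = FALSE]
  hits <- hits[order(-hits$m_value), , drop = FALSE]
  row.names(hits) <- NULL
  uniq <- unique(sub(isoform_regex, "", hits$protein_id))
  list(table = m_table, hits = hits, unique_candidates = uniq,
       threshold = thr, mean = mu, sd = sdev, k = k)
}
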