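# XRCC4-like SIM motif scanning, acidic-context annotation and receptor
# enrichment testing.

#' Parse a motif pattern in bracket notation
#'
#' `"K[SDE][VLI][DES][FVLI]"` becomes an ordered list of allowed-residue
#' sets. The default pattern is the non-conventional, XRCC4-like SIM
#' K-\[SDE\]-\[VLI\]-\[DES\]-\[FVLI\].
#'
#' @param pattern Bracket-notation string.
#' @return A `motif_pattern`: list of character vectors, one per position.
#' @export
motif_pattern <- function(pattern = "K[SDE][VLI][DES][FVLI]") {
  if (inherits(pattern, "motif_pattern")) return(pattern)
  toks <- regmatches(pattern, gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(pattern))
    stop("malformed pattern: ", pattern)
  sets <- lapply(toks, function(t) strsplit(gsub("\\[|\\]", "", t), "")[[1]])
  if (any(lengths(sets) == 0L)) stop("empty position set in pattern: ", pattern)
  structure(sets, class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ",
      paste(vapply(x, function(s) {
        if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
      }, character(1)), collapse = "-"), "\n", sep = "")
  invisible(x)
}

.pattern_regex <- function(pattern) {
  paste0("(?=", paste(vapply(pattern, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = ""), ")")
}

#' Scan protein sequences for motif matches
#'
#' Reports all (overlapping) matches with 1-based start positions, in file
#' order then position order. Ambiguity letters (X, B, Z, ...) never match
#' any position set.
#'
#' @param sequences Named character vector of protein sequences, a
#'   `Biostrings::AAStringSet`, or a path to a FASTA file.
#' @param pattern A `motif_pattern`, bracket-notation string, or `NULL` for
#'   the default XRCC4-like SIM pattern.
#' @return Data frame of hits: `protein_id, start, matched`.
#' @export
scan_motifs <- function(sequences, pattern = NULL) {
  pattern <- motif_pattern(if (is.null(pattern)) "K[SDE][VLI][DES][FVLI]" else pattern)
  seqs <- .as_sequences(sequences)
  rx <- .pattern_regex(pattern)
  width <- length(pattern)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    starts <- m[m > 0]
    if (length(starts) == 0L) return(NULL)
    data.frame(protein_id = names(seqs)[[i]], start = as.integer(starts),
               matched = substring(s, starts, starts + width - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      matched = character(), stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}

# Accept FASTA path, AAStringSet, or named character vector.
.as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x))) {
    set <- tryCatch(Biostrings::readAAStringSet(x),
                    error = function(e) stop("unreadable FASTA file ", x, ": ",
                                             conditionMessage(e)))
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  if (methods::is(x, "AAStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret 'sequences' (need FASTA path, AAStringSet, ",
       "or named character vector)")
}

#' Annotate motif hits with acidic flanking context
#'
#' Counts aspartate/glutamate residues in the `window` positions flanking
#' the motif on each side (clipped at the termini); a hit has acidic
#' context when the count reaches `min_count`.
#'
#' @param hits Data frame from [scan_motifs()].
#' @param sequences Same sequence source used for the scan.
#' @param pattern Pattern used for the scan (for the motif width).
#' @param window Residues examined on each side (default 5).
#' @param min_count Acidic residues required for context (default 2).
#' @return `hits` with added columns `acidic_count, acidic_context`.
#' @export
acidic_context <- function(hits, sequences, pattern = NULL, window = 5L,
                           min_count = 2L) {
  stopifnot(window >= 0L)
  pattern <- motif_pattern(if (is.null(pattern)) "K[SDE][VLI][DES][FVLI]" else pattern)
  seqs <- .as_sequences(sequences)
  width <- length(pattern)
  count1 <- function(id, start) {
    s <- seqs[[id]]
    n <- nchar(s)
    left <- substring(s, max(1L, start - window), start - 1L)
    right <- substring(s, start + width, min(n, start + width + window - 1L))
    flank <- strsplit(paste0(left, right), "")[[1]]
    sum(flank %in% c("D", "E"))
  }
  hits$acidic_count <- if (nrow(hits) == 0L) integer() else
    mapply(count1, hits$protein_id, hits$start, USE.NAMES = FALSE)
  hits$acidic_context <- hits$acidic_count >= min_count
  hits
}

#' Test enrichment of a receptor set among motif-containing proteins
#'
#' One-sided Fisher exact test (hypergeometric upper tail) for
#' over-representation of receptors among motif-positive proteins, on
#' per-protein presence/absence. The odds ratio is the sample odds ratio
#' with a Haldane 0.5 correction when any cell is zero.
#'
#' @param hits Data frame from [scan_motifs()] (or a character vector of
#'   motif-positive protein ids).
#' @param receptor_ids Character vector of receptor protein ids (must be a
#'   subset of the universe).
#' @param universe_ids Character vector of all protein ids considered.
#' @return List with `k` (motif-positive receptors), `K` (receptors),
#'   `n` (motif-positive proteins), `N` (universe size), `odds_ratio`,
#'   `p_value`.
#' @export
motif_enrichment <- function(hits, receptor_ids, universe_ids) {
  positives <- if (is.data.frame(hits)) unique(hits$protein_id) else unique(hits)
  universe_ids <- unique(universe_ids)
  receptor_ids <- unique(receptor_ids)
  if (length(universe_ids) == 0L) stop("empty universe")
  if (!all(receptor_ids %in% universe_ids))
    stop("receptor_ids must be a subset of universe_ids")
  positives <- intersect(positives, universe_ids)
  N <- length(universe_ids); K <- length(receptor_ids)
  n <- length(positives); k <- length(intersect(positives, receptor_ids))
  tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2,
                dimnames = list(receptor = c("yes", "no"),
                                motif = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  a <- k; b <- K - k; cc <- n - k; d <- N - K - n + k
  if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  list(k = k, K = K, n = n, N = N, odds_ratio = (a * d) / (b * cc), p_value = p)
}
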