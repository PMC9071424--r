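# In-code fixture builders (no binary fixtures; everything generated at
# test time).

# minimal spot table; vectors recycled to the longest length
make_spots <- function(feature_id, fg, bg = 100, bg_sd = 10, flag = 0L,
                       is_control = FALSE, protein_id = feature_id,
                       block_id = 1L) {
  n <- max(length(feature_id), length(fg))
  data.frame(block_id = rep_len(block_id, n),
             row = ((seq_len(n) - 1L) %/% 10L) + 1L,
             col = ((seq_len(n) - 1L) %% 10L) + 1L,
             x = as.numeric(((seq_len(n) - 1L) %% 10L + 1L) * 100),
             y = as.numeric(((seq_len(n) - 1L) %/% 10L + 1L) * 100),
             feature_id = rep_len(feature_id, n),
             protein_id = rep_len(protein_id, n),
             is_control = rep_len(is_control, n),
             fg_median = rep_len(fg, n),
             bg_median = rep_len(bg, n),
             bg_sd = rep_len(bg_sd, n),
             flag = rep_len(flag, n),
             stringsAsFactors = FALSE)
}

# tiny 4-row GPR file: 2 features in duplicate
write_tiny_gpr <- function(path, drop_col = NULL) {
  cols <- c("Block", "Row", "Column", "X", "Y", "ID", "Name",
            "F median", "B median", "B SD", "Flags")
  rows <- list(
    c(1, 1, 1, 100, 100, "FT1", "PROT1", 900, 100, 10, 0),
    c(1, 1, 2, 200, 100, "FT1", "PROT1", 910, 100, 10, 0),
    c(1, 2, 1, 100, 200, "FT2", "PROT2", 300, 100, 10, 0),
    c(1, 2, 2, 200, 200, "FT2", "PROT2", 310, 100, 10, 0))
  keep <- if (is.null(drop_col)) seq_along(cols) else which(cols != drop_col)
  lines <- c("ATF\t1.0", paste0(1, "\t", length(keep)), "\"Type=test\"",
             paste(cols[keep], collapse = "\t"),
             vapply(rows, function(r) paste(r[keep], collapse = "\t"), ""))
  writeLines(lines, path)
  path
}
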