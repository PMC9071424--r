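# Carbene footprinting: digestion, fractional modification, masking
# classification, residue painting.

test_that("digest applies the trypsin rule with proline blocking", {
  p <- digest("MKRAPK", max_missed = 0)
  expect_equal(p$sequence, c("MK", "R", "APK"))
  expect_equal(p$start, c(1, 3, 4))
  expect_equal(p$end, c(2, 3, 6))
  # K followed by P blocks cleavage; terminal R never cuts anything after it
  expect_equal(digest("MKPR", max_missed = 0)$sequence, "MKPR")
  expect_error(digest("MKXR"), "position")
})

test_that("missed-cleavage peptides are concatenations of adjacent peptides", {
  p <- digest("MKRAPK", max_missed = 1)
  mc1 <- p[p$missed_cleavages == 1L, ]
  expect_equal(mc1$sequence, c("MKR", "RAPK"))
  expect_equal(mc1$start, c(1, 3))
  full <- p[p$missed_cleavages == 0L, ]
  expect_equal(paste(full$sequence, collapse = ""), "MKRAPK")
})

test_that("fully-cleaved peptides reconcatenate to the input (property)", {
  set.seed(42)
  for (i in 1:100) {
    s <- random_protein(sample(20:200, 1))
    p <- digest(s, max_missed = 0)
    expect_identical(paste(p$sequence, collapse = ""), s)
    expect_identical(substring(s, p$start, p$end), p$sequence)
  }
})

test_that("fractional modification matches the closed form and edge cases", {
  expect_equal(fractional_modification(5, 5), 0.5)
  expect_equal(fractional_modification(0, 7), 0)
  expect_equal(fractional_modification(3, 1), 0.75)
  expect_true(is.na(fractional_modification(0, 0)))
  expect_error(fractional_modification(-1, 1), "non-negative")
  # invariant under common scaling of both areas
  set.seed(5)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(fractional_modification(a * 1e3, b * 1e3),
               fractional_modification(a, b))
})

make_records <- function(p_apo, p_bound, total = 1e6) {
  rbind(
    data.frame(peptide_start = 1L, peptide_end = 5L, condition = "apo",
               replicate = seq_along(p_apo), area_labelled = p_apo * total,
               area_unlabelled = (1 - p_apo) * total),
    data.frame(peptide_start = 1L, peptide_end = 5L, condition = "bound",
               replicate = seq_along(p_bound), area_labelled = p_bound * total,
               area_unlabelled = (1 - p_bound) * total))
}

test_that("classify_peptides calls masked/unmasked/unchanged with Welch t", {
  apo <- c(0.60, 0.62, 0.61); bnd <- c(0.20, 0.22, 0.21)
  res <- classify_peptides(make_records(apo, bnd))
  expect_equal(res$klass, "masked")
  expect_equal(res$effect, -0.40, tolerance = 1e-12)
  expect_equal(res$t_pvalue, welch_p_hand(apo, bnd), tolerance = 1e-12)
  expect_lt(res$t_pvalue, 1e-5)

  res_un <- classify_peptides(make_records(c(0.30, 0.30, 0.30),
                                           c(0.50, 0.52, 0.48)))
  expect_equal(res_un$klass, "unmasked")
  expect_equal(res_un$t_pvalue,
               welch_p_hand(c(0.30, 0.30, 0.30), c(0.50, 0.52, 0.48)),
               tolerance = 1e-12)

  # identical replicate sets in both conditions -> unchanged, effect 0
  res_id <- classify_peptides(make_records(apo, apo))
  expect_equal(res_id$klass, "unchanged")
  expect_equal(res_id$effect, 0)

  # < 2 usable replicates -> undetected
  rec <- make_records(apo, bnd)[-(4:5), ]
  expect_equal(classify_peptides(rec)$klass, "undetected")
})

test_that("swapping condition labels flips masked <-> unmasked, p unchanged", {
  set.seed(8)
  rec <- make_records(runif(3, 0.5, 0.6), runif(3, 0.2, 0.3))
  res <- classify_peptides(rec)
  rec2 <- rec
  rec2$condition <- ifelse(rec$condition == "apo", "bound", "apo")
  res2 <- classify_peptides(rec2)
  expect_equal(res2$t_pvalue, res$t_pvalue)
  expect_equal(res2$effect, -res$effect)
  expect_setequal(c(res$klass, res2$klass), c("masked", "unmasked"))
})

test_that("map_to_residues paints spans with |effect| precedence", {
  res <- data.frame(peptide_start = 66L, peptide_end = 71L,
                    effect = -0.4, t_pvalue = 1e-4, klass = "masked")
  m <- map_to_residues(res, 164)
  expect_equal(m$klass[66:71], rep("masked", 6))
  expect_equal(unique(m$klass[-(66:71)]), "undetected")

  # overlapping masked (|effect| .4) and unchanged: overlap stays masked
  res2 <- rbind(res, data.frame(peptide_start = 69L, peptide_end = 80L,
                                effect = 0.01, t_pvalue = 0.8,
                                klass = "unchanged"))
  m2 <- map_to_residues(res2, 164)
  expect_equal(unique(m2$klass[66:71]), "masked")
  expect_equal(unique(m2$klass[72:80]), "unchanged")

  # conflicting significant peptides: larger |effect| wins
  res3 <- rbind(res, data.frame(peptide_start = 69L, peptide_end = 80L,
                                effect = 0.6, t_pvalue = 1e-4,
                                klass = "unmasked"))
  m3 <- map_to_residues(res3, 164)
  expect_equal(unique(m3$klass[69:71]), "unmasked")
  expect_error(map_to_residues(res, 50), "outside")
})

test_that("attribute scripts round-trip the residue map", {
  m <- data.frame(residue = 1:3, klass = c("masked", "unchanged", "undetected"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_attribute_script(m, path)
  back <- read_attribute_script(path)
  expect_equal(back$residue, m$residue)
  expect_equal(back$klass, m$klass)
  expect_equal(back$colour[1], "#FF0000")
  # empty map -> header-only file
  write_attribute_script(m[0, ], path)
  expect_true(all(grepl("^#", readLines(path))))
  expect_equal(nrow(read_attribute_script(path)), 0L)
})

test_that("masked-call power matches an independent Welch simulation", {
  # package route: areas -> classify_peptides; oracle route: logit-normal
  # P replicates -> hand-coded Welch formula. Same generative model
  # (multiplicative area noise sd sigma_a <=> logit-P noise sd sqrt(2)*sigma_a).
  sigma_a <- 0.05; p0 <- 0.5; eff <- -0.05; n_sim <- 1000
  set.seed(301)
  pkg_hits <- 0L
  for (i in seq_len(n_sim)) {
    pa <- plogis(qlogis(p0) + rnorm(3, 0, sqrt(2) * sigma_a))
    pb <- plogis(qlogis(p0 + eff) + rnorm(3, 0, sqrt(2) * sigma_a))
    if (classify_peptides(make_records(pa, pb))$klass == "masked")
      pkg_hits <- pkg_hits + 1L
  }
  oracle_hits <- 0L
  for (i in seq_len(n_sim)) {
    pa <- plogis(qlogis(p0) + rnorm(3, 0, sqrt(2) * sigma_a))
    pb <- plogis(qlogis(p0 + eff) + rnorm(3, 0, sqrt(2) * sigma_a))
    if (welch_p_hand(pa, pb) < 0.05 && mean(pb) < mean(pa))
      oracle_hits <- oracle_hits + 1L
  }
  expect_lt(abs(pkg_hits - oracle_hits) / n_sim, 0.05)
})
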