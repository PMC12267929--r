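# Codon counting, RSCU, the rank-based tests, and MILC.

test_that("codon extraction counts sense and stop codons", {
  cc <- extract_codons(c(g1 = "ATGAAAAAGTAA"))
  expect_equal(unname(cc$counts["ATG"]), 1L)
  expect_equal(unname(cc$counts["AAA"]), 1L)
  expect_equal(unname(cc$counts["AAG"]), 1L)
  expect_equal(sum(cc$counts), 3L)
  expect_equal(unname(cc$stops["TAA"]), 1L)
  # 79 sense codons excluded by the 80 AA hard filter
  short <- paste0(paste(rep("GCT", 79), collapse = ""), "TAA")
  lng <- paste0(paste(rep("GCT", 80), collapse = ""), "TAA")
  cc2 <- extract_codons(c(short = short, lng = lng), min_len_aa = 80)
  expect_equal(cc2$excluded, "short")
  expect_equal(cc2$n_genes, 1L)
  expect_warning(extract_codons(c(g = "ATGAAAA")), "multiple of 3")
})

test_that("codon counts equal a 3-mer stepping oracle", {
  set.seed(601)
  cds <- sim_cds(n_genes = 3, len_range_aa = c(20, 60), seed = 77)
  cc <- extract_codons(cds)
  brute <- table(unlist(lapply(cds, function(s) {
    sapply(seq(1, nchar(s) - 2, by = 3), function(i)
      substr(s, i, i + 2))
  })))
  for (cd in names(cc$counts))
    expect_equal(unname(cc$counts[cd]),
                 if (cd %in% names(brute)) unname(brute[[cd]]) else 0L)
})

test_that("RSCU follows its closed form and normalization", {
  # two-fold family with counts (3, 1): Lys AAA/AAG
  v <- setNames(rep(0, 61), codon_families()$codon)
  v["AAA"] <- 3; v["AAG"] <- 1
  r <- rscu(v)
  expect_equal(unname(r["AAA"]), 1.5)
  expect_equal(unname(r["AAG"]), 0.5)
  # uniform usage in the four-fold Ala family
  v2 <- v; v2[c("GCT", "GCC", "GCA", "GCG")] <- 7
  expect_equal(unname(rscu(v2)[c("GCT", "GCC", "GCA", "GCG")]),
               rep(1, 4))
  # random counts: family sums equal degeneracy wherever defined
  set.seed(602)
  fams <- codon_families()
  for (i in 1:10) {
    vr <- setNames(rpois(61, 20), fams$codon)
    rr <- rscu(vr)
    for (f in unique(fams$family)) {
      idx <- fams$family == f
      if (sum(vr[fams$codon[idx]]) > 0)
        expect_equal(sum(rr[fams$codon[idx]]), fams$r[idx][1],
                     tolerance = 1e-12)
    }
  }
})

test_that("KW within an amino acid behaves at the boundaries", {
  fams <- codon_families()
  flat <- matrix(1, nrow = 6, ncol = 61,
                 dimnames = list(NULL, fams$codon))
  expect_equal(kw_by_amino_acid(flat, "A"), 1)
  # completely separated codon values over 10 rows
  m <- flat[rep(1, 10), ]
  m[, "GCT"] <- seq(10, 11, length.out = 10)
  m[, "GCC"] <- seq(20, 21, length.out = 10)
  expect_lt(kw_by_amino_acid(m, "A"), 0.01)
  expect_error(kw_by_amino_acid(flat, "M"), "degeneracy")
})

test_that("Dunn z agrees with an independent rank computation", {
  set.seed(603)
  fams <- codon_families()
  m <- matrix(runif(8 * 61), nrow = 8, dimnames = list(NULL, fams$codon))
  tab <- dunn_posthoc(m, "K")  # Lys: AAA vs AAG, one comparison
  x <- c(m[, "AAA"], m[, "AAG"])
  g <- rep(c("AAA", "AAG"), each = 8)
  rk <- rank(x)
  N <- length(x)
  z_hand <- (mean(rk[g == "AAA"]) - mean(rk[g == "AAG"])) /
    sqrt((N * (N + 1) / 12) * (1 / 8 + 1 / 8))
  expect_equal(tab$z, z_hand, tolerance = 1e-9)
  expect_equal(tab$p_adj, tab$p)  # single comparison: factor 1
  # four-fold family: 6 comparisons, Bonferroni factor 6
  tab4 <- dunn_posthoc(m, "A")
  expect_equal(nrow(tab4), 6L)
  free <- tab4$p * 6
  expect_equal(tab4$p_adj, pmin(1, free))
  # identical groups: everything null
  flat <- matrix(1, 6, 61, dimnames = list(NULL, fams$codon))
  expect_true(all(dunn_posthoc(flat, "A")$p_adj == 1))
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(604)
  fams <- codon_families()
  m <- matrix(rexp(10 * 61), nrow = 10,
              dimnames = list(NULL, fams$codon))
  expect_equal(kw_by_amino_acid(m, "G"), kw_by_amino_acid(exp(m), "G"))
  expect_equal(dunn_posthoc(m, "G")$z, dunn_posthoc(exp(m), "G")$z)
})

test_that("organelle contrasts flag planted shifts with direction", {
  set.seed(605)
  fams <- codon_families()
  mk <- function(n, shift_codons = NULL, delta = 0) {
    m <- matrix(rnorm(n * 61, mean = 1, sd = 0.05), nrow = n,
                dimnames = list(NULL, fams$codon))
    if (!is.null(shift_codons)) m[, shift_codons] <- m[, shift_codons] +
        delta
    m
  }
  same <- mk(8)
  none <- compare_organelles(same, same + 0)
  expect_false(any(none$significant))
  planted <- c("GCT", "AAA", "CGG", "TTT", "GGA")
  hits <- 0
  for (rep_i in 1:20) {
    mt <- mk(8, planted, 1.5)
    pt <- mk(8)
    tab <- compare_organelles(mt, pt)
    if (setequal(tab$codon[tab$significant], planted)) hits <- hits + 1
    # swapping labels flips the direction signs
    rev <- compare_organelles(pt, mt)
    expect_equal(tab$direction, -rev$direction)
  }
  expect_gte(hits, 19)
})

test_that("Pearson concordance spans its range", {
  x <- c(a = 1, b = 2, c = 3)
  expect_equal(pearson_concordance(x, x * 2 + setNames(rep(1, 3),
                                                       names(x))), 1)
  expect_equal(pearson_concordance(x, setNames(-x, names(x))), -1)
  expect_true(is.na(pearson_concordance(x, setNames(rep(2, 3),
                                                    names(x)))))
  set.seed(606)
  a <- setNames(runif(61), codon_families()$codon)
  b <- setNames(runif(61), codon_families()$codon)
  closed <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_concordance(a, b), closed, tolerance = 1e-12)
})

test_that("MILC vanishes in the information term when f equals g", {
  fams <- codon_families()
  # a gene with exactly uniform usage inside every family
  v <- setNames(rep(6, 61), fams$codon)
  pg <- matrix(v, nrow = 1, dimnames = list("g1", fams$codon))
  uniform <- setNames(rep(1, 61), fams$codon)
  L <- sum(v)
  got <- milc(pg, expected = uniform, min_len_aa = 0)
  corr_df <- sum(tapply(fams$r, fams$family, function(x) x[1]) - 1)
  expect_equal(unname(got), 0 - (corr_df / L - 0.5), tolerance = 1e-12)
  # the short-gene filter
  pg2 <- rbind(g1 = v, g2 = round(v / 8))  # well under 80 codons
  expect_lt(sum(pg2["g2", ]), 80)
  out <- milc(pg2, expected = uniform, min_len_aa = 80)
  expect_equal(names(out), "g1")
  expect_error(milc(pg2, expected = uniform, min_len_aa = 1000),
               "length filter")
})

test_that("MILC trends to its floor as genes grow under the model", {
  set.seed(607)
  meds <- sapply(c(100, 400, 1600), function(L) {
    cds <- sim_cds(n_genes = 60, len_range_aa = c(L, L),
                   seed = 607 + L)
    median(milc(extract_codons(cds), min_len_aa = 0))
  })
  expect_true(all(diff(meds) < 0))
  expect_gt(meds[3], 0.4)  # approaches but stays near the 0.5 floor
})
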