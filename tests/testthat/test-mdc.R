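# MDC semantics: fixed-in-query, absent-from-reference columns, the
# ambiguity policies, taxon comparisons, and discrimination reports.

aln_from_cols <- function(cols, ids) {
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  dna_alignment(m, "toy")
}

test_that("the MDC definition and the query-polymorphism exclusion hold",
{
  a <- aln_from_cols(list(c("A", "A", "C", "C", "C"),
                          c("A", "T", "C", "C", "C"),
                          c("G", "G", "G", "G", "G")),
                     c("q1", "q2", "r1", "r2", "r3"))
  sites <- find_mdcs(a, c("q1", "q2"), c("r1", "r2", "r3"))
  expect_equal(sites$column, 0L)       # fixed A vs all-C
  expect_equal(sites$query_state, "A")
  # column 2 is query-polymorphic (A/T), column 3 invariant
  expect_equal(nrow(sites), 1L)
})

test_that("conservative policy is documented by the full code table", {
  # single reference character from each IUPAC code against each base
  for (b in BASES4) for (code in names(ORACLE_IUPAC)) {
    a <- aln_from_cols(list(c(b, b, code)), c("q1", "q2", "r1"))
    got <- nrow(find_mdcs(a, c("q1", "q2"), "r1", "conservative"))
    want <- as.integer(!(b %in% ORACLE_IUPAC[[code]]))
    expect_equal(got, want,
                 info = sprintf("query %s vs ref %s", b, code))
  }
  # gap always disqualifies under the conservative policy
  g <- aln_from_cols(list(c("A", "A", "-")), c("q1", "q2", "r1"))
  expect_equal(nrow(find_mdcs(g, c("q1", "q2"), "r1")), 0L)
  # strict policy ignores the gap but needs an unambiguous reference
  expect_equal(nrow(find_mdcs(g, c("q1", "q2"), "r1", "strict_acgt")),
               0L)
  s <- aln_from_cols(list(c("A", "A", "R", "C")),
                     c("q1", "q2", "r1", "r2"))
  expect_equal(nrow(find_mdcs(s, c("q1", "q2"), c("r1", "r2"),
                              "conservative")), 0L)
  expect_equal(nrow(find_mdcs(s, c("q1", "q2"), c("r1", "r2"),
                              "strict_acgt")), 1L)
})

test_that("find_mdcs equals the brute-force column scan on random panels",
{
  set.seed(401)
  for (trial in 1:60) {
    ns <- sample(3:8, 1)
    L <- sample(40:200, 1)
    m <- rand_aln_matrix(ns, L)
    nq <- sample(1:(ns - 1), 1)
    q <- rownames(m)[1:nq]
    r <- rownames(m)[(nq + 1):ns]
    a <- dna_alignment(m, "rand")
    for (pol in c("conservative", "strict_acgt")) {
      got <- find_mdcs(a, q, r, pol)$column + 1L
      want <- brute_mdc_columns(m, q, r, pol)
      expect_equal(got, want, info = paste(trial, pol))
    }
  }
})

test_that("adding samples never increases the MDC count", {
  set.seed(402)
  for (trial in 1:20) {
    m <- rand_aln_matrix(6, 150)
    a <- dna_alignment(m, "mono")
    base <- nrow(find_mdcs(a, "s1", c("s3", "s4")))
    more_ref <- nrow(find_mdcs(a, "s1", c("s3", "s4", "s5")))
    more_query <- nrow(find_mdcs(a, c("s1", "s2"), c("s3", "s4")))
    expect_lte(more_ref, base)
    expect_lte(more_query, base)
  }
})

test_that("compare_taxa is asymmetric and bounded by pairwise variants",
{
  # 7 reciprocally fixed columns
  base <- strrep("A", 50)
  plant <- function(s, pos, ch) {
    v <- strsplit(s, "")[[1]]; v[pos] <- ch; paste(v, collapse = "")
  }
  ta <- plant(base, 1:7, "T")
  tb <- plant(base, 1:7, "C")
  a <- dna_alignment(c(a1 = ta, a2 = ta, b1 = tb, b2 = tb), "x")
  expect_equal(unname(compare_taxa(a, c("a1", "a2"), c("b1", "b2"))),
               c(7L, 7L))
  # A fixed at 3 columns where B is polymorphic
  tb1 <- plant(base, 1:3, "G")
  a2 <- dna_alignment(c(a1 = plant(base, 1:3, "T"),
                        a2 = plant(base, 1:3, "T"),
                        b1 = tb1, b2 = base), "y")
  expect_equal(unname(compare_taxa(a2, c("a1", "a2"), c("b1", "b2"))),
               c(3L, 0L))
  # identical taxa
  a3 <- dna_alignment(c(a1 = base, b1 = base), "z")
  expect_equal(unname(compare_taxa(a3, "a1", "b1")), c(0L, 0L))
  # symmetry bound against any cross-pair variant count
  set.seed(403)
  m <- rand_aln_matrix(4, 300)
  a4 <- dna_alignment(m, "w")
  ct <- compare_taxa(a4, c("s1", "s2"), c("s3", "s4"))
  for (x in c("s1", "s2")) for (y in c("s3", "s4"))
    expect_lte(max(ct), count_pairwise_variants(a4, x, y))
})

test_that("pairwise variant counts use pairwise deletion", {
  a <- dna_alignment(c(x = "ACGT", y = "ACCT"), "t")
  expect_equal(count_pairwise_variants(a, "x", "y"), 1L)
  b <- dna_alignment(c(x = "ACGT", y = "ACGT"), "t")
  expect_equal(count_pairwise_variants(b, "x", "y"), 0L)
  d <- dna_alignment(c(x = "AC-TN", y = "AGGTC"), "t")
  expect_equal(count_pairwise_variants(d, "x", "y"), 1L)
})

test_that("sole congeners are flagged not-evaluable under genus scope", {
  panel <- species_panel(data.frame(
    sample_id = c("a1", "b1", "c1"),
    species = c("spA", "spB", "spC"),
    genus = c("G1", "G1", "G2")))
  base <- strrep("A", 30)
  v <- strsplit(base, "")[[1]]; v[5] <- "T"
  a <- dna_alignment(c(a1 = paste(v, collapse = ""), b1 = base,
                       c1 = base), "c1")
  rep <- discrimination(list(a), panel, scope = "genus")
  expect_equal(rep$denominator, 2L)
  expect_false(rep$per_species$evaluable[rep$per_species$taxon == "spC"])
  # the variant is fixed in spA and absent from spB, and vice versa:
  # in a two-species genus the diagnostic is reciprocal
  expect_true(rep$per_species$identified[rep$per_species$taxon == "spA"])
  expect_true(rep$per_species$identified[rep$per_species$taxon == "spB"])
  expect_equal(rep$efficiency, 100)
  # panel scope evaluates all three species
  rep2 <- discrimination(list(a), panel, scope = "panel")
  expect_equal(rep2$denominator, 3L)
})

test_that("identical monomorphic species yield zero efficiency", {
  panel <- species_panel(data.frame(
    sample_id = paste0("s", 1:4),
    species = rep(c("spA", "spB"), each = 2),
    genus = "G1"))
  a <- dna_alignment(setNames(rep(strrep("ACGT", 10), 4),
                              paste0("s", 1:4)), "c1")
  rep <- discrimination(list(a), panel)
  expect_equal(rep$efficiency, 0)
  expect_true(all(rep$per_species$total_mdcs == 0))
})
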