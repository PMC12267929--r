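# Diversity statistics and window tracks.

test_that("variable and parsimony-informative site definitions hold", {
  a <- dna_alignment(c(s1 = "AAAA", s2 = "AAAC", s3 = "AATG",
                       s4 = "ATTT"),
                     "toy")
  # columns: AAAA (const), AAAT-ish... count with the brute census below
  m <- as.matrix(a)
  brute_var <- sum(apply(m, 2, function(co)
    length(unique(co[co %in% BASES4])) >= 2))
  expect_equal(variable_sites(a), brute_var)
  cols <- list(c("A", "A", "A", "A"), c("A", "A", "A", "T"),
               c("A", "A", "T", "T"), c("A", "C", "G", "T"))
  mm <- do.call(cbind, cols); rownames(mm) <- paste0("s", 1:4)
  b <- dna_alignment(mm, "toy2")
  expect_equal(variable_sites(b), 3L)
  expect_equal(parsimony_informative_sites(b), 1L)
  ident <- dna_alignment(c(x = "ACGT", y = "ACGT"), "id")
  expect_equal(variable_sites(ident), 0L)
  expect_equal(parsimony_informative_sites(ident), 0L)
})

test_that("site counts match a brute-force census on random alignments",
{
  set.seed(501)
  for (i in 1:10) {
    m <- rand_aln_matrix(6, 200)
    a <- dna_alignment(m, "r")
    bv <- sum(apply(m, 2, function(co)
      length(unique(co[co %in% BASES4])) >= 2))
    bp <- sum(apply(m, 2, function(co) {
      tb <- table(co[co %in% BASES4])
      sum(tb >= 2) >= 2
    }))
    expect_equal(variable_sites(a), bv)
    expect_equal(parsimony_informative_sites(a), bp)
  }
})

test_that("pairwise identity and GC match hand counts", {
  ident <- dna_alignment(c(x = "ACGTACGT", y = "ACGTACGT"), "id")
  expect_equal(pairwise_identity(ident), 100)
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("GGCC"), 100)
  # 3-sequence toy: pairs (x,y): 1 diff/4, (x,z): 2/4, (y,z): 1/4
  a <- dna_alignment(c(x = "ACGT", y = "ACCT", z = "TCCT"), "t")
  expect_equal(pairwise_identity(a),
               100 * mean(c(3 / 4, 2 / 4, 3 / 4)))
  # gaps excluded from GC denominator
  expect_equal(gc_content(dna_alignment(c(x = "GC--", y = "ATNN"), "g")),
               50)
})

test_that("pi matches the hand-enumerated toy and its decomposition", {
  ident <- dna_alignment(c(x = "AAAA", y = "AAAA"), "i")
  expect_equal(pi_diversity(ident), 0)
  # 4 sequences, length 10, pairwise differences {1,2,0,1,1,2}
  s1 <- "AAAAAAAAAA"
  s2 <- "AAAAAAAAAT"
  s3 <- "AAAAAAAATT"
  s4 <- "AAAAAAAAAA"
  a <- dna_alignment(c(s1 = s1, s2 = s2, s3 = s3, s4 = s4), "t")
  pw <- orgbarcode:::pairwise_stats(a)
  expect_equal(sort(pw$diffs), c(0L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(pi_diversity(a), (7 / 6) / 10)
  # site decomposition: on gap-free data pi equals the mean per-column
  # pairwise heterozygosity
  set.seed(502)
  for (i in 1:10) {
    m <- rand_aln_matrix(5, 80, BASES4, rep(0.25, 4))
    al <- dna_alignment(m, "r")
    h <- apply(m, 2, function(co) {
      pr <- combn(length(co), 2)
      mean(co[pr[1, ]] != co[pr[2, ]])
    })
    expect_equal(pi_diversity(al), mean(h), tolerance = 1e-12)
    expect_gte(pi_diversity(al), 0)
  }
})

test_that("window tracks obey the count formula", {
  set.seed(503)
  for (i in 1:100) {
    L <- sample(50:2000, 1)
    w <- sample(10:600, 1)
    s <- sample(5:200, 1)
    n <- length(orgbarcode:::window_starts(L, w, s))
    expect_equal(n, if (L < w) 0L else floor((L - w) / s) + 1L)
  }
  a <- dna_alignment(rand_aln_matrix(4, 1500, BASES4, rep(0.25, 4)),
                     "w")
  tr <- pi_windows(a, window = 600, step = 100)
  expect_equal(nrow(tr), floor((1500 - 600) / 100) + 1)
  # window values agree with direct pi on the column slice
  for (k in c(1, 5, nrow(tr))) {
    sub <- dna_alignment(as.matrix(a)[, (tr$start[k] + 1):tr$end[k]],
                         "sub")
    expect_equal(tr$value[k], pi_diversity(sub))
  }
})

test_that("MDC density conserves counts and matches a histogram", {
  tr <- mdc_density(c(0, 10, 500, 999, 800), length = 5000,
                    window = 1000)
  expect_equal(tr$value[1], 5)
  expect_equal(sum(tr$value), 5)
  set.seed(504)
  pos <- sample(0:4999, 120)
  tr2 <- mdc_density(pos, length = 5000, window = 1000)
  expect_equal(tr2$value,
               as.numeric(table(cut(pos, seq(0, 5000, by = 1000),
                                    right = FALSE))))
  expect_equal(sum(tr2$value), 120)
  # partial last window flagged and still counted
  tr3 <- mdc_density(c(0, 1040), length = 1050, window = 1000)
  expect_equal(sum(tr3$value), 2)
  expect_true(tr3$partial[2])
})

test_that("gc windows tile the sequence", {
  g <- paste0(strrep("G", 100), strrep("A", 100))
  tr <- gc_windows(g, window = 100)
  expect_equal(tr$value, c(100, 0))
})

test_that("divergent blocks of a focal sample are localized", {
  set.seed(505)
  L <- 1200
  base <- sample(BASES4, L, TRUE)
  m <- matrix(rep(base, 5), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), NULL))
  # plant a 243-column divergent block at 50% divergence in s1
  blk <- 301:543
  flip <- sample(blk, round(length(blk) * 0.5))
  for (p in flip) m["s1", p] <- sample(setdiff(BASES4, m["s1", p]), 1)
  a <- dna_alignment(m, "hv")
  iv <- divergent_block_scan(a, "s1", min_run = 100, min_frac = 0.3)
  expect_equal(nrow(iv), 1L)
  expect_lte(iv[1, 1], 300)
  expect_gte(iv[1, 2], 543)
  expect_equal(nrow(divergent_block_scan(a, "s2", 100, 0.3)), 0L)
  # two separated blocks give two intervals
  m2 <- m
  blk2 <- 901:1100
  for (p in sample(blk2, 100))
    m2["s1", p] <- sample(setdiff(BASES4, m2["s1", p]), 1)
  iv2 <- divergent_block_scan(dna_alignment(m2, "hv2"), "s1", 100, 0.3)
  expect_equal(nrow(iv2), 2L)
})

test_that("statistics are invariant under row reordering", {
  set.seed(506)
  m <- rand_aln_matrix(5, 150)
  a <- dna_alignment(m, "o")
  b <- dna_alignment(m[sample(5), ], "o")
  expect_equal(pi_diversity(a), pi_diversity(b))
  expect_equal(variable_sites(a), variable_sites(b))
  expect_equal(pairwise_identity(a), pairwise_identity(b))
})
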