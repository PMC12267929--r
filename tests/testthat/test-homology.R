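# Homology scan: e-value algebra, planted-transfer recovery, duplicate
# collapsing, self-repeat masks, and agreement with full
# Smith-Waterman on small fixtures.

test_that("e-values scale linearly in search space and invert exactly", {
  sc <- scoring_scheme()
  expect_equal(evalue(120, 2e5, 1e5, sc) * 2, evalue(120, 4e5, 1e5, sc))
  expect_true(evalue(80, 1e5, 1e5, sc) > evalue(120, 1e5, 1e5, sc))
  # the score solving E = 1e-5 at m = n = 4e5, by bisection
  f <- function(S) evalue(S, 4e5, 4e5, sc) - 1e-5
  s_bisect <- uniroot(f, c(1, 500), tol = 1e-9)$root
  s_closed <- (log(sc$K * 4e5 * 4e5) - log(1e-5)) / sc$lambda
  expect_equal(s_bisect, s_closed, tolerance = 1e-6)
  expect_error(evalue(100, 0, 1e5, sc), "positive")
})

test_that("degenerate scoring schemes are rejected", {
  expect_error(scoring_scheme(match = 3, mismatch = -1), "degenerate")
  expect_error(scoring_scheme(match = 2, mismatch = -5), "Karlin")
})

test_that("a verbatim planted transfer is recovered in full", {
  set.seed(301)
  for (i in 1:5) {
    B <- rand_seq(8000, gc = 0.44)
    A <- plant_insert(rand_seq(8000, gc = 0.44), B, 3001, 3200, 4001)
    h <- find_hits(genome_record("A", A), genome_record("B", B))
    expect_equal(nrow(h), 1L)
    expect_lte(h$query_start, 4000)
    expect_gte(h$query_end, 4200)
    expect_gte(h$pct_identity, 99)
    expect_lt(h$evalue, 1e-5)
  }
})

test_that("unrelated random sequences yield no hits (SW-confirmed)", {
  set.seed(302)
  for (i in 1:8) {
    A <- rand_seq(3000); B <- rand_seq(3000)
    h <- find_hits(genome_record("A", A), genome_record("B", B),
                   min_raw_score = 100)
    expect_equal(nrow(h), 0L)
    expect_lt(sw_score(A, B), 100)
  }
})

test_that("a 5%-diverged insert is recovered near its true identity", {
  set.seed(303)
  for (i in 1:5) {
    B <- rand_seq(8000, gc = 0.44)
    A <- plant_insert(rand_seq(8000, gc = 0.44), B, 2001, 2500, 1001,
                      divergence = 0.05)
    h <- find_hits(genome_record("A", A), genome_record("B", B))
    expect_equal(nrow(h), 1L)
    cov <- (min(h$query_end, 1500) - max(h$query_start, 1000)) / 500
    expect_gte(cov, 0.9)
    expect_gte(h$pct_identity, 92)
    expect_lte(h$pct_identity, 98)
    # the hit's score equals the SW optimum of the region
    expect_equal(h$raw_score, sw_score(A, B))
  }
})

test_that("best hit score equals the Smith-Waterman optimum on <=2 kb",
{
  set.seed(304)
  for (i in 1:5) {
    B <- rand_seq(1500)
    seg <- strsplit(substr(B, 501, 900), "")[[1]]
    mut <- sample(400, 12)
    for (p in mut) seg[p] <- sample(setdiff(BASES4, seg[p]), 1)
    seg <- seg[-sample(length(seg), 3)]  # deletions exercise gapped DP
    A0 <- rand_seq(1500)
    A <- paste0(substr(A0, 1, 600), paste(seg, collapse = ""),
                substr(A0, 1001, 1500))
    h <- find_hits(genome_record("A", A), genome_record("B", B),
                   min_raw_score = 50)
    expect_gt(nrow(h), 0)
    expect_equal(max(h$raw_score), sw_score(A, B))
  }
})

test_that("reverse-complementing the subject flips strand, not score", {
  set.seed(305)
  B <- rand_seq(6000)
  A <- plant_insert(rand_seq(6000), B, 2001, 2400, 3001,
                    divergence = 0.02)
  h_fwd <- find_hits(genome_record("A", A), genome_record("B", B))
  Brc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(B)))
  h_rev <- find_hits(genome_record("A", A), genome_record("Brc", Brc))
  expect_equal(nrow(h_fwd), nrow(h_rev))
  expect_equal(sort(h_fwd$raw_score), sort(h_rev$raw_score))
  expect_true(all(h_fwd$strand != h_rev$strand))
  expect_equal(h_fwd$query_start, h_rev$query_start)
})

test_that("duplicate hits collapse to unique region pairs", {
  two_same <- data.frame(hit_id = 1:2,
                         query_start = c(100, 100), query_end = c(500, 500),
                         subject_start = c(900, 900),
                         subject_end = c(1300, 1300),
                         raw_score = c(700, 650))
  expect_equal(nrow(dedupe_hits(two_same)), 1L)
  disjoint <- data.frame(hit_id = 1:3,
                         query_start = c(0, 1000, 2000),
                         query_end = c(300, 1300, 2300),
                         subject_start = c(0, 1000, 2000),
                         subject_end = c(300, 1300, 2300),
                         raw_score = 500)
  expect_equal(nrow(dedupe_hits(disjoint)), 3L)
  # one plastid locus hit at two mitogenome loci: subject overlap links
  dup <- data.frame(hit_id = 1:2,
                    query_start = c(100, 5000), query_end = c(600, 5500),
                    subject_start = c(900, 900),
                    subject_end = c(1400, 1400),
                    raw_score = c(800, 790))
  dd <- dedupe_hits(dup)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$n_members, 2L)
})

test_that("dedupe matches a brute-force clustering oracle", {
  set.seed(306)
  for (trial in 1:25) {
    n <- sample(2:6, 1)
    qs <- sample(0:5000, n)
    ss <- sample(0:5000, n)
    len <- sample(100:800, n, replace = TRUE)
    hits <- data.frame(hit_id = seq_len(n),
                       query_start = qs, query_end = qs + len,
                       subject_start = ss, subject_end = ss + len,
                       raw_score = sample(100:900, n))
    frac <- runif(1, 0.3, 0.9)
    got <- nrow(dedupe_hits(hits, overlap_frac = frac))
    want <- length(unique(brute_cluster(hits, frac)))
    expect_equal(got, want)
  }
})

test_that("gene content classification separates complete from fragment",
{
  pairs <- data.frame(region_id = 1L, subject_intervals = "50-500",
                      query_intervals = "0-450")
  feats <- data.frame(name = c("inG", "halfG", "outG"),
                      start = c(100, 200, 600), end = c(400, 600, 700),
                      strand = "+", kind = "gene")
  tab <- classify_gene_content(pairs, feats)
  expect_equal(tab$completeness[tab$gene == "inG"], "complete")
  expect_equal(tab$completeness[tab$gene == "halfG"], "fragment")
  expect_false("outG" %in% tab$gene)
})

test_that("self-repeat masks recover planted duplications only", {
  set.seed(307)
  g0 <- rand_seq(20000)
  seg <- substr(g0, 3001, 4000)
  g <- paste0(substr(g0, 1, 12000), seg, substr(g0, 13001, 20000))
  mask <- self_repeats(genome_record("g", g), min_len = 500)
  expect_gte(nrow(mask), 2L)
  covers <- function(m, s, e) any(m[, 1] <= s + 25 & m[, 2] >= e - 25)
  expect_true(covers(mask, 3000, 4000))
  expect_true(covers(mask, 12000, 13000))
  # mask algebra: sorted, non-overlapping, in bounds
  expect_true(all(diff(mask[, 1]) > 0))
  expect_true(all(mask[-nrow(mask), 2] <= mask[-1, 1]))
  expect_true(all(mask[, 1] >= 0 & mask[, 2] <= nchar(g)))

  plain <- self_repeats(genome_record("r", rand_seq(15000)),
                        min_len = 200)
  expect_equal(nrow(plain), 0L)

  micro <- paste0(rand_seq(3000), strrep("AT", 150), rand_seq(3000))
  msat <- self_repeats(genome_record("m", micro), min_len = 100)
  expect_true(covers(msat, 3000, 3300))
})

test_that("hits crossing a circular origin are reported split", {
  set.seed(308)
  B <- rand_seq(6000)
  # insert wraps the origin of a 8000 bp circular query
  seg <- substr(B, 2001, 2400)
  bg <- rand_seq(8000)
  A <- paste0(substr(seg, 201, 400), substr(bg, 201, 7800),
              substr(seg, 1, 200))
  h <- find_hits(genome_record("A", A, circular = TRUE),
                 genome_record("B", B))
  split_rows <- h[h$origin_split, ]
  expect_equal(nrow(split_rows), 2L)
  expect_equal(length(unique(split_rows$hit_id)), 1L)
  spans <- sum(split_rows$query_end - split_rows$query_start)
  expect_gte(spans, 395)
})
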