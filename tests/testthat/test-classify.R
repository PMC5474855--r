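test_that("base classification follows the four-way coverage rule", {
  bl <- classify_bases(cov_set(chr = c(3L, 3L)), cov_set(chr = c(0L, 0L)))
  expect_identical(as.character(bl$labels$chr), c("S", "S"))
  expect_equal(unname(bl$fractions["S"]), 1)

  bl2 <- classify_bases(cov_set(chr = 2L), cov_set(chr = 5L))
  expect_identical(as.character(bl2$labels$chr), "COLLAPSED")

  bl3 <- classify_bases(cov_set(chr = 0L), cov_set(chr = 0L))
  expect_identical(as.character(bl3$labels$chr), "UNMAPPED")
  expect_equal(sum(bl3$fractions), 1)
})

test_that("fractions always partition the assembly", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    cs <- cov_set(a = rpois(n, 1), b = rpois(n, 2))
    ct <- cov_set(a = rpois(n, 2), b = rpois(n, 1))
    bl <- classify_bases(cs, ct)
    expect_equal(sum(bl$fractions), 1)
    expect_identical(sum(vapply(bl$labels, length, integer(1))), 2L * n)
  }
})

test_that("swapping the ancestor tracks swaps S and T only", {
  set.seed(6)
  cs <- cov_set(chr = rpois(300, 1))
  ct <- cov_set(chr = rpois(300, 1))
  a <- classify_bases(cs, ct)
  b <- classify_bases(ct, cs)
  map <- c(S = "T", T = "S", COLLAPSED = "COLLAPSED", UNMAPPED = "UNMAPPED")
  expect_identical(unname(map[as.character(a$labels$chr)]),
                   as.character(b$labels$chr))
})

test_that("track length or name mismatches are refused", {
  expect_error(classify_bases(cov_set(a = 1:3), cov_set(b = 1:3)), "differ")
  expect_error(classify_bases(cov_set(a = 1:3), cov_set(a = 1:4)), "differ")
})

test_that("binning uses half-open windows with a width-normalised tail", {
  d <- cov_set(chr = rep(7L, 120000L))
  b <- bin_density(d, 50000L)
  expect_identical(nrow(b), 3L)
  expect_identical(b$end - b$start + 1L, c(50000L, 50000L, 20000L))
  expect_true(all(b$value == 7))

  d2 <- cov_set(chr = c(rep(10L, 500L), rep(0L, 500L)))
  b2 <- bin_density(d2, 1000L)
  expect_equal(b2$value, 5)

  lab <- classify_bases(cov_set(chr = c(rep(1L, 600L), rep(0L, 400L))),
                        cov_set(chr = rep(0L, 1000L)))
  b3 <- bin_density(lab, 1000L)
  expect_equal(b3$value[b3$class == "S"], 0.6)
  expect_equal(sum(b3$value), 1)
})

test_that("genic overlap partitions class bases into exon/intron/non-genic", {
  genes <- data.frame(gene_id = "g1", seqid = "chr", start = 41L, end = 140L)
  exons <- data.frame(gene_id = "g1", seqid = "chr",
                      start = c(41L, 101L), end = c(80L, 140L))
  mk_labels <- function(cls_span, L = 200L) {
    v <- factor(rep("S", L), levels = c("S", "T", "COLLAPSED", "UNMAPPED"))
    v[cls_span] <- "UNMAPPED"
    structure(list(labels = list(chr = v)), class = "base_labels")
  }
  # 100-base class region: 40 exon (41:80), 30 intron (81:100 + 101..110 is
  # exon) -> use region 41:140 pieces: here region 51:150
  lab <- mk_labels(51:150)
  ov <- genic_overlap(lab, genes, exons, "UNMAPPED")
  expect_equal(ov$total, 100)
  expect_equal(unname(ov$counts["exon"]), 30 + 40)   # 51:80 and 101:140
  expect_equal(unname(ov$counts["intron"]), 20)      # 81:100
  expect_equal(unname(ov$counts["non_genic"]), 10)   # 141:150
  expect_equal(sum(ov$fractions), 1)

  # fully inside one exon
  ov2 <- genic_overlap(mk_labels(45:60), genes, exons, "UNMAPPED")
  expect_equal(unname(ov2$fractions["exon"]), 1)

  # no genes on the sequence
  ov3 <- genic_overlap(mk_labels(45:60), genes[0, ], exons[0, ], "UNMAPPED")
  expect_equal(unname(ov3$fractions["non_genic"]), 1)
})

test_that("genic overlap is invariant to region splitting and record order", {
  genes <- data.frame(gene_id = c("g1", "g2"), seqid = "chr",
                      start = c(41L, 300L), end = c(140L, 420L))
  exons <- data.frame(gene_id = c("g1", "g1", "g2"), seqid = "chr",
                      start = c(41L, 101L, 300L), end = c(80L, 140L, 360L))
  v <- factor(rep("S", 500L), levels = c("S", "T", "COLLAPSED", "UNMAPPED"))
  v[c(51:150, 280:340)] <- "UNMAPPED"
  lab <- structure(list(labels = list(chr = v)), class = "base_labels")
  ov1 <- genic_overlap(lab, genes, exons, "UNMAPPED")
  ov2 <- genic_overlap(lab, genes[2:1, ], exons[c(3, 1, 2), ], "UNMAPPED")
  expect_equal(ov1$counts, ov2$counts)
})

test_that("exons outside their gene span are an error", {
  genes <- data.frame(gene_id = "g1", seqid = "chr", start = 41L, end = 140L)
  exons <- data.frame(gene_id = "g1", seqid = "chr", start = 30L, end = 80L)
  v <- factor(rep("UNMAPPED", 200L),
              levels = c("S", "T", "COLLAPSED", "UNMAPPED"))
  lab <- structure(list(labels = list(chr = v)), class = "base_labels")
  expect_error(genic_overlap(lab, genes, exons, "UNMAPPED"), "malformed")
})

test_that("the enrichment test matches the closed-form statistic", {
  eq <- enrichment_test(c(70, 30), c(0.7, 0.3))
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)

  ht <- enrichment_test(c(98, 2), c(0.7, 0.3))
  expect_equal(unname(ht$statistic), 784 / 70 + 784 / 30, tolerance = 1e-12)
  expect_equal(unname(ht$statistic), 37.333, tolerance = 1e-4)
  expect_identical(unname(ht$parameter), 1L)
})

test_that("the enrichment test agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    obs <- sample(5:200, k, replace = TRUE)
    p <- runif(k) + 0.1
    p <- p / sum(p)
    mine <- enrichment_test(obs, p)
    ref <- suppressWarnings(stats::chisq.test(obs, p = p))
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(mine$parameter), unname(ref$parameter))
  }
})

test_that("degenerate enrichment inputs are refused", {
  expect_error(enrichment_test(c(10, 5), c(1, 0)), "merge categories")
  expect_error(enrichment_test(c(10, 5), c(0.6, 0.6)), "sum to 1")
  expect_error(enrichment_test(c(-1, 5), c(0.5, 0.5)), ">= 0")
})

test_that("scaffold origin calls use strict 50%/10% thresholds", {
  mk <- function(s_frac, t_frac, L = 1000L) {
    list(S = cov_set(chr = as.integer(seq_len(L) <= s_frac * L)),
         T = cov_set(chr = as.integer(seq_len(L) <= t_frac * L)))
  }
  x <- mk(0.60, 0.05)
  expect_identical(call_scaffold_origin(x$S, x$T)$call, "S")
  x <- mk(0.60, 0.15)
  expect_identical(call_scaffold_origin(x$S, x$T)$call, "UNDETERMINED")
  x <- mk(0.50, 0.05)
  expect_identical(call_scaffold_origin(x$S, x$T)$call, "UNDETERMINED")
  x <- mk(0.05, 0.70)
  expect_identical(call_scaffold_origin(x$S, x$T)$call, "T")
})
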