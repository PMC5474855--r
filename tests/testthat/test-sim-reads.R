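test_that("read count per sequence is length x depth / read length", {
  cfg <- small_config(scaffold_length = 1000L, depth = 10, read_length = 100L,
                      gene_density = 1)
  genome <- c(chr = paste(rep("ACGT", 250), collapse = ""))
  rd <- simulate_reads(genome, cfg)
  expect_identical(nrow(rd), 100L)
  expect_true(all(nchar(rd$seq) == 100L))
  expect_false(anyDuplicated(rd$id) > 0)
})

test_that("error-free reads are exact substrings after strand normalisation", {
  cfg <- small_config(error_rate = 0, scaffold_length = 5000L,
                      read_length = 60L, depth = 3)
  anc <- simulate_ancestral_genomes(cfg)
  rd <- simulate_reads(anc$S, cfg)
  for (i in sample(nrow(rd), 25)) {
    fwd <- if (rd$strand[i] == "+") rd$seq[i] else revcomp_plain(rd$seq[i])
    src <- substr(anc$S[[rd$source_seq[i]]], rd$source_start[i],
                  rd$source_start[i] + 59L)
    expect_identical(fwd, src)
  }
})

test_that("sequencing errors appear at the requested rate", {
  cfg <- small_config(error_rate = 0.02, scaffold_length = 5000L,
                      read_length = 100L, depth = 2)
  anc <- simulate_ancestral_genomes(cfg)
  rd <- simulate_reads(anc$S, cfg)
  mm <- 0L
  for (i in seq_len(nrow(rd))) {
    fwd <- if (rd$strand[i] == "+") rd$seq[i] else revcomp_plain(rd$seq[i])
    src <- substr(anc$S[[rd$source_seq[i]]], rd$source_start[i],
                  rd$source_start[i] + 99L)
    mm <- mm + sum(strsplit(fwd, "")[[1]] != strsplit(src, "")[[1]])
  }
  expected <- nrow(rd) * 100 * 0.02
  expect_gt(mm, 0.5 * expected)
  expect_lt(mm, 1.5 * expected)
})

test_that("reads longer than every sequence are rejected", {
  cfg <- small_config(read_length = 200L)
  expect_error(simulate_reads(c(chr = random_seq(150)), cfg), "read_length")
})

test_that("a read matching a unique locus maps there without mismatches", {
  set.seed(1)
  asm <- c(chr1 = random_seq(3000), chr2 = random_seq(2000))
  read <- substr(asm[["chr2"]], 501, 600)
  rd <- data.frame(id = "r1", seq = read, stringsAsFactors = FALSE)
  aln <- map_reads(rd, asm)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$target, "chr2")
  expect_identical(aln$start, 501L)
  expect_identical(aln$mismatches, 0L)
  expect_identical(aln$strand, "+")
})

test_that("reverse-strand reads map to the forward locus", {
  set.seed(2)
  asm <- c(chr = random_seq(2000))
  read <- revcomp_plain(substr(asm[["chr"]], 301, 400))
  aln <- map_reads(data.frame(id = "r1", seq = read), asm)
  expect_identical(aln$start, 301L)
  expect_identical(aln$strand, "-")
})

test_that("reads beyond the mismatch limit are not reported", {
  set.seed(3)
  asm <- c(chr = random_seq(2000))
  read5 <- mutate_seq(substr(asm[["chr"]], 101, 200), 5L)
  read6 <- mutate_seq(substr(asm[["chr"]], 101, 200), 6L)
  a5 <- map_reads(data.frame(id = "r", seq = read5), asm, max_mismatches = 5)
  a6 <- map_reads(data.frame(id = "r", seq = read6), asm, max_mismatches = 5)
  expect_identical(nrow(a5), 1L)
  expect_lte(a5$mismatches, 5L)
  expect_identical(nrow(a6), 0L)
})

test_that("multi-mapping reads get one seeded, reproducible placement", {
  set.seed(4)
  unit <- random_seq(120)
  asm <- c(chr = paste0(unit, random_seq(500), unit))
  read <- substr(unit, 11, 110)
  rd <- data.frame(id = "r1", seq = read)
  a1 <- map_reads(rd, asm, seed = 9L)
  a2 <- map_reads(rd, asm, seed = 9L)
  expect_identical(nrow(a1), 1L)
  expect_true(a1$start %in% c(11L, 631L))
  expect_identical(a1, a2)
})

test_that("degenerate mapper inputs raise errors", {
  rd <- data.frame(id = "r1", seq = "ACGTACGT")
  expect_error(map_reads(rd, character(0)), "empty assembly")
  asm <- c(a = random_seq(100), a = random_seq(100))
  expect_error(map_reads(rd, asm), "duplicate")
})

test_that("the seeded mapper agrees with an all-position Hamming scan", {
  set.seed(11)
  for (rep in 1:4) {
    asm <- c(c1 = random_seq(sample(2000:4000, 1)),
             c2 = random_seq(sample(1000:3000, 1)))
    n <- 40L
    reads <- data.frame(
      id = sprintf("r%03d", seq_len(n)),
      seq = vapply(seq_len(n), function(i) {
        nm <- sample(names(asm), 1)
        st <- sample(nchar(asm[[nm]]) - 49L, 1)
        mutate_seq(substr(asm[[nm]], st, st + 49L), sample(0:7, 1))
      }, character(1)), stringsAsFactors = FALSE)
    aln <- map_reads(reads, asm, max_mismatches = 5)
    for (i in seq_len(n)) {
      oracle <- brute_force_best(reads$seq[i], asm)
      hit <- aln[aln$read_id == reads$id[i], ]
      if (oracle$mm > 5) {
        expect_identical(nrow(hit), 0L)
      } else {
        expect_identical(nrow(hit), 1L)
        expect_identical(hit$mismatches, as.integer(oracle$mm))
        if (length(oracle$hits) == 1L) {
          expect_identical(hit$target, oracle$hits[[1]]$target)
          expect_identical(hit$start, as.integer(oracle$hits[[1]]$start))
          expect_identical(hit$strand, oracle$hits[[1]]$strand)
        }
      }
    }
  }
})
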