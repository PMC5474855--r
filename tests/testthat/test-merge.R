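test_that("a short gap flanked by perfect HSPs is filled", {
  cs <- gap_case(gap_len = 8L, flank = 96L)   # 200 bp contig
  m <- merge_wgp(cs$assembly, cs$contigs, cs$hsps)
  d <- m$decisions
  expect_identical(d$action, "FILL_GAP")
  expect_equal(d$measure, 8)
  expect_identical(m$assembly[["tgt"]],
                   paste0(substr(cs$assembly[["tgt"]], 1, 300), cs$interior,
                          substr(cs$assembly[["tgt"]], 309, 608)))
  expect_false(grepl("N", m$assembly[["tgt"]]))
})

test_that("a 50-bp gap fails the length rule for a 200-bp contig", {
  cs <- gap_case(gap_len = 50L, flank = 75L)   # 200 bp contig, 50/200 = 25%
  m <- merge_wgp(cs$assembly, cs$contigs, cs$hsps)
  expect_identical(m$decisions$action, "REJECT")
  expect_identical(m$decisions$rule, "length_rule")
  # the gap is untouched and the contig is appended
  expect_identical(substr(m$assembly[["tgt"]], 301, 350), strrep("N", 50))
  expect_true("c1" %in% names(m$assembly))
})

test_that("a 50-bp gap passes the 10% rule for a 600-bp contig", {
  cs <- gap_case(gap_len = 50L, flank = 275L)  # 600 bp contig, 8.3% < 10%
  m <- merge_wgp(cs$assembly, cs$contigs, cs$hsps)
  expect_identical(m$decisions$action, "FILL_GAP")
})

test_that("flanking identity below 95% rejects the fill", {
  cs <- gap_case(gap_len = 8L, flank = 100L, flank_mm = 10L)  # 90% identity
  m <- merge_wgp(cs$assembly, cs$contigs, cs$hsps)
  expect_identical(m$decisions$action, "REJECT")
  expect_identical(m$decisions$rule, "identity_below_95")
})

test_that("conflicting contigs resolve by coverage then shortest overhang", {
  c1 <- gap_case(gap_len = 8L, flank = 150L, interior_len = 30L,
                 contig_id = "cA", seed = 5L)
  c2 <- gap_case(gap_len = 8L, flank = 150L, interior_len = 5L,
                 contig_id = "cB", seed = 5L)
  m <- merge_wgp(c1$assembly, c(c1$contigs, c2$contigs),
                 rbind(c1$hsps, c2$hsps))
  d <- m$decisions
  expect_identical(d$action[d$contig == "cB"], "FILL_GAP")
  expect_identical(d$action[d$contig == "cA"], "REJECT")
  expect_identical(d$rule[d$contig == "cA"], "conflict")
  expect_identical(substr(m$assembly[["tgt"]], 301, 305), c2$interior)
})

test_that("contigs without HSPs are appended and logged", {
  cs <- gap_case(gap_len = 8L, flank = 96L)
  contigs <- c(cs$contigs, orphan = random_seq(120))
  m <- merge_wgp(cs$assembly, contigs, cs$hsps)
  expect_identical(nrow(m$decisions), 2L)
  expect_identical(m$decisions$action[m$decisions$contig == "orphan"],
                   "APPEND")
  expect_identical(m$assembly[["orphan"]], contigs[["orphan"]])
})

test_that("merging preserves untouched bases and never loses defined bases", {
  set.seed(31)
  inst <- make_merge_instance(n_gaps = 4L, n_contigs = 6L)
  m <- merge_wgp(inst$assembly, inst$contigs, inst$hsps)
  expect_identical(nrow(m$decisions), length(inst$contigs))
  expect_gte(count_defined_bases(m$assembly),
             count_defined_bases(c(inst$assembly, inst$contigs)) -
               count_defined_bases(inst$contigs))
  # every non-N stretch of the input target survives verbatim
  tgt_in <- inst$assembly[["tgt"]]
  tgt_out <- m$assembly[["tgt"]]
  for (piece in strsplit(tgt_in, "N+")[[1]]) {
    expect_true(grepl(piece, tgt_out, fixed = TRUE))
  }
  # rerunning reproduces the decision log exactly
  m2 <- merge_wgp(inst$assembly, inst$contigs, inst$hsps)
  expect_identical(m$decisions, m2$decisions)
})

test_that("accepted (contig, gap) pairs equal the exhaustive oracle's", {
  set.seed(33)
  for (i in 1:6) {
    inst <- make_merge_instance(n_gaps = sample(1:6, 1),
                                n_contigs = sample(2:8, 1))
    m <- merge_wgp(inst$assembly, inst$contigs, inst$hsps)
    got <- m$decisions[m$decisions$action == "FILL_GAP", ]
    expect_identical(sort(paste(got$contig, got$gap_start)),
                     merge_oracle(inst$meta))
  }
})
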