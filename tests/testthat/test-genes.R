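one_gene <- data.frame(gene_id = "g1", seqid = "chr", start = 1L, end = 100L,
                       stringsAsFactors = FALSE)

const_cov <- function(depth_s, depth_t, frac_s = 1, frac_t = 1, L = 100L) {
  mk <- function(d, f) {
    v <- integer(L)
    v[seq_len(round(f * L))] <- as.integer(d)
    v
  }
  list(S = cov_set(chr = mk(depth_s, frac_s)), T = cov_set(chr = mk(depth_t, frac_t)))
}

test_that("firm origin calls need half coverage and double depth", {
  cv <- const_cov(20, 8, frac_s = 0.6, frac_t = 0.6)
  calls <- assign_gene_origin(one_gene, cv$S, cv$T)
  expect_identical(calls$call, "S")   # mean 12 vs 4.8: covered 60%, >= 2x

  # higher covered fraction and mean-depth difference >= 10, but below 2x
  # (means 25.2 vs 14.3 over the gene)
  cv2 <- const_cov(36, 22, frac_s = 0.7, frac_t = 0.65)
  calls2 <- assign_gene_origin(one_gene, cv2$S, cv2$T)
  expect_identical(calls2$call, "PUTATIVE_S")

  cv3 <- const_cov(0, 0)
  calls3 <- assign_gene_origin(one_gene, cv3$S, cv3$T)
  expect_identical(calls3$call, "UNMAPPED")

  cv4 <- const_cov(10, 10)
  calls4 <- assign_gene_origin(one_gene, cv4$S, cv4$T)
  expect_identical(calls4$call, "COLLAPSED")
})

test_that("every gene receives exactly one call and swapping tracks mirrors it", {
  sim <- study_sim()
  calls <- assign_gene_origin(sim$genes, sim$covS, sim$covT)
  expect_identical(nrow(calls), nrow(sim$genes))
  expect_false(any(is.na(calls$call)))
  swapped <- assign_gene_origin(sim$genes, sim$covT, sim$covS)
  map <- c(S = "T", T = "S", PUTATIVE_S = "PUTATIVE_T",
           PUTATIVE_T = "PUTATIVE_S", COLLAPSED = "COLLAPSED",
           UNMAPPED = "UNMAPPED")
  expect_identical(unname(map[calls$call]), swapped$call)
})

test_that("zero-length genes are an error", {
  g <- data.frame(gene_id = "g0", seqid = "chr", start = 10L, end = 10L)
  cv <- const_cov(1, 1)
  expect_error(assign_gene_origin(g, cv$S, cv$T), "g0")
})

pile_of <- function(counts_s, counts_t) {
  L <- ncol(counts_s)
  list(S = structure(list(chr = counts_s), class = "pileup_set"),
       T = structure(list(chr = counts_t), class = "pileup_set"))
}

one_col <- function(A = 0, C = 0, G = 0, T = 0) {
  matrix(as.integer(c(A, C, G, T)), nrow = 4,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

test_that("diagnostic sites need depth, purity and differing consensus", {
  p <- pile_of(one_col(A = 10), one_col(G = 8))
  s <- find_diagnostic_sites(p$S, p$T)
  expect_identical(nrow(s), 1L)
  expect_identical(s$s_allele, "A")
  expect_identical(s$t_allele, "G")

  # purity 0.5 < 0.9 on the S side
  p2 <- pile_of(one_col(A = 5, G = 5), one_col(G = 8))
  expect_identical(nrow(find_diagnostic_sites(p2$S, p2$T)), 0L)

  # both ancestors agree -> not diagnostic
  p3 <- pile_of(one_col(C = 10), one_col(C = 8))
  expect_identical(nrow(find_diagnostic_sites(p3$S, p3$T)), 0L)

  # depth below the site minimum
  p4 <- pile_of(one_col(A = 4), one_col(G = 8))
  expect_identical(nrow(find_diagnostic_sites(p4$S, p4$T)), 0L)
})

test_that("collapsed genes are rescued by majority diagnostic sites", {
  calls <- data.frame(gene_id = "g1", seqid = "chr", start = 1L, end = 100L,
                      call = "COLLAPSED", stringsAsFactors = FALSE)
  asm <- c(chr = strrep("A", 100))
  mk_sites <- function(n_s, n_t) {
    n <- n_s + n_t
    data.frame(seqid = rep("chr", n), pos = seq_len(n),
               s_allele = c(rep("A", n_s), rep("C", n_t)),
               t_allele = c(rep("G", n_s), rep("A", n_t)),
               s_depth = rep(10L, n), t_depth = rep(10L, n),
               stringsAsFactors = FALSE)
  }
  # 9 of 10 sites match the S allele
  out <- assign_collapsed_genes(calls, mk_sites(9L, 1L), asm)
  expect_identical(out$call, "COLLAPSED_PUTATIVE_S")
  expect_identical(out$n_match_s, 9L)

  # 2 matching sites fail min_sites = 3
  out2 <- assign_collapsed_genes(calls, mk_sites(0L, 2L), asm)
  expect_identical(out2$call, "COLLAPSED")

  # no sites at all
  out3 <- assign_collapsed_genes(calls, mk_sites(0L, 0L), asm)
  expect_identical(out3$call, "COLLAPSED")

  # non-collapsed calls are never touched
  calls$call <- "S"
  out4 <- assign_collapsed_genes(calls, mk_sites(9L, 1L), asm)
  expect_identical(out4$call, "S")
})

expr_grid <- function(tpms) {
  # tpms: named list tissue -> matrix timepoints x 3 reps for one gene
  do.call(rbind, lapply(names(tpms), function(ti) {
    m <- tpms[[ti]]
    data.frame(gene_id = "g1", tissue = ti,
               timepoint = paste0("ZT", seq_len(nrow(m))),
               rep1 = m[, 1], rep2 = m[, 2], rep3 = m[, 3],
               stringsAsFactors = FALSE)
  }))
}

test_that("a gene is expressed iff all three replicates pass at one time-point", {
  e <- expr_grid(list(root = rbind(c(1.0, 1.2, 3.0), c(0, 0, 0)),
                      shoot = rbind(c(0.9, 5.0, 5.0), c(0.9, 5.0, 5.0))))
  fl <- flag_expressed(e, threshold = 1)
  expect_identical(fl$per_tissue$root, "g1")
  expect_identical(fl$per_tissue$shoot, character(0))
  expect_identical(fl$n_expressed_any, 1L)
  expect_identical(fl$n_expressed_all, 0L)

  zero <- expr_grid(list(root = rbind(c(0, 0, 0)), shoot = rbind(c(0, 0, 0))))
  fl0 <- flag_expressed(zero)
  expect_identical(fl0$n_expressed_any, 0L)
})

test_that("raising the TPM threshold never adds an expressed gene", {
  cfg <- small_config()
  expr <- simulate_expression(sprintf("g%03d", 1:40), cfg)
  prev <- NULL
  for (th in c(0.5, 1, 2, 5)) {
    cur <- flag_expressed(expr, threshold = th)
    if (!is.null(prev)) {
      for (ti in names(cur$per_tissue)) {
        expect_true(all(cur$per_tissue[[ti]] %in% prev$per_tissue[[ti]]))
      }
    }
    prev <- cur
  }
})

test_that("incomplete replicate sets are refused", {
  e <- expr_grid(list(root = rbind(c(1, 1, 1))))
  e$rep3 <- NA_real_
  expect_error(flag_expressed(e), "3 replicates")
  dup <- rbind(e, e)
  expect_error(flag_expressed(dup), "3 replicates")
})
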