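# Constructive toy instances for the WGP merge: a target sequence with known
# N-gaps and contigs built from the true flanks, with controlled flank
# identities, so acceptance can be predicted by direct rule application
# without going through the HSP machinery.

FLANK <- 150L

# builds a target with one N-gap and a contig whose flanks align 1:1 around
# it; flank identities and interior length are controlled exactly
gap_case <- function(gap_len, flank, interior_len = gap_len,
                     flank_mm = 0L, contig_id = "c1", seed = 1L) {
  set.seed(seed)
  left <- random_seq(300)
  right <- random_seq(300)
  target <- paste0(left, strrep("N", gap_len), right)
  lf <- substr(left, 300 - flank + 1L, 300)
  rf <- substr(right, 1L, flank)
  interior <- random_seq(interior_len)
  contig <- paste0(mutate_seq(lf, flank_mm), interior, mutate_seq(rf, flank_mm))
  clen <- nchar(contig)
  ident <- 100 * (flank - flank_mm) / flank
  hsps <- parse_hsps(rbind(
    data.frame(qseqid = contig_id, sseqid = "tgt", pident = ident,
               length = flank, mismatch = flank_mm, gapopen = 0L, qstart = 1L,
               qend = flank, sstart = 300L - flank + 1L, send = 300L,
               evalue = 0, bitscore = 100),
    data.frame(qseqid = contig_id, sseqid = "tgt", pident = ident,
               length = flank, mismatch = flank_mm, gapopen = 0L,
               qstart = flank + interior_len + 1L, qend = clen,
               sstart = 300L + gap_len + 1L, send = 300L + gap_len + flank,
               evalue = 0, bitscore = 100)))
  list(assembly = c(tgt = target), contigs = stats::setNames(contig, contig_id),
       hsps = hsps, interior = interior, gap_start = 301L,
       gap_end = 300L + gap_len)
}

# returns list(assembly, contigs, hsps, meta) where meta has one row per
# (contig, gap) candidate with the values the rules test
make_merge_instance <- function(n_gaps = 3L, n_contigs = 4L) {
  gap_len <- sample(3:60, n_gaps, replace = TRUE)
  block <- random_seq(400L)
  pieces <- character(0)
  gap_start <- integer(n_gaps)
  pos <- 0L
  seqs <- list()
  for (g in seq_len(n_gaps)) {
    left <- random_seq(400L)
    pieces <- c(pieces, left)
    pos <- pos + 400L
    gap_start[g] <- pos + 1L
    pieces <- c(pieces, strrep("N", gap_len[g]))
    pos <- pos + gap_len[g]
  }
  pieces <- c(pieces, random_seq(400L))
  target <- paste(pieces, collapse = "")

  meta <- list()
  contigs <- character(0)
  hsps <- list()
  # candidate contigs: each addresses one gap; duplicates create conflicts
  gap_of <- sample(seq_len(n_gaps), n_contigs, replace = TRUE)
  for (ci in seq_len(n_contigs)) {
    g <- gap_of[ci]
    gs <- gap_start[g]
    ge <- gs + gap_len[g] - 1L
    # flank lengths vary so chain coverages differ and conflicts resolve
    # without ties
    fl <- FLANK + sample(0:40, 1L)
    fr <- FLANK + sample(0:40, 1L)
    left_t <- substr(target, gs - fl, gs - 1L)
    right_t <- substr(target, ge + 1L, ge + fr)
    # contig carries its own version of the gap interior
    interior <- random_seq(gap_len[g])
    mml <- sample(c(0L, 0L, 0L, as.integer(round(fl * 0.08))), 1L)
    mmr <- sample(c(0L, 0L, as.integer(round(fr * 0.08))), 1L)
    cseq <- paste0(mutate_seq(left_t, mml), interior, mutate_seq(right_t, mmr))
    cid <- sprintf("wgp%02d", ci)
    contigs[cid] <- cseq
    clen <- nchar(cseq)
    idl <- 100 * (fl - mml) / fl
    idr <- 100 * (fr - mmr) / fr
    hsps[[length(hsps) + 1L]] <- data.frame(
      qseqid = cid, sseqid = "tgt", pident = round(idl, 2), length = fl,
      mismatch = mml, gapopen = 0L, qstart = 1L, qend = fl,
      sstart = gs - fl, send = gs - 1L, evalue = 0, bitscore = 2 * fl,
      stringsAsFactors = FALSE)
    hsps[[length(hsps) + 1L]] <- data.frame(
      qseqid = cid, sseqid = "tgt", pident = round(idr, 2), length = fr,
      mismatch = mmr, gapopen = 0L, qstart = fl + gap_len[g] + 1L,
      qend = clen, sstart = ge + 1L, send = ge + fr, evalue = 0,
      bitscore = 2 * fr, stringsAsFactors = FALSE)
    meta[[ci]] <- data.frame(
      contig = cid, gap = g, gap_start = gs, gap_len = gap_len[g],
      contig_len = clen, identity = min(idl, idr), coverage = fl + fr,
      overhang = clen - fl - fr, stringsAsFactors = FALSE)
  }
  list(assembly = c(tgt = target), contigs = contigs,
       hsps = parse_hsps(do.call(rbind, hsps)),
       meta = do.call(rbind, meta))
}

# exhaustive oracle: which (contig, gap) pairs must be accepted, by direct
# application of the identity, length and conflict rules to the metadata
merge_oracle <- function(meta, min_identity = 95, max_abs = 10,
                         max_frac = 0.1) {
  m <- meta
  m$pass <- m$identity >= min_identity &
    (m$gap_len < max_abs | m$gap_len < max_frac * m$contig_len)
  acc <- m[m$pass, , drop = FALSE]
  acc <- acc[order(acc$gap, -acc$coverage, acc$overhang, acc$contig), ]
  acc <- acc[!duplicated(acc$gap), , drop = FALSE]
  sort(paste(acc$contig, acc$gap_start))
}
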