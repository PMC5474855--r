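#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences (names truncated at the first
#'   whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_plain_seqs(x)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- if (inherits(seqs, "DNAStringSet")) seqs else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits gene / mRNA / exon features; exon coordinates come from the exon
#' table, the mRNA spans the gene.
#' @param genes Gene table (gene_id, seqid, start, end, strand).
#' @param exons Exon table (gene_id, seqid, start, end).
#' @param path Output file.
#' @export
write_gff3 <- function(genes, exons, path) {
  rows <- character(0)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    e <- exons[exons$gene_id == gid, ]
    e <- e[order(e$start), ]
    rows <- c(rows,
      sprintf("%s\tpolyorigin\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              genes$seqid[i], genes$start[i], genes$end[i], genes$strand[i], gid),
      sprintf("%s\tpolyorigin\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              genes$seqid[i], genes$start[i], genes$end[i], genes$strand[i],
              gid, gid),
      sprintf("%s\tpolyorigin\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
              e$seqid, e$start, e$end, genes$strand[i], gid,
              seq_len(nrow(e)), gid))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 file with gene / mRNA / exon features.
#' @return List with \code{genes} and \code{exons} tables.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  g <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = g$ID, seqid = as.character(g$seqnames),
                      start = g$start, end = g$end,
                      strand = as.character(g$strand), stringsAsFactors = FALSE)
  e <- df[df$type == "exon", ]
  parent <- vapply(e$Parent, `[`, character(1), 1L)
  exons <- data.frame(gene_id = sub("\\.t1$", "", parent),
                      seqid = as.character(e$seqnames),
                      start = e$start, end = e$end, stringsAsFactors = FALSE)
  exons <- exons[order(exons$seqid, exons$gene_id, exons$start), ]
  rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write alignments as SAM text
#'
#' Plain 11-column SAM v1 with an NM tag carrying the mismatch count; FLAG is
#' 0 or 16 (reverse strand), CIGAR is full-length match (substitution-only
#' alignments).
#' @param alignments An \code{alignments} data.frame.
#' @param seqlengths Named lengths of the target sequences (for \verb{@SQ}).
#' @param path Output file.
#' @export
write_sam <- function(alignments, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  a <- alignments
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  a$read_id, ifelse(a$strand == "-", 16L, 0L), a$target,
                  a$start, a$aln_length, a$seq, a$mismatches)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignments table
#' @param path SAM file (text; mapped, substitution-only records).
#' @return An \code{alignments} data.frame.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L) return(empty_alignments())
  f <- strsplit(ln, "\t", fixed = TRUE)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag) == 0L) NA_integer_ else as.integer(sub("NM:i:", "", tag[1]))
  }, integer(1))
  flag <- as.integer(vapply(f, `[`, character(1), 2L))
  sq <- vapply(f, `[`, character(1), 10L)
  out <- data.frame(
    read_id = vapply(f, `[`, character(1), 1L),
    target = vapply(f, `[`, character(1), 3L),
    start = as.integer(vapply(f, `[`, character(1), 4L)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mismatches = nm, aln_length = nchar(sq), seq = sq,
    stringsAsFactors = FALSE)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Write a coverage track as bedGraph
#' @param cov A \code{coverage_set}.
#' @param path Output file.
#' @export
write_bedgraph <- function(cov, path) {
  rows <- lapply(names(cov), function(nm) {
    runs <- label_runs(cov[[nm]])
    # 0-based half-open intervals, as the format requires
    sprintf("%s\t%d\t%d\t%s", nm, runs$start - 1L, runs$end, runs$label)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write per-base labels as a BED file of constant-label runs
#' @param labels A \code{base_labels} object or a named list of label vectors.
#' @param path Output file.
#' @export
write_label_bed <- function(labels, path) {
  lab <- if (inherits(labels, "base_labels")) labels$labels else labels
  rows <- lapply(names(lab), function(nm) {
    runs <- label_runs(lab[[nm]])
    sprintf("%s\t%d\t%d\t%s\t0\t.", nm, runs$start - 1L, runs$end, runs$label)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Read a label BED back into per-sequence label vectors
#' @param path BED file written by [write_label_bed()].
#' @param seqlengths Named sequence lengths.
#' @return Named list of character label vectors.
#' @export
read_label_bed <- function(path, seqlengths) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(names(seqlengths), function(nm) {
    v <- character(as.integer(seqlengths[[nm]]))
    b <- bed[bed[[1]] == nm, ]
    for (j in seq_len(nrow(b))) v[(b[[2]][j] + 1L):b[[3]][j]] <- b[[4]][j]
    v
  })
  names(out) <- names(seqlengths)
  out
}

#' Simulate a TPM expression table
#'
#' Emulates a multi-tissue RNA-seq design: three tissues, four time-points,
#' three biological replicates. Per gene and tissue a lognormal baseline is
#' drawn; a fraction of gene x tissue combinations is silent; replicate TPMs
#' scatter around the baseline with gamma noise.
#'
#' @param gene_ids Character vector of gene ids.
#' @param config A [sim_config()] (only the seed is used).
#' @param tissues,timepoints Design factors.
#' @param silent_fraction Fraction of gene x tissue pairs with no expression.
#' @return Long-format data.frame: gene_id, tissue, timepoint, rep1..rep3.
#' @export
simulate_expression <- function(gene_ids, config,
                                tissues = c("root", "shoot", "apex"),
                                timepoints = c("ZT0", "ZT6", "ZT12", "ZT18"),
                                silent_fraction = 0.1) {
  set.seed(config$seed + 30L)
  grid <- expand.grid(gene_id = gene_ids, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$base <- rlnorm(nrow(grid), meanlog = 2, sdlog = 1.5)
  grid$base[runif(nrow(grid)) < silent_fraction] <- 0
  out <- do.call(rbind, lapply(timepoints, function(tp) {
    g <- grid
    g$timepoint <- tp
    mu <- g$base * exp(stats::rnorm(nrow(g), 0, 0.2))
    reps <- vapply(1:3, function(r) {
      ifelse(mu > 0, rgamma(nrow(g), shape = 25, rate = 25 / pmax(mu, 1e-9)), 0)
    }, numeric(nrow(g)))
    data.frame(gene_id = g$gene_id, tissue = g$tissue, timepoint = tp,
               rep1 = reps[, 1], rep2 = reps[, 2], rep3 = reps[, 3],
               stringsAsFactors = FALSE)
  }))
  out[order(out$gene_id, out$tissue, out$timepoint), ]
}

#' Write all simulator artifacts to a directory
#'
#' Emits the assembly and ancestor FASTAs, GFF3 gene models, per-ancestor SAM
#' and bedGraph, the truth labels as a BED of constant-label runs, the
#' per-gene truth table, and a TPM table. Every file round-trips through the
#' package readers losslessly.
#'
#' @param sim Output of [simulate_tetraploid()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  cfg <- sim$config
  p <- function(f) file.path(out_dir, f)
  seqlen <- seqlengths_of(sim$assembly)
  exons <- gene_exons(sim$genes, cfg)

  write_fasta(sim$assembly, p("assembly.fasta"))
  write_fasta(sim$ancestors$S, p("ancestor_S.fasta"))
  write_fasta(sim$ancestors$T, p("ancestor_T.fasta"))
  write_gff3(sim$genes, exons, p("genes.gff3"))
  write_label_bed(sim$truth, p("truth.bed"))
  utils::write.table(sim$gene_truth, p("gene_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (anc in c("S", "T")) {
    write_sam(sim$alignments[[anc]], seqlen,
              p(sprintf("alignments_%s.sam", anc)))
    write_bedgraph(compute_depth(sim$alignments[[anc]], seqlen),
                   p(sprintf("coverage_%s.bedgraph", anc)))
  }
  expr <- simulate_expression(sim$genes$gene_id, cfg)
  utils::write.table(expr, p("tpm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(assembly = p("assembly.fasta"), ancestor_S = p("ancestor_S.fasta"),
             ancestor_T = p("ancestor_T.fasta"), genes = p("genes.gff3"),
             truth = p("truth.bed"), gene_truth = p("gene_truth.tsv"),
             sam_S = p("alignments_S.sam"), sam_T = p("alignments_T.sam"),
             bedgraph_S = p("coverage_S.bedgraph"),
             bedgraph_T = p("coverage_T.bedgraph"), tpm = p("tpm.tsv"))
  invisible(files)
}
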