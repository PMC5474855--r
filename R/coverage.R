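utils::globalVariables(c(
  ".", "ridx", "strand", "target", "start", "tpos", "off", "mm", "key",
  "qseqid", "sseqid"))

#' Per-base read depth from alignments, SAM or bedGraph
#'
#' Builds one coverage track per assembly sequence: \code{depth[i]} is the
#' number of alignments covering base \code{i}. Accepts an \code{alignments}
#' data.frame (from [map_reads()]), a SAM file, or a bedGraph file (expanded
#' verbatim to per-base depth).
#'
#' @param x Alignments data.frame, or path to a \code{.sam} / bedGraph file.
#' @param assembly Named sequences or named integer vector of sequence
#'   lengths; every alignment target must be present.
#' @return A \code{coverage_set}: named list of integer depth vectors.
#' @export
compute_depth <- function(x, assembly) {
  seqlen <- if (is.numeric(assembly)) assembly else seqlengths_of(as_plain_seqs(assembly))
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.sam$", x, ignore.case = TRUE)) {
      read_sam(x)
    } else {
      return(bedgraph_to_coverage(x, seqlen))
    }
  }
  aln <- x
  bad <- setdiff(unique(aln$target), names(seqlen))
  if (length(bad) > 0L) {
    stop("unknown alignment target(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  over <- aln$start + aln$aln_length - 1L > seqlen[aln$target] | aln$start < 1L
  if (any(over)) {
    stop("alignment beyond sequence end for read(s): ",
         paste(utils::head(aln$read_id[over], 3L), collapse = ", "),
         call. = FALSE)
  }
  cov <- lapply(names(seqlen), function(nm) {
    L <- as.integer(seqlen[[nm]])
    d <- integer(L + 1L)
    sel <- aln$target == nm
    if (any(sel)) {
      st <- aln$start[sel]
      en <- st + aln$aln_length[sel] - 1L
      d <- d + tabulate(st, nbins = L + 1L) - tabulate(en + 1L, nbins = L + 1L)
    }
    cumsum(d)[seq_len(L)]
  })
  names(cov) <- names(seqlen)
  structure(cov, class = "coverage_set")
}

bedgraph_to_coverage <- function(path, seqlen) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- lapply(names(seqlen), function(nm) {
    L <- as.integer(seqlen[[nm]])
    d <- integer(L)
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == nm]
    if (length(sel) > 0L) {
      st <- GenomicRanges::start(sel); en <- GenomicRanges::end(sel)
      sc <- as.integer(S4Vectors::mcols(sel)$score)
      for (j in seq_along(sel)) d[st[j]:en[j]] <- sc[j]
    }
    d
  })
  names(cov) <- names(seqlen)
  structure(cov, class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("Coverage over %d sequence(s), %s bp; mean depth %.2f\n",
              length(x), format(sum(lengths(x)), big.mark = ","),
              sum(vapply(x, sum, numeric(1))) / sum(lengths(x))))
  invisible(x)
}

#' Base-composition pileup from alignments
#'
#' Tallies, for every assembly position, how many aligned reads carry each of
#' A, C, G, T there (reads are substitution-only alignments, so read offset
#' maps directly to target offset). Used to find ancestor-diagnostic
#' polymorphic sites.
#'
#' @param alignments An \code{alignments} data.frame with the aligned read
#'   sequence in column \code{seq}, or a SAM path.
#' @param assembly Named sequences or named lengths.
#' @return A \code{pileup_set}: named list of 4 x L integer matrices with
#'   rows A, C, G, T.
#' @export
compute_pileup <- function(alignments, assembly) {
  seqlen <- if (is.numeric(assembly)) assembly else seqlengths_of(as_plain_seqs(assembly))
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_sam(alignments)
  }
  aln <- alignments
  out <- lapply(names(seqlen), function(nm) {
    L <- as.integer(seqlen[[nm]])
    sel <- which(aln$target == nm)
    counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
    if (length(sel) > 0L) {
      rl <- aln$aln_length[sel][1L]
      ch <- matrix(unlist(strsplit(aln$seq[sel], "", fixed = TRUE),
                          use.names = FALSE), nrow = rl)
      pos <- outer(0:(rl - 1L), aln$start[sel], `+`)
      code <- base_codes(as.vector(ch))
      ok <- !is.na(code)
      cell <- (as.vector(pos)[ok] - 1L) * 4L + code[ok]
      counts[] <- tabulate(cell, nbins = 4L * L)
    }
    counts
  })
  names(out) <- names(seqlen)
  structure(out, class = "pileup_set")
}
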