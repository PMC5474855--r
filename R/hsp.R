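#' Parse BLAST tabular (outfmt 6) high-scoring pairs
#'
#' Reads the standard 12-column tabular BLAST output. Minus-strand target
#' hits (sstart > send) are normalised to sstart < send with the strand
#' recorded.
#'
#' @param x Path to a BLAST outfmt-6 file, or a data.frame already holding the
#'   12 standard columns.
#' @return An \code{hsp_set} data.frame: qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore, strand.
#' @export
parse_hsps <- function(x) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (is.character(x) && length(x) == 1L) {
    ln <- readLines(x)
    ln <- ln[nzchar(ln)]
    if (length(ln) == 0L) {
      h <- as.data.frame(stats::setNames(
        rep(list(character(0)), 12L), cols), stringsAsFactors = FALSE)
      h$strand <- character(0)
      class(h) <- c("hsp_set", "data.frame")
      return(h)
    }
    f <- strsplit(ln, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 12L)
    if (length(bad) > 0L) {
      stop("malformed HSP row at line ", bad[1L], call. = FALSE)
    }
    m <- do.call(rbind, lapply(f, `[`, 1:12))
    h <- data.frame(m, stringsAsFactors = FALSE)
    names(h) <- cols
    num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
             "sstart", "send", "evalue", "bitscore")
    h[num] <- lapply(h[num], as.numeric)
    if (anyNA(h[num])) {
      stop("malformed HSP row at line ",
           which(rowSums(is.na(h[num])) > 0)[1L], call. = FALSE)
    }
  } else {
    h <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!all(cols %in% names(h))) {
      stop("HSP table must carry the 12 outfmt-6 columns", call. = FALSE)
    }
  }
  h$strand <- ifelse(h$sstart <= h$send, "+", "-")
  rev <- h$strand == "-"
  tmp <- h$sstart[rev]
  h$sstart[rev] <- h$send[rev]
  h$send[rev] <- tmp
  int <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  h[int] <- lapply(h[int], as.integer)
  class(h) <- c("hsp_set", "data.frame")
  h
}

# weighted longest-increasing-subsequence over target order for HSPs already
# sorted by query start; weight = query-aligned length. Returns row indices
# of the collinear chain.
collinear_chain <- function(sstart, weight, decreasing = FALSE) {
  n <- length(sstart)
  if (n == 0L) return(integer(0))
  key <- if (decreasing) -sstart else sstart
  best <- weight
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (key[j] < key[i] && best[j] + weight[i] > best[i]) {
        best[i] <- best[j] + weight[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  chain <- integer(0)
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  chain
}

# collinear HSP chain and query coverage for one (query, target, strand)
chain_for_target <- function(h) {
  h <- h[order(h$qstart, h$sstart), ]
  idx <- collinear_chain(h$sstart, h$qend - h$qstart + 1L,
                         decreasing = (h$strand[1L] == "-"))
  chain <- h[idx, ]
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(chain$qstart, chain$qend))))
  list(chain = chain, coverage = cov)
}

#' Select the best-matching target for a contig's HSPs
#'
#' Per candidate target, HSPs violating collinearity (monotone query and
#' target order, strand-aware) are dropped and the remaining chain is scored
#' by its query-length coverage. The top target wins only if every
#' alternative scores less than \code{ratio} times the best coverage;
#' otherwise the match is ambiguous.
#'
#' @param hsps \code{hsp_set} rows for one query contig.
#' @param min_identity Identity floor (percent) applied before scoring.
#' @param ratio Dominance threshold: an alternative with
#'   \code{coverage / best >= ratio} makes the choice ambiguous.
#' @return List: \code{target} (id or NA), \code{ambiguous}, \code{coverage},
#'   \code{chain} (the winning collinear HSPs), \code{strand},
#'   \code{best_ratio} (strongest alternative / best), \code{scores}.
#' @export
select_best_target <- function(hsps, min_identity = 95, ratio = 0.6) {
  if (is.null(hsps$strand)) hsps <- parse_hsps(hsps)
  h <- hsps[hsps$pident >= min_identity, ]
  if (nrow(h) == 0L) {
    return(list(target = NA_character_, ambiguous = FALSE, coverage = 0L,
                chain = h, strand = NA_character_, best_ratio = NA_real_,
                scores = numeric(0)))
  }
  groups <- split(h, paste(h$sseqid, h$strand, sep = "\r"))
  chains <- lapply(groups, chain_for_target)
  covs <- vapply(chains, `[[`, numeric(1), "coverage")
  # per target keep the better strand
  tgt <- vapply(strsplit(names(chains), "\r", fixed = TRUE), `[`,
                character(1), 1L)
  scores <- tapply(covs, tgt, max)
  best_i <- which.max(covs)
  best_target <- tgt[best_i]
  alts <- scores[names(scores) != best_target]
  best_ratio <- if (length(alts) == 0L) 0 else max(alts) / covs[best_i]
  list(target = if (best_ratio >= ratio) NA_character_ else best_target,
       ambiguous = best_ratio >= ratio,
       coverage = as.integer(covs[best_i]),
       chain = chains[[best_i]]$chain,
       strand = chains[[best_i]]$chain$strand[1L],
       best_ratio = best_ratio,
       scores = scores)
}
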