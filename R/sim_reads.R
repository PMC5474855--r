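#' Simulate single-end reads from a genome
#'
#' Draws \code{round(length * depth / read_length)} reads per sequence at
#' uniform positions, reverse-complementing reads drawn from the minus strand
#' and introducing substitution errors at \code{config$error_rate}.
#'
#' @param genome Named character vector (or \code{DNAStringSet}) of sequences.
#' @param config A [sim_config()].
#' @param prefix Read-id prefix, conventionally the source ancestor ("S"/"T").
#' @param seed_offset Added to \code{config$seed} for this read set's RNG
#'   stream, so the S and T libraries are independent but reproducible.
#' @return A \code{read_set} data.frame: id, seq, source_seq, source_start
#'   (1-based, forward-strand coordinate), strand.
#' @export
simulate_reads <- function(genome, config, prefix = "rd", seed_offset = 10L) {
  genome <- as_plain_seqs(genome)
  rl <- config$read_length
  if (rl > min(nchar(genome))) {
    stop("read_length (", rl, ") exceeds shortest sequence (",
         min(nchar(genome)), ")", call. = FALSE)
  }
  set.seed(config$seed + seed_offset)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    s <- genome[[i]]
    L <- nchar(s)
    n <- as.integer(round(L * config$depth / rl))
    starts <- sample.int(L - rl + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    sq <- substring(s, starts, starts + rl - 1L)
    neg <- strand == "-"
    if (any(neg)) sq[neg] <- revcomp_chr(sq[neg])
    if (config$error_rate > 0) {
      nerr <- stats::rbinom(n, rl, config$error_rate)
      for (j in which(nerr > 0L)) {
        ch <- seq_chars(sq[j])
        ch <- mutate_bases(ch, sample.int(rl, nerr[j]))
        sq[j] <- seq_collapse(ch)
      }
    }
    out[[i]] <- data.frame(
      id = sprintf("%s_%s_%06d", prefix, names(genome)[i], seq_len(n)),
      seq = sq, source_seq = names(genome)[i], source_start = starts,
      strand = strand, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("read_set", "data.frame")
  res
}

#' Map reads to an assembly by seeded Hamming search
#'
#' End-to-end, substitution-only read mapping: each read (both strands) is
#' anchored by exact k-mer seeds and verified by full-length Hamming
#' comparison; the single best alignment is reported iff its mismatch count is
#' at most \code{max_mismatches} (the default 5 matches the standard filter
#' used for ancestral-read mapping). Exact ties on mismatch count are broken
#' by a seeded uniform choice among the tied loci, emulating a mapper's single
#' reported best hit. With the default seed length
#' \code{floor(read_length / (max_mismatches + 1))}, the pigeonhole principle
#' guarantees every alignment within the mismatch limit is found.
#'
#' @param reads A \code{read_set} (or data.frame with columns id, seq); all
#'   reads must share one length.
#' @param assembly Named character vector or \code{DNAStringSet}; duplicate
#'   sequence ids are an error.
#' @param max_mismatches Maximum mismatches for a reported alignment.
#' @param k Seed length; defaults to the pigeonhole-exact value.
#' @param seed RNG seed for tie-breaking.
#' @return An \code{alignments} data.frame: read_id, target, start (1-based),
#'   strand, mismatches, aln_length, seq (read sequence in target
#'   orientation). Unmapped reads are omitted.
#' @export
map_reads <- function(reads, assembly, max_mismatches = 5L, k = NULL,
                      seed = 1L) {
  if (length(assembly) == 0L) stop("empty assembly", call. = FALSE)
  assembly <- as_plain_seqs(assembly)
  if (anyDuplicated(names(assembly))) {
    stop("duplicate sequence ids in assembly", call. = FALSE)
  }
  rl <- unique(nchar(reads$seq))
  if (length(rl) != 1L) stop("reads must share a single length", call. = FALSE)
  if (is.null(k)) k <- max(4L, rl %/% (as.integer(max_mismatches) + 1L))
  k <- as.integer(k)
  if (k > rl) stop("seed length k exceeds read length", call. = FALSE)

  tlen <- nchar(assembly)
  idx <- data.table::rbindlist(lapply(names(assembly), function(nm) {
    L <- tlen[[nm]]
    if (L < k) return(NULL)
    data.table::data.table(
      kmer = substring(assembly[[nm]], 1:(L - k + 1L), k:L),
      target = nm, tpos = 1:(L - k + 1L))
  }))
  data.table::setkey(idx, kmer)

  nseg <- rl %/% k
  offs <- (seq_len(nseg) - 1L) * k + 1L
  n <- nrow(reads)
  oriented <- list(`+` = reads$seq, `-` = revcomp_chr(reads$seq))

  cand <- data.table::rbindlist(lapply(c("+", "-"), function(st) {
    sq <- oriented[[st]]
    data.table::rbindlist(lapply(offs, function(o) {
      data.table::data.table(kmer = substring(sq, o, o + k - 1L),
                             ridx = seq_len(n), strand = st, off = o)
    }))
  }))
  cand <- idx[cand, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0L) {
    return(empty_alignments())
  }
  cand[, start := tpos - off + 1L]
  cand[, c("kmer", "tpos", "off") := NULL]
  cand <- unique(cand[start >= 1L & start + rl - 1L <= tlen[target],
                      .(ridx, strand, target, start)])

  # full-length Hamming verification, chunked per target
  cand[, mm := NA_integer_]
  for (nm in unique(cand$target)) {
    rows <- which(cand$target == nm)
    for (ch in split(rows, ceiling(seq_along(rows) / 20000L))) {
      x <- substring(assembly[[nm]], cand$start[ch], cand$start[ch] + rl - 1L)
      y <- ifelse(cand$strand[ch] == "+", oriented[["+"]][cand$ridx[ch]],
                  oriented[["-"]][cand$ridx[ch]])
      data.table::set(cand, ch, "mm", hamming_pairs(x, y, rl))
    }
  }
  cand <- cand[mm <= max_mismatches]
  if (nrow(cand) == 0L) return(empty_alignments())

  # single best placement per read; exact ties broken by seeded uniform draw
  data.table::setorder(cand, ridx, mm, target, start, strand)
  set.seed(seed)
  cand[, key := runif(.N)]
  data.table::setorder(cand, ridx, mm, key)
  best <- cand[!duplicated(ridx)]

  out <- data.frame(
    read_id = reads$id[best$ridx], target = best$target, start = best$start,
    strand = best$strand, mismatches = best$mm, aln_length = rl,
    seq = ifelse(best$strand == "+", oriented[["+"]][best$ridx],
                 oriented[["-"]][best$ridx]),
    stringsAsFactors = FALSE)
  class(out) <- c("alignments", "data.frame")
  out
}

empty_alignments <- function() {
  out <- data.frame(read_id = character(0), target = character(0),
                    start = integer(0), strand = character(0),
                    mismatches = integer(0), aln_length = integer(0),
                    seq = character(0), stringsAsFactors = FALSE)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Run the full simulation pipeline
#'
#' Convenience wrapper: ancestral genomes, tetraploid assembly, one read set
#' per ancestor, and both read sets mapped to the assembly.
#'
#' @param config A [sim_config()].
#' @return The \code{allotetraploid_sim} object with elements \code{$reads}
#'   (list S/T of read sets) and \code{$alignments} (list S/T) added.
#' @export
simulate_tetraploid <- function(config = sim_config()) {
  anc <- simulate_ancestral_genomes(config)
  sim <- build_allotetraploid(anc, config)
  sim$ancestors <- anc
  sim$reads <- list(
    S = simulate_reads(anc$S, config, prefix = "S", seed_offset = 10L),
    T = simulate_reads(anc$T, config, prefix = "T", seed_offset = 11L))
  sim$alignments <- list(
    S = map_reads(sim$reads$S, sim$assembly, seed = config$seed + 20L),
    T = map_reads(sim$reads$T, sim$assembly, seed = config$seed + 21L))
  sim
}
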