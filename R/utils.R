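#' @import data.table
#' @importFrom stats runif rlnorm rgamma pchisq setNames
#' @importFrom utils read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a sequence string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

seq_collapse <- function(v) paste(v, collapse = "")

revcomp_chr <- function(s) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
  vapply(comp, function(x) seq_collapse(rev(seq_chars(x))), character(1L),
         USE.NAMES = FALSE)
}

# integer codes 1..4 for A,C,G,T; NA for anything else
base_codes <- function(chars) match(chars, DNA_BASES)

random_dna <- function(n) seq_collapse(sample(DNA_BASES, n, replace = TRUE))

# substitute bases at `pos` (1-based) with a uniformly chosen different base
mutate_bases <- function(chars, pos) {
  if (length(pos) == 0L) return(chars)
  old <- base_codes(chars[pos])
  # shift by 1..3 mod 4 guarantees a different base
  shift <- sample.int(3L, length(pos), replace = TRUE)
  chars[pos] <- DNA_BASES[((old - 1L + shift) %% 4L) + 1L]
  chars
}

# run-length encode a label vector into 1-based closed intervals
label_runs <- function(labels) {
  r <- rle(as.character(labels))
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, label = r$values,
             stringsAsFactors = FALSE)
}

# locate runs of 'N' in a sequence string; 1-based closed coordinates
find_n_runs <- function(s) {
  m <- gregexpr("N+", s)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             length = as.integer(len))
}

count_defined_bases <- function(seqs) {
  sum(vapply(seqs, function(s) nchar(gsub("N", "", s, fixed = TRUE)),
             numeric(1L)))
}

# Hamming distance between equal-length strings, vectorised over pairs.
# Both vectors must hold strings of identical length `len`.
hamming_pairs <- function(x, y, len) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  rx <- charToRaw(paste(x, collapse = ""))
  ry <- charToRaw(paste(y, collapse = ""))
  diff <- rx != ry
  as.integer(colSums(matrix(diff, nrow = len)))
}

seqlengths_of <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) {
    stats::setNames(Biostrings::width(seqs), names(seqs))
  } else {
    vapply(seqs, nchar, integer(1L))
  }
}

as_plain_seqs <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) {
    stats::setNames(as.character(seqs), names(seqs))
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    seqs
  }
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x)) {
    stop("configuration error: '", name, "' must be a strictly positive integer",
         call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("configuration error: '", name, "' must be a fraction in [0, 1]",
         call. = FALSE)
  }
  as.numeric(x)
}
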