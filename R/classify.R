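LABEL_LEVELS <- c("S", "T", "COLLAPSED", "UNMAPPED")

#' Classification parameters
#'
#' @param min_depth A base counts as "mapped" by an ancestor when its depth is
#'   at least this value (default 1: covered by at least one read).
#' @param bin_size Window size in bp for density tracks (default 50 kb).
#' @export
classifier_params <- function(min_depth = 1L, bin_size = 50000L) {
  list(min_depth = check_positive_int(min_depth, "min_depth"),
       bin_size = check_positive_int(bin_size, "bin_size"))
}

#' Classify every assembly base by ancestral origin
#'
#' Each base is labelled from the two parental coverage tracks: \code{S} if
#' only the S-ancestor reads map there, \code{T} symmetrically,
#' \code{COLLAPSED} if reads from both ancestors map (assembly collapse of
#' near-identical homeologs, or loss of one parental copy), and
#' \code{UNMAPPED} if neither maps (diverged or introgressed sequence).
#'
#' @param covS,covT \code{coverage_set}s over the same sequences.
#' @param params [classifier_params()].
#' @return A \code{base_labels} object: per-sequence label factors plus the
#'   genome-wide class fractions (summing to 1).
#' @export
classify_bases <- function(covS, covT, params = classifier_params()) {
  check_same_tracks(covS, covT)
  md <- params$min_depth
  labels <- lapply(names(covS), function(nm) {
    s <- covS[[nm]] >= md
    t <- covT[[nm]] >= md
    code <- ifelse(s & t, 3L, ifelse(s, 1L, ifelse(t, 2L, 4L)))
    factor(LABEL_LEVELS[code], levels = LABEL_LEVELS)
  })
  names(labels) <- names(covS)
  counts <- Reduce(`+`, lapply(labels, function(f) as.integer(table(f))))
  fractions <- stats::setNames(counts / sum(counts), LABEL_LEVELS)
  structure(list(labels = labels, fractions = fractions,
                 min_depth = md), class = "base_labels")
}

check_same_tracks <- function(covS, covT) {
  if (!identical(names(covS), names(covT)) ||
      !identical(lengths(covS), lengths(covT))) {
    stop("coverage tracks differ in sequences or lengths", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.base_labels <- function(x, ...) {
  cat("Per-base ancestral origin classification\n")
  cat(sprintf("  %d sequence(s), %s bp, min_depth %d\n", length(x$labels),
              format(sum(lengths(x$labels)), big.mark = ","), x$min_depth))
  for (nm in names(x$fractions)) {
    cat(sprintf("  %-10s %6.2f%%\n", nm, 100 * x$fractions[[nm]]))
  }
  invisible(x)
}

#' Bin a coverage or label track into fixed windows
#'
#' Consecutive half-open windows of \code{bin_size} bp; the final partial bin
#' is normalised by its true width. For a coverage track the value is the mean
#' depth per bin; for a label track, the fraction of each class per bin.
#'
#' @param track A \code{coverage_set} or \code{base_labels} object.
#' @param bin_size Window size in bp.
#' @return A data.frame with columns seqid, start, end (1-based closed) and
#'   \code{value} (plus \code{class} for label tracks).
#' @export
bin_density <- function(track, bin_size = 50000L) {
  bin_size <- check_positive_int(bin_size, "bin_size")
  if (inherits(track, "base_labels")) {
    return(bin_labels(track, bin_size))
  }
  out <- lapply(names(track), function(nm) {
    d <- track[[nm]]
    L <- length(d)
    if (L == 0L) return(NULL)
    bin <- (seq_len(L) - 1L) %/% bin_size
    m <- tapply(d, bin, mean)
    st <- as.integer(names(m)) * bin_size + 1L
    data.frame(seqid = nm, start = st, end = pmin(st + bin_size - 1L, L),
               value = as.numeric(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

bin_labels <- function(track, bin_size) {
  out <- lapply(names(track$labels), function(nm) {
    f <- track$labels[[nm]]
    L <- length(f)
    if (L == 0L) return(NULL)
    bin <- (seq_len(L) - 1L) %/% bin_size
    tab <- table(bin, f)
    widths <- as.integer(rowSums(tab))
    st <- as.integer(rownames(tab)) * bin_size + 1L
    do.call(rbind, lapply(colnames(tab), function(cl) {
      data.frame(seqid = nm, start = st, end = pmin(st + bin_size - 1L, L),
                 class = cl, value = as.numeric(tab[, cl]) / widths,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

genes_to_iranges <- function(genes, exons, seqid) {
  g <- genes[genes$seqid == seqid, ]
  e <- exons[exons$seqid == seqid, ]
  if (nrow(e) > 0L) {
    span <- stats::setNames(g$end, g$gene_id)
    bad <- e$start < g$start[match(e$gene_id, g$gene_id)] |
      e$end > g$end[match(e$gene_id, g$gene_id)]
    if (any(bad)) {
      stop("malformed gene models: exon outside gene span for ",
           paste(unique(e$gene_id[bad]), collapse = ", "), call. = FALSE)
    }
  }
  list(span = IRanges::reduce(IRanges::IRanges(g$start, g$end)),
       exon = IRanges::reduce(IRanges::IRanges(e$start, e$end)))
}

#' Genic-space partition of one origin class
#'
#' Splits the bases of one origin class into exon, intron and non-genic
#' compartments: exon bases are the union of exon intervals, intron bases lie
#' within a gene span but outside exons, and the remainder is non-genic.
#' Overlapping genes are resolved by interval union with exon precedence.
#'
#' @param labels A \code{base_labels} object.
#' @param genes Gene table (gene_id, seqid, start, end).
#' @param exons Exon table (gene_id, seqid, start, end).
#' @param cls The class to partition ("UNMAPPED", "COLLAPSED", "S" or "T").
#' @return List with per-compartment base counts, fractions over all
#'   class-\code{cls} bases, and the total class base count.
#' @export
genic_overlap <- function(labels, genes, exons, cls = "UNMAPPED") {
  cls <- match.arg(cls, LABEL_LEVELS)
  counts <- c(exon = 0, intron = 0, non_genic = 0)
  total <- 0
  for (nm in names(labels$labels)) {
    runs <- label_runs(labels$labels[[nm]])
    runs <- runs[runs$label == cls, ]
    if (nrow(runs) == 0L) next
    cls_ir <- IRanges::IRanges(runs$start, runs$end)
    total <- total + sum(IRanges::width(cls_ir))
    ir <- genes_to_iranges(genes, exons, nm)
    intron_ir <- IRanges::setdiff(ir$span, ir$exon)
    ex <- sum(IRanges::width(IRanges::intersect(cls_ir, ir$exon)))
    it <- sum(IRanges::width(IRanges::intersect(cls_ir, intron_ir)))
    counts["exon"] <- counts["exon"] + ex
    counts["intron"] <- counts["intron"] + it
    counts["non_genic"] <- counts["non_genic"] + sum(IRanges::width(cls_ir)) - ex - it
  }
  fractions <- if (total > 0) counts / total else counts * NA_real_
  list(class = cls, counts = counts, fractions = fractions, total = total)
}

#' Chi-squared goodness-of-fit enrichment test
#'
#' Tests whether observed category counts depart from expected genome-wide
#' fractions (e.g. whether unmapped sequence falls outside gene space more
#' often than the whole assembly does): \code{X2 = sum((O - E)^2 / E)} with
#' \code{E = N * fraction}, \code{df = k - 1}, upper-tail p-value. No
#' continuity correction is applied.
#'
#' @param observed Non-negative category counts.
#' @param expected_fractions Fractions summing to 1, aligned with
#'   \code{observed}.
#' @return An object of class \code{htest}.
#' @examples
#' enrichment_test(c(98, 2), c(0.7, 0.3))
#' @export
enrichment_test <- function(observed, expected_fractions) {
  if (length(observed) != length(expected_fractions)) {
    stop("observed and expected_fractions must align", call. = FALSE)
  }
  if (any(observed < 0)) stop("observed counts must be >= 0", call. = FALSE)
  if (abs(sum(expected_fractions) - 1) > 1e-8) {
    stop("expected fractions must sum to 1", call. = FALSE)
  }
  N <- sum(observed)
  E <- N * expected_fractions
  if (any(E == 0)) {
    stop("expected count of zero in some category; merge categories before testing",
         call. = FALSE)
  }
  chi2 <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(
    statistic = c(`X-squared` = chi2), parameter = c(df = df), p.value = p,
    method = "Chi-squared goodness-of-fit test (no continuity correction)",
    data.name = deparse(substitute(observed)),
    observed = observed, expected = E), class = "htest")
}

#' Per-scaffold ancestral origin call
#'
#' A scaffold is assigned to one ancestor when that ancestor's reads map more
#' than 50\% of its bases and the other ancestor's reads map less than 10\%
#' (both strict); otherwise it is \code{UNDETERMINED}.
#'
#' @param covS,covT \code{coverage_set}s.
#' @param min_depth Depth at which a base counts as mapped.
#' @return data.frame: seqid, s_pct, t_pct, call.
#' @export
call_scaffold_origin <- function(covS, covT, min_depth = 1L) {
  check_same_tracks(covS, covT)
  out <- lapply(names(covS), function(nm) {
    s_pct <- 100 * mean(covS[[nm]] >= min_depth)
    t_pct <- 100 * mean(covT[[nm]] >= min_depth)
    call <- if (s_pct > 50 && t_pct < 10) "S"
            else if (t_pct > 50 && s_pct < 10) "T"
            else "UNDETERMINED"
    data.frame(seqid = nm, s_pct = s_pct, t_pct = t_pct, call = call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
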