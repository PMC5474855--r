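GENE_CALLS <- c("S", "T", "PUTATIVE_S", "PUTATIVE_T", "COLLAPSED",
                "COLLAPSED_PUTATIVE_S", "COLLAPSED_PUTATIVE_T", "UNMAPPED")

#' Gene origin-call parameters
#'
#' @param min_depth Depth at which a base counts as covered (shared with the
#'   base classifier).
#' @param assigned_min_frac Minimum covered fraction of the gene for a firm
#'   origin call (half the gene length).
#' @param depth_ratio Fold-difference in mean depth required for a firm call
#'   (the dominant ancestor must have at least double the other's depth).
#' @param putative_delta Mean-depth difference (reads) for a putative call.
#' @param unmapped_max_frac Both ancestors below this covered fraction means
#'   the gene is unmapped.
#' @param window "span" measures coverage over the whole gene span,
#'   "exon" over exons only.
#' @export
gene_call_params <- function(min_depth = 1L, assigned_min_frac = 0.5,
                             depth_ratio = 2, putative_delta = 10,
                             unmapped_max_frac = 0.1,
                             window = c("span", "exon")) {
  list(min_depth = check_positive_int(min_depth, "min_depth"),
       assigned_min_frac = check_fraction(assigned_min_frac, "assigned_min_frac"),
       depth_ratio = depth_ratio,
       putative_delta = putative_delta,
       unmapped_max_frac = check_fraction(unmapped_max_frac, "unmapped_max_frac"),
       window = match.arg(window))
}

#' Assign ancestral origin to genes from parental coverage
#'
#' Applies, in order of precedence: a firm call (\code{S} / \code{T}) when at
#' least half the gene length is covered by one ancestor's reads at a mean
#' depth at least double the other's; a putative call when one ancestor shows
#' a higher covered fraction and a mean depth at least 10 reads greater;
#' \code{COLLAPSED} when both ancestors cover at least half the gene;
#' \code{UNMAPPED} when both covered fractions fall below
#' \code{unmapped_max_frac}; remaining genes are \code{COLLAPSED}.
#'
#' @param genes Gene table (gene_id, seqid, start, end); optionally with an
#'   exon table via \code{exons} when \code{params$window == "exon"}.
#' @param covS,covT \code{coverage_set}s over the gene sequences.
#' @param params [gene_call_params()].
#' @param exons Exon table, only used for the exon-window mode.
#' @return A \code{gene_origin_calls} data.frame with one call per gene and
#'   the evidence behind it (covered fractions and mean depths).
#' @export
assign_gene_origin <- function(genes, covS, covT,
                               params = gene_call_params(), exons = NULL) {
  check_same_tracks(covS, covT)
  if (any(genes$end < genes$start) || any(genes$end == genes$start)) {
    stop("zero-length gene span for ",
         paste(genes$gene_id[genes$end <= genes$start], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(genes)
  covered_s <- covered_t <- mean_s <- mean_t <- numeric(n)
  call <- character(n)
  for (i in seq_len(n)) {
    nm <- genes$seqid[i]
    if (is.null(covS[[nm]])) {
      stop("no coverage track for sequence ", nm, call. = FALSE)
    }
    idx <- if (params$window == "exon" && !is.null(exons)) {
      e <- exons[exons$gene_id == genes$gene_id[i], ]
      unlist(mapply(`:`, e$start, e$end, SIMPLIFY = FALSE))
    } else {
      genes$start[i]:genes$end[i]
    }
    ds <- covS[[nm]][idx]; dt <- covT[[nm]][idx]
    cs <- mean(ds >= params$min_depth); ct <- mean(dt >= params$min_depth)
    ms <- mean(ds); mt <- mean(dt)
    covered_s[i] <- cs; covered_t[i] <- ct; mean_s[i] <- ms; mean_t[i] <- mt

    call[i] <-
      if (cs >= params$assigned_min_frac && ms >= params$depth_ratio * mt &&
          ms > mt) "S"
      else if (ct >= params$assigned_min_frac && mt >= params$depth_ratio * ms &&
               mt > ms) "T"
      else if (cs > ct && ms - mt >= params$putative_delta) "PUTATIVE_S"
      else if (ct > cs && mt - ms >= params$putative_delta) "PUTATIVE_T"
      else if (cs >= params$assigned_min_frac && ct >= params$assigned_min_frac)
        "COLLAPSED"
      else if (cs < params$unmapped_max_frac && ct < params$unmapped_max_frac)
        "UNMAPPED"
      else "COLLAPSED"
  }
  out <- data.frame(gene_id = genes$gene_id, seqid = genes$seqid,
                    start = genes$start, end = genes$end, call = call,
                    covered_s = covered_s, covered_t = covered_t,
                    mean_s = mean_s, mean_t = mean_t,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_origin_calls", "data.frame")
  out
}

#' @export
print.gene_origin_calls <- function(x, ...) {
  cat("Gene ancestral-origin calls\n")
  tab <- table(factor(x$call, levels = GENE_CALLS))
  for (nm in names(tab)) {
    if (tab[[nm]] > 0L) cat(sprintf("  %-22s %6d (%5.1f%%)\n", nm, tab[[nm]],
                                    100 * tab[[nm]] / nrow(x)))
  }
  invisible(x)
}

#' Find ancestor-diagnostic polymorphic sites
#'
#' A position is diagnostic when each ancestor's read pileup reaches
#' \code{site_min_depth}, at least \code{site_purity} of each pileup agrees on
#' one allele, and the two consensus alleles differ — a fixed polymorphism
#' between the parental genomes, usable to assign origin of collapsed
#' sequence.
#'
#' @param pileS,pileT \code{pileup_set}s from [compute_pileup()] over the
#'   same assembly.
#' @param site_min_depth Minimum pileup depth per ancestor.
#' @param site_purity Minimum consensus allele fraction per ancestor.
#' @return data.frame: seqid, pos, s_allele, t_allele, s_depth, t_depth.
#' @export
find_diagnostic_sites <- function(pileS, pileT, site_min_depth = 5L,
                                  site_purity = 0.9) {
  if (!identical(names(pileS), names(pileT)) ||
      !identical(vapply(pileS, ncol, integer(1)),
                 vapply(pileT, ncol, integer(1)))) {
    stop("pileups differ in sequences or lengths", call. = FALSE)
  }
  out <- lapply(names(pileS), function(nm) {
    ps <- pileS[[nm]]; pt <- pileT[[nm]]
    ds <- colSums(ps); dt <- colSums(pt)
    as_ <- max.col(t(ps), ties.method = "first")
    at_ <- max.col(t(pt), ties.method = "first")
    L <- ncol(ps)
    maxs <- ps[cbind(as_, seq_len(L))]; maxt <- pt[cbind(at_, seq_len(L))]
    ok <- ds >= site_min_depth & dt >= site_min_depth &
      maxs >= site_purity * ds & maxt >= site_purity * dt & as_ != at_
    pos <- which(ok)
    if (length(pos) == 0L) return(NULL)
    data.frame(seqid = nm, pos = pos, s_allele = DNA_BASES[as_[pos]],
               t_allele = DNA_BASES[at_[pos]], s_depth = ds[pos],
               t_depth = dt[pos], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seqid = character(0), pos = integer(0),
                      s_allele = character(0), t_allele = character(0),
                      s_depth = integer(0), t_depth = integer(0))
  }
  res
}

#' Rescue collapsed genes from diagnostic polymorphisms
#'
#' For genes called \code{COLLAPSED}, counts the diagnostic sites inside the
#' gene span whose assembly consensus base matches the S or the T allele; the
#' gene is putatively assigned to the ancestor whose allele dominates
#' (\code{>= majority_fraction} of sites, at least \code{min_sites} matches),
#' reflecting which parental copy survives in the assembly.
#'
#' @param calls A \code{gene_origin_calls} table.
#' @param sites Diagnostic sites from [find_diagnostic_sites()].
#' @param assembly Named assembly sequences.
#' @param min_sites Minimum matching sites for a rescue.
#' @param majority_fraction Minimum share of in-gene diagnostic sites that
#'   must match the winning allele.
#' @return The calls table with \code{COLLAPSED} genes upgraded to
#'   \code{COLLAPSED_PUTATIVE_S} / \code{COLLAPSED_PUTATIVE_T} where the
#'   evidence suffices, plus site-tally columns.
#' @export
assign_collapsed_genes <- function(calls, sites, assembly, min_sites = 3L,
                                   majority_fraction = 0.8) {
  assembly <- as_plain_seqs(assembly)
  calls$n_sites <- 0L
  calls$n_match_s <- 0L
  calls$n_match_t <- 0L
  idx <- which(calls$call == "COLLAPSED")
  for (i in idx) {
    st <- sites[sites$seqid == calls$seqid[i] & sites$pos >= calls$start[i] &
                  sites$pos <= calls$end[i], ]
    if (nrow(st) == 0L) next
    cons <- substring(assembly[[calls$seqid[i]]], st$pos, st$pos)
    n_s <- sum(cons == st$s_allele)
    n_t <- sum(cons == st$t_allele)
    n <- nrow(st)
    calls$n_sites[i] <- n
    calls$n_match_s[i] <- n_s
    calls$n_match_t[i] <- n_t
    if (n_s >= min_sites && n_s / n >= majority_fraction) {
      calls$call[i] <- "COLLAPSED_PUTATIVE_S"
    } else if (n_t >= min_sites && n_t / n >= majority_fraction) {
      calls$call[i] <- "COLLAPSED_PUTATIVE_T"
    }
  }
  calls
}

#' Expressed-gene filter from a TPM table
#'
#' A gene counts as expressed in a tissue if, for at least one time-point, its
#' TPM is at or above \code{threshold} in each of the three biological
#' replicates.
#'
#' @param expr Long-format data.frame with columns gene_id, tissue, timepoint,
#'   rep1, rep2, rep3 (one row per gene x tissue x time-point).
#' @param threshold TPM threshold (default 1).
#' @return List: \code{per_tissue} (named list of expressed gene-id vectors),
#'   \code{n_expressed_any} and \code{n_expressed_all} (genes expressed in at
#'   least one / in every tissue).
#' @export
flag_expressed <- function(expr, threshold = 1.0) {
  need <- c("gene_id", "tissue", "timepoint", "rep1", "rep2", "rep3")
  if (!all(need %in% names(expr))) {
    stop("expression table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(expr[, c("gene_id", "tissue", "timepoint")])) {
    stop("a tissue x time-point must have exactly 3 replicates ",
         "(one row per gene x tissue x time-point)", call. = FALSE)
  }
  if (any(is.na(expr[, c("rep1", "rep2", "rep3")]))) {
    stop("a tissue x time-point must have exactly 3 replicates (missing TPMs)",
         call. = FALSE)
  }
  ok <- expr$rep1 >= threshold & expr$rep2 >= threshold & expr$rep3 >= threshold
  agg <- stats::aggregate(ok, by = list(gene_id = expr$gene_id,
                                        tissue = expr$tissue), FUN = any)
  tissues <- sort(unique(expr$tissue))
  per_tissue <- lapply(tissues, function(ti) {
    sort(agg$gene_id[agg$tissue == ti & agg$x])
  })
  names(per_tissue) <- tissues
  all_genes <- Reduce(union, per_tissue)
  common <- Reduce(intersect, per_tissue)
  list(per_tissue = per_tissue,
       n_expressed_any = length(all_genes),
       n_expressed_all = length(common),
       expressed_all = sort(common))
}
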