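#' Parameters for WGP-contig merging
#'
#' @param merge_min_identity Minimum percent identity of the HSPs supporting a
#'   gap fill or extension (the 95\% rule).
#' @param selection_min_identity Identity floor applied when choosing the best
#'   target; lower than the merge floor so near-miss matches are still
#'   audited (and rejected) rather than silently unselected.
#' @param max_len_abs,max_len_frac A fill/extension is accepted when its
#'   measured length is below \code{max_len_abs} bp or below
#'   \code{max_len_frac} of the contig length (the "<10 bp or <10\% of the
#'   contig" rule; both strict).
#' @param ratio Target-dominance threshold passed to [select_best_target()].
#' @param length_measure What the length rule measures for a gap fill: the
#'   N-run ("gap", default) or the contig-derived replacement sequence
#'   ("replacement").
#' @export
merge_params <- function(merge_min_identity = 95, selection_min_identity = 80,
                         max_len_abs = 10, max_len_frac = 0.1, ratio = 0.6,
                         length_measure = c("gap", "replacement")) {
  list(merge_min_identity = merge_min_identity,
       selection_min_identity = selection_min_identity,
       max_len_abs = max_len_abs, max_len_frac = max_len_frac,
       ratio = ratio, length_measure = match.arg(length_measure))
}

# orient a chain (and its query coordinates) onto the forward strand of the
# oriented contig, so downstream logic is strand-free
orient_chain <- function(chain, contig) {
  clen <- nchar(contig)
  if (nrow(chain) > 0L && chain$strand[1L] == "-") {
    qs <- clen - chain$qend + 1L
    qe <- clen - chain$qstart + 1L
    chain$qstart <- qs
    chain$qend <- qe
    contig <- revcomp_chr(contig)
  }
  list(chain = chain[order(chain$sstart), ], contig = contig)
}

empty_decision <- function(contig, clen) {
  data.frame(contig = contig, action = "APPEND", target = NA_character_,
             rule = "no_target", gap_start = NA_integer_, gap_end = NA_integer_,
             measure = NA_real_, contig_len = clen, identity = NA_real_,
             coverage = 0L, best_ratio = NA_real_, overhang = NA_integer_,
             inserted_len = NA_integer_, stringsAsFactors = FALSE)
}

# enumerate candidate edits (gap fills, extensions) of one contig on its
# selected target; each row carries pass/fail of the identity and length rules
contig_candidates <- function(contig_id, oriented, clen, target_id, tseq,
                              params) {
  chain <- oriented$chain
  o <- oriented$contig
  tlen <- nchar(tseq)
  runs <- find_n_runs(tseq)
  out <- list()
  for (g in seq_len(nrow(runs))) {
    left <- chain[chain$send < runs$start[g], ]
    right <- chain[chain$sstart > runs$end[g], ]
    if (nrow(left) == 0L || nrow(right) == 0L) next
    hl <- left[which.max(left$send), ]
    hr <- right[which.min(right$sstart), ]
    if (hl$qend >= hr$qstart) next
    repl <- substr(o, hl$qend + 1L, hr$qstart - 1L)
    meas <- if (params$length_measure == "gap") runs$length[g] else nchar(repl)
    ident <- min(hl$pident, hr$pident)
    out[[length(out) + 1L]] <- data.frame(
      contig = contig_id, action = "FILL_GAP", target = target_id,
      gap_start = runs$start[g], gap_end = runs$end[g], measure = meas,
      identity = ident, replacement = repl,
      id_ok = ident >= params$merge_min_identity,
      len_ok = meas < params$max_len_abs | meas < params$max_len_frac * clen,
      stringsAsFactors = FALSE)
  }
  if (nrow(chain) > 0L) {
    hl0 <- chain[1L, ]
    ov <- (hl0$qstart - 1L) - (hl0$sstart - 1L)
    if (ov > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        contig = contig_id, action = "EXTEND", target = target_id,
        gap_start = 0L, gap_end = 0L, measure = ov, identity = hl0$pident,
        replacement = substr(o, 1L, ov),
        id_ok = hl0$pident >= params$merge_min_identity,
        len_ok = ov < params$max_len_abs | ov < params$max_len_frac * clen,
        stringsAsFactors = FALSE)
    }
    hr0 <- chain[nrow(chain), ]
    ov <- (clen - hr0$qend) - (tlen - hr0$send)
    if (ov > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        contig = contig_id, action = "EXTEND", target = target_id,
        gap_start = tlen + 1L, gap_end = tlen + 1L, measure = ov,
        identity = hr0$pident, replacement = substr(o, clen - ov + 1L, clen),
        id_ok = hr0$pident >= params$merge_min_identity,
        len_ok = ov < params$max_len_abs | ov < params$max_len_frac * clen,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

#' Merge WGP local contigs into a WGS assembly from BLAST HSPs
#'
#' For every local contig, the best-matching assembly sequence is chosen by
#' collinear HSP-chain coverage with a dominance test against alternative
#' targets. A contig whose chain flanks an N-run with both flanking HSPs at or
#' above 95\% identity fills the gap with its own sequence if the gap is
#' shorter than 10 bp or shorter than 10\% of the contig; a terminal HSP
#' extending past the sequence end appends the overhang under the same length
#' rule. When several contigs compete for one gap or terminus the one with
#' the highest chain coverage, then the shortest unaligned overhang, wins.
#' Contigs with no accepted edit are appended to the assembly as new
#' sequences (the decision log distinguishes contigs with no usable target,
#' \code{APPEND}, from contigs whose candidate edit failed a rule or lost a
#' conflict, \code{REJECT}).
#'
#' Untouched assembly bases are preserved verbatim and the count of defined
#' (non-N) bases never decreases.
#'
#' @param assembly Named character vector (or DNAStringSet) of assembly
#'   sequences (gaps as runs of N).
#' @param contigs Named character vector of WGP contig sequences.
#' @param hsps An \code{hsp_set} from [parse_hsps()] (query = contig id,
#'   target = assembly id).
#' @param params [merge_params()].
#' @return List of class \code{wgp_merge}: \code{$assembly} (merged sequences)
#'   and \code{$decisions} (one row per input contig: action, rule fired and
#'   the values tested).
#' @export
merge_wgp <- function(assembly, contigs, hsps, params = merge_params()) {
  assembly <- as_plain_seqs(assembly)
  contigs <- as_plain_seqs(contigs)
  if (nrow(hsps) > 0L) {
    bad <- setdiff(unique(c(hsps$qseqid, hsps$sseqid)),
                   c(names(contigs), names(assembly)))
    if (length(bad) > 0L) {
      stop("HSP ids not resolvable in inputs: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  sels <- list()
  cands <- list()
  decisions <- list()
  for (cid in names(contigs)) {
    clen <- nchar(contigs[[cid]])
    h <- hsps[hsps$qseqid == cid, , drop = FALSE]
    dec <- empty_decision(cid, clen)
    if (nrow(h) == 0L) {
      decisions[[cid]] <- dec
      next
    }
    sel <- select_best_target(h, min_identity = params$selection_min_identity,
                              ratio = params$ratio)
    dec$best_ratio <- sel$best_ratio
    dec$coverage <- sel$coverage
    if (is.na(sel$target)) {
      dec$rule <- if (sel$ambiguous) "ambiguous_target" else "no_target"
      decisions[[cid]] <- dec
      next
    }
    dec$target <- sel$target
    dec$overhang <- clen - sel$coverage
    oriented <- orient_chain(sel$chain, contigs[[cid]])
    cc <- contig_candidates(cid, oriented, clen, sel$target,
                            assembly[[sel$target]], params)
    if (is.null(cc)) {
      dec$rule <- "no_candidate_edit"
      decisions[[cid]] <- dec
      next
    }
    cc$contig_len <- clen
    cc$coverage <- sel$coverage
    cc$contig_overhang <- clen - sel$coverage
    sels[[cid]] <- sel
    cands[[cid]] <- cc
    decisions[[cid]] <- dec
  }
  cand <- if (length(cands) > 0L) do.call(rbind, cands) else NULL

  accepted <- NULL
  if (!is.null(cand)) {
    ok <- cand[cand$id_ok & cand$len_ok, , drop = FALSE]
    # one edit per contig: prefer a gap fill, then the shortest measure
    ok <- ok[order(ok$contig, ok$action != "FILL_GAP", ok$measure,
                   ok$gap_start), ]
    ok <- ok[!duplicated(ok$contig), , drop = FALSE]
    # one contig per gap/terminus: highest chain coverage, shortest overhang
    ok <- ok[order(ok$target, ok$gap_start, -ok$coverage, ok$contig_overhang,
                   ok$contig), ]
    key <- paste(ok$target, ok$action, ok$gap_start)
    accepted <- ok[!duplicated(key), , drop = FALSE]
    losers <- ok[duplicated(key), , drop = FALSE]
    for (i in seq_len(nrow(losers))) {
      d <- decisions[[losers$contig[i]]]
      d$action <- "REJECT"; d$rule <- "conflict"
      d$gap_start <- losers$gap_start[i]; d$gap_end <- losers$gap_end[i]
      d$measure <- losers$measure[i]; d$identity <- losers$identity[i]
      decisions[[losers$contig[i]]] <- d
    }
    # contigs whose every candidate failed a rule
    failed <- setdiff(unique(cand$contig), ok$contig)
    for (cid in failed) {
      cf <- cand[cand$contig == cid, , drop = FALSE]
      cf <- cf[order(!cf$id_ok & !cf$len_ok, cf$measure), ]
      b <- cf[1L, ]
      d <- decisions[[cid]]
      d$action <- "REJECT"
      d$rule <- if (!b$id_ok) "identity_below_95" else "length_rule"
      d$gap_start <- b$gap_start; d$gap_end <- b$gap_end
      d$measure <- b$measure; d$identity <- b$identity
      decisions[[cid]] <- d
    }
    for (i in seq_len(nrow(accepted))) {
      a <- accepted[i, ]
      d <- decisions[[a$contig]]
      d$action <- a$action; d$rule <- if (a$action == "FILL_GAP")
        "fill_gap" else "extend"
      d$gap_start <- a$gap_start; d$gap_end <- a$gap_end
      d$measure <- a$measure; d$identity <- a$identity
      d$inserted_len <- nchar(a$replacement)
      decisions[[a$contig]] <- d
    }
  }

  merged <- assembly
  if (!is.null(accepted) && nrow(accepted) > 0L) {
    for (nm in unique(accepted$target)) {
      ed <- accepted[accepted$target == nm, , drop = FALSE]
      ed <- ed[order(-ed$gap_start), ]
      s <- merged[[nm]]
      for (i in seq_len(nrow(ed))) {
        if (ed$action[i] == "FILL_GAP") {
          s <- paste0(substr(s, 1L, ed$gap_start[i] - 1L), ed$replacement[i],
                      substr(s, ed$gap_end[i] + 1L, nchar(s)))
        } else if (ed$gap_start[i] == 0L) {
          s <- paste0(ed$replacement[i], s)
        } else {
          s <- paste0(s, ed$replacement[i])
        }
      }
      merged[[nm]] <- s
    }
  }
  dec <- do.call(rbind, decisions[names(contigs)])
  rownames(dec) <- NULL
  # everything not merged into a target is carried as a new sequence
  appended <- dec$contig[dec$action %in% c("APPEND", "REJECT")]
  merged <- c(merged, contigs[appended])

  structure(list(assembly = merged, decisions = dec), class = "wgp_merge")
}

#' @export
print.wgp_merge <- function(x, ...) {
  tab <- table(factor(x$decisions$action,
                      levels = c("FILL_GAP", "EXTEND", "APPEND", "REJECT")))
  cat("WGP merge:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  %d sequence(s), %s defined bp\n", length(x$assembly),
              format(count_defined_bases(x$assembly), big.mark = ",")))
  invisible(x)
}
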