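TRUTH_LEVELS <- c("S", "T", "COLLAPSED", "INTROGRESSED")

# Randomly place non-overlapping items of given lengths on [1, L] by
# distributing the free space between them (order is randomised first).
place_items <- function(lengths, L) {
  n <- length(lengths)
  if (n == 0L) return(integer(0))
  free <- L - sum(lengths)
  if (free < 0) {
    stop("configuration error: features (genes + segments) exceed scaffold length",
         call. = FALSE)
  }
  gaps <- diff(c(0, sort(runif(n) * free), free))[seq_len(n)]
  starts <- as.integer(floor(cumsum(gaps))) + cumsum(c(0L, lengths[-n])) + 1L
  starts
}

#' Simulate two diverged ancestral diploid genomes
#'
#' Generates the S (maternal-donor) genome, derives the T (paternal-donor)
#' genome from it by independent substitution at
#' \code{config$ancestor_divergence}, and places regular gene models at
#' identical coordinates in both ancestors. Designated collapsed segments and
#' homeolog-loss gene spans diverge at the much lower
#' \code{config$collapsed_divergence} so that, after tetraploidisation, reads
#' from both ancestors map there.
#'
#' @param config A [sim_config()] object.
#' @return An object of class \code{ancestral_genomes}: named sequence sets
#'   \code{$S} and \code{$T}, a \code{$genes} table, a \code{$segments} table
#'   of designated collapsed / introgression segments, and the ids of genes
#'   marked for homeolog loss.
#' @export
simulate_ancestral_genomes <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  L <- config$scaffold_length
  nsc <- config$n_scaffolds_per_ancestor
  col_div <- min(config$collapsed_divergence, config$ancestor_divergence)

  n_genes <- max(1L, as.integer(round(L / 1000 * config$gene_density)))
  n_col <- as.integer(round(L * config$collapsed_fraction / config$segment_length))
  n_int <- as.integer(round(L * config$introgression_fraction / config$segment_length))

  S <- T_ <- character(nsc)
  genes <- vector("list", nsc)
  segments <- vector("list", nsc)
  for (i in seq_len(nsc)) {
    s_chars <- seq_chars(random_dna(L))

    types <- c(rep("gene", n_genes), rep("collapsed", n_col),
               rep("introgression", n_int))
    lens <- c(rep(config$gene_span, n_genes),
              rep(config$segment_length, n_col + n_int))
    ord <- sample.int(length(types))
    starts <- place_items(lens[ord], L)
    feat <- data.frame(type = types[ord], start = starts,
                       end = starts + lens[ord] - 1L)

    g <- feat[feat$type == "gene", ]
    g <- g[order(g$start), ]
    genes[[i]] <- data.frame(
      gene_id = sprintf("g%02d_%03d", i, seq_len(nrow(g))),
      scaffold = i, start = g$start, end = g$end,
      strand = sample(c("+", "-"), nrow(g), replace = TRUE),
      stringsAsFactors = FALSE)
    sf <- feat[feat$type != "gene", , drop = FALSE]
    segments[[i]] <- data.frame(
      scaffold = rep(i, nrow(sf)), start = sf$start, end = sf$end,
      type = sf$type, stringsAsFactors = FALSE)

    S[i] <- seq_collapse(s_chars)
  }
  names(S) <- paste0("S", seq_len(nsc))
  genes <- do.call(rbind, genes)
  segments <- do.call(rbind, segments)

  # genes losing one homeolog: chosen now so their spans can be set to low
  # divergence before the T genome is derived
  n_loss <- as.integer(round(config$homeolog_loss_rate * nrow(genes)))
  loss_ids <- sort(sample(genes$gene_id, n_loss))

  for (i in seq_len(nsc)) {
    t_chars <- seq_chars(S[i])
    rate <- rep(config$ancestor_divergence, L)
    seg <- segments[segments$scaffold == i & segments$type == "collapsed", ]
    for (j in seq_len(nrow(seg))) rate[seg$start[j]:seg$end[j]] <- col_div
    gl <- genes[genes$scaffold == i & genes$gene_id %in% loss_ids, ]
    for (j in seq_len(nrow(gl))) rate[gl$start[j]:gl$end[j]] <- col_div
    pos <- which(runif(L) < rate)
    t_chars <- mutate_bases(t_chars, pos)
    T_[i] <- seq_collapse(t_chars)
  }
  names(T_) <- paste0("T", seq_len(nsc))

  structure(list(S = S, T = T_, genes = genes, segments = segments,
                 loss_gene_ids = loss_ids, config = config),
            class = "ancestral_genomes")
}

#' @export
print.ancestral_genomes <- function(x, ...) {
  cat(sprintf("Ancestral genomes: %d scaffold(s)/ancestor, %s bp each; %d genes, %d marked for homeolog loss\n",
              length(x$S), format(nchar(x$S[1]), big.mark = ","),
              nrow(x$genes), length(x$loss_gene_ids)))
  invisible(x)
}

#' Exon coordinates of simulated gene models
#'
#' Expands the simulator's regular gene structure (fixed exon and intron
#' sizes from the configuration) into one row per exon, for GFF3 emission and
#' genic-overlap analysis.
#'
#' @param genes Gene table with gene_id, start, end (and seqid if present).
#' @param config The [sim_config()] that generated the genes.
#' @return data.frame: gene_id, seqid, start, end.
#' @export
gene_exons <- function(genes, config) {
  k <- config$exons_per_gene
  step <- config$exon_length + config$intron_length
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    es <- genes$start[i] + (seq_len(k) - 1L) * step
    out[[i]] <- data.frame(gene_id = genes$gene_id[i],
                           seqid = genes$seqid[i] %||% NA_character_,
                           start = es, end = es + config$exon_length - 1L,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build an allotetraploid assembly with known per-base origin
#'
#' Combines the two ancestral genomes into one assembly: every S and T
#' scaffold is carried over; for each gene marked for homeolog loss the copy
#' from one (randomly chosen) ancestor is deleted and the surviving copy is
#' truth-labelled \code{COLLAPSED}; designated collapsed segments (present in
#' both near-identical copies) are labelled \code{COLLAPSED} on both copies;
#' introgression segments are replaced by fresh random sequence labelled
#' \code{INTROGRESSED}; all other bases carry their source ancestor's label.
#'
#' @param ancestors An \code{ancestral_genomes} object.
#' @param config The same [sim_config()]; defaults to the one stored in
#'   \code{ancestors}.
#' @return An object of class \code{allotetraploid_sim} with the assembly
#'   sequences, per-base truth labels (factors over S / T / COLLAPSED /
#'   INTROGRESSED), assembly-coordinate gene models, and a per-gene truth
#'   table.
#' @export
build_allotetraploid <- function(ancestors, config = ancestors$config) {
  stopifnot(inherits(ancestors, "ancestral_genomes"))
  set.seed(config$seed + 1L)
  nsc <- config$n_scaffolds_per_ancestor

  loss <- data.frame(gene_id = ancestors$loss_gene_ids, stringsAsFactors = FALSE)
  loss$lost <- sample(c("S", "T"), nrow(loss), replace = TRUE)

  assembly <- character(0)
  truth <- list()
  genes_out <- list()
  gene_truth <- list()
  for (anc in c("S", "T")) {
    other <- if (anc == "S") "T" else "S"
    for (i in seq_len(nsc)) {
      src <- ancestors[[anc]][[paste0(anc, i)]]
      chars <- seq_chars(src)
      L <- length(chars)
      lab <- rep(anc, L)
      seg <- ancestors$segments[ancestors$segments$scaffold == i, ]
      for (j in seq_len(nrow(seg))) {
        span <- seg$start[j]:seg$end[j]
        if (seg$type[j] == "collapsed") {
          lab[span] <- "COLLAPSED"
        } else {
          chars[span] <- seq_chars(random_dna(length(span)))
          lab[span] <- "INTROGRESSED"
        }
      }
      g <- ancestors$genes[ancestors$genes$scaffold == i, ]
      g$copy_of <- g$gene_id
      g$gene_id <- paste0(g$gene_id, "_", anc)
      g$seqid <- paste0("scaffold_", anc, i)
      g$truth <- anc
      g$retained <- NA_character_

      lost_here <- loss$gene_id[loss$lost == anc]
      surv_here <- loss$gene_id[loss$lost == other]
      g$truth[g$copy_of %in% surv_here] <- "COLLAPSED"
      g$retained[g$copy_of %in% surv_here] <- anc
      for (gid in intersect(surv_here, g$copy_of)) {
        r <- g[g$copy_of == gid, ]
        lab[r$start:r$end] <- "COLLAPSED"
      }

      # delete lost homeolog copies, right to left so coordinates stay valid
      del <- g[g$copy_of %in% lost_here, ]
      keep <- rep(TRUE, L)
      for (j in seq_len(nrow(del))) keep[del$start[j]:del$end[j]] <- FALSE
      g <- g[!g$copy_of %in% lost_here, ]
      if (!all(keep)) {
        offset <- cumsum(!keep)
        g$start <- g$start - offset[g$start]
        g$end <- g$end - offset[g$end]
        chars <- chars[keep]
        lab <- lab[keep]
      }

      nm <- paste0("scaffold_", anc, i)
      assembly[nm] <- seq_collapse(chars)
      truth[[nm]] <- factor(lab, levels = TRUTH_LEVELS)
      genes_out[[nm]] <- g[, c("gene_id", "seqid", "start", "end", "strand",
                               "copy_of")]
      gene_truth[[nm]] <- g[, c("gene_id", "truth", "retained")]
    }
  }
  genes_out <- do.call(rbind, genes_out)
  gene_truth <- do.call(rbind, gene_truth)
  rownames(genes_out) <- rownames(gene_truth) <- NULL

  structure(list(assembly = assembly, truth = truth, genes = genes_out,
                 gene_truth = gene_truth, loss = loss,
                 segments = ancestors$segments, config = config),
            class = "allotetraploid_sim")
}

#' @export
print.allotetraploid_sim <- function(x, ...) {
  fr <- truth_fractions(x)
  cat(sprintf("Allotetraploid simulation: %d sequences, %s bp, %d genes\n",
              length(x$assembly),
              format(sum(nchar(x$assembly)), big.mark = ","), nrow(x$genes)))
  cat("  truth label fractions:",
      paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", "), "\n")
  invisible(x)
}

#' Truth label fractions of a simulated assembly
#' @param sim An \code{allotetraploid_sim} object.
#' @return Named fractions over S, T, COLLAPSED, INTROGRESSED (summing to 1).
#' @export
truth_fractions <- function(sim) {
  tab <- Reduce(`+`, lapply(sim$truth, function(f) table(f)))
  as.numeric(tab) / sum(tab) -> fr
  stats::setNames(fr, names(tab))
}
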