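#' Simulation configuration for a synthetic allotetraploid
#'
#' Parameterises the synthetic genome used to exercise the pipeline against a
#' known per-base origin. Two diverged diploid ancestors (called S and T, for
#' the maternal and paternal genome donors of an allotetraploid) are generated,
#' combined into a tetraploid assembly carrying collapsed regions, homeolog
#' losses and introgressed segments, and sequenced in silico.
#'
#' @param seed Integer seed; the same seed and configuration reproduce every
#'   downstream artifact byte for byte.
#' @param n_scaffolds_per_ancestor Number of scaffolds simulated per ancestor.
#' @param scaffold_length Length of each ancestral scaffold in bp.
#' @param ancestor_divergence Substitutions per site between homeologous S and
#'   T sequence outside collapsed regions.
#' @param collapsed_fraction Fraction of each scaffold emitted as
#'   low-divergence ("collapsed") segments where reads from both ancestors map.
#' @param homeolog_loss_rate Fraction of genes whose copy from one ancestor is
#'   deleted from the assembly; the surviving copy is truth-labelled collapsed.
#' @param introgression_fraction Fraction of assembly bases replaced by novel
#'   sequence matching neither ancestor.
#' @param read_length Simulated read length in bp (single-end).
#' @param depth Mean fold-coverage per ancestor.
#' @param error_rate Per-base sequencing error fraction.
#' @param gene_density Genes per kb of scaffold.
#' @param exons_per_gene Exons per gene model.
#' @param collapsed_divergence Substitutions per site inside collapsed segments
#'   and homeolog-loss gene spans; must stay well below
#'   \code{max_mismatches / read_length} so both ancestors' reads map there.
#' @param exon_length,intron_length Exon and intron sizes (bp) of the regular
#'   gene structure used by the simulator.
#' @param segment_length Length (bp) of individual collapsed / introgressed
#'   segments.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_scaffolds_per_ancestor = 1,
#'                   scaffold_length = 20000)
#' cfg$ancestor_divergence
#' @export
sim_config <- function(seed = 42L,
                       n_scaffolds_per_ancestor = 2L,
                       scaffold_length = 200000L,
                       ancestor_divergence = 0.08,
                       collapsed_fraction = 0.05,
                       homeolog_loss_rate = 0.1,
                       introgression_fraction = 0.05,
                       read_length = 100L,
                       depth = 10,
                       error_rate = 0,
                       gene_density = 0.2,
                       exons_per_gene = 4L,
                       collapsed_divergence = 0.005,
                       exon_length = 200L,
                       intron_length = 150L,
                       segment_length = 2000L) {
  cfg <- list(
    seed = check_positive_int(seed, "seed"),
    n_scaffolds_per_ancestor =
      check_positive_int(n_scaffolds_per_ancestor, "n_scaffolds_per_ancestor"),
    scaffold_length = check_positive_int(scaffold_length, "scaffold_length"),
    ancestor_divergence = check_fraction(ancestor_divergence, "ancestor_divergence"),
    collapsed_fraction = check_fraction(collapsed_fraction, "collapsed_fraction"),
    homeolog_loss_rate = check_fraction(homeolog_loss_rate, "homeolog_loss_rate"),
    introgression_fraction =
      check_fraction(introgression_fraction, "introgression_fraction"),
    read_length = check_positive_int(read_length, "read_length"),
    depth = depth,
    error_rate = check_fraction(error_rate, "error_rate"),
    gene_density = gene_density,
    exons_per_gene = check_positive_int(exons_per_gene, "exons_per_gene"),
    collapsed_divergence =
      check_fraction(collapsed_divergence, "collapsed_divergence"),
    exon_length = check_positive_int(exon_length, "exon_length"),
    intron_length = check_positive_int(intron_length, "intron_length"),
    segment_length = check_positive_int(segment_length, "segment_length")
  )
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) || depth <= 0) {
    stop("configuration error: 'depth' must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(gene_density) || gene_density <= 0) {
    stop("configuration error: 'gene_density' must be strictly positive",
         call. = FALSE)
  }
  if (cfg$collapsed_fraction + cfg$introgression_fraction > 1) {
    stop("configuration error: 'collapsed_fraction' + 'introgression_fraction' ",
         "exceed 1 within a scaffold", call. = FALSE)
  }
  gene_span <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  cfg$gene_span <- as.integer(gene_span)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Allotetraploid simulation configuration\n")
  cat(sprintf("  %d scaffold(s)/ancestor x %s bp, divergence %.3g (collapsed %.3g)\n",
              x$n_scaffolds_per_ancestor,
              format(x$scaffold_length, big.mark = ","),
              x$ancestor_divergence, x$collapsed_divergence))
  cat(sprintf("  collapsed %.1f%%, homeolog loss %.1f%% of genes, introgression %.1f%%\n",
              100 * x$collapsed_fraction, 100 * x$homeolog_loss_rate,
              100 * x$introgression_fraction))
  cat(sprintf("  reads: %d bp single-end, %gx per ancestor, error rate %.3g\n",
              x$read_length, x$depth, x$error_rate))
  cat(sprintf("  genes: %.3g per kb, %d exons of %d bp (span %d bp)\n",
              x$gene_density, x$exons_per_gene, x$exon_length, x$gene_span))
  invisible(x)
}
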