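#' Read variant records from a VCF file
#'
#' Extracts the fields needed for consensus correction: position, reference
#' and alternate alleles, total read depth (INFO/DP) and alternate allele
#' fraction (INFO/AF).
#'
#' @param path VCF v4.x file.
#' @return data.frame: seqid, pos (1-based), ref, alt, depth, alt_fraction.
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  data.frame(seqid = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, depth = dp, alt_fraction = af,
             stringsAsFactors = FALSE)
}

#' Write variant records as a minimal VCF v4.2 file
#' @param variants data.frame as returned by [read_vcf_variants()].
#' @param path Output file.
#' @param seqlengths Optional named lengths for contig header lines.
#' @export
write_vcf_variants <- function(variants, path, seqlengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total Depth\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">")
  if (!is.null(seqlengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
                          as.integer(seqlengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                  variants$seqid, variants$pos, variants$ref, variants$alt,
                  as.integer(variants$depth), variants$alt_fraction)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Correct an assembly consensus from filtered variant calls
#'
#' Applies bi-allelic variants whose read depth and alternate allele fraction
#' pass the thresholds: SNPs are substituted in place; insertions and
#' deletions are applied right to left per sequence so earlier coordinates
#' stay valid. Multi-allelic records are skipped with a warning; overlapping
#' accepted indels keep the first by position and log a conflict. Reference
#' alleles are verified against the assembly before anything is changed.
#'
#' @param assembly Named sequences.
#' @param variants data.frame (seqid, pos, ref, alt, depth, alt_fraction) or
#'   a VCF path.
#' @param min_depth Minimum total depth for an applied variant.
#' @param min_alt_fraction Minimum alternate allele fraction.
#' @return List of class \code{vcf_correction}: \code{$assembly} (corrected)
#'   and \code{$log} (one row per record with its status).
#' @export
apply_vcf_corrections <- function(assembly, variants, min_depth = 10,
                                  min_alt_fraction = 0.9) {
  assembly <- as_plain_seqs(assembly)
  if (is.character(variants) && length(variants) == 1L) {
    variants <- read_vcf_variants(variants)
  }
  v <- variants
  if (nrow(v) > 0L) {
    bad <- setdiff(unique(v$seqid), names(assembly))
    if (length(bad) > 0L) {
      stop("variant on unknown sequence: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out_of_bounds <- v$pos < 1L | v$pos + nchar(v$ref) - 1L >
      nchar(assembly)[v$seqid]
    if (any(out_of_bounds)) {
      stop("variant position out of bounds at ", v$seqid[out_of_bounds][1L],
           ":", v$pos[out_of_bounds][1L], call. = FALSE)
    }
    obs <- substring(assembly[v$seqid], v$pos, v$pos + nchar(v$ref) - 1L)
    mism <- obs != v$ref
    if (any(mism)) {
      stop("reference allele mismatch at ", v$seqid[mism][1L], ":",
           v$pos[mism][1L], " (assembly has ", obs[mism][1L], ", VCF says ",
           v$ref[mism][1L], ")", call. = FALSE)
    }
  }

  v$status <- "applied"
  multi <- grepl(",", v$alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v$status[multi] <- "skipped_multiallelic"
  }
  v$status[!multi & v$depth < min_depth] <- "skipped_depth"
  v$status[!multi & v$depth >= min_depth &
             v$alt_fraction < min_alt_fraction] <- "skipped_allele_fraction"

  # overlapping accepted indel spans: keep the first by position
  v <- v[order(v$seqid, v$pos), ]
  acc <- which(v$status == "applied")
  last_end <- stats::setNames(rep(0L, length(assembly)), names(assembly))
  for (i in acc) {
    span_end <- v$pos[i] + nchar(v$ref[i]) - 1L
    if (v$pos[i] <= last_end[[v$seqid[i]]]) {
      v$status[i] <- "conflict_overlap"
    } else {
      last_end[v$seqid[i]] <- span_end
    }
  }

  app <- v[v$status == "applied", , drop = FALSE]
  app <- app[order(app$seqid, -app$pos), ]
  for (i in seq_len(nrow(app))) {
    nm <- app$seqid[i]
    s <- assembly[[nm]]
    assembly[[nm]] <- paste0(substr(s, 1L, app$pos[i] - 1L), app$alt[i],
                             substr(s, app$pos[i] + nchar(app$ref[i]),
                                    nchar(s)))
  }
  structure(list(assembly = assembly, log = v), class = "vcf_correction")
}

#' @export
print.vcf_correction <- function(x, ...) {
  tab <- table(x$log$status)
  cat("Consensus correction:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
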