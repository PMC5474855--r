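# small configurations and shared fixtures built in code

small_config <- function(...) {
  args <- list(seed = 7L, n_scaffolds_per_ancestor = 1L,
               scaffold_length = 30000L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# the study-condition simulation (seed 42, 2 x 200 kb per ancestor,
# divergence 0.08, collapsed 5%, homeolog loss 10%, introgression 5%,
# 10x coverage of 100 bp error-free reads), computed once per session
.study_env <- new.env(parent = emptyenv())

study_sim <- function() {
  if (is.null(.study_env$sim)) {
    cfg <- sim_config(seed = 42L)
    sim <- simulate_tetraploid(cfg)
    sim$covS <- compute_depth(sim$alignments$S, sim$assembly)
    sim$covT <- compute_depth(sim$alignments$T, sim$assembly)
    .study_env$sim <- sim
  }
  .study_env$sim
}

# coverage_set from plain per-base depth vectors
cov_set <- function(...) {
  structure(lapply(list(...), as.integer), class = "coverage_set")
}

# fraction of bases whose predicted label matches truth, restricted to bases
# more than `margin` bp from any truth-run boundary; INTROGRESSED counts as
# UNMAPPED since reads from neither ancestor map there
truth_recovery <- function(sim, labels, margin = 100L) {
  num <- den <- 0
  for (nm in names(labels$labels)) {
    tr <- as.character(sim$truth[[nm]])
    pred <- as.character(labels$labels[[nm]])
    tr_exp <- ifelse(tr == "INTROGRESSED", "UNMAPPED", tr)
    runs <- rle(tr)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- rep(TRUE, length(tr))
    for (b in sort(unique(c(starts - 1L, ends)))) {
      lo <- max(1L, b - margin)
      hi <- min(length(tr), b + margin)
      keep[lo:hi] <- FALSE
    }
    num <- num + sum(pred[keep] == tr_exp[keep])
    den <- den + sum(keep)
  }
  num / den
}

# all-position Hamming scan over both strands of every target; the
# independent mapping oracle (Biostrings, not the package's seeded search)
brute_force_best <- function(read, assembly) {
  best_mm <- Inf
  hits <- list()
  for (nm in names(assembly)) {
    subj <- Biostrings::DNAString(assembly[[nm]])
    L <- length(subj)
    m <- nchar(read)
    if (L < m) next
    for (st in c("+", "-")) {
      pat <- Biostrings::DNAString(if (st == "+") read else revcomp_plain(read))
      ed <- Biostrings::neditStartingAt(pat, subj, starting.at = 1:(L - m + 1),
                                        with.indels = FALSE)
      mn <- min(ed)
      if (mn < best_mm) {
        best_mm <- mn
        hits <- list()
      }
      if (mn == best_mm) {
        for (p in which(ed == mn)) {
          hits[[length(hits) + 1L]] <- list(target = nm, start = p, strand = st)
        }
      }
    }
  }
  list(mm = best_mm, hits = hits)
}

revcomp_plain <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# inject `k` substitutions into a sequence string at distinct positions
mutate_seq <- function(s, k) {
  if (k == 0L) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}
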