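#' Read scaffold-to-linkage-group assignments
#'
#' @param path TSV with columns scaffold, group, order, orientation
#'   (orientation in +, -, or "unknown").
#' @return data.frame of assignments.
#' @export
read_chrom_assignments <- function(path) {
  a <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("scaffold", "group", "order", "orientation")
  if (!all(need %in% names(a))) {
    stop("assignment table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  a
}

#' Build pseudomolecules from anchored scaffolds
#'
#' Per linkage group, concatenates the assigned scaffolds in map order —
#' reverse-complementing minus-orientation scaffolds, treating unknown
#' orientation as forward — separated by a fixed spacer of Ns (100 by
#' convention for map-anchored pseudomolecules). Emits AGP v2.1 alongside:
#' W lines for components, U gap lines (type "scaffold", linkage yes,
#' evidence "map") for spacers. Scaffolds without an assignment pass through
#' unplaced.
#'
#' @param assembly Named scaffold sequences.
#' @param assignments data.frame with columns scaffold, group, order,
#'   orientation; (group, order) must be unique and every scaffold must exist.
#' @param spacer Number of Ns between consecutive scaffolds.
#' @return List of class \code{pseudomolecule_set}: \code{$sequences} (named:
#'   one per group, then unplaced scaffolds) and \code{$agp} (data.frame of
#'   AGP v2.1 rows).
#' @export
build_pseudomolecules <- function(assembly, assignments, spacer = 100L) {
  assembly <- as_plain_seqs(assembly)
  a <- assignments
  missing <- setdiff(a$scaffold, names(assembly))
  if (length(missing) > 0L) {
    stop("assigned scaffold(s) missing from assembly: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(a[, c("group", "order")])) {
    stop("duplicate (group, order) index in assignments", call. = FALSE)
  }
  if (anyDuplicated(a$scaffold)) {
    stop("scaffold assigned more than once", call. = FALSE)
  }
  seqs <- character(0)
  agp <- list()
  for (grp in unique(a$group)) {
    g <- a[a$group == grp, ]
    g <- g[order(g$order), ]
    parts <- character(nrow(g))
    pos <- 0L
    part_no <- 0L
    for (i in seq_len(nrow(g))) {
      if (i > 1L) {
        part_no <- part_no + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object = grp, object_beg = pos + 1L, object_end = pos + spacer,
          part_number = part_no, component_type = "U",
          component_id = as.character(spacer), component_beg = "scaffold",
          component_end = "yes", orientation = "map", stringsAsFactors = FALSE)
        pos <- pos + spacer
      }
      s <- assembly[[g$scaffold[i]]]
      ori <- if (g$orientation[i] == "-") "-" else "+"
      parts[i] <- if (ori == "-") revcomp_chr(s) else s
      part_no <- part_no + 1L
      agp[[length(agp) + 1L]] <- data.frame(
        object = grp, object_beg = pos + 1L, object_end = pos + nchar(s),
        part_number = part_no, component_type = "W",
        component_id = g$scaffold[i], component_beg = "1",
        component_end = as.character(nchar(s)), orientation = ori,
        stringsAsFactors = FALSE)
      pos <- pos + nchar(s)
    }
    seqs[grp] <- paste(parts, collapse = strrep("N", spacer))
  }
  unplaced <- setdiff(names(assembly), a$scaffold)
  for (nm in unplaced) {
    agp[[length(agp) + 1L]] <- data.frame(
      object = nm, object_beg = 1L, object_end = nchar(assembly[[nm]]),
      part_number = 1L, component_type = "W", component_id = nm,
      component_beg = "1", component_end = as.character(nchar(assembly[[nm]])),
      orientation = "+", stringsAsFactors = FALSE)
  }
  seqs <- c(seqs, assembly[unplaced])
  structure(list(sequences = seqs, agp = do.call(rbind, agp)),
            class = "pseudomolecule_set")
}

#' Write an AGP v2.1 file
#' @param agp AGP rows from [build_pseudomolecules()].
#' @param path Output file.
#' @export
write_agp <- function(agp, path) {
  writeLines(c("##agp-version 2.1",
               apply(agp, 1L, function(r) paste(r, collapse = "\t"))), path)
  invisible(path)
}

#' Read an AGP file
#' @param path AGP file.
#' @return data.frame of AGP rows.
#' @export
read_agp <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  agp <- data.frame(f, stringsAsFactors = FALSE)
  names(agp) <- c("object", "object_beg", "object_end", "part_number",
                  "component_type", "component_id", "component_beg",
                  "component_end", "orientation")
  agp$object_beg <- as.integer(agp$object_beg)
  agp$object_end <- as.integer(agp$object_end)
  agp$part_number <- as.integer(agp$part_number)
  agp
}

#' Reconstruct object sequences from AGP and component sequences
#'
#' @param agp AGP rows ([read_agp()] / [build_pseudomolecules()]).
#' @param components Named component (scaffold) sequences.
#' @return Named character vector of reconstructed objects.
#' @export
apply_agp <- function(agp, components) {
  components <- as_plain_seqs(components)
  out <- character(0)
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, ]
    rows <- rows[order(rows$part_number), ]
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type %in% c("N", "U")) {
        strrep("N", r$object_end - r$object_beg + 1L)
      } else {
        s <- substr(components[[r$component_id]], as.integer(r$component_beg),
                    as.integer(r$component_end))
        if (r$orientation == "-") revcomp_chr(s) else s
      }
    }, character(1))
    out[obj] <- paste(parts, collapse = "")
  }
  out
}
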