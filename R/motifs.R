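# Group-defining sequence motifs of the ArgR family.
#
# Three mutually exclusive motifs separate the family's major phylogenetic
# groups: the Ec group carries L-I-A-R-x-x-D in the ligand-binding helix
# (alpha5), while the Bs and Mt groups carry charged triads in the
# interdomain linker helix (alpha4): K-x-x-R-x-x-x-D and R-x-x-R-x-x-x-E
# respectively (spacings taken from the triad residue numbering, e.g.
# K75/R78/D82 and R97/R100/E104). Wildcards match any of the 20 standard
# residues; X matches nothing.

.standard_aa <- "ACDEFGHIKLMNPQRSTVWY"

#' Group-defining motif patterns
#'
#' @return named list of `motif_pattern` objects (`Ec`, `Bs`, `Mt`), each with
#'   `group`, `template` (fixed letters, "x" = wildcard), and `length`.
#' @export
motif_patterns <- function() {
  mk <- function(group, template)
    structure(list(group = group, template = template,
                   length = nchar(template)),
              class = "motif_pattern")
  list(Ec = mk("Ec", "LIARxxD"),
       Bs = mk("Bs", "KxxRxxxD"),
       Mt = mk("Mt", "RxxRxxxE"))
}

motif_regex <- function(pattern) {
  wild <- paste0("[", .standard_aa, "]")
  chars <- strsplit(pattern$template, "")[[1L]]
  paste0(ifelse(chars == "x", wild, chars), collapse = "")
}

check_sequence <- function(sequence) {
  s <- toupper(gsub("[ \t\n*]", "", sequence))
  bad <- gsub(paste0("[", .standard_aa, "X]"), "", s)
  if (nchar(bad))
    stop("illegal sequence character(s): ", paste(unique(strsplit(bad, "")[[1L]]),
                                                  collapse = ","))
  s
}

#' Scan a sequence for a motif
#'
#' All (possibly overlapping) match start positions, 1-based.
#'
#' @param sequence amino-acid string (standard one-letter codes; X allowed,
#'   matching neither fixed nor wildcard positions)
#' @param pattern a `motif_pattern` from [motif_patterns()]
#' @return data.frame: group, start, match (empty when no hit)
#' @export
scan_motif <- function(sequence, pattern) {
  s <- check_sequence(sequence)
  rx <- paste0("(?=(", motif_regex(pattern), "))")
  m <- gregexpr(rx, s, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(group = character(), start = integer(),
                      match = character()))
  starts <- as.integer(m)
  data.frame(group = pattern$group, start = starts,
             match = substring(s, starts, starts + pattern$length - 1L))
}

#' Classify a sequence into an ArgR phylogenetic group
#'
#' The motifs are mutually exclusive in the family; should several match, the
#' first group in `precedence` wins and all hits are retained in the report.
#' A sequence with no hit is `unassigned` (the "grey" outliers of the family
#' tree).
#'
#' @param sequence amino-acid string
#' @param patterns list of patterns (default [motif_patterns()])
#' @param precedence group precedence for multi-hit sequences
#' @param clade_label optional externally assigned group; a disagreement with
#'   the motif group sets `outlier_flag`
#' @param sequence_id identifier carried into the result
#' @return object of class `group_assignment`: `sequence_id`, `group`,
#'   `hits` (data.frame), `multi_hit`, `outlier_flag`
#' @export
classify_group <- function(sequence, patterns = motif_patterns(),
                           precedence = c("Ec", "Bs", "Mt"),
                           clade_label = NULL, sequence_id = NA_character_) {
  hits <- do.call(rbind, lapply(patterns, function(p) scan_motif(sequence, p)))
  rownames(hits) <- NULL
  groups_hit <- unique(hits$group)
  group <- "unassigned"
  for (g in precedence) if (g %in% groups_hit) { group <- g; break }
  outlier <- !is.null(clade_label) && !is.na(clade_label) && clade_label != group
  structure(list(sequence_id = sequence_id, group = group, hits = hits,
                 multi_hit = length(groups_hit) > 1L,
                 outlier_flag = outlier),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %s -> %s (%d hit(s)%s%s)\n",
              x$sequence_id, x$group, nrow(x$hits),
              if (x$multi_hit) ", MULTI-HIT" else "",
              if (x$outlier_flag) ", OUTLIER vs clade label" else ""))
  invisible(x)
}

#' Classify every record of a FASTA file
#'
#' @param fasta path to a FASTA file of amino-acid sequences
#' @param clade_labels optional named character vector (names = record ids)
#'   of externally assigned groups; mismatches set `outlier_flag`
#' @param ... passed to [classify_group()]
#' @return data.frame: sequence_id, group, n_hits, first_start, first_match,
#'   multi_hit, outlier_flag
#' @export
batch_classify <- function(fasta, clade_labels = NULL, ...) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (!length(seqs)) stop("empty FASTA file: ", fasta)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  rows <- lapply(seq_along(seqs), function(i) {
    ga <- classify_group(as.character(seqs[[i]]),
                         clade_label = clade_labels[ids[i]],
                         sequence_id = ids[i], ...)
    data.frame(sequence_id = ga$sequence_id, group = ga$group,
               n_hits = nrow(ga$hits),
               first_start = if (nrow(ga$hits)) ga$hits$start[1L] else NA_integer_,
               first_match = if (nrow(ga$hits)) ga$hits$match[1L] else NA_character_,
               multi_hit = ga$multi_hit, outlier_flag = ga$outlier_flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
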