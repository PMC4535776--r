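#' Heligoland mitochondrial mutation table (reconstruction)
#'
#' The packaged table of new mitochondrial mutations found in the 11
#' Heligoland genomes carrying the colonizing haplotype: position (1-based,
#' mouse reference NCBI37/mm9 chrM), region annotation, cohort consensus
#' base, per-animal calls (`.` = consensus, `X/Y` = heteroplasmic double
#' peak) and the bases of six comparator species (rat, human, orangutan,
#' dog, horse, opossum) used for the conservation screen.
#'
#' The published table is only available as flattened text with an ambiguous
#' row-to-column mapping, so this fixture is a reconstruction: internally
#' consistent and reproducing the published summary counts (10 counted
#' positions, 3 conserved across all six species), but not guaranteed to
#' match the original cell-for-cell.
#'
#' @return Data frame with one row per mutation position.
#' @export
heligoland_mutation_table <- function() {
  path <- system.file("extdata", "heligoland_mito_mutations_synthetic.tsv",
                      package = "islandmouse", mustWork = TRUE)
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Expand a mutation table into a synthetic cohort alignment
#'
#' Builds a full-length alignment whose columns at the tabulated positions
#' carry exactly the tabulated per-animal bases (heteroplasmies as IUPAC
#' two-base codes) and whose remaining columns are invariant filler, so the
#' consensus-calling and mutation-counting machinery can be run end to end
#' on the in-table data.
#'
#' @param table A data frame shaped like [heligoland_mutation_table()].
#' @param genome_length Alignment length in bp (default 16,299, the mouse
#'   reference mitochondrial genome).
#' @param control_region Half-open 0-based interval passed to
#'   [mito_alignment()].
#' @param filler Base used for columns not present in the table.
#' @return A [mito_alignment()] with one genome per animal column.
#' @export
mutation_table_alignment <- function(table,
                                     genome_length = 16299L,
                                     control_region = c(15422L, 16299L),
                                     filler = "A") {
  animal_cols <- setdiff(names(table),
                         c("position", "annotation", "consensus",
                           "Rat", "Human", "Orangutan", "Dog", "Horse",
                           "Opossum"))
  if (max(table$position) > genome_length)
    stop("table positions exceed genome_length")
  m <- matrix(filler, nrow = length(animal_cols), ncol = genome_length,
              dimnames = list(animal_cols, NULL))
  for (r in seq_len(nrow(table))) {
    pos <- table$position[r]
    for (a in animal_cols) {
      cell <- table[[a]][r]
      m[a, pos] <- if (cell == ".") {
        table$consensus[r]
      } else if (grepl("/", cell, fixed = TRUE)) {
        .iupac_code_for(strsplit(cell, "/", fixed = TRUE)[[1]])
      } else {
        cell
      }
    }
  }
  mito_alignment(m, control_region)
}

#' Comparator-species conservation matrix from a mutation table
#'
#' @param table A data frame shaped like [heligoland_mutation_table()].
#' @return Data frame with `position` and one base column per species,
#'   suitable for [conserved_positions()].
#' @export
mutation_table_conservation <- function(table) {
  species <- intersect(c("Rat", "Human", "Orangutan", "Dog", "Horse",
                         "Opossum"), names(table))
  table[, c("position", species)]
}
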