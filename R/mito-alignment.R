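#' Construct a mitochondrial alignment object
#'
#' Bundles a set of aligned, equal-length mitochondrial genome sequences with
#' the coordinates of the control region (D-loop). The control region is
#' excluded from the mutation-frequency clock: hypervariable sites there do
#' not behave like the rest of the molecule, so both the numerator (calls)
#' and the denominator (sequenced nucleotides) of the clock omit it.
#'
#' @param sequences Named character vector of equal-length nucleotide strings
#'   (IUPAC two-base ambiguity codes allowed, interpreted as double peaks), a
#'   character matrix (rows = genomes), or a [Biostrings::XStringSet].
#' @param control_region Half-open 0-based interval `c(start, end)` in
#'   alignment coordinates, or `NULL` if no region is masked. The default
#'   `c(15422, 16299)` is the mouse reference (NCBI37/mm9) chrM annotation:
#'   877 bp of D-loop at the end of a 16,299 bp molecule, leaving 15,422
#'   counted positions.
#' @return An object of class `mito_alignment`: a list with elements `seqs`
#'   (genome x position character matrix), `ids`, `length`, and
#'   `control_region`.
#' @export
mito_alignment <- function(sequences, control_region = c(15422L, 16299L)) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must have unique names")
    m <- .seq_to_matrix(sequences)
  }
  L <- ncol(m)
  if (!is.null(control_region)) {
    control_region <- as.integer(control_region)
    if (length(control_region) != 2L || control_region[1] < 0L ||
        control_region[2] > L || control_region[1] >= control_region[2])
      stop("control_region must be a half-open 0-based interval within [0, ",
           L, ")")
  }
  structure(
    list(seqs = m, ids = rownames(m), length = L,
         control_region = control_region),
    class = "mito_alignment"
  )
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("mito_alignment:", nrow(x$seqs), "genomes x", x$length, "bp\n")
  if (!is.null(x$control_region))
    cat("  control region (0-based, half-open): [",
        x$control_region[1], ", ", x$control_region[2], ")\n", sep = "")
  invisible(x)
}

#' Drop genomes from an alignment
#'
#' Used to remove recent immigrants identified by independent evidence before
#' any clock statistic is computed; the analysis never auto-detects them.
#'
#' @param alignment A [mito_alignment()].
#' @param ids Genome identifiers to exclude.
#' @return A `mito_alignment` without the excluded genomes.
#' @export
exclude_genomes <- function(alignment, ids) {
  stopifnot(inherits(alignment, "mito_alignment"))
  missing <- setdiff(ids, alignment$ids)
  if (length(missing))
    stop("unknown genome id(s): ", paste(missing, collapse = ", "))
  keep <- setdiff(alignment$ids, ids)
  if (length(keep) < 1L) stop("exclusion would remove every genome")
  mito_alignment(alignment$seqs[keep, , drop = FALSE],
                 alignment$control_region)
}

#' Number of counted (non-control-region) positions in an alignment
#' @param alignment A [mito_alignment()].
#' @return Integer number of alignment columns outside the control region.
#' @export
counted_length <- function(alignment) {
  stopifnot(inherits(alignment, "mito_alignment"))
  if (is.null(alignment$control_region)) return(alignment$length)
  alignment$length - (alignment$control_region[2] - alignment$control_region[1])
}

# positions: 1-based vector; TRUE where inside the control region
.in_control_region <- function(alignment, positions) {
  cr <- alignment$control_region
  if (is.null(cr)) return(rep(FALSE, length(positions)))
  positions > cr[1] & positions <= cr[2]
}
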