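#' Cohort consensus sequence
#'
#' Per-column strict-majority base over the cohort. Unambiguous bases carry
#' full weight; two-base IUPAC ambiguity codes (double peaks) contribute half
#' a weight to each constituent base. A tie, or a column with no unambiguous
#' call at all, is an error rather than an arbitrary choice, so repeated runs
#' can never disagree.
#'
#' @param alignment A [mito_alignment()] with at least two sequences.
#' @return Character string of the same length as the alignment.
#' @export
consensus_sequence <- function(alignment) {
  stopifnot(inherits(alignment, "mito_alignment"))
  m <- alignment$seqs
  if (nrow(m) < 2L) stop("consensus requires at least 2 sequences")
  cons <- m[1L, ]
  # columns where any genome differs from the first are the only ones that
  # need the weighted vote; uniform columns are the first row's base
  diffs <- t(m) != cons          # L x n, recycles cons down each genome
  variable <- which(rowSums(diffs) > 0L)
  uniform <- setdiff(seq_len(alignment$length), variable)
  bad_uniform <- uniform[cons[uniform] %in% names(.IUPAC2)]
  if (length(bad_uniform))
    stop("no unambiguous calls in column ", bad_uniform[1])
  for (j in variable) {
    cons[j] <- .column_consensus(m[, j], j)
  }
  paste(cons, collapse = "")
}

.column_consensus <- function(col, j) {
  w <- c(A = 0, C = 0, G = 0, T = 0)
  n_unambig <- 0L
  for (b in col) {
    if (b %in% names(w)) {
      w[b] <- w[b] + 1
      n_unambig <- n_unambig + 1L
    } else if (b %in% names(.IUPAC2)) {
      for (cb in .iupac_constituents(b)) w[cb] <- w[cb] + 0.5
    } else if (b == "-") {
      next  # gaps carry no weight; indel columns are handled downstream
    }
    # N and other codes are ignored
  }
  if (n_unambig == 0L) {
    if (all(col == "-")) return("-")
    stop("no unambiguous calls in column ", j)
  }
  top <- which(w == max(w))
  if (length(top) > 1L)
    stop("consensus tie in column ", j, " (",
         paste(names(w)[top], collapse = "/"), ")")
  names(w)[top]
}

#' Call new mutations against the cohort consensus
#'
#' Scans every alignment column and reports positions where at least one
#' genome differs from the consensus. Each distinct derived base at a
#' position yields one call, recording the genomes fixed for the derived
#' allele and the genomes showing it only as a double peak (heteroplasmy).
#'
#' The `counted` flag implements the clock's counting rules: a call enters
#' the mutation-frequency numerator only if (i) it lies outside the control
#' region and (ii) at least one genome carries the derived base as a fixed
#' call. A variant seen *only* as a heteroplasmy is treated as inherited
#' rather than new (double peaks whose derived base is also present fixed in
#' another animal reflect shared ancestry, and a lone double peak is not
#' counted either); the position is counted once regardless of how many
#' heteroplasmic co-carriers it has. Columns containing alignment gaps are
#' indel columns and are excluded from point-mutation calling.
#'
#' @param alignment A [mito_alignment()].
#' @param consensus Consensus string; computed from the alignment by default.
#' @param annotation Optional data frame with columns `position` (1-based)
#'   and `annotation` used to label calls (gene, tRNA, replication origin...).
#' @return A data frame of class `mutation_calls` with one row per
#'   (position, derived base): `position` (1-based), `consensus`, `derived`,
#'   `carriers` and `heteroplasmic_carriers` (comma-separated ids),
#'   `n_carriers`, `in_control_region`, `counted`, `annotation`.
#' @export
call_new_mutations <- function(alignment, consensus = NULL,
                               annotation = NULL) {
  stopifnot(inherits(alignment, "mito_alignment"))
  if (is.null(consensus)) consensus <- consensus_sequence(alignment)
  if (nchar(consensus) != alignment$length)
    stop("consensus length must equal alignment length")
  m <- alignment$seqs
  cons <- strsplit(toupper(consensus), "")[[1]]
  diffs <- t(m) != cons
  variable <- which(rowSums(diffs) > 0L)
  rows <- list()
  for (j in variable) {
    col <- m[, j]
    if (any(col == "-") || cons[j] == "-") next  # indel column
    fixed <- list()   # derived base -> ids
    het <- list()
    for (i in seq_along(col)) {
      b <- col[i]
      if (b == cons[j] || b == "N") next
      if (b %in% c("A", "C", "G", "T")) {
        fixed[[b]] <- c(fixed[[b]], rownames(m)[i])
      } else if (b %in% names(.IUPAC2)) {
        for (db in setdiff(.iupac_constituents(b), cons[j]))
          het[[db]] <- c(het[[db]], rownames(m)[i])
      }
    }
    for (db in sort(union(names(fixed), names(het)))) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = j,
        consensus = cons[j],
        derived = db,
        carriers = paste(fixed[[db]], collapse = ","),
        heteroplasmic_carriers = paste(het[[db]], collapse = ","),
        n_carriers = length(fixed[[db]]),
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), consensus = character(),
               derived = character(), carriers = character(),
               heteroplasmic_carriers = character(),
               n_carriers = integer(), stringsAsFactors = FALSE)
  calls$in_control_region <- .in_control_region(alignment, calls$position)
  calls$counted <- calls$n_carriers > 0L & !calls$in_control_region
  calls$annotation <- rep(NA_character_, nrow(calls))
  if (!is.null(annotation) && nrow(calls)) {
    idx <- match(calls$position, annotation$position)
    calls$annotation <- annotation$annotation[idx]
  }
  class(calls) <- c("mutation_calls", "data.frame")
  calls
}

#' Per-nucleotide mutation frequency
#'
#' The clock statistic: counted mutation positions divided by the total
#' number of nucleotides sequenced outside the control region, i.e.
#' `n_positions / (n_genomes * counted_length)`. A position carrying a
#' counted call is counted exactly once even if several derived alleles or
#' heteroplasmic co-carriers are recorded there.
#'
#' @param calls A `mutation_calls` data frame from [call_new_mutations()],
#'   or directly the integer number of counted positions.
#' @param n_genomes Number of genomes in the cohort (after exclusions).
#' @param counted_length Number of counted positions per genome, excluding
#'   the control region (see [counted_length()]).
#' @return Frequency per nucleotide (dimensionless).
#' @export
mutation_frequency <- function(calls, n_genomes, counted_length) {
  if (inherits(calls, "mutation_calls") || is.data.frame(calls)) {
    n_counted <- length(unique(calls$position[calls$counted]))
  } else {
    n_counted <- as.integer(calls)
    if (length(n_counted) != 1L || is.na(n_counted) || n_counted < 0L)
      stop("calls must be a mutation_calls table or a non-negative count")
  }
  if (n_genomes < 1L) stop("n_genomes must be >= 1")
  if (counted_length <= 0) stop("counted_length must be positive")
  n_counted / (n_genomes * counted_length)
}

#' Date a colonization by mutation-frequency calibration
#'
#' Under a star genealogy every lineage accumulates new mutations
#' independently since colonization, so the expected per-nucleotide mutation
#' frequency grows linearly with time and the age of one island cohort can
#' be read off another island whose colonization date is known from
#' historical records. The estimate is
#' `age = calibration_age * focal_frequency / calibration_frequency`.
#'
#' Rounding modes: `"ratio"` (default) rounds the frequency ratio to the
#' nearest integer before multiplying, reflecting the resolution the clock
#' actually has at these mutation counts ("about twice as old"); `"signif"`
#' rounds the year value to one significant figure; `"none"` returns the raw
#' value.
#'
#' @param focal_frequency Per-nucleotide mutation frequency of the cohort
#'   being dated (from [mutation_frequency()]).
#' @param calibration_frequency,calibration_age The calibration point: the
#'   frequency observed in a reference population and its known colonization
#'   age in years.
#' @param rounding One of `"ratio"`, `"signif"`, `"none"`.
#' @return List with `age` (point estimate, years), `age_unrounded`, and
#'   `ratio` (focal / calibration frequency).
#' @export
estimate_age <- function(focal_frequency, calibration_frequency,
                         calibration_age,
                         rounding = c("ratio", "signif", "none")) {
  rounding <- match.arg(rounding)
  if (focal_frequency < 0) stop("focal_frequency must be >= 0")
  if (calibration_frequency <= 0) stop("calibration_frequency must be > 0")
  if (calibration_age <= 0) stop("calibration_age must be > 0")
  ratio <- focal_frequency / calibration_frequency
  unrounded <- calibration_age * ratio
  age <- switch(rounding,
    ratio = round(ratio) * calibration_age,
    signif = signif(unrounded, 1),
    none = unrounded
  )
  list(age = age, age_unrounded = unrounded, ratio = ratio)
}

#' Resampling interval for the colonization age
#'
#' The dominant uncertainty in the clock is the Poisson noise of the small
#' mutation count. Counts are resampled from Poisson(n_counted), each
#' resample is converted to a frequency and an (unrounded) age, and a
#' percentile interval is returned.
#'
#' @param n_counted Observed number of counted mutation positions.
#' @param n_genomes,counted_length Denominator of the frequency (see
#'   [mutation_frequency()]).
#' @param calibration_frequency,calibration_age Calibration point.
#' @param n_boot Number of Poisson resamples (>= 100).
#' @param level Interval coverage level (default 0.95).
#' @param seed Optional integer seed.
#' @return Numeric vector `c(lower, upper)` in years, with attributes
#'   `point` (unrounded point estimate) and `level`.
#' @export
age_uncertainty <- function(n_counted, n_genomes, counted_length,
                            calibration_frequency, calibration_age,
                            n_boot = 10000L, level = 0.95, seed = NULL) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(n_boot, lambda = n_counted)
  freqs <- counts / (n_genomes * counted_length)
  ages <- calibration_age * freqs / calibration_frequency
  alpha <- (1 - level) / 2
  ci <- unname(quantile(ages, c(alpha, 1 - alpha), type = 7))
  point <- calibration_age *
    mutation_frequency(n_counted, n_genomes, counted_length) /
    calibration_frequency
  structure(ci, point = point, level = level)
}

#' Cross-species conservation screen for called mutations
#'
#' A new mutation falling at a position where a panel of distant comparator
#' species all carry the cohort consensus base lies in an otherwise highly
#' conserved region and is a candidate slightly-deleterious variant still
#' segregating after the colonization bottleneck.
#'
#' @param calls A `mutation_calls` data frame; only counted calls are
#'   screened.
#' @param conservation Data frame with a `position` column (1-based) and one
#'   column of bases per comparator species. A `consensus` column, if
#'   present, is ignored in favour of the calls' own consensus.
#' @return The subset of counted calls at positions where every comparator
#'   species carries the consensus base. With an empty species set all
#'   counted calls are returned.
#' @export
conserved_positions <- function(calls, conservation) {
  counted <- calls[calls$counted, , drop = FALSE]
  missing <- setdiff(counted$position, conservation$position)
  if (length(missing))
    stop("position(s) missing from conservation matrix: ",
         paste(missing, collapse = ", "))
  species <- setdiff(names(conservation), c("position", "consensus",
                                            "annotation"))
  if (length(species) == 0L) return(counted)
  idx <- match(counted$position, conservation$position)
  keep <- vapply(seq_len(nrow(counted)), function(i) {
    all(toupper(unlist(conservation[idx[i], species])) ==
          counted$consensus[i])
  }, logical(1))
  counted[keep, , drop = FALSE]
}
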