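#' Observed heterozygosity per locus
#'
#' Per locus, the fraction of scored individuals (both alleles present)
#' carrying two distinct alleles; loci with no scored individual in the
#' population are excluded with a warning.
#'
#' @param genotypes Data frame with columns `individual`, `population`,
#'   `locus`, `allele1`, `allele2` (integer alleles, `NA` = missing).
#' @param population Population to summarize.
#' @return List: `per_locus` (named numeric vector), `mean`.
#' @export
observed_heterozygosity <- function(genotypes, population) {
  g <- .pop_genotypes(genotypes, population)
  per <- vapply(split(g, g$locus), function(d) {
    scored <- !is.na(d$allele1) & !is.na(d$allele2)
    if (!any(scored)) return(NA_real_)
    mean(d$allele1[scored] != d$allele2[scored])
  }, numeric(1))
  .finish_locus_stats(per)
}

#' Expected heterozygosity per locus
#'
#' Allele frequencies are estimated from scored alleles only. The `"plain"`
#' estimator is gene diversity `1 - sum(p^2)`; the default
#' `"nei_unbiased"` applies Nei's small-sample correction
#' `2n/(2n - 1) * (1 - sum(p^2))` with `n` the number of scored diploid
#' individuals (the convention of classic population-genetics software).
#' Monomorphic loci return 0.
#'
#' @inheritParams observed_heterozygosity
#' @param estimator `"nei_unbiased"` (default) or `"plain"`.
#' @return List: `per_locus` (named numeric vector), `mean`.
#' @export
expected_heterozygosity <- function(genotypes, population,
                                    estimator = c("nei_unbiased", "plain")) {
  estimator <- match.arg(estimator)
  g <- .pop_genotypes(genotypes, population)
  per <- vapply(split(g, g$locus), function(d) {
    alleles <- c(d$allele1, d$allele2)
    alleles <- alleles[!is.na(alleles)]
    n2 <- length(alleles)
    if (n2 == 0L) return(NA_real_)
    p <- table(alleles) / n2
    h <- 1 - sum(p^2)
    if (estimator == "nei_unbiased" && n2 > 1L) h <- h * n2 / (n2 - 1)
    h
  }, numeric(1))
  .finish_locus_stats(per)
}

#' Mean number of alleles per locus
#'
#' @inheritParams observed_heterozygosity
#' @return Arithmetic mean over loci of the number of distinct observed
#'   alleles.
#' @export
mean_alleles_per_locus <- function(genotypes, population) {
  g <- .pop_genotypes(genotypes, population)
  per <- vapply(split(g, g$locus), function(d) {
    alleles <- c(d$allele1, d$allele2)
    length(unique(alleles[!is.na(alleles)]))
  }, numeric(1))
  mean(per[per > 0])
}

#' Per-population diversity summary table
#'
#' One row per population: number of individuals (N), mean observed
#' heterozygosity, mean expected heterozygosity (both estimators) and mean
#' number of alleles per locus.
#'
#' @param genotypes Long-format genotype data frame (see
#'   [observed_heterozygosity()]).
#' @return Data frame with columns `population`, `N`, `H_obs`,
#'   `H_exp_unbiased`, `H_exp_plain`, `A_av`.
#' @export
microsat_summary <- function(genotypes) {
  pops <- unique(genotypes$population)
  do.call(rbind, lapply(pops, function(p) {
    g <- genotypes[genotypes$population == p, , drop = FALSE]
    data.frame(
      population = p,
      N = length(unique(g$individual)),
      H_obs = observed_heterozygosity(genotypes, p)$mean,
      H_exp_unbiased = expected_heterozygosity(genotypes, p,
                                               "nei_unbiased")$mean,
      H_exp_plain = expected_heterozygosity(genotypes, p, "plain")$mean,
      A_av = mean_alleles_per_locus(genotypes, p),
      stringsAsFactors = FALSE)
  }))
}

.pop_genotypes <- function(genotypes, population) {
  g <- genotypes[genotypes$population == population, , drop = FALSE]
  if (nrow(g) == 0L) stop("no individuals in population ", population)
  bad <- c(g$allele1, g$allele2)
  bad <- bad[!is.na(bad)]
  if (any(bad <= 0)) stop("alleles must be positive integers")
  g
}

.finish_locus_stats <- function(per) {
  if (any(is.na(per))) {
    warning("locus/loci with zero scored individuals excluded: ",
            paste(names(per)[is.na(per)], collapse = ", "))
    per <- per[!is.na(per)]
  }
  list(per_locus = per, mean = mean(per))
}

#' Read a GenePop genotype file
#'
#' Parses the classic GenePop format: a title line, one locus name per line
#' (or one comma-separated line), `Pop` separators, and per-individual
#' lines `id , 0102 0304 ...` with 2- or 3-digit allele codes (00/000 =
#' missing). Populations are named after their first individual unless
#' `pop_names` is supplied.
#'
#' @param path Path to a GenePop file.
#' @param pop_names Optional character vector of population names.
#' @return Long-format genotype data frame (see
#'   [observed_heterozygosity()]).
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nchar(lines) > 0]
  if (length(lines) < 3L) stop("not a GenePop file: too short")
  body <- lines[-1]
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("no Pop separator found")
  loci_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nchar(loci) > 0]
  out <- list()
  bounds <- c(pop_idx, length(body) + 1L)
  for (p in seq_along(pop_idx)) {
    ind_lines <- body[seq(bounds[p] + 1L, bounds[p + 1] - 1L)]
    first_id <- trimws(strsplit(ind_lines[1], ",")[[1]][1])
    pname <- if (!is.null(pop_names)) pop_names[p] else first_id
    for (line in ind_lines) {
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2L) stop("malformed individual line: ", line)
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                        "[[:space:]]+")[[1]]
      if (length(codes) != length(loci))
        stop("individual ", id, " has ", length(codes),
             " genotypes for ", length(loci), " loci")
      width <- nchar(codes[1]) / 2
      if (!width %in% c(2, 3)) stop("allele codes must be 4 or 6 digits")
      a1 <- as.integer(substr(codes, 1, width))
      a2 <- as.integer(substr(codes, width + 1, 2 * width))
      a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
      out[[length(out) + 1L]] <- data.frame(
        individual = id, population = pname, locus = loci,
        allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
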