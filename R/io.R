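#' Read a FASTA file
#'
#' Line-wrapping-agnostic, order- and identifier-preserving; gap characters
#' and IUPAC ambiguity codes pass through untouched.
#'
#' @param path Path to a FASTA file.
#' @param to_upper Normalize to uppercase (default `TRUE`).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, to_upper = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- setNames(as.character(set), ids)
  if (to_upper) seqs <- toupper(seqs)
  seqs
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# blocks/segments here use 1-based starts with half-open ends in bp; a BED
# record for the same region is (start - 1, end - 1), 0-based half-open.
.intervals_to_granges <- function(df, score = NULL) {
  if (any(df$end <= df$start)) stop("interval end must exceed start")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end - 1))
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write genomic intervals as BED (0-based, half-open)
#'
#' @param intervals Data frame with `chrom`, `start` (1-based bp), `end`
#'   (half-open), optionally `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) { file.create(path); return(invisible(path)) }
  if (is.unsorted(order(intervals$chrom, intervals$start))) {
    warning("unsorted intervals: sorting on write")
  }
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  gr <- .intervals_to_granges(intervals)
  if (!is.null(intervals$name)) names(gr) <- intervals$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into the package interval convention
#' @param path Path to a BED file.
#' @return Data frame with `chrom`, `start` (1-based), `end` (half-open).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr) + 1,
             stringsAsFactors = FALSE)
}

#' Write a copy-number profile as bedGraph
#'
#' @param profile Data frame from [copy_count_profile()].
#' @param path Output path.
#' @export
write_bedgraph <- function(profile, path) {
  if (nrow(profile) == 0) { file.create(path); return(invisible(path)) }
  gr <- .intervals_to_granges(profile, score = profile$n_copies)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a haplotype network to GML or DOT
#'
#' Node attributes carry haplotype frequency, population label and the
#' median-vector flag (as 0/1, so the file round-trips through the GML
#' reader); edges carry the mutational step count.
#'
#' @param network A [median_joining()] result.
#' @param path Output path.
#' @param format `"gml"` or `"dot"`.
#' @export
write_network <- function(network, path, format = c("gml", "dot")) {
  format <- match.arg(format)
  g <- network$graph
  igraph::V(g)$median <- as.integer(igraph::V(g)$median)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Read a GML haplotype network written by [write_network()]
#' @param path Path to a GML file.
#' @return An igraph object with the node/edge attributes restored.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  igraph::V(g)$median <- as.logical(igraph::V(g)$median)
  g
}

#' Write / read landmark coordinates as TSV
#'
#' Long format: `specimen_id`, `group`, `landmark` (1-based index), `x`,
#' `y`.
#'
#' @param coords n x k x 2 array.
#' @param groups One label per specimen.
#' @param path Output path.
#' @export
write_landmarks <- function(coords, groups, path) {
  n <- dim(coords)[1]; k <- dim(coords)[2]
  ids <- dimnames(coords)[[1]]
  if (is.null(ids)) ids <- sprintf("spec_%03d", seq_len(n))
  df <- data.frame(
    specimen_id = rep(ids, each = k),
    group = rep(as.character(groups), each = k),
    landmark = rep(seq_len(k), n),
    x = as.vector(t(coords[, , 1])),
    y = as.vector(t(coords[, , 2])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @param path Path to a landmark TSV.
#' @return For `read_landmarks`: list with `coords` (n x k x 2 array) and
#'   `group`.
#' @export
read_landmarks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$specimen_id)
  k <- max(df$landmark)
  coords <- array(NA_real_, dim = c(length(ids), k, 2),
                  dimnames = list(ids, NULL, c("x", "y")))
  group <- character(length(ids))
  for (i in seq_along(ids)) {
    d <- df[df$specimen_id == ids[i], ]
    d <- d[order(d$landmark), ]
    coords[i, , ] <- cbind(d$x, d$y)
    group[i] <- d$group[1]
  }
  list(coords = coords, group = group)
}

#' Write / read landmarks in TPS format
#'
#' The minimal TPS dialect used by digitizing software: an `LM=k` line, k
#' coordinate lines, and an `ID=` line per specimen.
#'
#' @param coords n x k x 2 array.
#' @param path Output path.
#' @export
write_tps <- function(coords, path) {
  n <- dim(coords)[1]; k <- dim(coords)[2]
  ids <- dimnames(coords)[[1]]
  if (is.null(ids)) ids <- sprintf("spec_%03d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("LM=%d", k), con)
    writeLines(sprintf("%.10g %.10g", coords[i, , 1], coords[i, , 2]), con)
    writeLines(sprintf("ID=%s", ids[i]), con)
  }
  invisible(path)
}

#' @rdname write_tps
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nchar(lines) > 0]
  specs <- list(); ids <- character()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i])) stop("expected LM= line at line ", i)
    k <- as.integer(sub("^LM=", "", lines[i]))
    xy <- do.call(rbind, lapply(lines[i + seq_len(k)], function(l)
      as.numeric(strsplit(l, "[[:space:]]+")[[1]])))
    i <- i + k + 1L
    id <- if (i <= length(lines) && grepl("^ID=", lines[i])) {
      v <- sub("^ID=", "", lines[i]); i <- i + 1L; v
    } else sprintf("spec_%03d", length(specs) + 1L)
    specs[[length(specs) + 1L]] <- xy
    ids <- c(ids, id)
  }
  coords <- array(NA_real_, dim = c(length(specs), nrow(specs[[1]]), 2),
                  dimnames = list(ids, NULL, c("x", "y")))
  for (j in seq_along(specs)) coords[j, , ] <- specs[[j]]
  coords
}

#' Read / write local-ancestry probability tracks
#'
#' Tab-separated with header `individual`, `haplotype`, `chrom`, `pos`
#' (1-based bp), `prob_sourceA` (probability, or the literal 9 for unknown
#' ancestry).
#'
#' @param path Path to a track TSV.
#' @return Data frame in the track format.
#' @export
read_ancestry_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "haplotype", "chrom", "pos", "prob_sourceA")
  if (!all(need %in% names(df)))
    stop("track file must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_ancestry_track
#' @param track Track data frame.
#' @export
write_ancestry_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes file (two columns: chrom, length)
#' @param path Path to a chrom.sizes TSV.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write a provenance record for a run
#'
#' Every command writes a JSON block sufficient to re-run it identically:
#' package version, timestamp, and the full parameter set including any
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param command Name of the command or function.
#' @param params Named list of parameters.
#' @return Path of the written JSON, invisibly.
#' @export
write_provenance <- function(dir, command, params) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(
    list(tool = "islandmouse",
         version = as.character(packageVersion("islandmouse")),
         command = command,
         timestamp = format(Sys.time(), tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ"),
         parameters = params),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
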