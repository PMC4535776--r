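#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences are merged into haplotype classes. Identity is judged
#' over substitution sites only: alignment columns containing gap characters
#' are treated as indel columns, and a maximal run of adjacent gap columns
#' with an identical gap pattern across sequences counts as one indel event,
#' recorded separately (mitochondrial D-loop indels are hypermutable and are
#' conventionally excluded from mutational-step counts).
#'
#' @param sequences Named character vector of equal-length aligned
#'   sequences.
#' @param labels Optional named character vector mapping sequence id ->
#'   population label.
#' @param indel_policy `"annotate"` (default) records indel events;
#'   `"ignore"` drops them.
#' @return List of class `haplotype_table`: `haplotypes` (data frame with
#'   `haplotype_id`, `sequence` -- the states at variable sites --,
#'   `frequency`, `members`, `populations`), `variable_sites` (1-based
#'   alignment columns), `indel_events` (data frame with `start`, `end`
#'   half-open columns and per-haplotype carrier status), and `n_sequences`.
#' @export
collapse_haplotypes <- function(sequences, labels = NULL,
                                indel_policy = c("annotate", "ignore")) {
  indel_policy <- match.arg(indel_policy)
  if (length(sequences) == 0L) stop("no input sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  m <- .seq_to_matrix(sequences)
  gap_col <- apply(m == "-", 2, any)
  sub_sites <- which(!gap_col &
                       apply(m, 2, function(x) length(unique(x)) > 1L))
  key <- if (length(sub_sites))
    apply(m[, sub_sites, drop = FALSE], 1, paste, collapse = "") else
      rep("", nrow(m))
  classes <- split(rownames(m), key)
  classes <- classes[order(names(classes))]   # deterministic ids
  hap <- data.frame(
    haplotype_id = sprintf("H%d", seq_along(classes)),
    sequence = names(classes),
    frequency = vapply(classes, length, integer(1)),
    stringsAsFactors = FALSE)
  hap$members <- unname(classes)
  hap$populations <- lapply(classes, function(ids) {
    if (is.null(labels)) character() else sort(unique(unname(labels[ids])))
  })
  rownames(hap) <- NULL
  indel_events <- data.frame(start = integer(), end = integer())
  if (indel_policy == "annotate" && any(gap_col)) {
    pat <- apply(m == "-", 2, paste, collapse = "")
    idx <- which(gap_col)
    runs <- split(idx, cumsum(c(TRUE, diff(idx) != 1L |
                                  pat[idx][-1] != pat[idx][-length(idx)])))
    indel_events <- do.call(rbind, lapply(runs, function(cols) {
      carried <- m[, cols[1]] != "-"      # TRUE = carries the inserted bases
      states <- vapply(classes, function(ids) {
        cs <- unique(carried[ids])
        if (length(cs) > 1L) "mixed" else if (cs) "insert" else "gap"
      }, character(1))
      cbind(data.frame(start = cols[1], end = cols[length(cols)] + 1L),
            as.data.frame(as.list(setNames(states, hap$haplotype_id)),
                          optional = TRUE))
    }))
    rownames(indel_events) <- NULL
  }
  structure(list(haplotypes = hap, variable_sites = sub_sites,
                 indel_events = indel_events,
                 n_sequences = length(sequences)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", nrow(x$haplotypes), "haplotypes from",
      x$n_sequences, "sequences;", length(x$variable_sites),
      "variable sites;", nrow(x$indel_events), "indel events\n")
  invisible(x)
}

# ---- internal graph machinery -------------------------------------------

.state_matrix <- function(x) {
  if (inherits(x, "haplotype_table")) {
    states <- do.call(rbind, strsplit(x$haplotypes$sequence, ""))
    rownames(states) <- x$haplotypes$haplotype_id
    states
  } else {
    .seq_to_matrix(x)
  }
}

.hamming <- function(states) {
  n <- nrow(states)
  D <- matrix(0L, n, n, dimnames = list(rownames(states), rownames(states)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- sum(states[i, ] != states[j, ])
  }
  D
}

# edges of the epsilon-relaxed minimum spanning network: (u,v) is a link iff
# u and v fall in different components of the graph restricted to edges
# strictly cheaper than d(u,v) - epsilon. epsilon = 0 gives the union of all
# minimum spanning trees.
.msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  edges <- NULL
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, length.out = n - i)) {
    comp <- seq_len(n)
    w <- D[i, j] - epsilon
    repeat {
      merged <- FALSE
      for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        if (D[a, b] < w && comp[a] != comp[b]) {
          comp[comp == comp[b]] <- comp[a]
          merged <- TRUE
        }
      }
      if (!merged) break
    }
    if (comp[i] != comp[j]) edges <- rbind(edges, c(i, j))
  }
  edges
}

# Kruskal MST total weight (cost is tie-break independent)
.mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[pairs], pairs[, 1], pairs[, 2])
  comp <- seq_len(n)
  cost <- 0
  for (k in ord) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (comp[a] != comp[b]) {
      cost <- cost + D[a, b]
      comp[comp == comp[b]] <- comp[a]
    }
  }
  cost
}

# quasi-medians of three aligned state vectors: coordinatewise majority where
# two agree; positions where all three differ expand combinatorially
.quasi_medians <- function(a, b, c, max_expand = 81L) {
  opts <- vector("list", length(a))
  for (p in seq_along(a)) {
    v <- c(a[p], b[p], c[p])
    t <- table(v)
    opts[[p]] <- if (max(t) >= 2) names(t)[which.max(t)] else unique(v)
  }
  n_comb <- prod(lengths(opts))
  if (n_comb > max_expand) {
    # keep only fully majority-resolved positions' expansion bounded by
    # fixing unresolved positions to the lexicographically smallest state
    opts <- lapply(opts, function(o) sort(o)[1])
  }
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

#' Median-joining haplotype network
#'
#' Builds a median-joining network: iterated minimum-spanning networks over
#' the observed haplotypes, augmented with inferred intermediate haplotypes
#' ("median vectors", quasi-medians of connected triples) where they reduce
#' the total connection cost, with unused median vectors pruned on
#' termination. With `epsilon = 0` (the default of the software tradition
#' this follows) the result contains the minimum-spanning network. Edge
#' weights are mutational steps (Hamming distance over variable sites);
#' non-binary characters are treated as distinct states.
#'
#' @param x A [collapse_haplotypes()] table, or a named character vector of
#'   distinct state strings.
#' @param epsilon Non-negative relaxation parameter of the
#'   minimum-spanning-network step.
#' @param max_rounds Safety cap on median-addition rounds.
#' @return List of class `haplotype_network`: `graph` (igraph object with
#'   node attributes `sequence`, `frequency`, `median`, `population` and
#'   edge attribute `steps`), `nodes`, `edges` data frames, `cost` (total
#'   mutational steps of a minimum spanning tree over the retained nodes)
#'   and `epsilon`.
#' @export
median_joining <- function(x, epsilon = 0, max_rounds = 25L) {
  states <- .state_matrix(x)
  if (nrow(states) < 2L) stop("need at least 2 haplotypes")
  freq <- if (inherits(x, "haplotype_table"))
    setNames(x$haplotypes$frequency, x$haplotypes$haplotype_id) else
      setNames(rep(1L, nrow(states)), rownames(states))
  pops <- if (inherits(x, "haplotype_table"))
    setNames(vapply(x$haplotypes$populations, paste, character(1),
                    collapse = ","), x$haplotypes$haplotype_id) else
      setNames(rep("", nrow(states)), rownames(states))
  observed <- rownames(states)
  mv_count <- 0L

  for (round in seq_len(max_rounds)) {
    D <- .hamming(states)
    msn <- .msn_edges(D, epsilon)
    link <- matrix(FALSE, nrow(states), nrow(states))
    if (!is.null(msn)) for (r in seq_len(nrow(msn)))
      link[msn[r, 1], msn[r, 2]] <- link[msn[r, 2], msn[r, 1]] <- TRUE
    existing <- apply(states, 1, paste, collapse = "")
    cand_states <- character()
    n <- nrow(states)
    if (n >= 3) {
      trip <- utils::combn(n, 3)
      for (t in seq_len(ncol(trip))) {
        u <- trip[1, t]; v <- trip[2, t]; w <- trip[3, t]
        if (link[u, v] + link[u, w] + link[v, w] < 2) next
        for (qm in .quasi_medians(states[u, ], states[v, ], states[w, ])) {
          s <- paste(qm, collapse = "")
          if (s %in% existing || s %in% cand_states) next
          cand_states <- c(cand_states, s)
        }
      }
    }
    if (!length(cand_states)) break
    new_states <- sort(cand_states)          # lexicographic determinism
    add <- do.call(rbind, strsplit(new_states, ""))
    rownames(add) <- sprintf("MV%d", mv_count + seq_len(nrow(add)))
    mv_count <- mv_count + nrow(add)
    states <- rbind(states, add)
  }

  # prune median vectors whose removal does not increase the minimum
  # spanning cost over the remaining nodes
  repeat {
    D <- .hamming(states)
    base <- .mst_cost(D)
    medians <- setdiff(rownames(states), observed)
    dropped <- FALSE
    for (mv in sort(medians)) {
      keep <- setdiff(rownames(states), mv)
      if (.mst_cost(D[keep, keep, drop = FALSE]) <= base) {
        states <- states[keep, , drop = FALSE]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  D <- .hamming(states)
  msn <- .msn_edges(D, epsilon)
  is_median <- !(rownames(states) %in% observed)
  nodes <- data.frame(
    id = rownames(states),
    sequence = apply(states, 1, paste, collapse = ""),
    frequency = ifelse(is_median, 0L, freq[rownames(states)]),
    median = is_median,
    population = ifelse(is_median, "", pops[rownames(states)]),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges <- if (is.null(msn))
    data.frame(from = character(), to = character(), steps = integer()) else
    data.frame(from = rownames(states)[msn[, 1]],
               to = rownames(states)[msn[, 2]],
               steps = D[msn], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges,
                 cost = .mst_cost(D), epsilon = epsilon),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$median), "median vectors ),", nrow(x$edges),
      "edges, cost", x$cost, "\n")
  invisible(x)
}
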