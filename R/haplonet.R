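#' Collapse an alignment into haplotypes
#'
#' Alignment columns containing any `N` or gap are removed first
#' (complete deletion, so that haplotype identity is transitive), then
#' identical sequences collapse into one haplotype.  Haplotypes are named
#' `H1, H2, ...` in order of decreasing frequency (ties by first
#' occurrence), and per-stratum counts are attached from the metadata.
#'
#' @param aln A [haplo_aln()] with at least one sample.
#' @param metadata Optional tibble with columns `sample`, `group`,
#'   `geography`, `race`; defaults to the alignment's population labels as
#'   `group`.
#' @return A `haplo_table`: tibble with `haplotype`, `freq`, `samples`
#'   (list), `seq`, plus nested `strata` counts, and the reduced site count
#'   in `attr(, "n_sites_used")`.
#' @export
collapse_haplotypes <- function(aln, metadata = NULL) {
  if (nrow(aln$seq) < 1L) abort("Empty alignment.", class = "popgenscan_empty_error")
  keep <- apply(aln$seq, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- aln$seq[, keep, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) seqs <- rep("", nrow(aln$seq))
  first <- match(unique(seqs), seqs)
  groups <- split(aln$samples, factor(seqs, levels = seqs[first]))
  ord <- order(-lengths(groups), match(names(groups), seqs[first]))
  groups <- groups[ord]
  if (is.null(metadata)) {
    metadata <- tibble(sample = aln$samples,
                       group = unname(aln$population[aln$samples]),
                       geography = NA_character_, race = NA_character_)
  }
  out <- tibble(
    haplotype = paste0("H", seq_along(groups)),
    freq = unname(lengths(groups)),
    samples = unname(groups),
    seq = names(groups)
  )
  out$strata <- purrr::map(out$samples, function(s) {
    md <- metadata[match(s, metadata$sample), ]
    list(group = table(md$group), geography = table(md$geography),
         race = table(md$race))
  })
  attr(out, "n_sites_used") <- ncol(m)
  class(out) <- c("haplo_table", class(out))
  out
}

#' Hamming distance matrix between haplotypes
#'
#' @param table A `haplo_table` from [collapse_haplotypes()].
#' @return Symmetric integer matrix of differing-site counts with zero
#'   diagonal, dimnames = haplotype ids.
#' @export
hamming_matrix <- function(table) {
  seqs <- strsplit(table$seq, "")
  k <- length(seqs)
  d <- matrix(0L, k, k, dimnames = list(table$haplotype, table$haplotype))
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- sum(seqs[[i]] != seqs[[j]])
    }
  }
  d
}

#' Minimum-spanning haplotype network
#'
#' Kruskal minimum spanning tree over the Hamming distances with
#' deterministic tie-breaking (ascending distance, then lexicographic
#' haplotype-id order).  Every non-tree edge whose distance equals the
#' largest distance on the tree path between its endpoints is also emitted,
#' flagged `alternative = TRUE` (a minimum spanning network).
#'
#' @param dist Symmetric distance matrix with haplotype dimnames.
#' @return Tibble of edges: `from`, `to`, `distance`, `in_spanning_tree`,
#'   `alternative`.
#' @export
build_network <- function(dist) {
  ids <- rownames(dist)
  k <- length(ids)
  if (k <= 1L) {
    return(tibble(from = character(0), to = character(0), distance = numeric(0),
                  in_spanning_tree = logical(0), alternative = logical(0)))
  }
  pairs <- which(upper.tri(dist), arr.ind = TRUE)
  edges <- tibble(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                  distance = dist[pairs])
  edges <- dplyr::arrange(edges, .data$distance, .data$from, .data$to)
  # Kruskal with union-find
  parent <- seq_len(k); names(parent) <- ids
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  intree <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ra <- find(match(edges$from[e], ids)); rb <- find(match(edges$to[e], ids))
    if (ra != rb) { parent[ra] <- rb; intree[e] <- TRUE }
  }
  edges$in_spanning_tree <- intree
  # adjacency of the tree for path-max queries
  tre <- edges[intree, ]
  adj <- lapply(setNames(seq_len(k), ids), function(i) integer(0))
  wts <- lapply(setNames(seq_len(k), ids), function(i) numeric(0))
  for (e in seq_len(nrow(tre))) {
    a <- tre$from[e]; b <- tre$to[e]; w <- tre$distance[e]
    adj[[a]] <- c(adj[[a]], match(b, ids)); wts[[a]] <- c(wts[[a]], w)
    adj[[b]] <- c(adj[[b]], match(a, ids)); wts[[b]] <- c(wts[[b]], w)
  }
  path_max <- function(a, b) {
    # DFS from a to b over the tree, tracking the max edge weight
    stack <- list(list(node = match(a, ids), maxw = -Inf, prev = 0L))
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (ids[cur$node] == b) return(cur$maxw)
      nb <- adj[[ids[cur$node]]]; w <- wts[[ids[cur$node]]]
      for (q in seq_along(nb)) {
        if (nb[q] != cur$prev) {
          stack[[length(stack) + 1L]] <- list(node = nb[q],
                                              maxw = max(cur$maxw, w[q]),
                                              prev = cur$node)
        }
      }
    }
    Inf
  }
  edges$alternative <- FALSE
  nontree <- which(!intree)
  for (e in nontree) {
    if (edges$distance[e] == path_max(edges$from[e], edges$to[e])) {
      edges$alternative[e] <- TRUE
    }
  }
  edges[edges$in_spanning_tree | edges$alternative, ]
}

#' Plot-ready haplotype network report
#'
#' Nodes carry the haplotype frequency and its per-stratum composition for
#' the chosen stratifier; edges carry substitution distances.  The report
#' can be serialised with [network_json()] and [network_dot()].
#'
#' @param table A `haplo_table`.
#' @param edges Edge tibble from [build_network()].
#' @param stratify_by One of `"group"`, `"geography"`, `"race"`.
#' @return A `haplo_network` list: `nodes` (tibble `haplotype`, `freq`,
#'   `composition` list of named counts), `edges`, `stratify_by`.
#' @export
network_report <- function(table, edges, stratify_by = c("group", "geography", "race")) {
  stratify_by <- match.arg(stratify_by)
  nodes <- tibble(
    haplotype = table$haplotype, freq = table$freq,
    composition = purrr::map(table$strata, function(s) {
      tb <- s[[stratify_by]]
      setNames(as.integer(tb), names(tb))
    })
  )
  structure(list(nodes = nodes, edges = edges, stratify_by = stratify_by,
                 seqs = setNames(table$seq, table$haplotype)),
            class = "haplo_network")
}

#' @rdname network_report
#' @param network A `haplo_network`.
#' @return `network_json()`: a JSON string; `network_dot()`: a DOT string.
#' @export
network_json <- function(network) {
  obj <- list(
    stratify_by = network$stratify_by,
    nodes = purrr::map(seq_len(nrow(network$nodes)), function(i) {
      list(haplotype = network$nodes$haplotype[i],
           freq = network$nodes$freq[i],
           composition = as.list(network$nodes$composition[[i]]))
    }),
    edges = purrr::map(seq_len(nrow(network$edges)), function(i) {
      as.list(network$edges[i, c("from", "to", "distance",
                                 "in_spanning_tree", "alternative")])
    })
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' @rdname network_report
#' @export
network_dot <- function(network) {
  lines <- c("graph haplotypes {")
  for (i in seq_len(nrow(network$nodes))) {
    lines <- c(lines, sprintf('  %s [label="%s (%d)", width=%.2f];',
                              network$nodes$haplotype[i], network$nodes$haplotype[i],
                              network$nodes$freq[i],
                              0.3 + sqrt(network$nodes$freq[i]) / 4))
  }
  for (i in seq_len(nrow(network$edges))) {
    style <- if (network$edges$in_spanning_tree[i]) "solid" else "dashed"
    lines <- c(lines, sprintf('  %s -- %s [label="%g", style=%s];',
                              network$edges$from[i], network$edges$to[i],
                              network$edges$distance[i], style))
  }
  paste(c(lines, "}"), collapse = "\n")
}
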