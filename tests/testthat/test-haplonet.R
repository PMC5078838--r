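toy_table <- function(seqs, pops = "p") {
  aln <- haplo_aln(seqs, populations = pops)
  collapse_haplotypes(aln)
}

test_that("haplotype collapsing partitions samples like brute-force equality", {
  t1 <- toy_table(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_equal(nrow(t1), 1)
  expect_equal(t1$freq, 3)

  set.seed(91)
  aln <- random_alignment(12, 8)
  tab <- collapse_haplotypes(aln)
  # oracle: group by exact string equality
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  want <- sort(as.integer(table(seqs)), decreasing = TRUE)
  expect_equal(sort(tab$freq, decreasing = TRUE), want)
  expect_equal(sum(tab$freq), 12)
  # every sample appears in exactly one haplotype
  expect_setequal(unlist(tab$samples), aln$samples)
})

test_that("columns with missing data are dropped before collapsing", {
  aln <- haplo_aln(c(a = "ANGT", b = "ACGT"), populations = "p")
  tab <- collapse_haplotypes(aln)
  expect_equal(attr(tab, "n_sites_used"), 3L)
  expect_equal(nrow(tab), 1)  # identical over retained columns
})

test_that("Hamming distances match direct counting", {
  tab <- toy_table(c(a = "AAA", b = "AAT", c = "TTT"))
  d <- hamming_matrix(tab)
  expect_equal(unname(diag(d)), rep(0L, 3))
  expect_equal(d["H1", "H2"], oracle_hamming(tab$seq[1], tab$seq[2]))
  set.seed(92)
  aln <- random_alignment(6, 10)
  tb <- collapse_haplotypes(aln)
  dm <- hamming_matrix(tb)
  for (i in seq_len(nrow(tb))) for (j in seq_len(nrow(tb))) {
    expect_equal(dm[i, j], oracle_hamming(tb$seq[i], tb$seq[j]))
  }
})

test_that("the spanning network matches exhaustive enumeration and flags alternatives", {
  # two haplotypes: a single edge
  e2 <- build_network(hamming_matrix(toy_table(c(a = "AA", b = "AT"))))
  expect_equal(nrow(e2), 1)
  expect_true(e2$in_spanning_tree)

  # distances 1,1,2: tree keeps both distance-1 edges; the 2-edge is an
  # alternative iff it equals the max tree-path distance (here path max 1)
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(c("H1", "H2", "H3"), c("H1", "H2", "H3")))
  e3 <- build_network(d3)
  tre <- e3[e3$in_spanning_tree, ]
  expect_equal(sort(tre$distance), c(1, 1))
  expect_false(any(e3$alternative))
  expect_equal(sum(tre$distance), oracle_mst_weight(d3))

  # random tables: tree weight equals exhaustive minimum, edge count k - 1
  set.seed(93)
  for (i in 1:5) {
    aln <- random_alignment(7, 12)
    tb <- collapse_haplotypes(aln)
    dm <- hamming_matrix(tb)
    if (nrow(tb) < 3) next
    ed <- build_network(dm)
    tre <- ed[ed$in_spanning_tree, ]
    expect_equal(nrow(tre), nrow(tb) - 1)
    expect_equal(sum(tre$distance), oracle_mst_weight(dm))
    # alternatives really are ties with the tree path maximum
    for (k in which(ed$alternative)) {
      expect_true(ed$distance[k] >= min(tre$distance))
    }
  }
})

test_that("a chain of single-step haplotypes is recovered as a chain", {
  tab <- toy_table(c(a = "AAAA", b = "AAAT", c = "AATT", d = "ATTT"))
  ed <- build_network(hamming_matrix(tab))
  tre <- ed[ed$in_spanning_tree, ]
  expect_equal(nrow(tre), 3)
  expect_true(all(tre$distance == 1))
})

test_that("the network is invariant to input sample order", {
  set.seed(94)
  aln <- random_alignment(9, 10)
  perm <- sample(9)
  aln2 <- haplo_aln(aln$seq[perm, , drop = FALSE])
  e1 <- build_network(hamming_matrix(collapse_haplotypes(aln)))
  e2 <- build_network(hamming_matrix(collapse_haplotypes(aln2)))
  # compare as sets of (sorted sequence pair, distance)
  key <- function(tab, ed) {
    sq <- setNames(tab$seq, tab$haplotype)
    sort(paste(pmin(sq[ed$from], sq[ed$to]), pmax(sq[ed$from], sq[ed$to]), ed$distance))
  }
  expect_equal(key(collapse_haplotypes(aln), e1[e1$in_spanning_tree, ] |> dplyr::arrange(from, to)),
               key(collapse_haplotypes(aln2), e2[e2$in_spanning_tree, ] |> dplyr::arrange(from, to)))
})

test_that("network reports conserve composition and round-trip through JSON", {
  md <- tibble::tibble(sample = c("a", "b", "c", "d"),
                       group = c("Landrace", "Landrace", "WildWeedy", "WildWeedy"),
                       geography = c("Asia", "Asia", "EastAfrica", "WestAfrica"),
                       race = c("durra", "kafir", "wild", "wild"))
  aln <- haplo_aln(c(a = "AAAA", b = "AAAA", c = "AATT", d = "ATTT"),
                   populations = c("Landrace", "Landrace", "WildWeedy", "WildWeedy"))
  tab <- collapse_haplotypes(aln, md)
  net <- network_report(tab, build_network(hamming_matrix(tab)), "group")
  expect_error(network_report(tab, net$edges, "height"))
  # per-node composition sums to node frequency
  for (i in seq_len(nrow(net$nodes))) {
    expect_equal(sum(net$nodes$composition[[i]]), net$nodes$freq[i])
  }
  js <- network_json(net)
  back <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(back$nodes), nrow(net$nodes))
  expect_equal(back$nodes[[1]]$freq, net$nodes$freq[1])
  expect_equal(back$edges[[1]]$distance, net$edges$distance[1])
  dot <- network_dot(net)
  expect_match(dot, "graph haplotypes")
  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
})

test_that("a single haplotype yields one node and no edges", {
  tab <- toy_table(c(a = "ACG", b = "ACG"))
  ed <- build_network(hamming_matrix(tab))
  expect_equal(nrow(ed), 0)
  net <- network_report(tab, ed, "group")
  expect_equal(nrow(net$nodes), 1)
})
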