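#' Haplotype alignment objects
#'
#' A haplotype alignment is a rectangular sample-by-site character matrix over
#' the alphabet `A, C, G, T, N, -`, carrying a population label per sample and
#' a region tag (`gene` or `CDS`).  It is the unit every diversity, Ka/Ks,
#' selection-scan and haplotype-network operation consumes.
#'
#' @param seqs Character matrix (samples x sites) or a character vector of
#'   equal-length sequences, one per sample.
#' @param samples Sample names; defaults to rownames/names of `seqs`.
#' @param populations Character vector of population labels, one per sample
#'   (recycled if length 1).
#' @param gene_id Gene identifier for the region.
#' @param feature Either `"gene"` or `"CDS"`.
#'
#' @return An object of class `haplo_aln`: a list with elements `seq`
#'   (character matrix), `samples`, `population`, `gene_id`, `feature`.
#' @examples
#' aln <- haplo_aln(c(s1 = "ACGT", s2 = "ACTT"), populations = "Landrace")
#' nsamples(aln)
#' @export
haplo_aln <- function(seqs, samples = NULL, populations = "pop1",
                      gene_id = "gene", feature = c("gene", "CDS")) {
  feature <- match.arg(feature)
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      abort("All sequences must have equal length.", class = "popgenscan_format_error")
    }
    samples <- samples %||% names(seqs) %||% paste0("s", seq_along(seqs))
    seqs <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(seqs) <- samples
  }
  if (!is.matrix(seqs) || !is.character(seqs)) {
    abort("`seqs` must be a character matrix or vector of sequences.")
  }
  samples <- samples %||% rownames(seqs) %||% paste0("s", seq_len(nrow(seqs)))
  seqs <- toupper(seqs)
  rownames(seqs) <- samples
  bad <- !(seqs %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) {
    warn(sprintf("%d non-ACGTN- characters mapped to N.", sum(bad)))
    seqs[bad] <- "N"
  }
  populations <- rep_len(as.character(populations), nrow(seqs))
  if (ncol(seqs) < 1L) abort("Alignment needs at least one site.")
  structure(
    list(seq = seqs, samples = samples, population = setNames(populations, samples),
         gene_id = gene_id, feature = feature),
    class = "haplo_aln"
  )
}

#' @export
print.haplo_aln <- function(x, ...) {
  cat(sprintf("<haplo_aln> %s [%s]: %d samples x %d sites; populations: %s\n",
              x$gene_id, x$feature, nrow(x$seq), ncol(x$seq),
              paste(sprintf("%s (%d)", names(table(x$population)),
                            as.integer(table(x$population))), collapse = ", ")))
  invisible(x)
}

#' @rdname haplo_aln
#' @param aln A `haplo_aln` object.
#' @export
nsamples <- function(aln) nrow(aln$seq)

#' @rdname haplo_aln
#' @export
nsites <- function(aln) ncol(aln$seq)

#' Subset an alignment to one population
#'
#' @param aln A `haplo_aln`.
#' @param pop Population label to keep.
#' @return A `haplo_aln` with only the samples of `pop`.
#' @export
aln_pop <- function(aln, pop) {
  keep <- aln$population == pop
  if (!any(keep)) abort(sprintf("No samples in population '%s'.", pop))
  haplo_aln(aln$seq[keep, , drop = FALSE],
            populations = aln$population[keep],
            gene_id = aln$gene_id, feature = aln$feature)
}

#' Bind two alignments over the same region
#'
#' @param a,b `haplo_aln` objects with equal site counts.
#' @return Combined `haplo_aln`.
#' @export
aln_bind <- function(a, b) {
  if (ncol(a$seq) != ncol(b$seq)) abort("Alignments differ in length.")
  haplo_aln(rbind(a$seq, b$seq),
            populations = c(a$population, b$population),
            gene_id = a$gene_id, feature = a$feature)
}

# internal: check sample-size preconditions
check_n <- function(aln, min_n, op) {
  if (nrow(aln$seq) < min_n) {
    abort(sprintf("%s requires at least %d sequences (got %d).", op, min_n, nrow(aln$seq)),
          class = "popgenscan_sample_error")
  }
  invisible(TRUE)
}
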