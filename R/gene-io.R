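#' Read a haplotype alignment from multi-FASTA
#'
#' All records must have equal length; lowercase is normalised to upper
#' case and any character outside `A,C,G,T,N,-` (e.g. IUPAC ambiguity
#' codes) becomes `N` with a warning.  Population labels are attached from
#' the metadata table.
#'
#' @param path FASTA file of aligned sequences.
#' @param metadata Tibble with columns `sample` and `group` (see
#'   [read_metadata()]); every record name must appear in it.
#' @param gene_id,feature Region tag for the alignment.
#' @return A [haplo_aln()].
#' @export
read_alignment_fasta <- function(path, metadata = NULL, gene_id = "gene",
                                 feature = "gene") {
  recs <- Biostrings::readBStringSet(path)
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) > 1L)
    abort("FASTA records have unequal lengths.", class = "popgenscan_format_error")
  nm <- sub("\\s.*$", "", names(recs))
  if (!is.null(metadata)) {
    missing <- setdiff(nm, metadata$sample)
    if (length(missing))
      abort(sprintf("Samples missing from metadata: %s", paste(missing, collapse = ", ")),
            class = "popgenscan_metadata_error")
    pops <- metadata$group[match(nm, metadata$sample)]
  } else {
    pops <- "pop1"
  }
  haplo_aln(setNames(as.character(recs), nm), populations = pops,
            gene_id = gene_id, feature = feature)
}

#' Write a haplotype alignment to multi-FASTA
#'
#' @param aln A [haplo_aln()].
#' @param path Output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(paste0(">", aln$samples, "\n", seqs), path)
  invisible(path)
}

#' Read and write the sample metadata table
#'
#' Tab-separated with columns `sample`, `group`, `geography`, `race`.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_metadata
#' @param metadata Tibble to write.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 subset
#'
#' Parses `gene` and `CDS` features from a GFF3 file (1-based inclusive
#' coordinates; CDS lines are matched to genes via the `Parent`/`ID`
#' attributes or, failing that, by containment).  CDS segments are sorted
#' 5'->3' in transcript order (reverse-sorted for minus-strand genes).
#'
#' @param path GFF3 file.
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `cds_segments` (list of two-column start/end matrices).
#' @export
read_gene_models <- function(path) {
  gff <- readr::read_tsv(path, comment = "#", col_names = c(
    "chrom", "source", "type", "start", "end", "score", "strand", "phase", "attr"
  ), show_col_types = FALSE, progress = FALSE)
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
    ifelse(lengths(regmatches(a, regexpr(paste0(key, "=[^;]+"), a))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  genes <- gff[gff$type == "gene", ]
  cds <- gff[gff$type == "CDS", ]
  gid <- unname(vapply(genes$attr, function(a) {
    x <- regmatches(a, regexpr("ID=[^;]+", a))
    if (length(x)) sub("ID=", "", x) else NA_character_
  }, character(1)))
  cparent <- unname(vapply(cds$attr, function(a) {
    x <- regmatches(a, regexpr("Parent=[^;]+", a))
    if (length(x)) sub("Parent=", "", x) else NA_character_
  }, character(1)))
  purrr::map(seq_len(nrow(genes)), function(i) {
    own <- which((!is.na(cparent) & cparent == gid[i]) |
                   (is.na(cparent) & cds$chrom == genes$chrom[i] &
                      cds$start >= genes$start[i] & cds$end <= genes$end[i]))
    seg <- cds[own, c("start", "end")]
    seg <- seg[order(seg$start, decreasing = genes$strand[i] == "-"), ]
    tibble(gene_id = gid[i], chrom = genes$chrom[i], start = genes$start[i],
           end = genes$end[i], strand = genes$strand[i],
           cds_segments = list(as.matrix(seg)))
  }) |> list_rbind()
}

#' Build a gene model row
#'
#' @param gene_id,chrom,start,end,strand Gene coordinates (1-based
#'   inclusive).
#' @param cds_segments Two-column matrix of segment `start`,`end` in
#'   transcript order (5'->3'); defaults to the whole gene.
#' @param family Optional gene-family label.
#' @return One-row tibble usable with [extract_region()].
#' @export
gene_model <- function(gene_id, chrom, start, end, strand = "+",
                       cds_segments = NULL, family = NA_character_) {
  if (start > end) abort("start must be <= end.", class = "popgenscan_config_error")
  if (is.null(cds_segments)) cds_segments <- cbind(start = start, end = end)
  cds_segments <- matrix(as.numeric(cds_segments), ncol = 2,
                         dimnames = list(NULL, c("start", "end")))
  if (any(cds_segments[, 1] > cds_segments[, 2]))
    abort("Every CDS segment needs start <= end.", class = "popgenscan_config_error")
  tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
         strand = strand, cds_segments = list(cds_segments), family = family)
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  rev(unname(comp[x]))
}

#' Extract per-sample haplotypes for a gene region from a VCF
#'
#' For each sample the reference sequence over the region is taken and the
#' sample's variant alleles substituted (haploid or homozygous genotypes;
#' heterozygous calls resolve to the first-listed allele with a warning,
#' matching a homozygous inbred panel).  For `feature = "CDS"` the
#' segments are concatenated in transcript order and minus-strand models
#' are reverse-complemented.  Coordinates are 1-based inclusive externally.
#'
#' @param vcf_path VCF 4.x file (plain text or bgzipped).
#' @param reference_fasta FASTA covering the gene span (sequence names
#'   matching the VCF chromosome).
#' @param model A one-row gene-model tibble ([gene_model()]).
#' @param samples Samples to extract; default: all in the VCF.
#' @param metadata Optional metadata for population labels.
#' @param feature `"gene"` (whole span) or `"CDS"`.
#' @return A [haplo_aln()].
#' @export
extract_region <- function(vcf_path, reference_fasta, model, samples = NULL,
                           metadata = NULL, feature = c("gene", "CDS")) {
  feature <- match.arg(feature)
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (!model$chrom %in% names(ref))
    abort(sprintf("Chromosome '%s' not in reference.", model$chrom),
          class = "popgenscan_data_error")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  n_var <- nrow(fix)
  gt <- if (n_var > 0) vcfR::extract.gt(vcf) else
    matrix(character(0), nrow = 0, ncol = ncol(vcf@gt) - 1L,
           dimnames = list(NULL, colnames(vcf@gt)[-1]))
  vcf_samples <- colnames(gt)
  samples <- samples %||% vcf_samples
  missing <- setdiff(samples, vcf_samples)
  if (length(missing))
    abort(sprintf("Samples absent from VCF: %s", paste(missing, collapse = ", ")),
          class = "popgenscan_metadata_error")
  chrom_seq <- strsplit(as.character(ref[[model$chrom]]), "")[[1]]
  in_region <- if (n_var == 0) integer(0) else {
    which(fix[, "CHROM"] == model$chrom &
            as.numeric(fix[, "POS"]) >= model$start &
            as.numeric(fix[, "POS"]) <= model$end)
  }
  # per-sample substituted chromosome-region sequence (gene span)
  span <- model$start:model$end
  base <- chrom_seq[span]
  mat <- matrix(rep(base, each = length(samples)), nrow = length(samples))
  rownames(mat) <- samples
  het_seen <- FALSE
  for (v in in_region) {
    pos <- as.numeric(fix[v, "POS"])
    refa <- fix[v, "REF"]
    alts <- strsplit(fix[v, "ALT"], ",")[[1]]
    if (nchar(refa) != 1L || any(nchar(alts) != 1L)) next  # SNPs only
    if (chrom_seq[pos] != refa)
      abort(sprintf("VCF REF '%s' disagrees with reference base '%s' at %s:%d.",
                    refa, chrom_seq[pos], model$chrom, pos),
            class = "popgenscan_data_error")
    for (s in samples) {
      g <- gt[v, s]
      if (is.na(g)) { mat[s, pos - model$start + 1L] <- "N"; next }
      al <- strsplit(g, "[/|]")[[1]]
      if (length(al) > 1L && length(unique(al)) > 1L) het_seen <- TRUE
      pick <- suppressWarnings(as.integer(al[1]))
      if (is.na(pick)) { mat[s, pos - model$start + 1L] <- "N"; next }
      if (pick > 0L) mat[s, pos - model$start + 1L] <- alts[pick]
    }
  }
  if (het_seen) warn("Heterozygous genotypes resolved to the first-listed allele.")
  if (feature == "CDS") {
    segs <- model$cds_segments[[1]]
    pieces <- lapply(seq_len(nrow(segs)), function(k) {
      cols <- (segs[k, 1] - model$start + 1L):(segs[k, 2] - model$start + 1L)
      sub <- mat[, cols, drop = FALSE]
      if (model$strand == "-") {
        t(apply(sub, 1L, revcomp_chars))
      } else sub
    })
    mat <- do.call(cbind, pieces)
    rownames(mat) <- samples
  }
  pops <- if (!is.null(metadata)) {
    metadata$group[match(samples, metadata$sample)]
  } else "pop1"
  haplo_aln(mat, samples = samples, populations = pops,
            gene_id = model$gene_id, feature = feature)
}

#' Write a results table as TSV
#'
#' Tab-separated with one header row; numeric columns are written with six
#' decimal places and undefined statistics as the literal string `NA`.
#'
#' @param records A data frame / tibble (may have zero rows).
#' @param path Output file.
#' @param digits Decimal places for numeric columns.
#' @export
write_results_table <- function(records, path, digits = 6) {
  fmt <- records
  for (cn in names(fmt)) {
    if (is.numeric(fmt[[cn]]) && !is.integer(fmt[[cn]])) {
      v <- fmt[[cn]]
      fmt[[cn]] <- ifelse(is.na(v), "NA",
                          ifelse(is.infinite(v), ifelse(v > 0, "Inf", "-Inf"),
                                 formatC(v, format = "f", digits = digits)))
    } else if (is.list(fmt[[cn]])) {
      fmt[[cn]] <- vapply(fmt[[cn]], function(x) paste(unlist(x), collapse = ","),
                          character(1))
    }
  }
  readr::write_tsv(fmt, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Export a simulated dataset to standard formats
#'
#' Writes one FASTA per gene (both populations, population encoded in the
#' metadata), the sample metadata TSV, the truth table TSV, and per gene a
#' minimal VCF 4.2 plus reference FASTA derived from the descendant +
#' ancestral haplotypes (haploid genotypes; the reference allele is the
#' consensus base).
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @param vcf Also write per-gene VCF + reference (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, vcf = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  for (g in names(dataset$genes)) {
    gd <- dataset$genes[[g]]
    comb <- aln_bind(gd$ancestral, gd$descendant)
    write_alignment_fasta(comb, file.path(dir, paste0(g, ".fasta")))
    writeLines(paste0(">outgroup\n", gd$outgroup), file.path(dir, paste0(g, "_outgroup.fasta")))
    if (vcf) export_gene_vcf(comb, file.path(dir, paste0(g, ".vcf")),
                             file.path(dir, paste0(g, "_ref.fasta")), chrom = g)
  }
  invisible(dir)
}

# minimal haploid VCF + reference writer for an alignment (SNP sites only)
export_gene_vcf <- function(aln, vcf_path, ref_path, chrom = aln$gene_id) {
  m <- aln$seq
  cons <- consensus_seq(m)
  writeLines(paste0(">", chrom, "\n", paste(cons, collapse = "")), ref_path)
  rows <- character(0)
  for (j in seq_len(ncol(m))) {
    b <- m[, j]
    obs <- unique(b[b %in% c("A", "C", "G", "T")])
    alts <- setdiff(obs, cons[j])
    if (!length(alts)) next
    gtv <- ifelse(b == cons[j], "0",
                  ifelse(b %in% alts, as.character(match(b, alts)), "."))
    rows <- c(rows, paste(c(chrom, j, ".", cons[j], paste(alts, collapse = ","),
                            ".", "PASS", ".", "GT", gtv), collapse = "\t"))
  }
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", chrom, ncol(m)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", aln$samples), collapse = "\t"))
  writeLines(c(header, rows), vcf_path)
  invisible(vcf_path)
}
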