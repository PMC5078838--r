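test_that("FASTA alignments round-trip and validate", {
  dir <- withr::local_tempdir()
  md <- tibble::tibble(sample = c("s1", "s2", "s3"), group = "Landrace",
                       geography = "Asia", race = "durra")
  aln <- haplo_aln(c(s1 = paste(rep("ACGT", 75), collapse = ""),
                     s2 = paste(rep("ACGA", 75), collapse = ""),
                     s3 = paste(rep("ACGT", 75), collapse = "")),
                   populations = "Landrace")
  f <- file.path(dir, "aln.fasta")
  write_alignment_fasta(aln, f)
  back <- read_alignment_fasta(f, md)
  expect_identical(back$seq, aln$seq)
  expect_equal(nsamples(back), 3)
  expect_equal(nsites(back), 300)

  # IUPAC code becomes N with a warning
  writeLines(c(">s1", "ACRT", ">s2", "ACGT"), file.path(dir, "amb.fasta"))
  expect_warning(amb <- read_alignment_fasta(file.path(dir, "amb.fasta"), md), "N")
  expect_equal(amb$seq[1, 3], "N", ignore_attr = TRUE)

  # ragged records are a format error; unknown samples a metadata error
  writeLines(c(">s1", "ACGTA", ">s2", "ACGT"), file.path(dir, "bad.fasta"))
  expect_error(read_alignment_fasta(file.path(dir, "bad.fasta"), md),
               class = "popgenscan_format_error")
  writeLines(c(">zz", "ACGT"), file.path(dir, "unk.fasta"))
  expect_error(read_alignment_fasta(file.path(dir, "unk.fasta"), md),
               class = "popgenscan_metadata_error")
})

write_toy_vcf <- function(path, chrom, rows, samples) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=100>", chrom),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
}

test_that("extract_region substitutes variants into the reference", {
  dir <- withr::local_tempdir()
  ref <- paste(rep("ACGT", 25), collapse = "")    # 100 bp
  writeLines(c(">chr1", ref), file.path(dir, "ref.fasta"))
  samples <- c("s1", "s2", "s3", "s4")
  model <- gene_model("g1", "chr1", 5, 40)

  # zero variants in the region: every sample equals the reference substring
  write_toy_vcf(file.path(dir, "empty.vcf"), "chr1", character(0), samples)
  aln0 <- extract_region(file.path(dir, "empty.vcf"), file.path(dir, "ref.fasta"),
                         model, samples)
  expect_true(all(apply(aln0$seq, 1, paste, collapse = "") ==
                    substr(ref, 5, 40)))

  # one biallelic SNP, one alternate-homozygous sample: exactly one cell differs
  rows <- paste(c("chr1", "10", ".", "C", "G", ".", "PASS", ".", "GT",
                  "0", "0", "1", "0"), collapse = "\t")
  write_toy_vcf(file.path(dir, "one.vcf"), "chr1", rows, samples)
  aln1 <- extract_region(file.path(dir, "one.vcf"), file.path(dir, "ref.fasta"),
                         model, samples)
  diffs <- which(aln1$seq != aln0$seq, arr.ind = TRUE)
  expect_equal(nrow(diffs), 1)
  expect_equal(aln1$seq["s3", 10 - 5 + 1], "G", ignore_attr = TRUE)

  # heterozygous call resolves to the first-listed allele with a warning
  rows_het <- paste(c("chr1", "12", ".", "T", "A", ".", "PASS", ".", "GT",
                      "1/0", "0", "0", "0"), collapse = "\t")
  write_toy_vcf(file.path(dir, "het.vcf"), "chr1", rows_het, samples)
  expect_warning(alnh <- extract_region(file.path(dir, "het.vcf"),
                                        file.path(dir, "ref.fasta"), model, samples),
                 "first-listed")
  expect_equal(alnh$seq["s1", 8], "A", ignore_attr = TRUE)

  # REF disagreeing with the reference sequence is a data error
  rows_bad <- paste(c("chr1", "10", ".", "A", "G", ".", "PASS", ".", "GT",
                      "0", "0", "1", "0"), collapse = "\t")
  write_toy_vcf(file.path(dir, "bad.vcf"), "chr1", rows_bad, samples)
  expect_error(extract_region(file.path(dir, "bad.vcf"), file.path(dir, "ref.fasta"),
                              model, samples), class = "popgenscan_data_error")
  expect_error(extract_region(file.path(dir, "one.vcf"), file.path(dir, "ref.fasta"),
                              model, c("s1", "missing")),
               class = "popgenscan_metadata_error")
})

test_that("minus-strand two-exon CDS extraction reverse-complements in transcript order", {
  dir <- withr::local_tempdir()
  ref <- "AAACCCGGGTTTAAACCCGGGTTT"
  writeLines(c(">chr1", ref), file.path(dir, "ref.fasta"))
  write_toy_vcf(file.path(dir, "v.vcf"), "chr1", character(0), "s1")
  # minus-strand gene 1..24, exons (transcript order): 16..21 then 4..9
  model <- gene_model("g1", "chr1", 1, 24, strand = "-",
                      cds_segments = rbind(c(16, 21), c(4, 9)))
  aln <- extract_region(file.path(dir, "v.vcf"), file.path(dir, "ref.fasta"),
                        model, "s1", feature = "CDS")
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  want <- paste0(rc(substr(ref, 16, 21)), rc(substr(ref, 4, 9)))
  expect_equal(paste(aln$seq[1, ], collapse = ""), want)
})

test_that("gene models parse from a GFF3 subset", {
  dir <- withr::local_tempdir()
  gff <- c("##gff-version 3",
           paste("chr1", "src", "gene", "100", "500", ".", "+", ".", "ID=gA", sep = "\t"),
           paste("chr1", "src", "CDS", "150", "200", ".", "+", "0", "Parent=gA", sep = "\t"),
           paste("chr1", "src", "CDS", "300", "350", ".", "+", "0", "Parent=gA", sep = "\t"))
  writeLines(gff, file.path(dir, "m.gff3"))
  gm <- read_gene_models(file.path(dir, "m.gff3"))
  expect_equal(gm$gene_id, "gA")
  expect_equal(gm$cds_segments[[1]][, 1], c(150, 300), ignore_attr = TRUE)
})

test_that("results tables obey the six-decimal and NA formatting contract", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.tsv")
  rec <- tibble::tibble(gene_id = c("a", "b"), fst = c(0.6946666, NA),
                        tajd = c(-0.5, NA))
  write_results_table(rec, f)
  lines <- readLines(f)
  expect_equal(lines[1], "gene_id\tfst\ttajd")
  expect_match(lines[2], "0.694667")
  expect_equal(strsplit(lines[3], "\t")[[1]][2], "NA")
  # empty records give a header-only file
  write_results_table(rec[0, ], f)
  expect_equal(length(readLines(f)), 1)
})

test_that("extract_region reproduces the simulator's own alignment from its VCF export", {
  cfg <- sim_config(n_ancestral = 4, n_descendant = 6, effective_size_ancestral = 15,
                    gene_length = 120, burn_in_factor = 6,
                    outgroup_divergence_time = 80, n_genes = 1, seed = 9)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  g <- names(ds$genes)[1]
  comb <- aln_bind(ds$genes[[g]]$ancestral, ds$genes[[g]]$descendant)
  model <- gene_model(g, g, 1, 120)
  back <- extract_region(file.path(dir, paste0(g, ".vcf")),
                         file.path(dir, paste0(g, "_ref.fasta")),
                         model, comb$samples, metadata = ds$metadata)
  expect_identical(unname(back$seq), unname(comb$seq))
  # FASTA round trip of the same alignment
  again <- read_alignment_fasta(file.path(dir, paste0(g, ".fasta")), ds$metadata,
                                gene_id = g)
  expect_identical(unname(again$seq), unname(comb$seq))
})
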