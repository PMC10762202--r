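#' Write and read genotype dosages as plain TSV
#'
#' The dosage TSV has one row per SNP with columns `snp`, `chrom`, `pos`,
#' `ref`, `alt` followed by one column per sample holding dosages in
#' \{0, 1, 2\} (NA for missing).
#'
#' @param genotypes A `genotypes` object (list with `dosages` and `map`).
#' @param path Output file path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$map[, c("snp", "chrom", "pos", "ref", "alt")],
              as.data.frame(t(genotypes$dosages)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @return `read_dosage_tsv()` returns a `genotypes` object.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("snp", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(df))) stop("malformed dosage TSV: ", path)
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  storage.mode(dos) <- "integer"
  colnames(dos) <- df$snp
  map <- df[, meta_cols]
  map$pos <- as.integer(map$pos)
  structure(list(dosages = dos, map = map), class = "genotypes")
}

#' Write and read genotypes as VCF
#'
#' Dosages are encoded as unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`).
#' Files are written gzip-compressed (`.vcf.gz`) via \pkg{vcfR}.
#'
#' @param genotypes A `genotypes` object.
#' @param path Output path; should end in `.vcf.gz`.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  map <- genotypes$map
  dos <- genotypes$dosages
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(map), nrow(dos))
  ok <- !is.na(t(dos))
  gt[ok] <- gt_code[as.character(t(dos)[ok])]
  fix <- cbind(CHROM = map$chrom, POS = as.character(map$pos), ID = map$snp,
               REF = map$ref, ALT = map$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", rownames(dos))
  vcf <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' @rdname write_vcf_genotypes
#' @return `read_vcf_genotypes()` returns a `genotypes` object with GT calls
#'   converted to alternate-allele dosages.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
    out
  }
  dos <- t(apply(gt, 2, count_alt))
  dos <- matrix(as.integer(dos), nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  map <- data.frame(snp = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  structure(list(dosages = dos, map = map), class = "genotypes")
}

#' Write a wide (taxon x sample) count table
#'
#' @param counts Samples x taxa integer matrix.
#' @param path Output file path.
#' @export
write_wide_counts <- function(counts, path) {
  df <- data.frame(taxon_id = colnames(counts), t(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-sample Bracken-style species reports
#'
#' One file per sample named `<sample>.bracken.tsv` with the standard
#' columns (`name`, `taxonomy_id`, `taxonomy_lvl`, `kraken_assigned_reads`,
#' `added_reads`, `new_est_reads`, `fraction_total_reads`).
#'
#' @param counts Samples x taxa integer matrix.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, named by sample.
#' @export
write_bracken_reports <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(rownames(counts), function(s) {
    x <- counts[s, ]
    df <- data.frame(
      name = names(x), taxonomy_id = seq_along(x), taxonomy_lvl = "S",
      kraken_assigned_reads = as.integer(round(x * 0.9)),
      added_reads = as.integer(x - round(x * 0.9)),
      new_est_reads = as.integer(x),
      fraction_total_reads = if (sum(x) > 0) x / sum(x) else 0,
      stringsAsFactors = FALSE
    )
    p <- file.path(dir, paste0(s, ".bracken.tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Write and read a taxonomy lineage table
#'
#' @param taxonomy Data frame with `taxon_id` and ranked lineage columns
#'   (kingdom, phylum, class, order, family, genus, species).
#' @param path File path.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy_tsv
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(tx)) stop("taxonomy table needs a taxon_id column")
  if (anyDuplicated(tx$taxon_id)) stop("duplicate taxon_id in taxonomy table")
  tx
}

#' Write a gene annotation as GFF3
#'
#' @param annotation Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output `.gff3` path.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = "+", type = "gene", ID = annotation$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene features from a GFF3 annotation
#'
#' Keeps `gene` features only (everything a locus-to-gene overlap needs);
#' coordinates stay 1-based inclusive.
#'
#' @param path A GFF3 file.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(GenomicRanges::mcols(gr)))
    gr <- gr[gr$type == "gene"]
  ids <- if ("ID" %in% names(GenomicRanges::mcols(gr))) as.character(gr$ID)
         else sprintf("gene%05d", seq_along(gr))
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a gene-to-pathway map
#'
#' @param path TSV with columns `gene_id`, `pathway_id` and optionally
#'   `pathway_name`.
#' @return Data frame with those columns.
#' @export
read_pathway_map <- function(path) {
  pw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "pathway_id") %in% names(pw)))
    stop("pathway map needs gene_id and pathway_id columns")
  if (!"pathway_name" %in% names(pw)) pw$pathway_name <- pw$pathway_id
  pw
}

#' Write a trait matrix or distance matrix as TSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path File path.
#' @param rowname_col Header for the row-name column.
#' @export
write_matrix_tsv <- function(x, path, rowname_col = "sample_id") {
  df <- data.frame(rn = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write merged loci as BED plus a locus-to-species table
#'
#' BED uses 0-based half-open coordinates; the companion TSV keeps the
#' package's 1-based inclusive intervals together with the member SNP ids
#' and associated species.
#'
#' @param loci Merged locus data frame from [merge_nonredundant()].
#' @param bed_path Output BED path.
#' @param table_path Output TSV path (optional).
#' @export
write_loci_bed <- function(loci, bed_path, table_path = NULL) {
  bed <- data.frame(chrom = loci$chrom, start = loci$start - 1L,
                    end = loci$end, name = loci$locus_id)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(table_path)) {
    df <- data.frame(
      locus_id = loci$locus_id, chrom = loci$chrom, start = loci$start,
      end = loci$end, n_snps = lengths(loci$snps),
      snps = vapply(loci$snps, paste, character(1), collapse = ","),
      species = vapply(loci$species, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bed_path)
}
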