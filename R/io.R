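# Cohort I/O: VCF v4.2 (GT:GQ:DP with site QUAL), a phenotype/covariate TSV
# and a gene-annotation TSV. Reading goes through vcfR; writing emits the
# small VCF subset these analyses use and is round-trip tested against it.

.gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write a cohort to VCF + TSV files
#'
#' Emits \code{<prefix>.vcf} (VCF v4.2, FORMAT \code{GT:GQ:DP}, site QUAL),
#' \code{<prefix>.pheno.tsv} (sample_id, status, covariates) and, when the
#' cohort carries a gene annotation, \code{<prefix>.genes.tsv} (gene, chrom,
#' start, end; 1-based inclusive). Missing genotypes are written as
#' \code{./.}; a round-trip through \code{\link{readCohort}} reproduces
#' dosages, missingness and quality fields exactly.
#'
#' @param cohort an \linkS4class{RVCohort}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, prefix) {
  if (nrow(cohort) == 0L || ncol(cohort) == 0L)
    stop("refusing to write an empty cohort")
  d <- dosages(cohort)
  gq <- genotypeQuality(cohort)
  dp <- readDepth(cohort)
  gr <- rowRanges(cohort)
  vcf <- paste0(prefix, ".vcf")

  gt <- matrix(.gtCode[as.character(d)], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  fmt <- gt
  if (!is.null(gq) && !is.null(dp)) {
    gqs <- ifelse(is.na(gq), ".", format(gq, trim = TRUE, scientific = FALSE))
    dps <- ifelse(is.na(dp), ".", format(dp, trim = TRUE, scientific = FALSE))
    fmt <- matrix(paste(gt, gqs, dps, sep = ":"), nrow(d), ncol(d))
  }
  qual <- mcols(gr)$QUAL
  qualStr <- ifelse(is.na(qual), ".", format(qual, trim = TRUE, digits = 10,
                                             scientific = FALSE))
  gene <- mcols(gr)$gene
  info <- if (is.null(gene)) rep(".", nrow(d)) else paste0("GENE=", gene)
  header <- c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene assignment\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"))
  body <- cbind(as.character(seqnames(gr)), start(gr), rownames(d),
                mcols(gr)$ref, mcols(gr)$alt, qualStr, "PASS", info,
                if (is.null(gq)) "GT" else "GT:GQ:DP", fmt)
  con <- file(vcf, "w")
  writeLines(header, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)

  pheno <- paste0(prefix, ".pheno.tsv")
  cd <- as.data.frame(colData(cohort))
  write.table(cbind(sample_id = colnames(d), cd), pheno, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- c(vcf = vcf, pheno = pheno)
  genes <- metadata(cohort)$genes
  if (!is.null(genes)) {
    gpath <- paste0(prefix, ".genes.tsv")
    write.table(genes, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["genes"] <- gpath
  }
  invisible(paths)
}

#' Read a cohort from VCF + TSV files
#'
#' @param vcf path to a VCF with GT (optionally GQ/DP) FORMAT fields.
#' @param pheno path to the phenotype/covariate TSV (column \code{sample_id}
#'   plus \code{status} and covariates).
#' @param genes optional path to a gene-annotation TSV.
#' @return an \linkS4class{RVCohort}.
#' @export
readCohort <- function(vcf, pheno, genes = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt %in% c("0/0", "0|0")] <- 0
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  d[gt %in% c("1/1", "1|1")] <- 2
  gq <- dp <- NULL
  if ("GQ" %in% strsplit(v@gt[1, 1], ":")[[1]]) {
    gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  }
  gene <- sub("^.*GENE=([^;]+).*$", "\\1", fix$INFO)
  gene[!grepl("GENE=", fix$INFO)] <- NA_character_
  gr <- GRanges(fix$CHROM, IRanges(as.integer(fix$POS), as.integer(fix$POS)),
                ref = fix$REF, alt = fix$ALT,
                QUAL = suppressWarnings(as.numeric(fix$QUAL)), gene = gene)
  ph <- read.table(pheno, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(identical(ph$sample_id, colnames(gt)))
  rownames(d) <- fix$ID
  samples <- ph[, setdiff(colnames(ph), "sample_id"), drop = FALSE]
  rownames(samples) <- ph$sample_id
  cohort <- RVCohort(d, gr, samples, GQ = gq, DP = dp)
  if (!is.null(genes))
    metadata(cohort)$genes <- read.table(genes, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE)
  cohort
}
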