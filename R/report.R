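# QQ diagnostics and report tables.

#' QQ data and genomic inflation factor
#'
#' Pairs the sorted observed statistics (or p-values) with theoretical
#' quantiles at (i - 0.5)/n and reports the inflation factor
#' median(observed)/median(theoretical).
#'
#' @param x numeric statistics (or p-values when \code{df} is NA).
#' @param df chi-square null degrees of freedom (3 for the 2 log BF
#'   statistics); \code{NA} treats \code{x} as p-values against Uniform(0,1).
#' @return list(expected, observed, inflation).
#' @export
qqData <- function(x, df = 3) {
  if (any(!is.finite(x)))
    stop("non-finite values at positions: ",
         paste(head(which(!is.finite(x)), 5), collapse = ", "))
  if (length(x) < 2) stop("need at least 2 values")
  if (var(x) == 0) stop("degenerate input: all values identical")
  n <- length(x)
  pp <- (seq_len(n) - 0.5) / n
  if (is.na(df)) {
    expected <- pp
    observed <- sort(x)
    inflation <- median(observed) / 0.5
  } else {
    expected <- qchisq(pp, df = df)
    observed <- sort(x)
    inflation <- median(observed) / qchisq(0.5, df = df)
  }
  list(expected = expected, observed = observed, inflation = inflation)
}

#' MAF-spectrum table
#'
#' Renders site counts in the bins 0, (0, 0.01), [0.01, 0.05), [0.05, 0.5]
#' with percentage proportions.
#'
#' @param x folded MAF vector, or precomputed named bin counts.
#' @return data.frame(bin, count, proportion_pct).
#' @export
mafSpectrumTable <- function(x) {
  counts <- if (is.null(names(x))) mafBinCounts(x) else x
  data.frame(bin = names(counts), count = as.integer(counts),
             proportion_pct = round(100 * counts / sum(counts), 2),
             row.names = NULL)
}

#' Case-control demographics chi-square test
#'
#' Counts of a categorical trait in cases vs. controls, tested with the
#' chi-square test (Yates continuity correction for 2x2 tables).
#'
#' @param caseCounts,controlCounts per-level counts.
#' @return the p-value.
#' @export
demographicsTest <- function(caseCounts, controlCounts) {
  stopifnot(length(caseCounts) == length(controlCounts))
  chisq.test(cbind(cases = caseCounts, controls = controlCounts))$p.value
}

.sci3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2E", x))

#' Render results tables to TSV (and markdown)
#'
#' Writes a ranked gene table (rank, gene, sites, prior p, gene p, optional
#' combined p; ranked by gene p ascending, scientific notation with 3
#' significant digits), a MAF-spectrum table, or a single-variant table,
#' depending on the columns present.
#'
#' @param results a \code{\link{genomeScan}}/\code{\link{twoStageSelect}}/
#'   \code{\link{singleVariantScan}}-style data.frame or a MAF bin table.
#' @param path output TSV path.
#' @param markdown also write a markdown rendering alongside (".md").
#' @return invisibly, the rendered data.frame.
#' @export
renderTables <- function(results, path, markdown = FALSE) {
  if (all(c("gene", "p") %in% colnames(results))) {
    need <- c("gene", "p")
    out <- results[order(results$p), ]
    out <- cbind(rank = seq_len(nrow(out)), out)
    for (cc in intersect(c("prior_p", "p", "Pd", "Pr", "combined_p", "q"),
                         colnames(out)))
      out[[cc]] <- .sci3(out[[cc]])
  } else if (all(c("bin", "count") %in% colnames(results))) {
    out <- results
  } else if ("variant" %in% colnames(results)) {
    out <- results
    for (cc in intersect(c("maf", "maf_case", "maf_control", "p", "q"),
                         colnames(out)))
      out[[cc]] <- .sci3(out[[cc]])
  } else stop("unrecognized results table; missing columns")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (markdown) {
    md <- paste0(sub("\\.tsv$", "", path), ".md")
    hdr <- paste0("| ", paste(colnames(out), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
    rows <- apply(out, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, rows), md)
  }
  invisible(out)
}

#' Published gene-level discovery/replication p-values (lung-cancer exome)
#'
#' Loads the bundled gene-level summary statistics from a published
#' lung-cancer case-control exome analysis: per gene, the prior p-value and
#' the Bayes-factor gene p-value in the discovery and replication cohorts,
#' for the KS-prior and SKAT-prior statistics.
#'
#' @param prior "ks" or "skat".
#' @return data.frame: gene, chr, n_sites, prior_p_discovery, p_discovery,
#'   prior_p_replication, p_replication.
#' @export
publishedGeneTables <- function(prior = c("ks", "skat")) {
  prior <- match.arg(prior)
  f <- system.file("extdata", paste0("lung_cancer_genes_", prior, ".tsv"),
                   package = "rvbf")
  read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}
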