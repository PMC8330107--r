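#' @importFrom GenomicRanges GRanges seqnames start end strand mcols
#'   findOverlaps granges sort width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Read chromatin domains from a BED file
#'
#' Domains are the unit of every statistic in the package: contiguous genomic
#' intervals (TADs or compartment domains) called upstream from Hi-C data.
#' Domains on one chromosome must be non-overlapping; they are returned sorted.
#'
#' @param path path to a BED file (3+ columns, 0-based half-open). If a 4th
#'   column is present it is used as the domain id, otherwise ids
#'   \code{D0001...} are generated in sorted genome order.
#' @return a \link[GenomicRanges]{GRanges} with names set to unique domain ids.
#' @export
readDomains <- function(path) {
  assertThat(file.exists(path), paste("domain BED file not found:", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) chromdaValidationError(
      paste("malformed BED file:", conditionMessage(e)))
  )
  gr <- GenomicRanges::sort(gr)
  ids <- if (!is.null(gr$name) && !anyNA(gr$name) && !any(gr$name == "")) {
    as.character(gr$name)
  } else {
    sprintf("D%04d", seq_along(gr))
  }
  names(gr) <- ids
  S4Vectors::mcols(gr) <- NULL
  validateDomains(gr)
}

#' Validate a domain set
#'
#' Checks the domain invariants: positive widths, unique ids, and no overlap
#' between domains on the same chromosome. Returns the sorted domains.
#'
#' @param domains a \link[GenomicRanges]{GRanges} with names as domain ids.
#' @return the validated, sorted GRanges.
#' @export
validateDomains <- function(domains) {
  assertThat(is(domains, "GRanges"), "domains must be a GRanges")
  assertThat(!is.null(names(domains)) && !anyNA(names(domains)),
             "domains must carry ids in names()")
  assertThat(!anyDuplicated(names(domains)), "domain ids must be unique")
  domains <- GenomicRanges::sort(domains)
  ov <- GenomicRanges::findOverlaps(domains, drop.self = TRUE,
                                    drop.redundant = TRUE)
  if (length(ov) > 0) {
    i <- S4Vectors::queryHits(ov)[1]
    j <- S4Vectors::subjectHits(ov)[1]
    chromdaValidationError(sprintf(
      "overlapping domains: %s and %s", names(domains)[i], names(domains)[j]))
  }
  domains
}

#' Read gene annotations (GFF3/GTF or minimal TSV)
#'
#' Genes carry the transcription start site (TSS) used for gene-to-domain
#' assignment: the start of the interval on the + strand, the end on the -
#' strand.
#'
#' @param path a GFF3/GTF file (records with \code{type == "gene"} are used)
#'   or a 5-column TSV with header \code{gene_id, chrom, strand, start, end}
#'   where start/end are 0-based half-open.
#' @param format \code{"auto"} (by extension), \code{"gff"} or \code{"tsv"}.
#' @return a \link[GenomicRanges]{GRanges} named by gene id, with metadata
#'   columns \code{tss} (the TSS coordinate, 1-based) and \code{gene_end}
#'   (the strand-aware 3' end used by the fallback assignment rule).
#' @export
readGenes <- function(path, format = c("auto", "gff", "tsv")) {
  format <- match.arg(format)
  assertThat(file.exists(path), paste("gene annotation file not found:", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)(\\.gz)?$", path, ignore.case = TRUE))
      "gff" else "tsv"
  }
  if (format == "gff") {
    gr <- rtracklayer::import(path)
    if ("type" %in% colnames(S4Vectors::mcols(gr))) {
      keep <- gr[gr$type == "gene"]
      if (length(keep) > 0) gr <- keep
    }
    ids <- gr$gene_id
    if (is.null(ids)) ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    assertThat(!is.null(ids), "GFF gene records carry no gene_id/ID attribute")
    df <- data.frame(gene_id = as.character(ids),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     strand = as.character(GenomicRanges::strand(gr)),
                     start1 = GenomicRanges::start(gr),
                     end1 = GenomicRanges::end(gr))
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end")
    assertThat(all(need %in% colnames(tab)),
               paste("gene TSV must have columns:", paste(need, collapse = ", ")))
    df <- data.frame(gene_id = as.character(tab$gene_id),
                     chrom = as.character(tab$chrom),
                     strand = as.character(tab$strand),
                     start1 = as.integer(tab$start) + 1L,  # 0-based -> 1-based
                     end1 = as.integer(tab$end))
  }
  makeGenes(df$gene_id, df$chrom, df$strand, df$start1, df$end1)
}

#' Build a validated gene GRanges from vectors (1-based inclusive coordinates)
#' @keywords internal
makeGenes <- function(gene_id, chrom, strand, start1, end1) {
  assertThat(all(strand %in% c("+", "-")),
             "every gene needs strand '+' or '-'")
  assertThat(!anyDuplicated(gene_id),
             paste("duplicated gene_id:",
                   paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")))
  assertThat(all(start1 <= end1), "gene start must precede gene end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                               strand = strand)
  names(gr) <- gene_id
  plus <- as.character(GenomicRanges::strand(gr)) == "+"
  gr$tss <- ifelse(plus, GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr$gene_end <- ifelse(plus, GenomicRanges::end(gr), GenomicRanges::start(gr))
  gr
}

#' Read an expression matrix with sample condition labels
#'
#' @param exprPath TSV: first column gene ids, header row of sample ids,
#'   non-negative expression values (count-like or normalized).
#' @param conditionPath 2-column TSV (header \code{sample, condition}) mapping
#'   every sample to one of exactly two condition labels. The order of first
#'   appearance in this file defines condition 1 and condition 2 (fold-changes
#'   are condition 2 over condition 1).
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"values"} and \code{colData(x)$condition} a two-level factor.
#' @export
readExpression <- function(exprPath, conditionPath) {
  assertThat(file.exists(exprPath), paste("expression file not found:", exprPath))
  assertThat(file.exists(conditionPath),
             paste("condition file not found:", conditionPath))
  tab <- read.delim(exprPath, check.names = FALSE, stringsAsFactors = FALSE)
  assertThat(ncol(tab) >= 3, "expression table needs >= 2 sample columns")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  ann <- read.delim(conditionPath, stringsAsFactors = FALSE)
  assertThat(ncol(ann) >= 2, "condition file needs columns sample, condition")
  colnames(ann)[1:2] <- c("sample", "condition")
  cond <- ann$condition[match(colnames(m), ann$sample)]
  assertThat(!anyNA(cond), "every expression sample needs a condition label")
  ExpressionData(m, cond)
}

#' Construct a validated expression container
#'
#' @param values genes x samples non-negative numeric matrix with row and
#'   column names.
#' @param condition character/factor of length \code{ncol(values)} with exactly
#'   two levels; level order (first appearance) defines condition 1 vs 2.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
ExpressionData <- function(values, condition) {
  assertThat(is.matrix(values) && is.numeric(values),
             "values must be a numeric matrix")
  assertThat(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
             "values must have unique gene ids as rownames")
  assertThat(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
             "values must have unique sample ids as colnames")
  assertThat(all(is.finite(values)) && all(values >= 0),
             "expression values must be finite and >= 0")
  if (!is.factor(condition)) condition <- factor(condition,
                                                 levels = unique(condition))
  assertThat(nlevels(condition) == 2, "condition must have exactly two levels")
  assertThat(all(table(condition) >= 2), "both conditions need >= 2 samples")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    colData = S4Vectors::DataFrame(condition = condition,
                                   row.names = colnames(values))
  )
}

## Internal accessors for the expression container.
exprValues <- function(ds) SummarizedExperiment::assay(ds, "values")
exprCondition <- function(ds) {
  cond <- SummarizedExperiment::colData(ds)$condition
  assertThat(!is.null(cond), "expression data carries no condition column")
  if (!is.factor(cond)) cond <- factor(cond, levels = unique(cond))
  cond
}

#' Read per-sample tumor purity scores
#'
#' @param path 2-column TSV with header \code{sample, purity}; purity in [0,1].
#' @return named numeric vector of purity scores.
#' @export
readPurity <- function(path) {
  assertThat(file.exists(path), paste("purity file not found:", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assertThat(ncol(tab) >= 2, "purity file needs columns sample, purity")
  p <- as.numeric(tab[[2]])
  names(p) <- as.character(tab[[1]])
  assertThat(all(is.finite(p)), "purity scores must be finite")
  p
}

#' Read gene-family annotations
#'
#' Multiple "|"-separated family annotations are resolved to the first-level
#' (most general) family.
#'
#' @param path 2-column TSV with header \code{gene_id, family}.
#' @return named character vector mapping gene id to family.
#' @export
readFamilies <- function(path) {
  assertThat(file.exists(path), paste("family file not found:", path))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  assertThat(ncol(tab) >= 2, "family file needs columns gene_id, family")
  fam <- sub("\\|.*$", "", as.character(tab[[2]]))
  names(fam) <- as.character(tab[[1]])
  fam[!duplicated(names(fam))]
}

#' Read an interaction-strength matrix
#'
#' Accepts either a dense matrix TSV (square, header = bin indices) or a
#' coordinate-triplet TSV with header \code{bin_i, bin_j, S} (1-based bins;
#' symmetrized on read).
#'
#' @param path input TSV.
#' @param chrom chromosome name for the matrix.
#' @param binSize bin size in bp.
#' @param nBins for triplet input, the matrix dimension (defaults to the
#'   largest bin index observed).
#' @return an \linkS4class{InteractionMatrix}.
#' @export
readInteractionMatrix <- function(path, chrom, binSize, nBins = NULL) {
  assertThat(file.exists(path), paste("interaction file not found:", path))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("bin_i", "bin_j", "S") %in% colnames(tab))) {
    i <- as.integer(tab$bin_i); j <- as.integer(tab$bin_j)
    n <- if (is.null(nBins)) max(i, j) else as.integer(nBins)
    S <- matrix(NA_real_, n, n)
    S[cbind(i, j)] <- tab$S
    S[cbind(j, i)] <- tab$S
  } else {
    S <- as.matrix(tab)
    storage.mode(S) <- "double"
    dimnames(S) <- NULL
  }
  InteractionMatrix(S, chrom, binSize)
}

## TSV writer with the package-wide conventions (tab, no quotes, header).
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
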