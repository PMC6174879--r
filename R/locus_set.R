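#' Multi-locus phased genotype container
#'
#' The unit all statistics consume: a set of sequence loci (e.g. UCEs), each
#' carrying a phased haplotype matrix over the sampled diploids, plus a
#' sample-to-population map and the annotation of invariant loci (needed so
#' per-site diversity can be scaled by the total surveyed length).
#'
#' Haplotype matrices have \code{2 * n_samples} rows — rows \code{2k-1} and
#' \code{2k} are the two phased haplotypes of sample \code{k}, in popmap
#' order — and one column per SNP, with alleles coded \code{0, 1, 2, ...}.
#' The container requires a complete matrix: no missing genotypes.
#'
#' @param loci a list, one element per variable locus, each a list with
#'   \code{name}, \code{length_bp}, \code{chrom_class} ("autosome" or "Z"),
#'   \code{positions} (strictly increasing 1-based positions within the
#'   locus) and \code{haps} (the haplotype matrix). An optional \code{gq}
#'   integer matrix (samples x SNPs) carries genotype qualities.
#' @param popmap a data frame with columns \code{sample} and
#'   \code{population}.
#' @param invariant a data frame of invariant loci with columns \code{name},
#'   \code{length_bp}, \code{chrom_class}; may be \code{NULL}.
#' @return An object of class \code{locus_set}.
#' @export
locus_set <- function(loci, popmap, invariant = NULL) {
  stopifnot(is.list(loci), is.data.frame(popmap),
            all(c("sample", "population") %in% names(popmap)))
  popmap$sample <- as.character(popmap$sample)
  popmap$population <- as.character(popmap$population)
  if (anyDuplicated(popmap$sample))
    stop("each sample must appear exactly once in the popmap")
  n_samp <- nrow(popmap)
  for (loc in loci) {
    stopifnot(!is.null(loc$name), !is.null(loc$length_bp),
              !is.null(loc$haps))
    if (nrow(loc$haps) != 2L * n_samp)
      stop("locus ", loc$name, ": haplotype rows must equal 2 x samples")
    if (ncol(loc$haps) != length(loc$positions))
      stop("locus ", loc$name, ": positions/columns mismatch")
    if (length(loc$positions) > 1 && any(diff(loc$positions) <= 0))
      stop("locus ", loc$name, ": positions must be strictly increasing")
    if (anyNA(loc$haps))
      stop("locus ", loc$name, ": missing genotypes are not permitted")
  }
  names(loci) <- vapply(loci, `[[`, "", "name")
  if (!is.null(invariant)) {
    invariant <- as.data.frame(invariant)
    stopifnot(all(c("name", "length_bp", "chrom_class") %in% names(invariant)))
  }
  structure(list(loci = loci, popmap = popmap, invariant = invariant),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("locus_set:", length(x$loci), "variable loci,",
      if (is.null(x$invariant)) 0L else nrow(x$invariant),
      "invariant loci,", nrow(x$popmap), "samples in",
      length(unique(x$popmap$population)), "population(s)\n")
  cat("  total SNPs:", n_snps(x),
      "| surveyed length:", total_surveyed_bp(x), "bp\n")
  invisible(x)
}

#' @rdname locus_set
#' @param ls a \code{locus_set}.
#' @export
n_snps <- function(ls) {
  sum(vapply(ls$loci, function(l) ncol(l$haps), 0L))
}

#' Total surveyed sequence length
#'
#' Sum of locus lengths over variable loci, plus invariant loci when
#' annotated and requested. Per-site diversity statistics divide by this.
#'
#' @param ls a \code{locus_set}.
#' @param include_invariant include annotated invariant loci (default TRUE).
#' @return Total length in bp.
#' @export
total_surveyed_bp <- function(ls, include_invariant = TRUE) {
  len <- sum(vapply(ls$loci, `[[`, 0, "length_bp"))
  if (include_invariant && !is.null(ls$invariant))
    len <- len + sum(ls$invariant$length_bp)
  len
}

# Population label of each haplotype row (length 2 * n_samples).
hap_populations <- function(ls) {
  rep(ls$popmap$population, each = 2L)
}

# Row indices of the haplotypes belonging to one population.
hap_rows_of_pop <- function(ls, pop) {
  which(hap_populations(ls) == pop)
}

# Names of the (expected two) populations, in popmap order of appearance.
population_names <- function(ls) {
  unique(ls$popmap$population)
}

# Diploid dosage matrix (samples x SNPs) over all loci, column-bound in
# locus order; attribute "locus" maps columns to loci.
dosage_matrix <- function(ls) {
  n_samp <- nrow(ls$popmap)
  mats <- lapply(ls$loci, function(l) {
    if (ncol(l$haps) == 0) return(matrix(0L, n_samp, 0))
    l$haps[seq(1, 2 * n_samp, by = 2), , drop = FALSE] +
      l$haps[seq(2, 2 * n_samp, by = 2), , drop = FALSE]
  })
  out <- do.call(cbind, mats)
  attr(out, "locus") <- rep(names(ls$loci),
                            vapply(ls$loci, function(l) ncol(l$haps), 0L))
  rownames(out) <- ls$popmap$sample
  out
}

#' Write a locus_set as VCF + popmap + annotation
#'
#' Writes the three-file interchange format used throughout the package: a
#' VCF v4.2 with phased GT and GQ fields (CHROM = locus name, POS = 1-based
#' position within the locus), a two-column popmap TSV, and a locus
#' annotation TSV (\code{locus}, \code{length_bp}, \code{chrom_class}).
#' Invariant loci appear in the annotation only.
#'
#' @param ls a \code{locus_set}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "dataset").
#' @return Invisibly, the three file paths.
#' @export
write_locus_set <- function(ls, dir, prefix = "dataset") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  popmap <- file.path(dir, paste0(prefix, ".popmap.tsv"))
  annot <- file.path(dir, paste0(prefix, ".loci.tsv"))

  n_samp <- nrow(ls$popmap)
  alleles <- c("A", "C", "G", "T")
  con <- file(vcf, "wb")  # binary mode: fixed \n line endings
  wl <- function(x) writeLines(x, con, sep = "\n")
  wl("##fileformat=VCFv4.2")
  wl("##source=ucepopgen")
  wl('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  wl('##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">')
  for (loc in ls$loci)
    wl(sprintf("##contig=<ID=%s,length=%d>", loc$name, loc$length_bp))
  wl(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT", ls$popmap$sample), collapse = "\t"))
  for (loc in ls$loci) {
    if (ncol(loc$haps) == 0) next
    for (j in seq_along(loc$positions)) {
      al <- loc$haps[, j]
      n_all <- max(al) + 1L
      gq <- if (!is.null(loc$gq)) loc$gq[, j] else rep(99L, n_samp)
      gt <- paste0(al[seq(1, 2 * n_samp, 2)], "|", al[seq(2, 2 * n_samp, 2)],
                   ":", gq)
      wl(paste(c(loc$name, loc$positions[j], ".", alleles[1],
                 paste(alleles[2:n_all], collapse = ","), ".", "PASS", ".",
                 "GT:GQ", gt), collapse = "\t"))
    }
  }
  close(con)

  write.table(ls$popmap[, c("sample", "population")], popmap,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ann <- data.frame(
    locus = c(names(ls$loci),
              if (!is.null(ls$invariant)) ls$invariant$name),
    length_bp = c(vapply(ls$loci, `[[`, 0, "length_bp"),
                  if (!is.null(ls$invariant)) ls$invariant$length_bp),
    chrom_class = c(vapply(ls$loci, `[[`, "", "chrom_class"),
                    if (!is.null(ls$invariant)) ls$invariant$chrom_class))
  write.table(ann, annot, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf, popmap = popmap, annotation = annot))
}

#' Read a locus_set from VCF + popmap + annotation
#'
#' Parses a phased VCF (via \pkg{vcfR}) together with the popmap and locus
#' annotation written by [write_locus_set()] (or equivalent files from an
#' external pipeline). Requires a complete matrix — any missing genotype is
#' an error — and phased genotypes.
#'
#' @param vcf path to the VCF file.
#' @param popmap path to the two-column popmap TSV (sample, population).
#' @param annotation path to the locus annotation TSV with header
#'   \code{locus length_bp chrom_class}.
#' @return A [locus_set()].
#' @export
read_locus_set <- function(vcf, popmap, annotation) {
  pm <- read.table(popmap, sep = "\t", header = FALSE,
                   col.names = c("sample", "population"),
                   colClasses = "character")
  ann <- read.table(annotation, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character"))
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) stop("missing genotypes in VCF; a complete matrix is required")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes in VCF; phased GT (\"|\") required")
  gt <- gt[, pm$sample, drop = FALSE]
  chrom <- v@fix[, "CHROM"]
  pos <- as.integer(v@fix[, "POS"])
  n_samp <- nrow(pm)

  a1 <- matrix(as.integer(sub("\\|.*", "", gt)), nrow = nrow(gt))
  a2 <- matrix(as.integer(sub(".*\\|", "", gt)), nrow = nrow(gt))

  loci <- list()
  for (i in seq_len(nrow(ann))) {
    name <- ann$locus[i]
    rows <- which(chrom == name)
    if (length(rows) == 0) next
    rows <- rows[order(pos[rows])]
    haps <- matrix(0L, 2L * n_samp, length(rows))
    haps[seq(1, 2 * n_samp, 2), ] <- t(a1[rows, , drop = FALSE])
    haps[seq(2, 2 * n_samp, 2), ] <- t(a2[rows, , drop = FALSE])
    loci[[name]] <- list(name = name, length_bp = ann$length_bp[i],
                         chrom_class = ann$chrom_class[i],
                         positions = pos[rows], haps = haps)
  }
  inv <- ann[!(ann$locus %in% names(loci)), , drop = FALSE]
  names(inv) <- c("name", "length_bp", "chrom_class")
  locus_set(loci, pm, invariant = if (nrow(inv)) inv else NULL)
}
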