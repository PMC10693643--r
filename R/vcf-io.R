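#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses GT fields of a VCF 4.x file (via vcfR) into a derived-allele
#' dosage matrix. Multiallelic records are skipped with a logged count;
#' \code{./.} becomes NA. VCF 1-based positions are converted to the
#' package-internal 0-based convention.
#'
#' @param path path to an uncompressed VCF.
#' @return List with \code{genotypes} (sites x individuals, 0/1/2/NA),
#'   \code{posBp} (0-based), \code{samples}, \code{phased} (logical matrix,
#'   TRUE where the GT call used the phased separator).
#' @export
readVCF <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("format error: ", conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(list(genotypes = matrix(integer(0), 0, max(0L, ncol(v@gt) - 1L)),
                posBp = numeric(0),
                samples = if (!is.null(colnames(v@gt))) colnames(v@gt)[-1] else character(0),
                phased = matrix(logical(0), 0, max(0L, ncol(v@gt) - 1L))))
  }
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  pos <- as.numeric(fix[!multi, "POS"]) - 1
  first <- substr(gt, 1, 1); sep <- substr(gt, 2, 2); second <- substr(gt, 3, 3)
  bad <- !is.na(gt) & !(first %in% c("0", "1", ".") & sep %in% c("|", "/") &
                          second %in% c("0", "1", "."))
  if (any(bad))
    stop("format error: unsupported GT value at record ",
         which(rowSums(bad) > 0)[1])
  toInt <- function(ch) ifelse(ch == ".", NA_integer_, as.integer(ch))
  g <- matrix(toInt(first) + toInt(second), nrow = nrow(gt),
              dimnames = dimnames(gt))
  g[is.na(gt)] <- NA_integer_
  phased <- !is.na(gt) & sep == "|"
  list(genotypes = g, posBp = pos, samples = colnames(gt), phased = phased)
}

#' Write a minimal phased/unphased VCF 4.2
#'
#' The inverse of \code{\link{readVCF}} on the supported subset: biallelic
#' SNP records with GT-only FORMAT. When \code{haplotypes} is supplied the
#' GT strings are phased (\code{a|b}) from the haplotype pair; entries
#' flagged in \code{unphase} (e.g. error-perturbed genotypes) are written
#' unphased from the dosage instead.
#'
#' @param genotypes dosage matrix, sites x individuals.
#' @param posBp 0-based positions (written 1-based), strictly increasing.
#' @param samples sample names.
#' @param path output path.
#' @param chrom chromosome name (default "1").
#' @param haplotypes optional 0/1 sites x (2 x individuals) matrix.
#' @param unphase optional logical matrix (sites x individuals).
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(genotypes, posBp, samples, path, chrom = "1",
                     haplotypes = NULL, unphase = NULL) {
  checkGenotypeMatrix(genotypes)
  if (nrow(genotypes) != length(posBp))
    stop("invalid input: one position per site required")
  if (length(posBp) > 1L && any(diff(posBp) <= 0))
    stop("invalid input: unsorted positions")
  if (ncol(genotypes) != length(samples))
    stop("invalid input: one sample name per column required")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  n <- nrow(genotypes)
  if (n == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  gtChar <- matrix("./.", n, ncol(genotypes))
  if (!is.null(haplotypes)) {
    h1 <- haplotypes[, seq(1, ncol(haplotypes), by = 2), drop = FALSE]
    h2 <- haplotypes[, seq(2, ncol(haplotypes), by = 2), drop = FALSE]
    gtChar[] <- paste0(h1, "|", h2)
  }
  fromDosage <- is.null(haplotypes) |
    (if (is.null(unphase)) matrix(FALSE, n, ncol(genotypes)) else unphase)
  dosStr <- c("0/0", "0/1", "1/1")
  sel <- which(fromDosage, arr.ind = TRUE)
  if (nrow(sel) > 0L) {
    dv <- genotypes[sel]
    gtChar[sel] <- ifelse(is.na(dv), "./.", dosStr[dv + 1L])
  }
  gtChar[is.na(genotypes)] <- "./."
  body <- paste(chrom, format(posBp + 1, scientific = FALSE, trim = TRUE),
                ".", "A", "G", ".", "PASS", ".", "GT",
                apply(gtChar, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
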