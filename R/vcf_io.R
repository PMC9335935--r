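#' Read a multi-sample VCF into a genotype table
#'
#' Parses a VCF 4.x file through \pkg{vcfR} and restricts it to the samples
#' of a [sample_sheet()], in sheet order. Genotypes are mapped by unphased
#' allele content: `0/0` to hom-ref, `0/1` or `1/0` to het, `1/1` to
#' hom-alt, `./.` to missing; phase separators are ignored. Genotypes
#' referencing higher alternate alleles are retained (coded by their
#' non-reference allele count) but such multi-allelic records are flagged
#' for removal by [apply_site_filters()].
#'
#' @param path path to a VCF file (plain or bgzip/gzip)
#' @param sheet a [sample_sheet()]; all of its samples must be present in
#'   the VCF header
#' @return a [genotype_table()]
#' @export
read_vcf <- function(path, sheet) {
  sheet <- validate_sample_sheet(sheet)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(sheet$sample_id, vcf_samples)
  if (length(absent)) {
    stop_config("sample sheet samples absent from VCF header: ",
                paste(absent, collapse = ", "))
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (nrow(fix) > 0 && !all(grepl("(^|:)GT(:|$)", fmt))) {
    stop_data("VCF records without a GT FORMAT field")
  }
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  dp_num <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  if (is.null(dp_num)) {
    dp_num <- matrix(NA_real_, nrow(gt_chr), ncol(gt_chr),
                     dimnames = dimnames(gt_chr))
  }
  gt_chr <- gt_chr[, sheet$sample_id, drop = FALSE]
  dp_num <- dp_num[, sheet$sample_id, drop = FALSE]

  geno <- genotype_codes_from_gt(gt_chr)
  depth <- round(dp_num)
  depth[is.na(depth)] <- 0L
  storage.mode(depth) <- "integer"
  rownames(geno) <- NULL
  rownames(depth) <- NULL

  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                      stringsAsFactors = FALSE)
  genotype_table(sites, geno, depth)
}

# map character GT strings to integer codes by unphased allele content
genotype_codes_from_gt <- function(gt_chr) {
  dims <- dim(gt_chr)
  flat <- gsub("|", "/", as.character(gt_chr), fixed = TRUE)
  u <- unique(flat)
  code_one <- function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (any(alleles == "." | alleles == "")) return(NA_integer_)
    sum(alleles != "0")
  }
  lut <- vapply(u, code_one, integer(1))
  geno <- matrix(lut[match(flat, u)], dims[1], dims[2],
                 dimnames = dimnames(gt_chr))
  storage.mode(geno) <- "integer"
  geno
}

#' Write a genotype table as minimal VCF 4.2
#'
#' Emits a plain-text VCF with `GT:DP` per-sample fields such that
#' `read_vcf(write_vcf(gt))` reproduces `gt` exactly (genotypes, depths
#' and site fields). Missing genotypes are written as `./.`.
#'
#' @param gt a [genotype_table()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(gt, path) {
  gt <- validate_genotype_table(gt)
  samples <- colnames(gt$geno)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=sdrscan-%s",
            as.character(utils::packageVersion("sdrscan"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  n <- nrow(gt$sites)
  if (n == 0) return(invisible(path))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt$geno + 1L], n, length(samples))
  gt_str[is.na(gt$geno)] <- "./."
  dp_str <- matrix(as.character(gt$depth), n, length(samples))
  dp_str[is.na(gt$depth)] <- "."
  cells <- matrix(paste(gt_str, dp_str, sep = ":"), n, length(samples))
  qual <- ifelse(is.na(gt$sites$qual), ".",
                 formatC(gt$sites$qual, format = "g", digits = 15))
  lines <- paste(gt$sites$chrom, gt$sites$pos, ".", gt$sites$ref,
                 gt$sites$alt, qual, "PASS", ".", "GT:DP",
                 apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
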