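#' Read allele dosages
#'
#' Reads a genotype dosage file into a \code{\link{dosage_matrix}}. Two
#' formats are supported:
#' \describe{
#'   \item{\code{"tsv"}}{a tab-separated table with header
#'     \code{sample_id<TAB>variant ids...} and one row per sample, plus a
#'     sidecar variant-metadata file named by replacing the trailing
#'     \code{.tsv} with \code{.variants.tsv}, with columns \code{id, chrom,
#'     pos, ref, alt, maf, imputation_r2}.}
#'   \item{\code{"vcf"}}{a VCF 4.2 file. The \code{DS} FORMAT field is used
#'     when present; otherwise \code{GT} calls are converted to ALT-allele
#'     counts 0/1/2.}
#' }
#'
#' @param path path to the dosage TSV or VCF file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return a \code{\link{dosage_matrix}}. MAF is recomputed from the data
#'   when absent from the metadata.
#' @export
read_dosages <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_dosages_tsv(path) else read_dosages_vcf(path)
}

read_dosages_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("dosage TSV has no variant columns: ", path)
  for (k in 2:ncol(dt)) {
    if (!is.numeric(dt[[k]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[k]]))))[1]
      stop("malformed dosage at line ", bad + 1L, " of ", path,
           " (column '", names(dt)[k], "')")
    }
  }
  mat <- as.matrix(dt[, -1, with = FALSE])
  sidecar <- sub("\\.tsv$", ".variants.tsv", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".variants.tsv")
  if (!file.exists(sidecar)) stop("variant sidecar not found: ", sidecar)
  v <- as.data.frame(data.table::fread(sidecar, sep = "\t", header = TRUE))
  if (!identical(as.character(v$id), colnames(mat))) {
    stop("variant sidecar ids do not match dosage columns in ", path)
  }
  dosage_matrix(mat, v, data.frame(sample_id = dt[[1]]))
}

read_dosages_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-variant files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  v <- data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT)
  if (anyNA(v$id) || any(v$id == ".")) {
    auto <- paste0(v$chrom, ":", v$pos, "_", v$ref, "_", v$alt)
    v$id <- ifelse(is.na(v$id) | v$id == ".", auto, v$id)
  }
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), gt_to_dosage)
  } else {
    stop("VCF has neither DS nor GT FORMAT fields: ", path)
  }
  if (anyNA(ds)) {
    bad <- which(is.na(ds), arr.ind = TRUE)[1, ]
    stop("missing dosage for variant '", v$id[bad[1]], "' in ", path,
         "; missing genotypes are not supported")
  }
  # extract.gt returns variants x samples
  dosage_matrix(t(ds), v, data.frame(sample_id = colnames(ds)))
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(as.numeric(alleles) > 0)
}

#' Write allele dosages (TSV dialect)
#'
#' Writes the dosage TSV plus its \code{.variants.tsv} sidecar; the pair
#' round-trips through \code{\link{read_dosages}}.
#'
#' @param dm a \code{\link{dosage_matrix}}.
#' @param path output path ending in \code{.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_dosages <- function(dm, path) {
  stopifnot(inherits(dm, "dosage_matrix"))
  dt <- data.table::data.table(sample_id = dm$samples$sample_id)
  dt <- cbind(dt, data.table::as.data.table(dm$dosages))
  data.table::fwrite(dt, path, sep = "\t")
  sidecar <- sub("\\.tsv$", ".variants.tsv", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".variants.tsv")
  v <- dm$variants[, c("id", "chrom", "pos", "ref", "alt", "maf",
                       "imputation_r2")]
  data.table::fwrite(v, sidecar, sep = "\t")
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' @param path TSV with columns \code{sample_id}, \code{trait}, \code{value}
#'   (one row per sample x trait; values are yield deviations, i.e.
#'   phenotypes pre-adjusted for environmental effects).
#' @return data.frame with those three columns.
#' @export
read_phenotypes <- function(path) {
  ph <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = 1:2)))
  need <- c("sample_id", "trait", "value")
  if (!all(need %in% names(ph))) {
    stop("phenotype table must have columns sample_id, trait, value: ", path)
  }
  if (anyDuplicated(ph[, c("sample_id", "trait")])) {
    stop("duplicate (sample, trait) phenotype records in ", path)
  }
  ph[, need]
}

#' Write a long-format phenotype table
#' @param pheno data.frame with columns \code{sample_id}, \code{trait},
#'   \code{value}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  data.table::fwrite(pheno[, c("sample_id", "trait", "value")], path,
                     sep = "\t")
  invisible(path)
}

#' Extract an aligned phenotype vector
#'
#' @param pheno long-format phenotype data.frame.
#' @param trait trait name to extract.
#' @param sample_ids sample ids, in the order of the genotype data.
#' @return named numeric vector aligned to \code{sample_ids}; samples
#'   without a record get \code{NA}.
#' @export
phenotype_vector <- function(pheno, trait, sample_ids) {
  ph <- pheno[pheno$trait == trait, ]
  y <- ph$value[match(sample_ids, ph$sample_id)]
  names(y) <- sample_ids
  y
}
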