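#' Read a multi-sample VCF into a genotype matrix
#'
#' Retains bi-allelic SNP records only (single-nucleotide REF and ALT, one
#' ALT allele); multi-allelic records and indels are dropped. Dosage is the
#' count of ALT alleles in the GT field; phased (`|`) and unphased (`/`)
#' separators are both accepted; half calls such as `./1` are treated as
#' missing. When a per-genotype DP field is present, genotypes with depth
#' below `min_genotype_depth` are set to missing; when DP is absent the
#' depth rule is skipped with a warning.
#'
#' @param path path to a VCF 4.x file (plain text).
#' @param min_genotype_depth minimum read depth for a genotype to be
#'   called (default 8, the usual GBS choice).
#' @return A [geno_matrix()] with per-locus mean depth computed over
#'   non-missing calls.
#' @export
read_vcf <- function(path, min_genotype_depth = 8L) {
  validate_vcf_text(path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- colnames(vcf@gt)[-1L]
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    calls <- matrix(integer(0), nrow = length(ids), ncol = 0,
                    dimnames = list(ids, NULL))
    loci <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
    return(geno_matrix(calls, loci))
  }
  snp <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  vcf <- vcf[snp, ]
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    calls <- matrix(integer(0), nrow = length(ids), ncol = 0,
                    dimnames = list(ids, NULL))
    loci <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
    return(geno_matrix(calls, loci))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  calls <- decode_gt(gt)                       # loci x samples
  has_dp <- any(grepl("DP", vcf@gt[, "FORMAT"], fixed = TRUE))
  depth <- NULL
  if (has_dp) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    low <- !is.na(dp) & dp < min_genotype_depth
    calls[low] <- NA_integer_
    depth <- t(dp)
    storage.mode(depth) <- "integer"
  } else if (min_genotype_depth > 0L) {
    warning("VCF has no per-genotype DP field; minimum-depth rule skipped")
  }
  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  calls <- t(calls)
  rownames(calls) <- ids
  geno_matrix(calls, loci, depth)
}

# GT strings -> alt dosage; anything containing "." is missing
decode_gt <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    a <- strsplit(s, "[/|]")[[1L]]
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai < 0L) || any(ai > 1L)) return(NA_integer_)
    sum(ai)
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

# cheap structural validation so format errors can name the line
validate_vcf_text <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
    stop("malformed VCF '", path, "': line 1 must be ##fileformat=VCF...",
         call. = FALSE)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr))
    stop("malformed VCF '", path, "': no #CHROM header line", call. = FALSE)
  hdr <- hdr[1L]
  nf <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  body <- seq_len(length(lines))[-seq_len(hdr)]
  for (i in body) {
    if (!nzchar(lines[i])) next
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1L]]) != nf)
      stop("malformed VCF '", path, "': line ", i,
           " has the wrong number of fields", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Dosages are re-encoded as GT (`0/0`, `0/1`, `1/1`, `./.`); per-genotype
#' depths, when present, are written in a DP field. Reading the file back
#' with `read_vcf(path, min_genotype_depth = 0)` reproduces the calls,
#' coordinates and sample order exactly.
#'
#' @param g a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  has_dp <- !is.null(g$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=clonekin",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(g)), collapse = "\t"))
  writeLines(header, con)
  if (n_loci(g) == 0L) return(invisible(path))
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(n_loci(g))) {
    d <- g$calls[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    if (has_dp) {
      dp <- g$depth[, j]
      gt <- paste0(gt, ":", ifelse(is.na(dp), ".", dp))
    }
    row <- paste(c(g$loci$chrom[j], g$loci$pos[j], ".", g$loci$ref[j],
                   g$loci$alt[j], ".", ".", ".",
                   if (has_dp) "GT:DP" else "GT", gt), collapse = "\t")
    writeLines(row, con)
  }
  invisible(path)
}
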