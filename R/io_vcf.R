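# Minimal VCF support: only CHROM/POS/ID/REF/ALT/GT are consumed on read
# (via vcfR) and emitted on write. The analysis needs genotypes and allele
# identities only; all other VCF machinery is out of scope.

parse_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse failure in ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single record drops dims
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF parse failure: no records in ", path)
  ref <- fix$REF; alt <- fix$ALT
  if (any(nchar(ref) != 1 | nchar(alt) != 1 | !ref %in% BASES |
          !alt %in% BASES))
    stop("VCF parse failure: non-SNP or multi-allelic record (only ",
         "biallelic A/C/G/T SNPs are supported)")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage of the designated allele = REF: number of 0 alleles in GT
  core <- gsub("[|]", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(core), ncol = ncol(core))
  dos[core == "0/0"] <- 2L
  dos[core == "0/1" | core == "1/0"] <- 1L
  dos[core == "1/1"] <- 0L
  bad <- !is.na(core) & is.na(dos) & core != "./." & core != "."
  if (any(bad))
    stop("VCF parse failure: unsupported GT value '", core[bad][1], "'")
  dosages <- t(dos)
  rownames(dosages) <- colnames(gt)
  colnames(dosages) <- ids
  lg <- fix$CHROM
  lg[lg == "."] <- NA_character_
  list(dosages = dosages,
       loci = data.frame(locus_id = ids, allele1 = ref, allele2 = alt,
                         linkage_group = lg, stringsAsFactors = FALSE))
}

emit_vcf <- function(panel, path) {
  loci <- panel$loci
  chrom <- ifelse(is.na(loci$linkage_group), ".", loci$linkage_group)
  gt <- matrix("./.", nrow = nrow(loci), ncol = nrow(panel$individuals))
  d <- t(panel$dosages)
  gt[!is.na(d) & d == 2L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 0L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=snpharmony",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$individuals$individual_id),
                    collapse = "\t"))
  body <- paste(chrom, seq_len(nrow(loci)), loci$locus_id, loci$allele1,
                loci$allele2, ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (nrow(panel$individuals) == 0)
    body <- paste(chrom, seq_len(nrow(loci)), loci$locus_id, loci$allele1,
                  loci$allele2, ".", ".", ".", "GT", sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
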