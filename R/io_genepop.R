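# Genepop dialect used throughout: diploid 4-digit genotypes, alleles coded
# 01=A 02=C 03=G 04=T so nucleotide identity (needed for strand-ambiguity
# classification) survives the round trip; 0000 codes a missing genotype.
# Genepop designates the lower allele code, so a loaded panel's designated
# allele is the alphabetically first base observed at each locus.

GENEPOP_CODE <- c(A = "01", C = "02", G = "03", T = "04")

#' Load a genotype panel from a standard file
#'
#' Reads genotypes from a Genepop file (4-digit diploid codes, alleles
#' 01-04 = A,C,G,T) or a VCF (only CHROM/POS/ID/REF/ALT/GT are consumed) and
#' joins them with a sample metadata table mapping each individual to its
#' sampling location and dataset of origin.
#'
#' For VCF the designated allele is REF; for Genepop it is the lower allele
#' code. The designation is recorded in the locus table (`allele1`) so that
#' round trips are stable.
#'
#' @param path genotype file.
#' @param format `"genepop"` or `"vcf"`.
#' @param metadata_path CSV with columns `individual_id`, `location_code`,
#'   `dataset` and optionally `lat`, `lon`. Every individual in the genotype
#'   file must appear here.
#' @return a `genotype_panel`.
#' @export
load_panel <- function(path, format = c("genepop", "vcf"), metadata_path) {
  format <- match.arg(format)
  meta <- read_sample_metadata(metadata_path)
  raw <- switch(format,
                genepop = parse_genepop(path),
                vcf = parse_vcf(path))
  ids <- rownames(raw$dosages)
  miss <- setdiff(ids, meta$individual_id)
  if (length(miss) > 0)
    stop("individuals in genotype file absent from metadata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  meta <- meta[match(ids, meta$individual_id), , drop = FALSE]
  individuals <- data.frame(individual_id = ids,
                            location_code = meta$location_code,
                            stringsAsFactors = FALSE)
  samples <- build_sample_table(meta)
  genotype_panel(raw$dosages, raw$loci, individuals, samples)
}

#' Write a genotype panel to a standard file
#'
#' Emits a Genepop or minimal GT-only VCF file, plus a sidecar metadata CSV
#' (`<path>.meta.csv` by default) carrying each individual's location and
#' dataset-of-origin so that multi-dataset merged panels remain fully
#' reconstructable: `load_panel(write_panel(p))` recovers `p` up to the
#' format's allele-designation convention.
#'
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @param format `"genepop"` or `"vcf"`.
#' @param metadata_path sidecar CSV path; `NULL` for `<path>.meta.csv`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("genepop", "vcf"),
                        metadata_path = NULL) {
  format <- match.arg(format)
  validate_panel(panel)
  if (any(is.na(panel$loci$allele2)) && format == "vcf")
    stop("VCF emission requires both alleles known at every locus")
  switch(format,
         genepop = emit_genepop(panel, path),
         vcf = emit_vcf(panel, path))
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".meta.csv")
  write_sample_metadata(panel, metadata_path)
  invisible(path)
}

parse_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("Genepop parse failure: file too short")
  lines <- lines[trimws(lines) != "" | seq_along(lines) == 1]
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (length(pop_idx) == 0)
    stop("Genepop parse failure: no 'Pop' line found in ", path)
  header <- lines[2:(pop_idx[1] - 1)]
  # locus names: one per line, or comma-separated on a single line
  locus_ids <- trimws(unlist(strsplit(header, ",")))
  locus_ids <- locus_ids[locus_ids != ""]
  n_loci <- length(locus_ids)
  ind_ids <- character(0)
  geno <- list()
  blocks <- c(pop_idx, length(lines) + 1)
  for (b in seq_len(length(pop_idx))) {
    if (blocks[b] + 1 > blocks[b + 1] - 1) next  # empty population block
    rows <- lines[seq(blocks[b] + 1, blocks[b + 1] - 1)]
    for (row in rows) {
      parts <- strsplit(row, ",")[[1]]
      if (length(parts) < 2)
        stop("Genepop parse failure at line: ", row)
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "[[:space:]]+")[[1]]
      if (length(codes) != n_loci)
        stop("Genepop parse failure: individual ", id, " has ",
             length(codes), " genotypes, expected ", n_loci)
      ind_ids <- c(ind_ids, id)
      geno[[length(geno) + 1]] <- codes
    }
  }
  if (length(geno) == 0)
    stop("Genepop parse failure: no individuals; allele identities ",
         "unrecoverable from a header-only file")
  gm <- do.call(rbind, geno)  # individuals x loci, 4-digit strings
  a_first <- substr(gm, 1, 2)
  a_second <- substr(gm, 3, 4)
  code2base <- stats::setNames(names(GENEPOP_CODE), GENEPOP_CODE)
  dosages <- matrix(NA_integer_, nrow = length(ind_ids), ncol = n_loci)
  allele1 <- allele2 <- rep(NA_character_, n_loci)
  for (j in seq_len(n_loci)) {
    c1 <- a_first[, j]; c2 <- a_second[, j]
    obs <- sort(unique(c(c1, c2)))
    obs <- obs[obs != "00"]
    if (any(!obs %in% GENEPOP_CODE))
      stop("Genepop parse failure: allele code outside 01-04 at locus ",
           locus_ids[j])
    if (length(obs) > 2)
      stop("Genepop parse failure: >2 alleles at locus ", locus_ids[j])
    if (length(obs) == 0) next  # fully missing locus
    allele1[j] <- code2base[[obs[1]]]            # lower code designated
    if (length(obs) == 2) allele2[j] <- code2base[[obs[2]]]
    called <- c1 != "00" & c2 != "00"
    dosages[called, j] <- (c1[called] == obs[1]) + (c2[called] == obs[1])
  }
  if (anyNA(allele1)) {
    j <- which(is.na(allele1))[1]
    stop("Genepop parse failure: locus ", locus_ids[j],
         " has no called genotypes, alleles unrecoverable")
  }
  rownames(dosages) <- ind_ids
  list(dosages = dosages,
       loci = data.frame(locus_id = locus_ids, allele1 = allele1,
                         allele2 = allele2, linkage_group = NA_character_,
                         stringsAsFactors = FALSE))
}

emit_genepop <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("snpharmony export; allele codes 01=A 02=C 03=G 04=T; ",
                    "datasets: ",
                    paste(unique(panel$samples$dataset), collapse = ",")), con)
  writeLines(panel$loci$locus_id, con)
  code1 <- GENEPOP_CODE[panel$loci$allele1]
  code2 <- ifelse(is.na(panel$loci$allele2), "00",
                  GENEPOP_CODE[panel$loci$allele2])
  if (nrow(panel$individuals) == 0) writeLines("Pop", con)  # header-only
  for (loc in panel$samples$location_code) {
    writeLines("Pop", con)
    rows <- which(panel$individuals$location_code == loc)
    for (i in rows) {
      g <- panel$dosages[i, ]
      geno <- character(length(g))
      geno[is.na(g)] <- "0000"
      geno[!is.na(g) & g == 2L] <- paste0(code1, code1)[!is.na(g) & g == 2L]
      geno[!is.na(g) & g == 1L] <- paste0(pmin(code1, code2),
                                          pmax(code1, code2))[!is.na(g) & g == 1L]
      geno[!is.na(g) & g == 0L] <- paste0(code2, code2)[!is.na(g) & g == 0L]
      if (any(geno == "0000" & !is.na(g)))
        stop("encoding error: genotype requires unknown second allele")
      writeLines(paste0(panel$individuals$individual_id[i], " ,  ",
                        paste(geno, collapse = " ")), con)
    }
  }
  invisible(path)
}
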