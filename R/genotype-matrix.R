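#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes for a set of animals, coded as counts of
#' the B allele (0, 1, 2) with `NA` marking a missing call. SNPs carry a
#' chromosome label and a base-pair position; within each chromosome,
#' positions must be strictly increasing, so that map order and position
#' order coincide.
#'
#' @param calls Integer matrix, animals in rows and SNPs in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param chromosome Character or integer vector, one label per SNP
#'   (autosomes `1..29` and `"X"` for cattle, but any labels are accepted).
#' @param position Integer vector of base-pair positions, one per SNP.
#' @param animal_ids,snp_ids Optional identifier vectors; default to the
#'   dimnames of `calls` or to generated labels.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `animal_ids`, `snp_ids`, `chromosome`, `position`.
#' @export
genotype_matrix <- function(calls, chromosome, position,
                            animal_ids = rownames(calls),
                            snp_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n_snp <- ncol(calls)
  if (is.null(animal_ids)) animal_ids <- sprintf("ID%04d", seq_len(nrow(calls)))
  if (is.null(snp_ids)) snp_ids <- sprintf("SNP%05d", seq_len(n_snp))
  animal_ids <- as.character(animal_ids)
  snp_ids <- as.character(snp_ids)
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  if (length(chromosome) != n_snp || length(position) != n_snp) {
    stop("chromosome and position must have one entry per SNP")
  }
  if (length(animal_ids) != nrow(calls)) {
    stop("animal_ids must have one entry per row of calls")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  for (chr in unique(chromosome)) {
    pos <- position[chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  dimnames(calls) <- list(animal_ids, snp_ids)
  structure(
    list(calls = calls, animal_ids = animal_ids, snp_ids = snp_ids,
         chromosome = chromosome, position = position),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$animal_ids), "animals x",
      length(x$snp_ids), "SNPs on", length(unique(x$chromosome)),
      "chromosome(s);",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

n_animals <- function(g) length(g$animal_ids)
n_snps <- function(g) length(g$snp_ids)

#' Subset a genotype matrix by SNP
#'
#' @param g A [genotype_matrix()].
#' @param keep Integer, logical or character index of SNPs to keep
#'   (original order preserved).
#' @return A `genotype_matrix` restricted to the kept SNPs.
#' @export
subset_snps <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$snp_ids)
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(as.integer(keep)))
  genotype_matrix(g$calls[, keep, drop = FALSE],
                  chromosome = g$chromosome[keep],
                  position = g$position[keep],
                  animal_ids = g$animal_ids,
                  snp_ids = g$snp_ids[keep])
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' The MAP file has four whitespace-separated columns (chromosome, SNP id,
#' genetic distance, base-pair position). The PED file has six leading
#' columns (family, individual, sire, dam, sex, phenotype) followed by two
#' allele columns per SNP; allele codes are taken from `alleles`, with `0`
#' meaning missing — a `0` in either member of a pair makes the call
#' missing. Calls are recoded to counts of `alleles[2]` (the B allele).
#'
#' @param ped,map Paths to the PED and MAP files.
#' @param alleles Length-2 character vector naming the A and B allele codes.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped, map, alleles = c("A", "B")) {
  if (!file.exists(ped)) stop("PED file not found: ", ped)
  if (!file.exists(map)) stop("MAP file not found: ", map)
  map_lines <- readLines(map)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nfield <- lengths(map_fields)
  if (any(nfield != 4)) {
    stop("MAP line ", which(nfield != 4)[1], ": expected 4 columns, found ",
         nfield[which(nfield != 4)[1]])
  }
  map_mat <- do.call(rbind, map_fields)
  chromosome <- map_mat[, 1]
  snp_ids <- map_mat[, 2]
  position <- as.integer(map_mat[, 4])
  n_snp <- length(snp_ids)

  ped_lines <- readLines(ped)
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * n_snp
  nfield <- lengths(ped_fields)
  if (any(nfield != expected)) {
    i <- which(nfield != expected)[1]
    stop("PED line ", i, ": expected ", expected, " columns (6 + 2 per SNP), found ",
         nfield[i])
  }
  animal_ids <- vapply(ped_fields, `[`, character(1), 2L)
  ok_codes <- c(alleles, "0")
  calls <- matrix(NA_integer_, nrow = length(ped_fields), ncol = n_snp)
  for (i in seq_along(ped_fields)) {
    al <- ped_fields[[i]][-(1:6)]
    bad <- !(al %in% ok_codes)
    if (any(bad)) {
      stop("PED line ", i, ": allele code '", al[bad][1],
           "' not in {", paste(ok_codes, collapse = ","), "}")
    }
    a1 <- al[c(TRUE, FALSE)]
    a2 <- al[c(FALSE, TRUE)]
    miss <- a1 == "0" | a2 == "0"
    calls[i, ] <- (a1 == alleles[2]) + (a2 == alleles[2])
    calls[i, miss] <- NA_integer_
  }
  genotype_matrix(calls, chromosome = chromosome, position = position,
                  animal_ids = animal_ids, snp_ids = snp_ids)
}

#' Write genotypes to PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: calls 0/1/2 become `A A`, `A B`, `B B`
#' (under the default allele codes) and missing becomes `0 0`. The PED
#' pedigree columns are written as unknown (sire = dam = 0, sex = 0,
#' phenotype = -9); the MAP genetic distance column is 0.
#'
#' @param g A [genotype_matrix()].
#' @param ped,map Output paths.
#' @param alleles Length-2 character vector of allele codes.
#' @return Invisibly, `c(ped, map)`.
#' @export
write_ped_map <- function(g, ped, map, alleles = c("A", "B")) {
  map_df <- data.frame(chr = g$chromosome, snp = g$snp_ids, cm = 0L,
                       pos = g$position)
  utils::write.table(map_df, map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- c(paste(alleles[1], alleles[1]), paste(alleles[1], alleles[2]),
            paste(alleles[2], alleles[2]))
  con <- file(ped, open = "wt")
  on.exit(close(con))
  for (i in seq_len(n_animals(g))) {
    geno <- code[g$calls[i, ] + 1L]
    geno[is.na(geno)] <- "0 0"
    writeLines(paste("FAM", g$animal_ids[i], "0", "0", "0", "-9",
                     paste(geno, collapse = " ")), con)
  }
  invisible(c(ped, map))
}
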