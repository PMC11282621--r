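#' Genotype matrix container
#'
#' Bundles a matrix of biallelic SNP calls with its individual and marker
#' metadata. Calls are coded 0/1/2 as the number of copies of the counted
#' allele (`allele_b` in `snps`) and `NA` for missing.
#'
#' @param calls integer matrix, individuals in rows and SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param ind data frame with columns `individual_id` and `breed_id`, one row
#'   per row of `calls`.
#' @param snps data frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b` and logical `mapped`, one row per column of `calls`.
#'
#' @return An object of class `genotypes`: a list with elements `calls`,
#'   `ind` and `snps`.
#' @export
genotypes <- function(calls, ind, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(ind))
    stop("calls has ", nrow(calls), " rows but ind describes ", nrow(ind),
         " individuals")
  if (ncol(calls) != nrow(snps))
    stop("calls has ", ncol(calls), " columns but snps describes ",
         nrow(snps), " markers")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b", "mapped")
  if (!all(need %in% names(snps)))
    stop("snps is missing columns: ", paste(setdiff(need, names(snps)), collapse = ", "))
  same <- !is.na(snps$allele_a) & !is.na(snps$allele_b) &
    snps$allele_a == snps$allele_b
  if (any(same))
    stop("allele_a equals allele_b for SNP ", snps$snp_id[which(same)[1]])
  if (any(snps$mapped & (is.na(snps$pos) | snps$pos < 1)))
    stop("mapped SNPs must have pos >= 1")
  rownames(calls) <- ind$individual_id
  colnames(calls) <- snps$snp_id
  structure(list(calls = calls, ind = as.data.frame(ind),
                 snps = as.data.frame(snps)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes: ", nrow(x$calls), " individuals x ", ncol(x$calls),
      " SNPs (", length(unique(x$ind$breed_id)), " breeds, ",
      sprintf("%.1f", 100 * mean(is.na(x$calls))), "% missing)\n", sep = "")
  invisible(x)
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PLINK text files. The PED family column is
#' used as the breed identifier; the allele code `"0"` marks a missing
#' allele, and a genotype with either allele missing becomes `NA`. For each
#' SNP the counted allele (`allele_b`) is the lexicographically later of the
#' two observed alleles, so the coding is deterministic and independent of
#' file order; all downstream statistics are invariant to this choice. SNPs
#' on chromosome `"0"` or with non-positive position are flagged unmapped.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [genotypes] object.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (!length(map_lines)) stop("no SNPs: MAP file is empty")
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  n_col <- lengths(map_fields)
  if (any(n_col != 4L))
    stop("malformed MAP line ", which(n_col != 4L)[1], ": expected 4 columns")
  map <- do.call(rbind, map_fields)
  n_snp <- nrow(map)
  pos <- suppressWarnings(as.integer(map[, 4]))
  mapped <- !is.na(pos) & pos >= 1L & map[, 1] != "0"

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  if (!length(ped_lines)) stop("PED file has no individuals")
  expected <- 6L + 2L * n_snp
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  bad <- which(lengths(fields) != expected)
  if (length(bad))
    stop("malformed PED line ", bad[1], ": expected ", expected,
         " fields, found ", lengths(fields)[bad[1]])
  ped <- do.call(rbind, fields)
  n_ind <- nrow(ped)
  a1 <- ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  allele_a <- allele_b <- character(n_snp)
  calls <- matrix(NA_integer_, n_ind, n_snp)
  for (j in seq_len(n_snp)) {
    obs <- sort(unique(c(a1[, j], a2[, j])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L)
      stop("triallelic site ", map[j, 2], ": alleles ",
           paste(obs, collapse = "/"))
    if (length(obs) == 2L) {
      allele_a[j] <- obs[1]; allele_b[j] <- obs[2]
    } else if (length(obs) == 1L) {
      # monomorphic: the sole observed allele is counted, the other unknown
      allele_a[j] <- "0"; allele_b[j] <- obs[1]
    } else {
      allele_a[j] <- "0"; allele_b[j] <- "N"
    }
    calls[, j] <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
  }
  genotypes(
    calls,
    ind = data.frame(individual_id = ped[, 2], breed_id = ped[, 1],
                     stringsAsFactors = FALSE),
    snps = data.frame(snp_id = map[, 2], chrom = map[, 1], pos = pos,
                      allele_a = allele_a, allele_b = allele_b,
                      mapped = mapped, stringsAsFactors = FALSE)
  )
}

#' Write genotypes to PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: genotype codes are expanded back to allele
#' pairs (`NA` becomes `"0 0"`). Unmapped SNPs are written with chromosome
#' and position `0`.
#'
#' @param g a [genotypes] object.
#' @param ped_path,map_path output paths.
#' @return Invisibly, `g`.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "genotypes"))
  s <- g$snps
  chrom <- ifelse(s$mapped, s$chrom, "0")
  pos <- ifelse(s$mapped, s$pos, 0L)
  writeLines(paste(chrom, s$snp_id, 0L, pos), map_path)
  aa <- ifelse(s$allele_a == "0", s$allele_b, s$allele_a)  # placeholder-safe
  n_snp <- nrow(s)
  lines <- vapply(seq_len(nrow(g$calls)), function(i) {
    code <- g$calls[i, ]
    x1 <- ifelse(is.na(code), "0", ifelse(code >= 1L, s$allele_b, aa))
    x2 <- ifelse(is.na(code), "0", ifelse(code == 2L, s$allele_b, aa))
    paste(g$ind$breed_id[i], g$ind$individual_id[i], 0, 0, 0, -9,
          paste(rbind(x1, x2), collapse = " "))
  }, character(1))
  writeLines(lines, ped_path)
  invisible(g)
}

# md5 of the packaged table; guards against silent edits of the fixture
.fixture_md5 <- "0572bcebad1c1953bdfeb01b88db29b7"

#' Load the packaged per-breed diversity tables
#'
#' Returns the published per-breed summary for 105 goat populations: 40
#' European, 43 African and 22 Asian breeds with country, subregion, sampling
#' coordinates (decimal degrees, N/E positive), sample size, observed and
#' expected heterozygosity, Fis, FST against the Iranian Markhoz reference
#' breed, and the published Vincenty distance (km) of each sampling site to
#' Ganj Dareh. FST and distance are absent (`NA`) for the three South African
#' commercial breeds (Boer, Savanna, Kalahari Red) and FST for the Markhoz
#' itself; the `f_roh` column is present for interface completeness but
#' carries no published values.
#'
#' @param continent `"all"` (default) or one of `"Europe"`, `"Africa"`,
#'   `"Asia"`.
#' @param check verify the file checksum before parsing (default `TRUE`).
#' @return A list with data frames `breeds` (identity, geography, sample
#'   size) and `diversity` (statistics and published distance), joined by
#'   `breed_id`, plus `table` holding the full joined table.
#' @export
load_goat_tables <- function(continent = c("all", "Europe", "Africa", "Asia"),
                             check = TRUE) {
  continent <- match.arg(continent)
  path <- system.file("extdata", "goat_breed_diversity.csv",
                      package = "goatclines", mustWork = TRUE)
  if (check) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .fixture_md5))
      stop("fixture integrity error: checksum mismatch for ", path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (continent != "all") tab <- tab[tab$continent == continent, ]
  rownames(tab) <- NULL
  list(
    breeds = tab[, c("breed_id", "breed_name", "country", "subregion",
                     "continent", "lon", "lat", "n")],
    diversity = tab[, c("breed_id", "ho", "he", "fis", "fst_vs_ref",
                        "f_roh", "distance_km")],
    table = tab
  )
}

#' Write or read a per-breed diversity table
#'
#' Plain CSV with a header; absent values are serialized as empty fields and
#' restored as `NA`, so tables round-trip losslessly.
#'
#' @param tab a data frame with at least a `breed_id` column.
#' @param path file path.
#' @return `write_diversity_table` returns `tab` invisibly;
#'   `read_diversity_table` returns the data frame.
#' @export
write_diversity_table <- function(tab, path) {
  stopifnot(is.data.frame(tab), "breed_id" %in% names(tab))
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(tab)
}

#' @rdname write_diversity_table
#' @export
read_diversity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}
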