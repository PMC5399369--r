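## File-format adapters: PLINK-style text genotypes (.ped/.map), TSV
## tables, connectivity CSV, and configuration YAML/JSON.  All dialects are
## plain text and round-trip the in-memory objects.

#' Write genotypes as PLINK-style text (.ped / .map)
#'
#' The .ped file carries six leading columns (family id, individual id,
#' paternal id, maternal id, sex coded 1 = M / 2 = F, phenotype -9) followed
#' by two allele characters per SNP; missing calls are written "0 0".  The
#' .map file has four columns: chromosome, snp id, genetic distance (0) and
#' base-pair position.
#'
#' @param g a [genotype_matrix()]; its snp table must carry `minor_allele`
#'   and `major_allele`.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param sex optional character vector ("M"/"F") aligned with subjects.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(g, prefix, sex = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!all(c("minor_allele", "major_allele") %in% names(g$snps))) {
    stop("snp table must carry 'minor_allele' and 'major_allele'")
  }
  sex_code <- if (is.null(sex)) rep(0L, length(g$subjects)) else
    ifelse(sex == "M", 1L, 2L)
  n <- length(g$subjects); m <- nrow(g$snps)
  allele_txt <- matrix("0 0", n, m)
  for (j in seq_len(m)) {
    mi <- g$snps$minor_allele[j]; ma <- g$snps$major_allele[j]
    codes <- c(paste(ma, ma), paste(ma, mi), paste(mi, mi))
    calls <- g$calls[, j]
    ok <- !is.na(calls)
    allele_txt[ok, j] <- codes[calls[ok] + 1L]
  }
  ped <- cbind(g$subjects, g$subjects, "0", "0", sex_code, "-9", allele_txt)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  write.table(ped, ped_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = " ")
  map <- data.frame(chr = g$snps$chr %||% rep(0L, m),
                    snp_id = g$snps$snp_id, cm = 0,
                    bp = g$snps$bp %||% rep(0L, m))
  write.table(map, map_path, quote = FALSE, row.names = FALSE,
              col.names = FALSE, sep = "\t")
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK-style text genotypes
#'
#' Parses the dialect written by [write_plink()].  When `minor_alleles` is
#' not supplied the minor allele of each SNP is determined empirically from
#' post-missingness allele counts, with ties at frequency 0.5 broken toward
#' the alphabetically first allele.
#'
#' @param ped,map file paths.
#' @param minor_alleles optional character vector (one per SNP, .map order)
#'   declaring the allele to count.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(ped, map, minor_alleles = NULL) {
  map_df <- read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map_df) < 4) stop("malformed .map: expected 4 columns")
  names(map_df)[1:4] <- c("chr", "snp_id", "cm", "bp")
  m <- nrow(map_df)
  lines <- readLines(ped)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 6 + 2 * m)
  if (length(bad)) {
    stop("malformed .ped line(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": expected ", 6 + 2 * m, " fields")
  }
  ped_mat <- do.call(rbind, fields)
  subjects <- ped_mat[, 2]
  a1 <- ped_mat[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- ped_mat[, 6 + 2 * seq_len(m), drop = FALSE]
  n <- length(subjects)
  calls <- matrix(NA_integer_, n, m)
  minor <- character(m); major <- character(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2) {
      stop("SNP ", map_df$snp_id[j], " has more than two alleles")
    }
    if (!is.null(minor_alleles)) {
      minor[j] <- minor_alleles[j]
      major[j] <- setdiff(alleles, minor[j])[1]
      if (is.na(major[j])) major[j] <- minor[j]
    } else if (length(alleles) == 0) {
      minor[j] <- major[j] <- NA_character_
    } else if (length(alleles) == 1) {
      major[j] <- alleles; minor[j] <- NA_character_
    } else {
      counts <- table(factor(obs, levels = alleles))
      minor[j] <- if (counts[1] == counts[2]) alleles[1] else
        names(which.min(counts))
      major[j] <- setdiff(alleles, minor[j])
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
    cnt[miss] <- NA_integer_
    calls[, j] <- as.integer(cnt)
  }
  snps <- data.frame(snp_id = map_df$snp_id, chr = map_df$chr,
                     bp = map_df$bp, minor_allele = minor,
                     major_allele = major, stringsAsFactors = FALSE)
  genotype_matrix(subjects, snps, calls)
}

#' Write / read a tab-separated table
#'
#' Plain TSV with a header row, no quoting, no row names; the dialect used
#' for every tabular output of the pipeline.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `write_tsv`: invisibly the path; `read_tsv`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a connectivity matrix as CSV
#'
#' 8 x 8 matrix with region names as header row and first column.  Reading
#' validates symmetry, zero diagonal and non-negativity, refusing matrices
#' that violate the connectivity contract.
#'
#' @param c_mat connectivity matrix.
#' @param path file path.
#' @return `write_connectivity_csv`: invisibly the path;
#'   `read_connectivity_csv`: the matrix.
#' @export
write_connectivity_csv <- function(c_mat, path) {
  df <- data.frame(region = rownames(c_mat), c_mat, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  if (!identical(rownames(m), colnames(m))) {
    stop("connectivity CSV row/column names disagree")
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("connectivity CSV is not symmetric")
  }
  if (any(diag(m) != 0) || any(m < 0)) {
    stop("connectivity CSV violates zero-diagonal / non-negativity")
  }
  m
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a configuration list (see [pipeline_config()]).
#' @param path file path.
#' @return `write_config`: invisibly the path; `read_config`: the list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
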