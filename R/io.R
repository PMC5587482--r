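#' Write a frequency table to TSV
#'
#' Dialect: a header row `population<TAB>locus labels...`, one row per deme,
#' frequencies written with full double precision so a write/read round trip
#' is lossless well beyond 10 significant digits.
#'
#' @param table A frequency table (tibble with a `population` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  freq_matrix(table)  # validates shape
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read a frequency table from TSV
#'
#' Validates the dialect of [write_frequency_table()]: a `population` column
#' first, unique deme identifiers, and all frequencies within `[0, 1]`.
#' Malformed input is rejected with the offending deme and locus named.
#'
#' @param path Input path.
#' @return A frequency-table tibble.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    stop("empty input: ", path, " contains no data", call. = FALSE)
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"population" %in% names(tbl) || names(tbl)[1] != "population") {
    stop("malformed frequency table: first column must be `population` (",
         path, ")", call. = FALSE)
  }
  if (nrow(tbl) == 0) {
    stop("empty input: ", path, " has a header but no rows", call. = FALSE)
  }
  dup <- tbl$population[duplicated(tbl$population)]
  if (length(dup) > 0) {
    stop("duplicate deme ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  loci <- setdiff(names(tbl), "population")
  for (lc in loci) {
    v <- tbl[[lc]]
    if (!is.numeric(v)) {
      stop("non-numeric frequencies at locus ", lc, call. = FALSE)
    }
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad) > 0) {
      stop(sprintf("frequency out of [0, 1] at locus %s, deme %s (value %s)",
                   lc, tbl$population[bad[1]], format(v[bad[1]])),
           call. = FALSE)
    }
  }
  tbl
}

#' Export per-deme genotype matrices as TSV
#'
#' One file per deme and species (`<prefix>_<species>_<deme>.tsv`), rows =
#' individuals, columns = loci, values 0/1.
#'
#' @param metapop A `metapop` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_genotypes <- function(metapop, dir, prefix = "genotypes") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (k in seq_along(metapop$demes)) {
    for (sp in c("host", "parasite")) {
      f <- file.path(dir, sprintf("%s_%s_%s.tsv", prefix, sp,
                                  names(metapop$demes)[k]))
      utils::write.table(metapop$demes[[k]][[sp]], f, sep = "\t",
                         row.names = FALSE,
                         col.names = sprintf("L%03d",
                                             seq_len(ncol(metapop$demes[[k]][[sp]]))))
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Per-population alternate-allele frequencies from a VCF
#'
#' Converts per-sample genotype calls into a frequency table usable by
#' [coev_scan()], one call per species' VCF. Only biallelic sites are used
#' (others are skipped with a message); missing genotypes are excluded from
#' the denominator; phased and unphased calls are treated identically
#' (allele counting only).
#'
#' @param vcf_path Path to a VCF (4.x, plain or bgzipped).
#' @param popmap_path Path to a two-column TSV (no header): sample ID, deme.
#'   Every sample in the VCF must be assigned.
#' @return A frequency-table tibble (demes x sites, alternate-allele
#'   frequency), site labels `CHROM:POS`.
#' @export
frequencies_from_vcf <- function(vcf_path, popmap_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("frequencies_from_vcf() requires the vcfR package", call. = FALSE)
  }
  if (!file.exists(vcf_path)) stop("file not found: ", vcf_path,
                                   call. = FALSE)
  popmap <- utils::read.table(popmap_path, sep = "\t", header = FALSE,
                              col.names = c("sample", "deme"),
                              colClasses = "character")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  missing_map <- setdiff(samples, popmap$sample)
  if (length(missing_map) > 0) {
    stop("sample(s) in VCF absent from population map: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  biallelic <- vcfR::is.biallelic(v)
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message("skipping ", n_skip, " non-biallelic site(s)")
  }
  gt <- gt[biallelic, , drop = FALSE]
  if (nrow(gt) == 0) stop("no biallelic sites in ", vcf_path, call. = FALSE)
  site_labels <- paste0(v@fix[biallelic, "CHROM"], ":",
                        v@fix[biallelic, "POS"])
  deme_of <- setNames(popmap$deme, popmap$sample)[samples]
  demes <- unique(popmap$deme[popmap$sample %in% samples])

  alt_count <- function(g) {
    # "0/1", "1|1", ".", "./." -> alt allele count and called allele count
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(0L, 0L))
    alleles <- strsplit(g, "[/|]")[[1]]
    alleles <- alleles[alleles != "."]
    c(sum(alleles == "1"), length(alleles))
  }
  freq_rows <- lapply(demes, function(d) {
    cols <- which(deme_of == d)
    vapply(seq_len(nrow(gt)), function(i) {
      counts <- rowSums(vapply(gt[i, cols], alt_count, integer(2)))
      if (counts[2] == 0) NA_real_ else counts[1] / counts[2]
    }, 0)
  })
  freqs <- do.call(rbind, freq_rows)
  all_missing <- apply(freqs, 2, function(x) any(is.na(x)))
  if (any(all_missing)) {
    message("skipping ", sum(all_missing),
            " site(s) with no called genotypes in some deme")
    freqs <- freqs[, !all_missing, drop = FALSE]
    site_labels <- site_labels[!all_missing]
  }
  if (ncol(freqs) == 0) stop("no usable sites after filtering", call. = FALSE)
  colnames(freqs) <- site_labels
  tibble::as_tibble(cbind(tibble::tibble(population = demes),
                          tibble::as_tibble(freqs)))
}

#' Write replicate records as JSON lines
#'
#' One JSON object per line per replicate: the drawn parameters (without the
#' long recombination vectors unless `full = TRUE`), the realized `L` and
#' bin, and the per-alpha error report.
#'
#' @param records A list of `replicate_record`s.
#' @param path Output path.
#' @param full Include the full recombination-rate vectors.
#' @return `path`, invisibly.
#' @export
write_replicate_records <- function(records, path, full = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in records) {
    p <- unclass(r$params)
    if (!full) p$r_host <- p$r_par <- NULL
    err <- r$errors
    err$detected_pairs <- lapply(err$detected_pairs, as.list)
    obj <- list(params = p, L = r$L, bin = r$bin,
                host_idx = r$arch$host_idx, par_idx = r$arch$par_idx,
                errors = err)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
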