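#' Read a trait table
#'
#' CSV or TSV (detected from the extension, or forced with `sep`) with header
#' columns `id` and `trait`. Rows with missing or non-positive trait values
#' are reported by line number.
#'
#' @param path file path.
#' @param sep field separator; `NULL` to infer from the extension
#'   (`.tsv`/`.txt` -> tab, otherwise comma).
#' @return Validated data frame with columns `id`, `trait`.
#' @export
read_traits <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "trait") %in% names(tab))) {
    stop("parse error in ", path, ": need header columns 'id' and 'trait'",
         call. = FALSE)
  }
  tab$trait <- suppressWarnings(as.numeric(tab$trait))
  bad <- which(!is.finite(tab$trait) | tab$trait <= 0)
  if (length(bad)) {
    stop("parse error in ", path, ": invalid trait value at data line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  .validate_traits(tab)
}

#' Write a trait table
#' @param traits data frame with `id`, `trait` (a `tier` column, if present,
#'   is kept).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format abundance table
#'
#' CSV with header columns `pair_id`, `strain_id`, `condition`, `time`,
#' `abundance`. Each strain x condition series must have strictly increasing
#' times.
#'
#' @param path file path.
#' @return Validated long-format data frame.
#' @export
read_abundances <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- .validate_abundances(tab)
  key <- interaction(tab$pair_id, tab$strain_id, tab$condition, drop = TRUE)
  for (k in levels(key)) {
    tt <- tab$time[key == k]
    if (any(diff(tt) <= 0)) {
      stop("non-monotone times for series ", k, " in ", path, call. = FALSE)
    }
  }
  tab
}

#' Write a long-format abundance table
#' @param abund long-format abundance data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_abundances <- function(abund, path) {
  utils::write.csv(abund, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix
#'
#' Either a TSV matrix (rows individuals with rownames, columns SNPs, codes
#' 0/1/2 with `NA` for missing) or a VCF restricted to biallelic sites
#' (requires the \pkg{vcfR} package; multiallelic sites are skipped with a
#' warning, GT fields converted to alternate-allele dosage).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`; default inferred from the extension.
#' @param max_missing maximum tolerated missing fraction per SNP; SNPs above
#'   it are dropped with a warning.
#' @return Numeric matrix individuals x SNPs.
#' @export
read_genotypes <- function(path, format = NULL, max_missing = 0.2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the 'vcfR' package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v))
    if (any(multi)) {
      warning(sum(multi), " multiallelic site(s) skipped", call. = FALSE)
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.numeric(strsplit(x, "[/|]")[[1]]))
    })
    geno <- t(dosage)
  } else {
    geno <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                        row.names = 1, check.names = FALSE))
  }
  storage.mode(geno) <- "double"
  if (!all(geno %in% c(0, 1, 2) | is.na(geno))) {
    stop("genotypes must be coded 0/1/2 or missing", call. = FALSE)
  }
  miss <- colMeans(is.na(geno))
  if (any(miss > max_missing)) {
    warning(sum(miss > max_missing), " SNP(s) above the missing-fraction cap (",
            max_missing, ") dropped", call. = FALSE)
    geno <- geno[, miss <= max_missing, drop = FALSE]
  }
  geno
}

#' Write a genotype matrix as TSV
#' @param geno individuals x SNPs matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  utils::write.table(as.data.frame(geno), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Export a network as an edge list and GraphML
#'
#' @param net an \pkg{igraph} graph.
#' @param path_csv edge-list CSV path (`from,to,weight`).
#' @param path_graphml optional GraphML path.
#' @return `path_csv`, invisibly.
#' @export
write_network <- function(net, path_csv, path_graphml = NULL) {
  el <- igraph::as_data_frame(net, what = "edges")
  utils::write.csv(el, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_graphml)) {
    igraph::write_graph(net, path_graphml, format = "graphml")
  }
  invisible(path_csv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
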