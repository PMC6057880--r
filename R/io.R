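#' Read / write the flat TSV formats
#'
#' All pipeline tables travel as plain tab-separated files with a header
#' row: caliper measurements (`model_id`, `mouse_id`, `arm`, `day`,
#' `shorter_mm`, `longer_mm`), read assignments (`read_id`,
#' `maps_human`, `maps_mouse`, `primary_is_human` as 0/1), annotated
#' variants (call columns plus annotation columns), and gene x sample
#' count matrices (first column `gene`, one column per sample).
#'
#' @param path file path.
#' @param x data.frame (or matrix for counts) to write.
#' @return the data.frame read, invisibly `path` for writers.
#' @name pdx_io
NULL

#' @rdname pdx_io
#' @export
read_measurements <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  growth_curves(df)  # validates
  df
}

#' @rdname pdx_io
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pdx_io
#' @export
read_read_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("maps_human", "maps_mouse", "primary_is_human")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname pdx_io
#' @export
read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("in_cosmic", "in_esp6500", "in_1000g",
                          "homopolymer_adjacent", "end_of_read_only"),
                        names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname pdx_io
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname pdx_io
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write_tsv(df, path)
}

VCF_INFO_KEYS <- c(
  GENE = "gene", REGION = "region", CSQ = "consequence",
  DBSNP = "dbsnp_status", COSMIC = "in_cosmic", ROLE = "gene_role",
  ESP = "in_esp6500", KG = "in_1000g", HP_ADJ = "homopolymer_adjacent",
  EOR = "end_of_read_only", CONF = "confidence", VERDICT = "verdict",
  SAMPLE = "sample_id", SRC = "source", DP = "depth", AR = "alt_reads",
  VAF = "vaf", AQ = "avg_alt_quality"
)

#' Write annotated variants as VCF
#'
#' Serializes an annotated variant table to a minimal VCFv4.2 file,
#' carrying the annotation and provenance columns in INFO keys (GENE,
#' REGION, CSQ, DBSNP, COSMIC, ROLE, ESP, KG, HP_ADJ, EOR, CONF,
#' VERDICT, SAMPLE, SRC, DP, AR, VAF, AQ). [read_variants_vcf()] inverts
#' the encoding.
#'
#' @param variants annotated variant data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_variants_vcf <- function(variants, path) {
  keys <- VCF_INFO_KEYS[VCF_INFO_KEYS %in% names(variants)]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pdxtrial",
    vapply(names(keys), function(k) {
      sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
              k, keys[[k]])
    }, character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    info <- paste(
      vapply(names(keys), function(k) {
        val <- variants[[keys[[k]]]][i]
        if (is.logical(val)) val <- as.integer(val)
        paste0(k, "=", gsub("[;=[:space:]]", "_", as.character(val)))
      }, character(1)),
      collapse = ";"
    )
    paste(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
          variants$alt[i], ".", ".", info, sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read annotated variants from a pdxtrial VCF
#'
#' @param path VCF path written by [write_variants_vcf()].
#' @return annotated variant data.frame.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    stop("VCF contains no records", call. = FALSE)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_info <- function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(vapply(kv, `[[`, character(1), 2L),
             vapply(kv, `[[`, character(1), 1L))
  }
  rows <- lapply(fields, function(f) {
    info <- parse_info(f[[8]])
    row <- list(chrom = f[[1]], pos = as.integer(f[[2]]), ref = f[[4]],
                alt = f[[5]])
    for (k in names(info)) {
      col <- VCF_INFO_KEYS[[k]]
      if (is.null(col)) next
      val <- info[[k]]
      row[[col]] <- switch(col,
        depth = , alt_reads = as.integer(val),
        vaf = , avg_alt_quality = as.numeric(val),
        in_cosmic = , in_esp6500 = , in_1000g = ,
        homopolymer_adjacent = , end_of_read_only = as.logical(as.integer(val)),
        val
      )
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
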