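#' Specification of a synthetic annotated-variant set
#'
#' Controls how many records [gen_variants()] constructs per cascade
#' rule (each built to fail exactly that rule) and per retention path
#' (each built to pass the whole cascade).
#'
#' @param n_per_rule records per discard rule (default 2).
#' @param n_retained_per_path records per retention path — oncogene at a
#'   COSMIC site, tumor suppressor at a COSMIC site, and novel tumor
#'   suppressor absent from the population databases (default 2).
#' @param seed integer seed.
#' @return object of class `pdx_variant_sim_spec`.
#' @export
variant_sim_spec <- function(n_per_rule = 2, n_retained_per_path = 2,
                             seed = 1) {
  if (n_per_rule < 0 || n_retained_per_path < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(
    list(n_per_rule = as.integer(n_per_rule),
         n_retained_per_path = as.integer(n_retained_per_path),
         seed = as.integer(seed)),
    class = "pdx_variant_sim_spec"
  )
}

# A fully annotated record that passes every cascade rule for the given
# role; rule-specific fields are then flipped one at a time.
variant_template <- function(role) {
  gene <- switch(role,
    oncogene = "BRAF", tumor_suppressor = "TP53", other = "OR4F5"
  )
  data.frame(
    chrom = "chr7", pos = NA_integer_, ref = "A", alt = "T",
    depth = 60L, alt_reads = 20L, vaf = 20 / 60, avg_alt_quality = 30,
    sample_id = "S1", source = "per_sample",
    gene = gene, region = "exonic", consequence = "missense",
    dbsnp_status = "absent", in_cosmic = TRUE, gene_role = role,
    in_esp6500 = FALSE, in_1000g = FALSE,
    homopolymer_adjacent = FALSE, end_of_read_only = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate annotated variants with per-rule ground truth
#'
#' Constructs an annotated variant table in which every record either
#' fails exactly one named cascade rule or passes the whole cascade via
#' one of the three retention paths, and records the expected verdict in
#' `truth`. Running [filter_cascade()] on the table must reproduce the
#' `truth` column exactly for every rule.
#'
#' @param spec a [variant_sim_spec()].
#' @return data.frame of annotated variants plus a `truth` column
#'   (`"retained"` or `"discarded:<rule>"`).
#' @export
gen_variants <- function(spec) {
  stopifnot(inherits(spec, "pdx_variant_sim_spec"))
  make <- function(rule) {
    # earlier-rule fields stay passing; only the named rule trips
    v <- switch(rule,
      non_exonic = {
        x <- variant_template("oncogene"); x$region <- "intronic"; x
      },
      synonymous = {
        x <- variant_template("oncogene"); x$consequence <- "synonymous"; x
      },
      dbsnp_nonflagged = {
        x <- variant_template("oncogene"); x$dbsnp_status <- "nonflagged"; x
      },
      oncogene_not_cosmic = {
        x <- variant_template("oncogene"); x$in_cosmic <- FALSE; x
      },
      suppressor_in_population = {
        x <- variant_template("tumor_suppressor")
        x$in_cosmic <- FALSE
        x$in_esp6500 <- TRUE
        x
      },
      other_gene_role = variant_template("other"),
      novel_artifact_context = {
        x <- variant_template("tumor_suppressor")
        x$in_cosmic <- FALSE
        x$homopolymer_adjacent <- TRUE
        x
      },
      retained_oncogene_cosmic = variant_template("oncogene"),
      retained_suppressor_cosmic = variant_template("tumor_suppressor"),
      retained_suppressor_novel = {
        x <- variant_template("tumor_suppressor"); x$in_cosmic <- FALSE; x
      }
    )
    v$truth <- if (startsWith(rule, "retained")) "retained"
               else paste0("discarded:", rule)
    v
  }
  recipes <- c(
    rep(DISCARD_RULES, each = spec$n_per_rule),
    rep(c("retained_oncogene_cosmic", "retained_suppressor_cosmic",
          "retained_suppressor_novel"), each = spec$n_retained_per_path)
  )
  if (!length(recipes)) {
    return(cbind(variant_template("oncogene")[0, ], truth = character(0)))
  }
  with_seed(spec$seed, {
    out <- do.call(rbind, lapply(recipes, make))
    out$pos <- 140000000L + seq_len(nrow(out)) * 10L
    refs <- sample(BASES, nrow(out), replace = TRUE)
    alts <- vapply(refs, function(r) sample(setdiff(BASES, r), 1), character(1))
    out$ref <- refs
    out$alt <- unname(alts)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a retained-variant cohort for oncoprint construction
#'
#' Builds a cohort-level retained-variant table in which stated numbers
#' of samples carry a hotspot mutation in each gene, for exercising
#' [oncoprint()] and [oncoprint_prevalence()] against known prevalences.
#' Mutant samples are drawn without replacement per gene.
#'
#' @param samples character vector of sample ids.
#' @param gene_counts named integer vector: number of mutant samples per
#'   gene (each <= `length(samples)`).
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `sample_id`, `confidence`
#'   (all `"high"`).
#' @export
gen_cohort_variants <- function(samples, gene_counts, seed = 1) {
  if (any(gene_counts > length(samples)) || any(gene_counts < 0)) {
    stop("gene counts must be between 0 and the number of samples",
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(names(gene_counts), function(g) {
      n <- gene_counts[[g]]
      if (n == 0L) return(NULL)
      data.frame(gene = g,
                 sample_id = sort(sample(samples, n)),
                 confidence = "high",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
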