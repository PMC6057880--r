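BASES <- c("A", "C", "G", "T")

DISCARD_RULES <- c(
  "non_exonic", "synonymous", "dbsnp_nonflagged", "oncogene_not_cosmic",
  "suppressor_in_population", "other_gene_role", "novel_artifact_context"
)

ANNOTATION_COLS <- c(
  "region", "consequence", "dbsnp_status", "in_cosmic", "gene_role",
  "in_esp6500", "in_1000g", "homopolymer_adjacent", "end_of_read_only"
)

#' Threshold-based pileup variant caller
#'
#' A deliberately sensitive consensus caller over pileup columns, tuned
#' for low-coverage RNA-seq of a small gene panel where allelic
#' imbalance and low expression make false negatives the main risk. At
#' each column, every non-reference base is emitted as a call when all
#' four inclusive thresholds are met:
#' depth >= `min_coverage`, supporting reads >= `min_reads2`,
#' VAF >= `min_var_freq`, mean supporting-base quality >= `min_avg_qual`.
#' Observations below the quality floor (`min_avg_qual`) are excluded
#' from support counting but still count toward depth, so the VAF
#' denominator is the full column depth.
#'
#' @param pileup data.frame with one row per read observation: columns
#'   `chrom`, `pos` (1-based), `ref` (A/C/G/T), `base` (observed base),
#'   `qual` (phred-scaled base quality, >= 0).
#' @param min_coverage minimum column depth (default 2).
#' @param min_reads2 minimum supporting reads for the alternate base
#'   (default 2).
#' @param min_var_freq minimum variant allele fraction (default 0.01).
#' @param min_avg_qual minimum average supporting-base quality, also the
#'   per-base quality floor for support counting (default 15).
#' @param sample_id sample label carried on the calls.
#' @param source provenance label (`"per_sample"` or `"pooled"`).
#' @return data.frame of calls: `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_reads`, `vaf`, `avg_alt_quality`, `sample_id`, `source`.
#' @export
call_pileup <- function(pileup, min_coverage = 2, min_reads2 = 2,
                        min_var_freq = 0.01, min_avg_qual = 15,
                        sample_id = "S1",
                        source = c("per_sample", "pooled")) {
  source <- match.arg(source)
  required <- c("chrom", "pos", "ref", "base", "qual")
  missing <- setdiff(required, names(pileup))
  if (length(missing)) {
    stop("pileup lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!pileup$ref %in% BASES) || any(!pileup$base %in% BASES)) {
    stop("invalid base in pileup (only A/C/G/T observations are accepted)",
         call. = FALSE)
  }
  if (any(pileup$pos < 1) || any(pileup$qual < 0)) {
    stop("positions must be >= 1 and qualities >= 0", call. = FALSE)
  }
  key <- paste(pileup$chrom, pileup$pos, sep = ":")
  calls <- list()
  for (k in unique(key)) {
    col <- pileup[key == k, , drop = FALSE]
    ref <- unique(col$ref)
    if (length(ref) != 1L) {
      stop("conflicting reference base at ", k, call. = FALSE)
    }
    depth <- nrow(col)
    if (depth < min_coverage) next
    for (alt in setdiff(unique(col$base), ref)) {
      sup_qual <- col$qual[col$base == alt & col$qual >= min_avg_qual]
      alt_reads <- length(sup_qual)
      if (alt_reads < min_reads2) next
      vaf <- alt_reads / depth
      if (vaf < min_var_freq) next
      avg_q <- mean(sup_qual)
      if (avg_q < min_avg_qual) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = col$chrom[1L], pos = col$pos[1L], ref = ref, alt = alt,
        depth = depth, alt_reads = alt_reads, vaf = vaf,
        avg_alt_quality = avg_q, sample_id = sample_id, source = source,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(calls)) {
    return(data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), depth = integer(0), alt_reads = integer(0),
      vaf = numeric(0), avg_alt_quality = numeric(0),
      sample_id = character(0), source = character(0)
    ))
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-sample and pooled call sets
#'
#' Calling is run once per sample and once on the pool of all samples to
#' maximize sensitivity; the resulting call sets are unioned on the key
#' (sample_id, chrom, pos, ref, alt). When the same key appears in both
#' sets, the record with more supporting reads wins (ties keep the
#' per-sample record, the evidence closest to the sample); source
#' provenance is preserved on the surviving record. The merge is
#' idempotent and insensitive to input order.
#'
#' @param per_sample_calls,pooled_calls call data.frames as produced by
#'   [call_pileup()] (the pooled set carries the sample each pooled call
#'   was assigned to).
#' @return merged call data.frame.
#' @export
merge_callsets <- function(per_sample_calls, pooled_calls) {
  all_calls <- rbind(per_sample_calls, pooled_calls)
  if (nrow(all_calls) == 0L) return(all_calls)
  locus <- paste(all_calls$chrom, all_calls$pos)
  for (l in unique(locus)) {
    if (length(unique(all_calls$ref[locus == l])) > 1L) {
      stop("conflicting reference base at locus ", l, call. = FALSE)
    }
  }
  key <- paste(all_calls$sample_id, all_calls$chrom, all_calls$pos,
               all_calls$ref, all_calls$alt)
  pref <- ifelse(all_calls$source == "per_sample", 0L, 1L)
  o <- order(key, -all_calls$alt_reads, pref)
  all_calls <- all_calls[o, , drop = FALSE]
  out <- all_calls[!duplicated(key[o]), , drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotation-driven variant retention cascade
#'
#' The specificity filter applied after sensitive calling and
#' annotation. Rules are tested in a fixed order and the verdict names
#' the first failing rule (ordering is observable only in the verdict
#' labels; the retained set is order-independent):
#'
#' 1. `non_exonic` — region not exonic or splicing;
#' 2. `synonymous` — synonymous consequence;
#' 3. `dbsnp_nonflagged` — present in the non-flagged (germline) subset
#'    of dbSNP;
#' 4. `oncogene_not_cosmic` — oncogene variants are retained only at
#'    known COSMIC sites;
#' 5. `suppressor_in_population` — tumor-suppressor variants outside
#'    COSMIC are retained only if absent from both ESP6500 and
#'    1000 Genomes (novel loss-of-function is expected in suppressors);
#' 6. `other_gene_role` — genes that are neither oncogene nor tumor
#'    suppressor are not reported;
#' 7. `novel_artifact_context` — novel (non-COSMIC) variants adjacent to
#'    homopolymer runs or supported only at read ends are artifacts.
#'
#' Each record is judged independently of every other record.
#' A `rescue` whitelist of (sample_id, chrom, pos, ref, alt) keys, the
#' manual-inspection additions, bypasses the cascade: matching records
#' are retained with `source = "manual"` (and are later flagged low
#' confidence by [flag_confidence()]).
#'
#' @param variants data.frame of annotated calls: the [call_pileup()]
#'   columns plus `gene`, `region`, `consequence`, `dbsnp_status`
#'   (`"absent"`, `"flagged"`, `"nonflagged"`), `in_cosmic`,
#'   `gene_role` (`"oncogene"`, `"tumor_suppressor"`, `"other"`),
#'   `in_esp6500`, `in_1000g`, `homopolymer_adjacent`,
#'   `end_of_read_only`.
#' @param rescue optional data.frame whitelist with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`.
#' @return the input with `verdict` (`"retained"` or
#'   `"discarded:<rule>"`) and possibly updated `source`.
#' @export
filter_cascade <- function(variants, rescue = NULL) {
  missing <- setdiff(ANNOTATION_COLS, names(variants))
  if (length(missing)) {
    stop("annotation column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(variants) == 0L) {
    variants$verdict <- character(0)
    return(variants)
  }
  if (anyNA(variants[, ANNOTATION_COLS])) {
    stop("missing annotation value(s); records must be fully annotated",
         call. = FALSE)
  }
  bad_role <- setdiff(unique(variants$gene_role),
                      c("oncogene", "tumor_suppressor", "other"))
  if (length(bad_role)) {
    stop("unknown gene_role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  v <- variants
  verdict <- rep(NA_character_, nrow(v))
  fail <- function(cond, rule) {
    hit <- is.na(verdict) & cond
    verdict[hit] <<- paste0("discarded:", rule)
  }
  fail(!(v$region %in% c("exonic", "splicing")), "non_exonic")
  fail(v$consequence == "synonymous", "synonymous")
  fail(v$dbsnp_status == "nonflagged", "dbsnp_nonflagged")
  fail(v$gene_role == "oncogene" & !v$in_cosmic, "oncogene_not_cosmic")
  fail(v$gene_role == "tumor_suppressor" & !v$in_cosmic &
         (v$in_esp6500 | v$in_1000g), "suppressor_in_population")
  fail(v$gene_role == "other", "other_gene_role")
  fail(!v$in_cosmic & (v$homopolymer_adjacent | v$end_of_read_only),
       "novel_artifact_context")
  verdict[is.na(verdict)] <- "retained"

  if (!is.null(rescue) && nrow(rescue)) {
    need <- c("sample_id", "chrom", "pos", "ref", "alt")
    if (length(setdiff(need, names(rescue)))) {
      stop("rescue whitelist needs columns sample_id/chrom/pos/ref/alt",
           call. = FALSE)
    }
    key <- do.call(paste, v[, need])
    hit <- key %in% do.call(paste, rescue[, need])
    verdict[hit] <- "retained"
    if ("source" %in% names(v)) v$source[hit] <- "manual"
  }
  v$verdict <- verdict
  v
}

#' Confidence flag for a retained variant
#'
#' Variants supported by very few reads, and all manual-rescue
#' additions, are flagged low confidence (rendered transparent in the
#' oncoprint).
#'
#' @param alt_reads supporting read counts.
#' @param source provenance (`"per_sample"`, `"pooled"`, `"manual"`).
#' @param max_low_reads supporting-read threshold at or below which a
#'   call is low confidence (default 2).
#' @return character vector, `"high"` or `"low"`.
#' @export
flag_confidence <- function(alt_reads, source = "per_sample",
                            max_low_reads = 2) {
  if (any(alt_reads < 0)) stop("negative supporting-read count", call. = FALSE)
  ifelse(alt_reads <= max_low_reads | source == "manual", "low", "high")
}

#' Homopolymer adjacency of a variant
#'
#' Novel variants next to homopolymer runs are common sequencing
#' artifacts. The predicate is true when a single-base run of length
#' >= `run_min` starts or ends within `adjacency` bases of the variant
#' position, or the variant lies inside such a run (the inclusive
#' reading: a variant inside a run is at least as suspect as one beside
#' it).
#'
#' @param context_sequence character string of reference context around
#'   the variant (A/C/G/T).
#' @param variant_offset 1-based position of the variant within
#'   `context_sequence`.
#' @param run_min minimum homopolymer run length (default 5).
#' @param adjacency maximum distance in bp between the variant and the
#'   run boundary (default 1).
#' @return logical.
#' @examples
#' homopolymer_adjacent("ACGTAAAAAG", 4)  # TRUE: A-run of 5 starts at 5
#' @export
homopolymer_adjacent <- function(context_sequence, variant_offset,
                                 run_min = 5, adjacency = 1) {
  chars <- strsplit(toupper(context_sequence), "")[[1]]
  n <- length(chars)
  if (n < 2 * adjacency + 1 || n < run_min) {
    stop("context window too short", call. = FALSE)
  }
  if (variant_offset < 1 || variant_offset > n) {
    stop("`variant_offset` outside the context window", call. = FALSE)
  }
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  long <- which(runs$lengths >= run_min)
  any(variant_offset >= starts[long] - adjacency &
        variant_offset <= ends[long] + adjacency)
}

#' Default gene-role table for melanoma panels
#'
#' Oncogene / tumor-suppressor assignments for recurrently mutated
#' melanoma genes, used by the retention cascade when the caller does
#' not supply a panel-specific table.
#'
#' @return data.frame with columns `gene`, `gene_role`.
#' @export
melanoma_gene_roles <- function() {
  data.frame(
    gene = c("BRAF", "NRAS", "KIT", "GNAQ", "GNA11", "CTNNB1", "MAP2K1",
             "RAC1", "KRAS", "HRAS",
             "NF1", "TP53", "CDKN2A", "PTEN", "ARID2", "PPP6C", "RB1",
             "DDX3X", "IDH1", "STK11"),
    gene_role = c(rep("oncogene", 10),
                  rep("tumor_suppressor", 8),
                  "oncogene", "tumor_suppressor"),
    stringsAsFactors = FALSE
  )
}

#' Oncoprint matrix of retained variants
#'
#' Gene-by-sample grid of mutation states for a cohort, with samples
#' ordered by response group (progression, suppression, regression, then
#' by sample id). Multiple variants in one cell collapse to the highest
#' confidence state; cells without variants are `"none"`.
#'
#' @param variants retained, confidence-flagged variants with columns
#'   `gene`, `sample_id`, `confidence`.
#' @param samples character vector of all samples (columns), mutated or
#'   not.
#' @param genes character vector of panel genes (rows).
#' @param groups named character vector mapping every sample to its
#'   response group.
#' @return object of class `pdx_oncoprint`: list with `matrix`
#'   (character matrix of `"none"`, `"mutated_low_conf"`,
#'   `"mutated_high_conf"`) and `groups` (per ordered sample).
#' @export
oncoprint <- function(variants, samples, genes, groups) {
  if (!all(samples %in% names(groups))) {
    stop("sample(s) without a response group: ",
         paste(setdiff(samples, names(groups)), collapse = ", "),
         call. = FALSE)
  }
  groups <- groups[samples]
  bad <- setdiff(unique(groups), RESPONSE_GROUPS)
  if (length(bad)) {
    stop("unknown response group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(match(groups, RESPONSE_GROUPS), samples)
  samples <- samples[ord]
  groups <- groups[ord]
  mat <- matrix("none", nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(variants)) {
    v <- variants[variants$gene %in% genes & variants$sample_id %in% samples, ,
                  drop = FALSE]
    for (i in seq_len(nrow(v))) {
      state <- if (v$confidence[i] == "high") "mutated_high_conf"
               else "mutated_low_conf"
      cur <- mat[v$gene[i], v$sample_id[i]]
      if (cur != "mutated_high_conf") mat[v$gene[i], v$sample_id[i]] <- state
    }
  }
  structure(list(matrix = mat, groups = groups), class = "pdx_oncoprint")
}

#' Per-gene mutation prevalence from an oncoprint
#'
#' Fraction of samples carrying any (high- or low-confidence) mutation
#' per gene, as an integer percentage rounded half away from zero (so
#' 20/31 reads 65\% and 11/31 reads 35\%).
#'
#' @param op a [oncoprint()] result.
#' @return data.frame with columns `gene`, `n_mutated`, `n_samples`,
#'   `percent`.
#' @export
oncoprint_prevalence <- function(op) {
  stopifnot(inherits(op, "pdx_oncoprint"))
  n_mut <- rowSums(op$matrix != "none")
  data.frame(
    gene = rownames(op$matrix),
    n_mutated = as.integer(n_mut),
    n_samples = ncol(op$matrix),
    percent = round_half_up(100 * n_mut / ncol(op$matrix)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
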