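#' Species verdict for one sequencing read
#'
#' The graft/host disambiguation rule for reads aligned against a
#' combined human+mouse reference: reads mapping only to human
#' chromosomes are kept, reads mapping only to mouse are dropped, and
#' reads mapping to both species are kept exactly when their primary
#' alignment is on the human reference — otherwise they are discarded as
#' ambiguous. The rule is a pure function of the three flags; unmapped
#' reads are out of band and rejected.
#'
#' @param maps_human,maps_mouse logical; whether the read has any
#'   alignment to the human / mouse part of the reference. Vectorized.
#' @param primary_is_human logical; whether the read's primary alignment
#'   is on the human reference (only consulted for dual mappers).
#' @return character vector with values `"keep_human"`, `"drop_mouse"`
#'   or `"drop_ambiguous"`.
#' @examples
#' assign_read(TRUE, TRUE, FALSE)  # dual mapper, primary on mouse
#' @export
assign_read <- function(maps_human, maps_mouse, primary_is_human) {
  n <- length(maps_human)
  if (length(maps_mouse) != n || length(primary_is_human) != n) {
    stop("flag vectors must have equal length", call. = FALSE)
  }
  maps_human <- as.logical(maps_human)
  maps_mouse <- as.logical(maps_mouse)
  primary_is_human <- as.logical(primary_is_human)
  if (anyNA(maps_human) || anyNA(maps_mouse)) {
    stop("mapping flags must be non-missing logicals", call. = FALSE)
  }
  if (any(!maps_human & !maps_mouse)) {
    stop("read maps to neither species (unmapped reads are out of band)",
         call. = FALSE)
  }
  ifelse(!maps_mouse, "keep_human",
         ifelse(!maps_human, "drop_mouse",
                ifelse(primary_is_human %in% TRUE, "keep_human",
                       "drop_ambiguous")))
}

#' Filter a read-assignment table
#'
#' Applies [assign_read()] to every row, returning the kept (human)
#' reads and the per-verdict counts. Counts are conserved: they sum to
#' the number of input rows.
#'
#' @param reads data.frame with columns `read_id`, `maps_human`,
#'   `maps_mouse`, `primary_is_human` (0/1 or logical).
#' @return list with `kept` (input rows with verdict `keep_human`, plus
#'   a `verdict` column), `table` (all rows with verdicts) and `counts`
#'   (named integer vector over the three verdicts).
#' @export
filter_read_table <- function(reads) {
  required <- c("read_id", "maps_human", "maps_mouse", "primary_is_human")
  missing <- setdiff(required, names(reads))
  if (length(missing)) {
    stop("read table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  verdicts <- c("keep_human", "drop_mouse", "drop_ambiguous")
  if (nrow(reads) == 0L) {
    empty <- cbind(reads, verdict = character(0))
    return(list(kept = empty, table = empty,
                counts = setNames(integer(3), verdicts)))
  }
  dup <- duplicated(reads$read_id)
  if (any(dup)) {
    ids <- unique(reads$read_id[dup])
    flags <- reads[, c("maps_human", "maps_mouse", "primary_is_human")]
    conflict <- vapply(ids, function(id) {
      rows <- flags[reads$read_id == id, , drop = FALSE]
      nrow(unique(rows)) > 1L
    }, logical(1))
    if (any(conflict)) {
      bad_rows <- which(reads$read_id %in% ids[conflict])
      stop("conflicting flags for duplicated read id(s) at row(s): ",
           paste(bad_rows, collapse = ", "), call. = FALSE)
    }
    reads <- reads[!dup, , drop = FALSE]
  }
  reads$verdict <- assign_read(reads$maps_human, reads$maps_mouse,
                               reads$primary_is_human)
  counts <- vapply(verdicts, function(v) sum(reads$verdict == v), integer(1))
  list(
    kept = reads[reads$verdict == "keep_human", , drop = FALSE],
    table = reads,
    counts = counts
  )
}

#' Extract read assignments from a SAM file
#'
#' Adapter from alignments against a combined two-species reference to
#' the per-read flag table consumed by [filter_read_table()]. Species is
#' recognised by a configurable reference-name prefix (e.g. `"hg19_"` /
#' `"mm10_"`); the primary-alignment flag is the standard SAM flag field
#' (bits 0x100 secondary, 0x800 supplementary, 0x4 unmapped). Alignments
#' of one read within one species collapse to a single flag.
#'
#' @param path path to a SAM text file.
#' @param human_prefix,mouse_prefix reference-name prefixes identifying
#'   the species of each target sequence.
#' @return data.frame with columns `read_id`, `maps_human`,
#'   `maps_mouse`, `primary_is_human`, one row per mapped read.
#' @export
read_sam_assignments <- function(path, human_prefix = "hg19_",
                                 mouse_prefix = "mm10_") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), maps_human = logical(0),
                      maps_mouse = logical(0), primary_is_human = logical(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  qname <- qname[mapped]; flag <- flag[mapped]; rname <- rname[mapped]
  is_primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  is_human <- startsWith(rname, human_prefix)
  is_mouse <- startsWith(rname, mouse_prefix)
  if (any(!is_human & !is_mouse)) {
    stop("reference name(s) match neither species prefix: ",
         paste(unique(rname[!is_human & !is_mouse])[1:3], collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(qname)
  data.frame(
    read_id = ids,
    maps_human = vapply(ids, function(i) any(is_human[qname == i]), logical(1)),
    maps_mouse = vapply(ids, function(i) any(is_mouse[qname == i]), logical(1)),
    primary_is_human = vapply(ids, function(i) {
      any(is_human[qname == i] & is_primary[qname == i])
    }, logical(1)),
    row.names = NULL
  )
}

#' Simulate a read-assignment table with known species truth
#'
#' Emits reads of three kinds in stated proportions: human-only, mouse-
#' only, and ambiguous dual mappers whose primary alignment lands on the
#' human reference with probability 1/2 (independent Bernoulli draws).
#' The `truth` column records the simulated origin, so the downstream
#' filter can be scored exactly.
#'
#' @param n_reads number of reads.
#' @param fraction_human,fraction_mouse,fraction_ambiguous proportions
#'   of the three read kinds; must sum to 1. Counts are assigned by
#'   largest remainder so they are exact.
#' @param seed integer seed.
#' @return data.frame with columns `read_id`, `maps_human`,
#'   `maps_mouse`, `primary_is_human`, `truth` (one of `"human"`,
#'   `"mouse"`, `"ambiguous"`).
#' @export
gen_reads <- function(n_reads, fraction_human = 0.7, fraction_mouse = 0.1,
                      fraction_ambiguous = 0.2, seed = 1) {
  fr <- c(human = fraction_human, mouse = fraction_mouse,
          ambiguous = fraction_ambiguous)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_reads < 0 || n_reads != round(n_reads)) {
    stop("`n_reads` must be a non-negative integer", call. = FALSE)
  }
  if (n_reads == 0L) {
    return(data.frame(read_id = character(0), maps_human = logical(0),
                      maps_mouse = logical(0), primary_is_human = logical(0),
                      truth = character(0)))
  }
  with_seed(seed, {
    truth <- sample(allocate_classes(fr, n_reads))
    maps_human <- truth != "mouse"
    maps_mouse <- truth != "human"
    primary <- ifelse(truth == "human", TRUE,
                      ifelse(truth == "mouse", FALSE,
                             runif(n_reads) < 0.5))
    data.frame(
      read_id = sprintf("read_%06d", seq_len(n_reads)),
      maps_human = maps_human,
      maps_mouse = maps_mouse,
      primary_is_human = primary,
      truth = truth,
      stringsAsFactors = FALSE
    )
  })
}
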