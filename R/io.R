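# Readers/writers for the plain-text formats the pipeline exchanges:
# clonotype TSV (VDJtools-style export), GMT gene sets, expression TSV
# (genes x samples), variant call TSV and survival TSV.  All tables are
# UTF-8, tab-delimited, unquoted, '.' decimal separator.

.read_tsv <- function(path, as_character = FALSE) {
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             check.names = FALSE, stringsAsFactors = FALSE,
             comment.char = "", fileEncoding = "UTF-8",
             colClasses = if (as_character) "character" else NA)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# pick the first matching synonym (case/punctuation insensitive)
.match_column <- function(nms, synonyms, what, required = TRUE) {
  canon <- tolower(gsub("[^a-z0-9]", "", tolower(nms)))
  for (s in synonyms) {
    hit <- which(canon == s)
    if (length(hit)) return(hit[1L])
  }
  if (required) {
    stop(sprintf("clonotype table is missing a '%s' column (accepted: %s)",
                 what, paste(synonyms, collapse = ", ")), call. = FALSE)
  }
  NA_integer_
}

#' Construct a clonotype table
#'
#' A `clonotype_table` holds one sample's TCR-beta repertoire: one row per
#' clonotype with CDR3 nucleotide/amino-acid sequence, V/D/J segment
#' assignment, read count and frequency.  Counts are authoritative:
#' frequencies are always recomputed as `count / total_count`.  Rows whose
#' clonotype key coincides (same CDR3 and V/J call) are merged by summing
#' counts, so duplicated rows never change downstream statistics.
#'
#' @param records A data.frame with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_segment`, `d_segment`, `j_segment`, `count`.
#' @param sample_id Sample identifier.
#' @param key_by Clonotype identity: `"nucleotide"` keys on
#'   (CDR3 nucleotide sequence, V, J); `"amino_acid"` keys on
#'   (CDR3 amino-acid sequence, V, J).
#' @return An object of class `clonotype_table`: a data.frame with the
#'   record columns plus `frequency` and `key`, and attributes
#'   `sample_id`, `total_count`, `key_by`.
#' @export
clonotype_table <- function(records, sample_id = "sample",
                            key_by = c("nucleotide", "amino_acid")) {
  key_by <- match.arg(key_by)
  needed <- c("cdr3_nt", "cdr3_aa", "v_segment", "d_segment", "j_segment",
              "count")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "))
  }
  records <- records[, needed, drop = FALSE]
  records$count <- as.numeric(records$count)
  if (any(!is.finite(records$count)) || any(records$count < 0)) {
    stop("clonotype counts must be finite and non-negative")
  }
  if (nrow(records) && any(!nzchar(records$cdr3_nt))) {
    stop("cdr3_nt must be non-empty for every record")
  }
  seq_col <- if (key_by == "nucleotide") "cdr3_nt" else "cdr3_aa"
  key <- paste(records[[seq_col]], records$v_segment, records$j_segment,
               sep = "|")
  if (anyDuplicated(key)) {
    agg <- rowsum(records$count, group = key, reorder = FALSE)
    keep <- !duplicated(key)
    records <- records[keep, , drop = FALSE]
    key <- key[keep]
    records$count <- as.numeric(agg[match(key, rownames(agg)), 1L])
  }
  total <- sum(records$count)
  records$frequency <- if (total > 0) records$count / total else
    rep(0, nrow(records))
  records$key <- key
  rownames(records) <- NULL
  structure(records, class = c("clonotype_table", "data.frame"),
            sample_id = sample_id, total_count = total, key_by = key_by)
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("clonotype_table '%s': %d clonotypes, %s reads\n",
              attr(x, "sample_id"), nrow(x),
              format(attr(x, "total_count"), big.mark = ",")))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a clonotype TSV export
#'
#' Reads one sample's repertoire from a tab-delimited clonotype table with
#' at least count, frequency, CDR3 nucleotide, CDR3 amino-acid, V and J
#' columns (column-name synonyms of the common repertoire-tool exports are
#' accepted; the D column may be absent).  Stored frequencies are checked
#' against counts and silently recomputed from counts when they disagree
#' (with a warning), so `frequency` always equals `count / total_count`.
#'
#' @param path Path to the tab-delimited file.
#' @inheritParams clonotype_table
#' @return A [clonotype_table].
#' @export
read_clonotype_table <- function(path, sample_id = NULL,
                                 key_by = c("nucleotide", "amino_acid")) {
  key_by <- match.arg(key_by)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- .read_tsv(path)
  nms <- names(df)
  idx <- c(
    count   = .match_column(nms, c("count", "clonecount", "reads",
                                   "readcount"), "count"),
    freq    = .match_column(nms, c("freq", "frequency", "fraction",
                                   "clonefraction"), "frequency"),
    cdr3_nt = .match_column(nms, c("cdr3nt", "nseqcdr3",
                                   "cdr3nucleotidesequence"), "cdr3 nt"),
    cdr3_aa = .match_column(nms, c("cdr3aa", "aaseqcdr3",
                                   "cdr3aminoacidsequence"), "cdr3 aa"),
    v       = .match_column(nms, c("v", "vsegm", "vgene", "bestvgene",
                                   "allvhitswithscore"), "V segment"),
    d       = .match_column(nms, c("d", "dsegm", "dgene", "bestdgene"),
                            "D segment", required = FALSE),
    j       = .match_column(nms, c("j", "jsegm", "jgene", "bestjgene",
                                   "alljhitswithscore"), "J segment")
  )
  count <- suppressWarnings(as.numeric(df[[idx[["count"]]]]))
  if (any(is.na(count))) {
    stop("non-numeric value in count column at row ",
         which(is.na(count))[1L])
  }
  if (any(count < 0)) {
    stop("negative count at row ", which(count < 0)[1L])
  }
  rec <- data.frame(
    cdr3_nt = as.character(df[[idx[["cdr3_nt"]]]]),
    cdr3_aa = as.character(df[[idx[["cdr3_aa"]]]]),
    v_segment = as.character(df[[idx[["v"]]]]),
    d_segment = if (is.na(idx[["d"]])) "" else
      as.character(df[[idx[["d"]]]]),
    j_segment = as.character(df[[idx[["j"]]]]),
    count = count,
    stringsAsFactors = FALSE
  )
  stored <- suppressWarnings(as.numeric(df[[idx[["freq"]]]]))
  total <- sum(count)
  if (total > 0 && any(abs(stored - count / total) > 1e-9, na.rm = TRUE)) {
    warning("stored frequencies disagree with counts in '", basename(path),
            "'; recomputed from counts", call. = FALSE)
  }
  clonotype_table(rec, sample_id = sample_id, key_by = key_by)
}

#' @rdname read_clonotype_table
#' @param table A [clonotype_table] to write.
#' @export
write_clonotype_table <- function(table, path) {
  stopifnot(inherits(table, "clonotype_table"))
  out <- as.data.frame(table)[, c("count", "frequency", "cdr3_nt",
                                  "cdr3_aa", "v_segment", "d_segment",
                                  "j_segment")]
  names(out) <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")
  .write_tsv(out, path)
}

#' Read a GMT gene-set collection
#'
#' Each line of a GMT file is: set name, description, then one gene
#' identifier per field, all tab-separated.  Duplicate genes within a set
#' are removed; duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name: ", nms[duplicated(nms)][1L])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nms
  if (any(!lengths(sets))) {
    stop("empty gene set: ", nms[!lengths(sets)][1L])
  }
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets A named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a gene-by-sample expression matrix
#'
#' Expression values are stored as a tab-delimited table whose first
#' column holds gene identifiers and whose remaining columns are samples.
#' Values are treated throughout the package as log2-scale intensities.
#'
#' @param path File path.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- .read_tsv(path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1L])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifier")
  if (any(!is.finite(m))) stop("non-finite expression value")
  rownames(m) <- genes
  m
}

#' @rdname read_expression_matrix
#' @param matrix Numeric gene-by-sample matrix with dimnames.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read / write a candidate somatic variant table
#'
#' The variant table is tab-delimited with one row per candidate call and
#' columns `chrom`, `pos`, `ref`, `alt`, `gene`, `effect`,
#' `germline_depth`, `germline_alt`, followed by one `<sample>_depth` /
#' `<sample>_alt` pair per tumor sample.  Unknown extra columns are kept
#' but ignored by the filters.
#'
#' @param path File path.
#' @return A data.frame of class `variant_table` with attribute `samples`.
#' @export
read_variant_table <- function(path) {
  # allele columns like "T" must never auto-convert to logicals
  df <- .read_tsv(path, as_character = TRUE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "effect",
                "germline_depth", "germline_alt")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("variant table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("pos", "germline_depth", "germline_alt")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v))) {
      stop("malformed numeric field '", col, "' at row ",
           which(is.na(v))[1L])
    }
    df[[col]] <- v
  }
  samples <- sub("_depth$", "",
                 grep("_depth$", setdiff(names(df), "germline_depth"),
                      value = TRUE))
  samples <- samples[paste0(samples, "_alt") %in% names(df)]
  for (s in samples) {
    for (suffix in c("_depth", "_alt")) {
      col <- paste0(s, suffix)
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(v))) {
        stop("malformed numeric field '", col, "' at row ",
             which(is.na(v))[1L])
      }
      df[[col]] <- v
    }
  }
  .validate_variants(df, samples)
  structure(df, class = c("variant_table", "data.frame"), samples = samples)
}

.validate_variants <- function(df, samples) {
  if (any(df$pos < 1)) stop("variant position must be >= 1")
  depth_cols <- c("germline_depth", paste0(samples, "_depth"))
  alt_cols <- c("germline_alt", paste0(samples, "_alt"))
  for (i in seq_along(depth_cols)) {
    d <- df[[depth_cols[i]]]
    a <- df[[alt_cols[i]]]
    if (any(a < 0) || any(d < a)) {
      stop("depth >= non-reference reads >= 0 violated in '",
           depth_cols[i], "'")
    }
  }
  invisible(TRUE)
}

#' @rdname read_variant_table
#' @param variants A `variant_table` (or plain data.frame with the same
#'   columns) to write.
#' @export
write_variant_table <- function(variants, path) {
  .write_tsv(as.data.frame(variants), path)
}

#' Read / write a patient survival table
#'
#' Tab-delimited with columns `patient`, `time` (follow-up, months) and
#' `event` (1 = event observed, 0 = censored).  Extra columns are kept.
#'
#' @param path File path.
#' @return A data.frame with at least `patient`, `time`, `event`.
#' @export
read_survival_table <- function(path) {
  df <- .read_tsv(path)
  missing <- setdiff(c("patient", "time", "event"), names(df))
  if (length(missing)) {
    stop("survival table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("time", "event")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v))) {
      stop("malformed numeric field '", col, "' at row ",
           which(is.na(v))[1L])
    }
    df[[col]] <- v
  }
  if (any(df$time <= 0)) {
    stop("follow-up time must be > 0 (row ", which(df$time <= 0)[1L], ")")
  }
  if (!all(df$event %in% c(0, 1))) {
    stop("event indicator must be 0 or 1 (row ",
         which(!df$event %in% c(0, 1))[1L], ")")
  }
  df$patient <- as.character(df$patient)
  df
}

#' @rdname read_survival_table
#' @param cohort Survival data.frame to write.
#' @export
write_survival_table <- function(cohort, path) {
  .write_tsv(as.data.frame(cohort), path)
}

#' Write a set of result tables to a directory
#'
#' Each element of `objects` (data.frame or matrix) is written as
#' `<name>.tsv` under `outdir`; matrices keep their row names in a leading
#' `id` column.
#'
#' @param objects Named list of data.frames / matrices.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_results <- function(objects, outdir) {
  stopifnot(is.list(objects), !is.null(names(objects)),
            all(nzchar(names(objects))))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(objects), function(nm) {
    x <- objects[[nm]]
    if (is.matrix(x)) {
      x <- data.frame(id = rownames(x), x, check.names = FALSE,
                      stringsAsFactors = FALSE)
    }
    .write_tsv(as.data.frame(x), file.path(outdir, paste0(nm, ".tsv")))
  }, character(1))
  invisible(paths)
}
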