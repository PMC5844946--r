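# TSV readers/writers for the pipeline's tabular formats. All formats are
# tab-delimited UTF-8 with '.' for missing values; write->read is identity.

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = ".", ...)
}

.write_tsv <- function(df, path, row_names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE, na = ".",
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Read / write a feature-by-sample count matrix (TSV)
#'
#' Features in rows, samples in columns, a `feature` id column first.
#' Counts must be nonnegative; integers are enforced for raw count matrices.
#'
#' @param path TSV path.
#' @param integer require integer counts (default TRUE).
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path, integer = TRUE) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) .stopf("count matrix needs a feature column plus samples")
  feats <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feats
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    .stopf("negative or missing count at row '%s', sample '%s'",
           feats[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  if (integer) {
    off <- which(m != round(m), arr.ind = TRUE)
    if (nrow(off))
      .stopf("non-integer count at row '%s', sample '%s'",
             feats[off[1L, 1L]], colnames(m)[off[1L, 2L]])
  }
  m
}

#' @rdname read_count_matrix
#' @param mat matrix to write (rownames = features, colnames = samples).
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read / write sample group labels (TSV sidecar: sample, group)
#'
#' @param path TSV path with columns `sample` and `group`.
#' @return Named character vector of group labels, names = samples.
#' @export
read_groups <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("sample", "group") %in% names(df)))
    .stopf("groups file needs columns 'sample' and 'group'")
  if (anyDuplicated(df$sample))
    .stopf("duplicate sample in groups file: %s",
           df$sample[duplicated(df$sample)][1L])
  setNames(as.character(df$group), as.character(df$sample))
}

#' @rdname read_groups
#' @param groups named character vector (names = samples).
#' @export
write_groups <- function(groups, path) {
  .write_tsv(data.frame(sample = names(groups), group = unname(groups),
                        stringsAsFactors = FALSE), path)
}

#' Construct an editing site table
#'
#' Container for annotated A-to-I sites with per-sample edited (G-supporting)
#' and total (A+G) read counts.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`), `site_class` (`alu`/`recoding`), and optional `gene`,
#'   `aa_change` (required for recoding sites).
#' @param edited,total integer matrices, sites x samples, with matching
#'   dimnames; `0 <= edited <= total` everywhere.
#' @param groups optional named group vector (names = sample names).
#' @return An `editing_site_table` object.
#' @export
editing_site_table <- function(sites, edited, total, groups = NULL) {
  need <- c("chrom", "pos", "strand", "site_class")
  miss <- setdiff(need, names(sites))
  if (length(miss)) .stopf("sites missing column(s): %s", paste(miss, collapse = ", "))
  if (!"gene" %in% names(sites)) sites$gene <- NA_character_
  if (!"aa_change" %in% names(sites)) sites$aa_change <- NA_character_
  if (any(sites$pos < 1L)) .stopf("site position must be >= 1 (row %d)",
                                  which(sites$pos < 1L)[1L])
  bad_strand <- which(!sites$strand %in% c("+", "-"))
  if (length(bad_strand))
    .stopf("unknown strand '%s' at site row %d", sites$strand[bad_strand[1L]],
           bad_strand[1L])
  bad_class <- which(!sites$site_class %in% c("alu", "recoding"))
  if (length(bad_class))
    .stopf("site_class must be 'alu' or 'recoding' (row %d)", bad_class[1L])
  rec <- sites$site_class == "recoding"
  if (any(rec & (is.na(sites$gene) | is.na(sites$aa_change))))
    .stopf("recoding sites require gene and aa_change (row %d)",
           which(rec & (is.na(sites$gene) | is.na(sites$aa_change)))[1L])
  edited <- as.matrix(edited); total <- as.matrix(total)
  if (!identical(dim(edited), dim(total)))
    .stopf("edited and total matrices must have identical dimensions")
  if (nrow(edited) != nrow(sites))
    .stopf("count matrices have %d rows for %d sites", nrow(edited), nrow(sites))
  if (any(edited < 0 | total < 0))
    .stopf("negative editing counts")
  over <- which(edited > total, arr.ind = TRUE)
  if (nrow(over))
    .stopf("edited > total at site row %d, sample '%s'",
           over[1L, 1L], colnames(edited)[over[1L, 2L]])
  if (!is.null(groups)) groups <- setNames(as.character(groups), names(groups))
  structure(list(sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 edited = edited, total = total, groups = groups),
            class = "editing_site_table")
}

#' @export
print.editing_site_table <- function(x, ...) {
  cat(sprintf("editing_site_table: %d sites (%d alu, %d recoding) x %d samples\n",
              nrow(x$sites), sum(x$sites$site_class == "alu"),
              sum(x$sites$site_class == "recoding"), ncol(x$edited)))
  invisible(x)
}

#' Read / write an editing pileup table (TSV)
#'
#' Columns: `chrom`, `pos`, `strand`, `class`, `gene`, `aa_change`, then a
#' pair `edited_<sample>` / `total_<sample>` per sample.
#'
#' @param path TSV path.
#' @param groups optional named group vector attached to the result.
#' @return An `editing_site_table`.
#' @export
read_pileup_table <- function(path, groups = NULL) {
  df <- .read_tsv(path)
  fixed <- c("chrom", "pos", "strand", "class", "gene", "aa_change")
  miss <- setdiff(fixed, names(df))
  if (length(miss)) .stopf("pileup table missing column(s): %s",
                           paste(miss, collapse = ", "))
  ecols <- grep("^edited_", names(df), value = TRUE)
  samples <- sub("^edited_", "", ecols)
  tcols <- paste0("total_", samples)
  miss_t <- setdiff(tcols, names(df))
  if (length(miss_t)) .stopf("missing total column(s): %s",
                             paste(miss_t, collapse = ", "))
  edited <- as.matrix(df[, ecols, drop = FALSE])
  total <- as.matrix(df[, tcols, drop = FALSE])
  colnames(edited) <- colnames(total) <- samples
  sites <- data.frame(chrom = as.character(df$chrom), pos = as.integer(df$pos),
                      strand = as.character(df$strand),
                      site_class = as.character(df$class),
                      gene = as.character(df$gene),
                      aa_change = as.character(df$aa_change),
                      stringsAsFactors = FALSE)
  editing_site_table(sites, edited, total, groups = groups)
}

#' @rdname read_pileup_table
#' @param table an `editing_site_table` to write.
#' @export
write_pileup_table <- function(table, path) {
  samples <- colnames(table$edited)
  df <- data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
                   strand = table$sites$strand, class = table$sites$site_class,
                   gene = table$sites$gene, aa_change = table$sites$aa_change,
                   stringsAsFactors = FALSE)
  for (s in samples) {
    df[[paste0("edited_", s)]] <- table$edited[, s]
    df[[paste0("total_", s)]] <- table$total[, s]
  }
  .write_tsv(df, path)
}

#' Read / write a long-format Ct table (TSV)
#'
#' Columns: `sample`, `group`, `gene`, `replicate`, `ct`. Replicate Ct
#' values are kept as-is; analysis functions average them per
#' (sample, gene).
#'
#' @param path TSV path.
#' @return A data.frame with those five columns.
#' @export
read_ct_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("Ct table missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct) | df$ct <= 0))
    .stopf("Ct values must be positive (row %d)",
           which(!is.finite(df$ct) | df$ct <= 0)[1L])
  df[need]
}

#' @rdname read_ct_table
#' @param ct data.frame to write.
#' @export
write_ct_table <- function(ct, path) .write_tsv(ct, path)

#' Read / write a BED-dialect site list
#'
#' BED uses 0-based half-open intervals; sites are converted to the 1-based
#' inclusive coordinates used internally (`pos = start + 1` for single-base
#' intervals). Export reverses the conversion, so ingest-then-export
#' round-trips the original intervals.
#'
#' @param path BED path (columns: chrom, start, end, name, score, strand).
#' @param site_class class assigned to the ingested sites
#'   (`"alu"` or `"recoding"`).
#' @return A data.frame of site records with 1-based `pos`.
#' @export
read_bed_sites <- function(path, site_class = "recoding") {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) .stopf("BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  if (ncol(df) >= 6L) names(df)[6L] <- "strand"
  if (any(df$end - df$start != 1L))
    .stopf("site BED intervals must be single-base (row %d)",
           which(df$end - df$start != 1L)[1L])
  strand <- if ("strand" %in% names(df)) df$strand else "+"
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) .stopf("unknown strand '%s' at BED row %d",
                          strand[bad[1L]], bad[1L])
  data.frame(chrom = df$chrom, pos = as.integer(df$start) + 1L,
             strand = strand, site_class = site_class,
             gene = if ("name" %in% names(df)) df$name else NA_character_,
             aa_change = NA_character_, stringsAsFactors = FALSE)
}

#' @rdname read_bed_sites
#' @param sites site data.frame with 1-based `pos`.
#' @export
write_bed_sites <- function(sites, path) {
  out <- data.frame(sites$chrom, sites$pos - 1L, sites$pos,
                    ifelse(is.na(sites$gene), ".", sites$gene), 0L,
                    sites$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
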