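# Domain containers and TSV readers/writers.
#
# Conventions shared by every table in the package:
#   * genomic coordinates are 1-based closed intervals (SEG convention);
#   * tables are data.frames carrying a lightweight S3 class tag;
#   * parsers never silently drop rows — skipped rows are recorded in
#     attr(x, "skipped") with a reason, so
#     nrow(input) == nrow(parsed) + nrow(skipped).

MODALITIES <- c("CNV", "MET_BETA", "EXPR_FPKM", "EXPR_COUNT")
REGION_CLASSES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                    "OpenSea")

#' Construct a gene-by-sample matrix tagged with its modality
#'
#' The central numeric container of the pipeline: a genes x samples matrix
#' with duplicate-free dimnames and modality-specific validation.
#' `MET_BETA` values must lie in `[0, 1]` where present (NA allowed only
#' for that modality, pre-imputation); `EXPR_FPKM` must be nonnegative;
#' `EXPR_COUNT` must be nonnegative integers.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param modality one of `"CNV"`, `"MET_BETA"`, `"EXPR_FPKM"`,
#'   `"EXPR_COUNT"`.
#' @return a `gene_matrix` object (a classed matrix with a `modality`
#'   attribute).
#' @export
gene_matrix <- function(values, modality) {
  modality <- match.arg(modality, MODALITIES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene_matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in gene_matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in gene_matrix")
  validate_modality(values, modality)
  structure(values, modality = modality,
            class = c("gene_matrix", class(values)))
}

validate_modality <- function(values, modality) {
  if (modality == "MET_BETA") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "MET_BETA values outside [0,1] at %d cell(s), e.g. [%s, %s] = %g",
        nrow(bad), rownames(values)[bad[1, 1]] %||% bad[1, 1],
        colnames(values)[bad[1, 2]] %||% bad[1, 2],
        values[bad[1, 1], bad[1, 2]]))
  } else {
    if (anyNA(values))
      stop(sprintf("NA values are only permitted for MET_BETA, not %s",
                   modality))
    if (modality %in% c("EXPR_FPKM", "EXPR_COUNT") && any(values < 0))
      stop(sprintf("%s values must be nonnegative", modality))
    if (modality == "EXPR_COUNT" && any(values != round(values)))
      stop("EXPR_COUNT values must be integers")
  }
  invisible(TRUE)
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix [%s]: %d genes x %d samples\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}

#' Modality tag of a gene matrix
#' @param x a `gene_matrix`.
#' @return character scalar.
#' @export
modality <- function(x) attr(x, "modality")

new_classed_df <- function(df, cls, skipped = NULL) {
  rownames(df) <- NULL
  structure(df, class = c(cls, "data.frame"),
            skipped = skipped %||% df[0, , drop = FALSE])
}

#' Construct / validate a CNV segment table
#'
#' @param df data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `value`. Coordinates are 1-based closed; `value` is a
#'   segment mean on a log2-ratio-like scale.
#' @return a `segment_table`.
#' @export
segment_table <- function(df) {
  need <- c("sample_id", "chrom", "start", "end", "n_probes", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment_table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$n_probes <- as.integer(df$n_probes)
  bad <- which(df$end < df$start)
  if (length(bad))
    stop(sprintf("segment end < start at row %d (%s:%d-%d)", bad[1],
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  if (any(df$n_probes < 0, na.rm = TRUE)) stop("negative n_probes")
  new_classed_df(df, "segment_table", attr(df, "skipped"))
}

#' Construct / validate a methylation probe manifest
#'
#' @param df data.frame with `probe_id`, `chrom`, `pos`, `region_class`
#'   (one of Island, N_Shore, S_Shore, N_Shelf, S_Shelf, OpenSea) and
#'   `gene_ids` (`;`-separated string, possibly empty).
#' @return a `probe_manifest`.
#' @export
probe_manifest <- function(df) {
  need <- c("probe_id", "chrom", "pos", "region_class", "gene_ids")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("probe_manifest missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids")
  bad <- setdiff(unique(df$region_class), REGION_CLASSES)
  if (length(bad)) stop("unknown region_class: ", paste(bad, collapse = ", "))
  df$pos <- as.integer(df$pos)
  new_classed_df(df, "probe_manifest")
}

#' Construct / validate a gene annotation table
#'
#' @param df data.frame with `gene_id`, `symbol`, `chrom`, `strand`
#'   (`+`/`-`), `gene_start`, `gene_end` (1-based closed), `gene_type`.
#'   The TSS is derived: `gene_start` on `+`, `gene_end` on `-`.
#' @return a `gene_annotation` with a computed `tss` column.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "symbol", "chrom", "strand", "gene_start",
            "gene_end", "gene_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene_annotation missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in annotation")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$gene_start <- as.integer(df$gene_start)
  df$gene_end <- as.integer(df$gene_end)
  if (any(df$gene_end < df$gene_start)) stop("gene_end < gene_start")
  df$tss <- ifelse(df$strand == "+", df$gene_start, df$gene_end)
  new_classed_df(df, "gene_annotation")
}

#' Construct / validate a mutation table
#'
#' @param df data.frame with `sample_id`, `gene_id`,
#'   `variant_classification`, `is_silent`, `is_intronic`.
#' @return a `mutation_table`.
#' @export
mutation_table <- function(df) {
  need <- c("sample_id", "gene_id", "variant_classification",
            "is_silent", "is_intronic")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutation_table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  stopifnot(is.logical(df$is_silent), is.logical(df$is_intronic))
  new_classed_df(df, "mutation_table")
}

#' Construct / validate a clinical table
#'
#' @param df data.frame with `sample_id`, `os_time`, `os_event`,
#'   `pfs_time`, `pfs_event`, `stage`, `grade`, `age`, `bmi`,
#'   `new_event_type`; extra columns (e.g. immune scores) pass through.
#' @return a `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "os_event", "pfs_time", "pfs_event",
            "stage", "grade", "age", "bmi", "new_event_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical_table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  for (ev in c("os_event", "pfs_event"))
    if (!all(df[[ev]] %in% c(0L, 1L))) stop(ev, " must be 0/1")
  for (tm in c("os_time", "pfs_time"))
    if (any(df[[tm]] < 0, na.rm = TRUE)) stop(tm, " must be nonnegative")
  if (!all(is.na(df$stage) | df$stage %in% c("I", "II", "III", "IV")))
    stop("stage outside vocabulary {I,II,III,IV,NA}")
  if (!all(is.na(df$grade) | df$grade %in% c("G1", "G2", "G3", "G4")))
    stop("grade outside vocabulary {G1..G4,NA}")
  new_classed_df(df, "clinical_table")
}

# ---- readers ------------------------------------------------------------

.seg_colmap <- c(sample_id = "sample", chrom = "chrom", start = "start",
                 end = "end", n_probes = "num_probes", value = "segment_mean")

match_header <- function(have, aliases) {
  hl <- tolower(gsub("[._ ]", "", have))
  idx <- match(tolower(gsub("[._ ]", "", aliases)), hl)
  idx[!is.na(idx)][1]
}

#' Read a SEG-like TSV of copy-number segments
#'
#' Accepts the common SEG header spellings (e.g. `Sample`/`ID`,
#' `Chromosome`, `Start`/`loc.start`, `End`/`loc.end`,
#' `Num_Probes`, `Segment_Mean`). Rows with unparseable coordinates raise
#' an error naming the line; rows violating `start <= end` likewise.
#'
#' @param path TSV file path.
#' @param dialect only `"seg_tsv"` is defined.
#' @return a [segment_table()].
#' @export
read_segments <- function(path, dialect = "seg_tsv") {
  if (!identical(dialect, "seg_tsv"))
    stop("unknown segment dialect: ", dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  aliases <- list(
    sample_id = c("sample", "id", "sample_id", "sampleid"),
    chrom = c("chrom", "chromosome", "chr"),
    start = c("start", "loc.start", "loc_start"),
    end = c("end", "loc.end", "loc_end"),
    n_probes = c("num_probes", "n_probes", "num.mark", "probes"),
    value = c("segment_mean", "seg.mean", "value", "seg_mean"))
  cols <- vapply(aliases, function(a) {
    i <- match_header(names(dt), a)
    if (is.na(i)) stop("SEG header missing a column for: ",
                       paste(a, collapse = "/"))
    names(dt)[i]
  }, character(1))
  out <- data.frame(sample_id = dt[[cols["sample_id"]]],
                    chrom = dt[[cols["chrom"]]],
                    stringsAsFactors = FALSE)
  for (f in c("start", "end", "n_probes", "value")) {
    v <- suppressWarnings(as.numeric(dt[[cols[f]]]))
    bad <- which(is.na(v) & !is.na(dt[[cols[f]]]) & dt[[cols[f]]] != "")
    if (length(bad))
      stop(sprintf("malformed %s at line %d of %s: '%s'", f, bad[1] + 1L,
                   path, dt[[cols[f]]][bad[1]]))
    out[[f]] <- v
  }
  segment_table(out)
}

#' Read a gene x sample TSV matrix
#'
#' First column = gene id, remaining columns = samples. Values are
#' validated against the declared modality (see [gene_matrix()]).
#'
#' @param path TSV file path.
#' @param modality one of the four modality tags.
#' @return a [gene_matrix()].
#' @export
read_gene_matrix <- function(path, modality) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  gene_matrix(m, modality)
}

#' Read a MAF-like mutation TSV
#'
#' Requires columns for the gene symbol (`Hugo_Symbol`), sample barcode
#' (`Tumor_Sample_Barcode`/`sample_id`) and `Variant_Classification`.
#' This reader only parses and annotates; filtering of silent/intronic
#' records happens in [filter_mutations()].
#'
#' @param path TSV file path.
#' @param silent_classes classifications mapped to `is_silent`
#'   (default `"Silent"`).
#' @param intron_classes classifications mapped to `is_intronic`
#'   (default `"Intron"`).
#' @return a [mutation_table()].
#' @export
read_maf <- function(path, silent_classes = "Silent",
                     intron_classes = "Intron") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  gi <- match_header(names(dt), c("hugo_symbol", "gene_id", "gene"))
  si <- match_header(names(dt), c("tumor_sample_barcode", "sample_id",
                                  "sample"))
  vi <- match_header(names(dt), "variant_classification")
  if (any(is.na(c(gi, si, vi))))
    stop("MAF missing a mandatory column (gene / sample / ",
         "Variant_Classification)")
  vc <- as.character(dt[[vi]])
  mutation_table(data.frame(
    sample_id = as.character(dt[[si]]),
    gene_id = as.character(dt[[gi]]),
    variant_classification = vc,
    is_silent = vc %in% silent_classes,
    is_intronic = vc %in% intron_classes,
    stringsAsFactors = FALSE))
}

#' Read a probe manifest TSV
#' @param path TSV with probe_id, chrom, pos, region_class, gene_ids.
#' @return a [probe_manifest()].
#' @export
read_probe_manifest <- function(path) {
  probe_manifest(as.data.frame(data.table::fread(path, sep = "\t",
                                                 na.strings = "NA")))
}

#' Read a gene annotation TSV
#' @param path TSV with gene_id, symbol, chrom, strand, gene_start,
#'   gene_end, gene_type.
#' @return a [gene_annotation()].
#' @export
read_annotation <- function(path) {
  gene_annotation(as.data.frame(data.table::fread(path, sep = "\t")))
}

#' Read a clinical TSV
#' @param path TSV with the [clinical_table()] columns.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  clinical_table(as.data.frame(data.table::fread(path, sep = "\t",
                                                 na.strings = "NA")))
}

#' Read a probe x sample beta matrix (NA tokens allowed)
#' @param path TSV, first column probe id.
#' @return numeric matrix (probes x samples), values in `[0,1]` or NA.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  m <- as.matrix(dt[, -1, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1]])
  if (any(!is.na(m) & (m < 0 | m > 1)))
    stop("beta values outside [0,1]")
  m
}

# ---- writers ------------------------------------------------------------

ow_write_one <- function(obj, path) {
  if (inherits(obj, "gene_matrix")) {
    dt <- data.table::data.table(gene_id = rownames(obj))
    dt <- cbind(dt, data.table::as.data.table(unclass(obj)))
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  } else if (is.matrix(obj)) {
    dt <- data.table::data.table(id = rownames(obj) %||%
                                   as.character(seq_len(nrow(obj))))
    dt <- cbind(dt, data.table::as.data.table(obj))
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  } else if (is.data.frame(obj)) {
    data.table::fwrite(as.data.frame(obj), path, sep = "\t", na = "NA",
                       quote = FALSE)
  } else if (is.list(obj)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else stop("don't know how to write object of class ",
              paste(class(obj), collapse = "/"))
  path
}

#' Write pipeline result objects to a directory
#'
#' Writes each named element of `objects` under a deterministic file name
#' (`<name>.tsv` for tables/matrices, `<name>.json` for plain lists).
#' Text round trips are exact at full double precision
#' (`fwrite` writes 15 significant digits).
#'
#' @param objects named list of tables / gene matrices / lists.
#' @param out_dir output directory (created if needed).
#' @param overwrite overwrite existing files? Default FALSE: an existing
#'   target file is a refusal error.
#' @return invisible character vector: the manifest of written paths.
#' @export
write_tables <- function(objects, out_dir, overwrite = FALSE) {
  stopifnot(is.list(objects), !is.null(names(objects)),
            all(nzchar(names(objects))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(objects), function(nm) {
    ext <- if (is.data.frame(objects[[nm]]) || is.matrix(objects[[nm]]))
      "tsv" else "json"
    file.path(out_dir, paste0(nm, ".", ext))
  }, character(1))
  clash <- paths[file.exists(paths)]
  if (length(clash) && !overwrite)
    stop("refusing to overwrite existing file(s): ",
         paste(basename(clash), collapse = ", "),
         " (use overwrite = TRUE)")
  for (i in seq_along(objects)) ow_write_one(objects[[i]], paths[i])
  invisible(paths)
}
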